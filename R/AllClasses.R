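#' @import methods
NULL

#' DWISeries: a multi-b-value diffusion-weighted series
#'
#' Container for one diffusion-weighted acquisition: one 3D magnitude volume
#' per b-value, together with the voxel spacing and the number of signal
#' averages acquired per b-value. All volumes must share a common grid.
#'
#' @slot volumes list of 3D numeric arrays, one per b-value, all the same
#'   dimension, intensities >= 0.
#' @slot bValues numeric vector of diffusion weightings in s/mm^2, strictly
#'   increasing, same length as \code{volumes}.
#' @slot averages numeric vector of signal averages per b-value (>= 1).
#' @slot spacing numeric length-3 voxel spacing in mm (x, y, z).
#' @slot modality either \code{"dwi"} or \code{"t2w"}.
#'
#' @seealso [simulateDWI()], [computeADCMap()]
#' @export
setClass("DWISeries",
  representation(
    volumes  = "list",
    bValues  = "numeric",
    averages = "numeric",
    spacing  = "numeric",
    modality = "character"
  ),
  prototype(modality = "dwi")
)

setValidity("DWISeries", function(object) {
  msg <- character()
  if (length(object@volumes) != length(object@bValues))
    msg <- c(msg, "one volume per b-value is required")
  if (length(object@bValues) && any(object@bValues < 0))
    msg <- c(msg, "b-values must be non-negative")
  if (length(object@bValues) > 1 && any(diff(object@bValues) <= 0))
    msg <- c(msg, "b-values must be strictly increasing")
  if (length(object@averages) != length(object@bValues))
    msg <- c(msg, "averages must have one entry per b-value")
  if (length(object@averages) && any(object@averages < 1))
    msg <- c(msg, "signal averages must be >= 1")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  if (!object@modality %in% c("dwi", "t2w"))
    msg <- c(msg, "modality must be 'dwi' or 't2w'")
  dims <- unique(lapply(object@volumes, dim))
  if (length(dims) > 1)
    msg <- c(msg, "all volumes must share the same dimensions")
  if (length(msg)) msg else TRUE
})

#' ADCMap: an apparent diffusion coefficient map
#'
#' Voxelwise ADC in micrometres^2/s (1 um^2/s = 1e-6 mm^2/s) together with a
#' validity mask marking voxels where the log-linear fit was performed, and
#' the b-values that entered the fit.
#'
#' @slot values 3D numeric array of ADC in um^2/s; finite on the valid mask.
#' @slot validMask 3D logical array, TRUE where the fit was performed.
#' @slot bUsed numeric vector of b-values used in the fit.
#' @slot spacing numeric length-3 voxel spacing in mm.
#'
#' @seealso [computeADCMap()]
#' @export
setClass("ADCMap",
  representation(
    values    = "array",
    validMask = "array",
    bUsed     = "numeric",
    spacing   = "numeric"
  )
)

setValidity("ADCMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@validMask)))
    msg <- c(msg, "values and validMask must share dimensions")
  if (!is.logical(object@validMask))
    msg <- c(msg, "validMask must be logical")
  if (any(!is.finite(object@values[object@validMask])))
    msg <- c(msg, "values must be finite on the valid mask")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' ROISet: labeled region-of-interest masks
#'
#' An integer label volume holding the 2D circular ROI masks used throughout
#' the analysis (default layout: 11 anatomical positions in 5 organ classes),
#' plus the label-to-name and label-to-organ maps. Circular masks have a
#' nominal in-plane area of 250 mm^2.
#'
#' @slot labels 3D integer array; 0 = background, labels 1..K are ROIs.
#' @slot labelNames character vector of anatomical position names, indexed by
#'   label.
#' @slot organOfLabel character vector mapping each label to an organ class.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @slot nominalAreaMm2 nominal in-plane mask area in mm^2.
#'
#' @seealso [makeROIMasks()], [roiStats()]
#' @export
setClass("ROISet",
  representation(
    labels         = "array",
    labelNames     = "character",
    organOfLabel   = "character",
    spacing        = "numeric",
    nominalAreaMm2 = "numeric"
  ),
  prototype(nominalAreaMm2 = 250)
)

setValidity("ROISet", function(object) {
  msg <- character()
  labs <- sort(unique(as.integer(object@labels[object@labels > 0])))
  if (length(object@labelNames) && length(labs) &&
      max(labs) > length(object@labelNames))
    msg <- c(msg, "labels present in the volume lack names")
  if (length(object@organOfLabel) != length(object@labelNames))
    msg <- c(msg, "organOfLabel must map every named label")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' @describeIn DWISeries number of b-values
#' @param x,object a \code{DWISeries}
#' @export
setMethod("length", "DWISeries", function(x) length(x@bValues))

#' b-values of an object
#'
#' @param x an object with b-value metadata
#' @return numeric vector of b-values in s/mm^2
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname bValues
#' @export
setMethod("bValues", "DWISeries", function(x) x@bValues)

#' @rdname bValues
#' @export
setMethod("bValues", "ADCMap", function(x) x@bUsed)

#' Voxel spacing in mm
#'
#' @param x an imaging object
#' @return numeric length-3 spacing (mm)
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "DWISeries", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ADCMap", function(x) x@spacing)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ROISet", function(x) x@spacing)

#' Intensity volumes of a DWI series
#'
#' @param x a \code{DWISeries}
#' @return list of 3D arrays, one per b-value
#' @export
setGeneric("seriesVolumes", function(x) standardGeneric("seriesVolumes"))

#' @rdname seriesVolumes
#' @export
setMethod("seriesVolumes", "DWISeries", function(x) x@volumes)

#' ADC values and validity mask
#'
#' @param x an \code{ADCMap}
#' @return \code{adcValues}: 3D array in um^2/s; \code{validMask}: 3D logical
#'   array.
#' @export
setGeneric("adcValues", function(x) standardGeneric("adcValues"))

#' @rdname adcValues
#' @export
setMethod("adcValues", "ADCMap", function(x) x@values)

#' @rdname adcValues
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname adcValues
#' @export
setMethod("validMask", "ADCMap", function(x) x@validMask)

#' ROI labels, names and organ classes
#'
#' @param x an \code{ROISet}
#' @return \code{roiLabels}: the integer label volume; \code{roiLabelNames}:
#'   anatomical position names; \code{organClasses}: organ class per label.
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname roiLabels
#' @export
setMethod("roiLabels", "ROISet", function(x) x@labels)

#' @rdname roiLabels
#' @export
setGeneric("roiLabelNames", function(x) standardGeneric("roiLabelNames"))

#' @rdname roiLabels
#' @export
setMethod("roiLabelNames", "ROISet", function(x) x@labelNames)

#' @rdname roiLabels
#' @export
setGeneric("organClasses", function(x) standardGeneric("organClasses"))

#' @rdname roiLabels
#' @export
setMethod("organClasses", "ROISet", function(x) x@organOfLabel)

setMethod("show", "DWISeries", function(object) {
  d <- if (length(object@volumes)) dim(object@volumes[[1]]) else c(0, 0, 0)
  cat(sprintf("DWISeries (%s): %d b-value(s) [%s] s/mm^2\n",
              object@modality, length(object@bValues),
              paste(object@bValues, collapse = ", ")))
  cat(sprintf("  grid %s, spacing %s mm\n",
              paste(d, collapse = " x "),
              paste(signif(object@spacing, 3), collapse = " x ")))
})

setMethod("show", "ADCMap", function(object) {
  v <- object@values[object@validMask]
  cat(sprintf("ADCMap: grid %s, b used [%s] s/mm^2\n",
              paste(dim(object@values), collapse = " x "),
              paste(object@bUsed, collapse = ", ")))
  if (length(v))
    cat(sprintf("  valid voxels: %d, median ADC %.0f um^2/s\n",
                length(v), stats::median(v)))
})

setMethod("show", "ROISet", function(object) {
  labs <- sort(unique(as.integer(object@labels[object@labels > 0])))
  cat(sprintf("ROISet: %d label(s), %d organ class(es), nominal area %g mm^2\n",
              length(labs), length(unique(object@organOfLabel)),
              object@nominalAreaMm2))
})
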