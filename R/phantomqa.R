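#' Temperature calibration curve for phantom ADC
#'
#' Linear-ratio model of the temperature dependence of the phantom
#' solution's ADC: \code{ratio(T) = 1 + alpha * (T - referenceTemp)}, so
#' \code{ratio(referenceTemp) = 1} and the curve is strictly increasing for
#' \code{alpha > 0}. The default slope 0.024 per degree C is a water-like
#' value; the slope is a configuration parameter to be replaced by the
#' phantom manufacturer's calibration.
#'
#' @param alpha fractional ADC change per degree C (> 0).
#' @param referenceTemp reference temperature, degrees C (default 20).
#' @param validRange temperatures at which the curve may be applied.
#' @return a list of class \code{"CalibrationCurve"} with a \code{ratio(T)}
#'   function.
#' @export
calibrationCurve <- function(alpha = 0.024, referenceTemp = 20,
                             validRange = c(15, 30)) {
  assertThat(alpha > 0, "alpha must be positive (strictly increasing curve)")
  structure(list(model = "linear_ratio", alpha = alpha,
                 referenceTemp = referenceTemp, validRange = validRange,
                 ratio = function(temp)
                   1 + alpha * (temp - referenceTemp)),
            class = "CalibrationCurve")
}

#' @rdname calibrationCurve
#' @param path a YAML file with keys \code{alpha}, \code{reference_temp},
#'   \code{valid_range}.
#' @export
readCalibrationCurve <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read calibration configs",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  calibrationCurve(alpha = cfg$alpha,
                   referenceTemp = cfg$reference_temp %||% 20,
                   validRange = unlist(cfg$valid_range %||% c(15, 30)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a phantom ADC to the reference temperature
#'
#' Three-step phantom QA uses the measured phantom temperature to transport
#' each site's ADC to a common standard temperature (20 degrees C):
#' \code{corrected = adc / ratio(measuredTemp)}. At the reference temperature
#' the correction is the identity; over the validity range the correction is
#' a bijection (correct of simulate-at-T recovers the 20 degree value for
#' any T).
#'
#' @param adcValue measured ADC in um^2/s (scalar or vector).
#' @param measuredTemp phantom temperature in degrees C.
#' @param curve a [calibrationCurve()].
#' @return the ADC at the reference temperature, um^2/s.
#' @export
temperatureCorrect <- function(adcValue, measuredTemp,
                               curve = calibrationCurve()) {
  assertThat(measuredTemp >= curve$validRange[1] &&
               measuredTemp <= curve$validRange[2],
             sprintf("temperature %.1f outside validity range [%g, %g]",
                     measuredTemp, curve$validRange[1], curve$validRange[2]))
  adcValue / curve$ratio(measuredTemp)
}

#' Automatically place a circular phantom ROI
#'
#' Places a circular ROI of fixed diameter (default 60 mm) on the central
#' slice of an ADC map, centered on the intensity centroid of that slice's
#' valid voxels, emulating an automatic fixed-size phantom ROI that avoids
#' edge and partial-volume voxels of a 200 mm sphere.
#'
#' @param adc an [ADCMap-class] of a centered phantom.
#' @param diameter ROI diameter in mm.
#' @return a logical 3D mask (TRUE inside the ROI, single slice).
#' @export
autoPhantomROI <- function(adc, diameter = 60) {
  dims <- dim(adc@values)
  k <- as.integer(ceiling(dims[3] / 2))
  slice <- adc@values[, , k]
  ok <- adc@validMask[, , k] & is.finite(slice) & slice > 0
  assertThat(any(ok), "empty valid mask on the central slice (QA failure)")
  w <- ifelse(ok, slice, 0)
  xs <- (seq_len(dims[1]) - 0.5) * adc@spacing[1]
  ys <- (seq_len(dims[2]) - 0.5) * adc@spacing[2]
  cx <- sum(outer(xs, rep(1, dims[2])) * w) / sum(w)
  cy <- sum(outer(rep(1, dims[1]), ys) * w) / sum(w)
  d2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
  # fixed size: the round(area / pixelArea) pixels nearest the centroid,
  # so the ROI area is identical across sites with equal spacing
  nPix <- round(pi * (diameter / 2)^2 / (adc@spacing[1] * adc@spacing[2]))
  sel <- order(d2)[seq_len(min(nPix, length(d2)))]
  mask <- array(FALSE, dims)
  slice <- mask[, , k]
  slice[sel] <- TRUE
  mask[, , k] <- slice
  mask
}

#' Cross-site dispersion statistics
#'
#' Summarizes per-site phantom ADC means: mean, sample standard deviation
#' (n - 1 denominator), coefficient of variation CoV = SD / mean, and the
#' maximum deviation (highest minus lowest site mean) as a percentage of the
#' cross-site mean. CoV and the maximum deviation are invariant under a
#' common rescaling of all site means.
#'
#' @param perSiteMeans numeric vector of per-site ADC means (um^2/s), length
#'   >= 2, all positive.
#' @return a list of class \code{"CrossSiteStats"}: \code{per_site_mean},
#'   \code{mean}, \code{sd}, \code{cov}, \code{max_deviation_pct}.
#' @examples
#' crossSiteStats(c(1600, 1632))
#' @export
crossSiteStats <- function(perSiteMeans) {
  assertThat(length(perSiteMeans) >= 2,
             "at least two sites are required (invalid argument)")
  assertThat(all(perSiteMeans > 0),
             "site means must be positive (invalid argument)")
  m <- mean(perSiteMeans)
  s <- stats::sd(perSiteMeans)
  structure(list(per_site_mean = perSiteMeans, mean = m, sd = s,
                 cov = s / m,
                 max_deviation_pct =
                   100 * (max(perSiteMeans) - min(perSiteMeans)) / m),
            class = "CrossSiteStats")
}

#' @export
print.CrossSiteStats <- function(x, ...) {
  cat(sprintf("Cross-site ADC: %.0f +/- %.0f um^2/s (CoV %.4f, max dev %.1f%%)\n",
              x$mean, x$sd, x$cov, x$max_deviation_pct))
  invisible(x)
}

#' Run phantom QA over a generated phantom study
#'
#' For each site: compute the central ADC map (b0 omitted), place the
#' automatic phantom ROI, take the ROI mean and within-ROI SD, and normalize
#' the mean to 20 degrees C via the calibration curve. Also records a
#' scanner-style mean computed with the site's own b-value set (including
#' b = 0 where the site's software required it).
#'
#' @param study a phantom study from [generateStudy()].
#' @param curve a [calibrationCurve()].
#' @param roiDiameter automatic ROI diameter, mm.
#' @return a list with \code{per_site} (data.frame: site, temperature, raw
#'   and corrected ROI means for central and scanner-style fits, within-ROI
#'   SDs) and \code{stats} (a list of [crossSiteStats()] results for
#'   raw/corrected x central/scanner).
#' @export
phantomQA <- function(study, curve = calibrationCurve(), roiDiameter = 60) {
  assertThat(identical(study$scenario, "phantom"),
             "phantomQA needs a phantom-scenario study")
  rows <- lapply(study$sites, function(s) {
    central <- computeADCMap(s$dwi, omitB0 = TRUE)
    scanner <- computeADCMap(s$dwi, omitB0 = FALSE)  # site's own b set
    roi <- autoPhantomROI(central, roiDiameter)
    inC <- roi & central@validMask
    inS <- roi & scanner@validMask
    data.frame(
      site_id = s$site_id, temperature = s$temperature,
      central_mean = mean(central@values[inC]),
      central_sd = stats::sd(central@values[inC]),
      scanner_mean = mean(scanner@values[inS]),
      scanner_sd = stats::sd(scanner@values[inS]),
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  per$central_corrected <- mapply(temperatureCorrect, per$central_mean,
                                  per$temperature,
                                  MoreArgs = list(curve = curve))
  per$scanner_corrected <- mapply(temperatureCorrect, per$scanner_mean,
                                  per$temperature,
                                  MoreArgs = list(curve = curve))
  list(per_site = per,
       stats = list(
         central_raw = crossSiteStats(per$central_mean),
         central_corrected = crossSiteStats(per$central_corrected),
         scanner_raw = crossSiteStats(per$scanner_mean),
         scanner_corrected = crossSiteStats(per$scanner_corrected)))
}
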