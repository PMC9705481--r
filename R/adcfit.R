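#' Compute an ADC map by log-linear least squares
#'
#' Central, vendor-independent apparent diffusion coefficient computation:
#' per voxel, the log signal ln S(b) is least-squares fitted to a linear
#' function of b by ordinary (unweighted) least squares; the negated slope is
#' the ADC, reported in um^2/s. By default the b = 0 s/mm^2 volume (if
#' present) is omitted from the fit, which removes the upward perfusion bias
#' of b0-inclusive fits in perfused tissue. Voxels with any non-positive
#' signal among the used b-values are excluded from the fit entirely (no
#' clamping) and marked FALSE in the validity mask; negative fitted slopes
#' (ADC < 0) are retained, not clipped.
#'
#' @param series a [DWISeries-class] with at least two usable b-values.
#' @param omitB0 drop the b = 0 volume before fitting (default TRUE).
#' @return an [ADCMap-class]; voxels outside the valid mask hold \code{NA}.
#' @examples
#' tm <- makePhantomTissueMap(dims = c(16, 16, 4), diameter = 30)
#' site <- data.frame(gain = 1, noise_sigma = 0, bias_amplitude = 0)
#' adc <- computeADCMap(simulateDWI(tm, site, seed = 1))
#' mean(adcValues(adc)[validMask(adc)])  # ~1600 um^2/s
#' @export
computeADCMap <- function(series, omitB0 = TRUE) {
  b <- series@bValues
  assertThat(all(b >= 0), "negative b-values are invalid")
  keep <- if (omitB0) b > 0 else rep(TRUE, length(b))
  assertThat(sum(keep) >= 2,
             "at least two usable b-values are required (invalid argument)")
  b <- b[keep]
  vols <- series@volumes[keep]
  dims <- dim(vols[[1]])
  V <- vapply(vols, as.numeric, numeric(prod(dims)))
  valid <- rowSums(V <= 0 | !is.finite(V)) == 0
  bc <- b - mean(b)
  denom <- sum(bc^2)
  slope <- rep(NA_real_, nrow(V))
  if (any(valid))
    slope[valid] <- (log(V[valid, , drop = FALSE]) %*% bc) / denom
  adc <- -slope * 1e6  # slope in mm^2/s -> um^2/s
  new("ADCMap", values = array(adc, dims),
      validMask = array(valid, dims), bUsed = b,
      spacing = series@spacing)
}

#' Compare inline (scanner) and central ADC maps over ROIs
#'
#' Paired per-ROI means of two co-registered ADC maps, e.g. the map a
#' scanner's inline reconstruction produced (possibly fitted with b = 0)
#' against the centrally computed map. The paired means feed a paired
#' Wilcoxon signed-rank comparison (see [pairedWilcoxon()]).
#'
#' @param inlineMap,centralMap two [ADCMap-class] objects on the same grid.
#' @param rois an [ROISet-class] aligned with the maps.
#' @return a \code{data.frame} with one row per ROI label: the paired means,
#'   their difference, the difference as a percentage of the central mean,
#'   and a \code{flagged} column marking ROIs empty on either valid mask.
#' @export
compareInlineVsCentral <- function(inlineMap, centralMap, rois) {
  assertThat(identical(dim(inlineMap@values), dim(centralMap@values)) &&
               identical(dim(inlineMap@values), dim(rois@labels)),
             "maps and ROIs must share one grid")
  labs <- sort(unique(as.integer(rois@labels[rois@labels > 0])))
  rows <- lapply(labs, function(l) {
    inRoi <- rois@labels == l
    vi <- inlineMap@values[inRoi & inlineMap@validMask]
    vc <- centralMap@values[inRoi & centralMap@validMask]
    flagged <- length(vi) == 0 || length(vc) == 0
    mi <- if (length(vi)) mean(vi) else NA_real_
    mc <- if (length(vc)) mean(vc) else NA_real_
    data.frame(roi_label = l,
               name = rois@labelNames[l],
               organ_class = unname(rois@organOfLabel[l]),
               mean_inline = mi, mean_central = mc,
               diff = mi - mc,
               pct_of_central = 100 * (mi - mc) / mc,
               flagged = flagged)
  })
  do.call(rbind, rows)
}
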