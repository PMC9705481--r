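#' Per-ROI summary statistics of a map
#'
#' Mean, SD and voxel count of a voxel map over each ROI label. Accepts an
#' [ADCMap-class] (only valid-mask voxels contribute), a \code{DWISeries}
#' (its first volume, e.g. a T2w gray-value volume) or a bare 3D array.
#' Labels that end up empty after masking are flagged rather than silently
#' dropped.
#'
#' @param map an \code{ADCMap}, \code{DWISeries} or 3D array.
#' @param rois an [ROISet-class] on the same grid.
#' @param site,timepoint optional identifiers copied into the output.
#' @return a \code{data.frame} with columns \code{site}, \code{timepoint},
#'   \code{roi_label}, \code{name}, \code{organ_class}, \code{mean},
#'   \code{sd}, \code{n_voxels}, \code{flagged}.
#' @export
roiStats <- function(map, rois, site = NA_character_,
                     timepoint = NA_character_) {
  if (is(map, "ADCMap")) {
    vals <- map@values; ok <- map@validMask
  } else if (is(map, "DWISeries")) {
    vals <- map@volumes[[1]]; ok <- array(TRUE, dim(vals))
  } else {
    vals <- map; ok <- array(TRUE, dim(vals))
  }
  assertThat(identical(dim(vals), dim(rois@labels)),
             "map and ROIs must share one grid")
  labs <- sort(unique(as.integer(rois@labels[rois@labels > 0])))
  rows <- lapply(labs, function(l) {
    v <- vals[rois@labels == l & ok]
    data.frame(site = site, timepoint = timepoint, roi_label = l,
               name = rois@labelNames[l],
               organ_class = unname(rois@organOfLabel[l]),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n_voxels = length(v),
               flagged = length(v) == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman analysis of paired ROI means
#'
#' Pairs test and retest ROI means by (site, roi_label) and reports the
#' per-pair relative difference in percent, using the pair mean as the
#' denominator (standard Bland-Altman percentage form):
#' \deqn{100 (m_2 - m_1) / ((m_1 + m_2)/2)}
#' plus the summary mean difference, SD of differences, and 95\% limits of
#' agreement (mean +/- 1.96 SD). A denominator based on the first
#' measurement is reported alongside (\code{rel_diff_vs_first_pct}).
#' Swapping test and retest negates the per-pair differences and the mean
#' while leaving the SD unchanged.
#'
#' @param test,retest \code{data.frame}s from [roiStats()] with matching
#'   (site, roi_label) keys.
#' @return a list of class \code{"BlandAltmanResult"}: \code{pairs}
#'   (data.frame with means, averages and relative differences),
#'   \code{mean_diff_pct}, \code{sd_diff_pct}, \code{loa} (length-2).
#' @export
blandAltman <- function(test, retest) {
  key <- function(d) paste(d$site, d$roi_label, sep = "\r")
  kt <- key(test); kr <- key(retest)
  bad <- union(setdiff(kt, kr), setdiff(kr, kt))
  if (length(bad))
    stop("unmatched (site, roi_label) pairs: ",
         paste(gsub("\r", ":", bad), collapse = ", "), call. = FALSE)
  retest <- retest[match(kt, kr), ]
  m1 <- test$mean; m2 <- retest$mean
  avg <- (m1 + m2) / 2
  rel <- 100 * (m2 - m1) / avg
  pairs <- data.frame(site = test$site, roi_label = test$roi_label,
                      organ_class = test$organ_class,
                      m1 = m1, m2 = m2, pair_mean = avg,
                      rel_diff_pct = rel,
                      rel_diff_vs_first_pct = 100 * (m2 - m1) / m1,
                      stringsAsFactors = FALSE)
  md <- mean(rel); sdd <- stats::sd(rel)
  structure(list(pairs = pairs, mean_diff_pct = md, sd_diff_pct = sdd,
                 loa = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd)),
            class = "BlandAltmanResult")
}

#' @export
print.BlandAltmanResult <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.2f%%, SD %.2f%%, LoA [%.2f, %.2f]%%, %d pairs\n",
              x$mean_diff_pct, x$sd_diff_pct, x$loa[1], x$loa[2],
              nrow(x$pairs)))
  invisible(x)
}

#' Traveling-volunteer cross-site deviations
#'
#' Per-(site, ROI) relative deviation of the ROI mean from the reference
#' site's mean, in percent: \code{100 (m_site - m_ref) / m_ref}. The
#' reference site's own rows are exactly zero, reproducing the convention of
#' anchoring the reference measurement at the origin.
#'
#' @param statsBySite a \code{data.frame} of [roiStats()] rows covering all
#'   sites (one row per site x ROI).
#' @param referenceSite site identifier of the reference site.
#' @return the input with an added \code{deviation_pct} column and a
#'   \code{ref_mean} column.
#' @export
travelingComparison <- function(statsBySite, referenceSite) {
  assertThat(referenceSite %in% statsBySite$site,
             "reference site absent from the table (invalid argument)")
  ref <- statsBySite[statsBySite$site == referenceSite, ]
  refMean <- ref$mean[match(statsBySite$roi_label, ref$roi_label)]
  statsBySite$ref_mean <- refMean
  statsBySite$deviation_pct <- 100 * (statsBySite$mean - refMean) / refMean
  statsBySite
}

#' Paired Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Two-sided paired signed-rank test. Zero differences are dropped
#' (Wilcoxon's original rule). For n <= 25 remaining pairs without ties in
#' the absolute differences, the p-value is computed from the exact null
#' distribution of the signed-rank statistic; otherwise a normal
#' approximation with tie correction is used. The significance flag is
#' evaluated at a Bonferroni-adjusted level (default 0.007).
#'
#' @param x,y paired measurement vectors of equal length.
#' @param alphaAdjusted significance level after multiplicity adjustment.
#' @return a list: \code{statistic} (V = sum of positive ranks),
#'   \code{p.value} (two-sided), \code{significant}, \code{n} (pairs used),
#'   \code{method}.
#' @examples
#' pairedWilcoxon(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))  # p = 0.0625
#' @export
pairedWilcoxon <- function(x, y, alphaAdjusted = 0.007) {
  assertThat(length(x) == length(y), "x and y must be paired")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, significant = FALSE, n = 0,
                method = "degenerate"))
  }
  assertThat(n >= 5, "need at least 5 non-zero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p <- 2 * min(stats::psignrank(V, n),
                 stats::psignrank(V - 1, n, lower.tail = FALSE))
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tieTab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tieTab^3 - tieTab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = V, p.value = p, significant = p < alphaAdjusted,
       n = n, method = method)
}
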