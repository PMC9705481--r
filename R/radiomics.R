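#' Resample a volume to isotropic spacing
#'
#' Resamples an image volume onto an isotropic grid (default 1 x 1 x 1 mm)
#' with trilinear interpolation, or nearest-neighbor when \code{isMask} is
#' TRUE (label and binary volumes stay label/binary). The output grid is
#' center-aligned with the input and preserves the physical extent to within
#' one voxel.
#'
#' @param volume a 3D array, or a [DWISeries-class] / [ADCMap-class] /
#'   [ROISet-class] (resampled slot-wise; masks and labels use
#'   nearest-neighbor).
#' @param spacing input voxel spacing in mm (taken from the object when the
#'   input is a class).
#' @param targetSpacing output spacing in mm, default \code{c(1, 1, 1)}.
#' @param isMask use nearest-neighbor interpolation (arrays only).
#' @return the resampled object of the same type; arrays gain a
#'   \code{"spacing"} attribute.
#' @export
resampleIsotropic <- function(volume, spacing = NULL,
                              targetSpacing = c(1, 1, 1), isMask = FALSE) {
  if (is(volume, "DWISeries")) {
    vols <- lapply(volume@volumes, resampleArray, spacing = volume@spacing,
                   target = targetSpacing, nearest = FALSE)
    return(new("DWISeries", volumes = vols, bValues = volume@bValues,
               averages = volume@averages, spacing = as.numeric(targetSpacing),
               modality = volume@modality))
  }
  if (is(volume, "ADCMap")) {
    v <- volume@values
    v[!volume@validMask] <- 0
    vals <- resampleArray(v, volume@spacing, targetSpacing, nearest = FALSE)
    msk <- resampleArray(volume@validMask + 0, volume@spacing, targetSpacing,
                         nearest = TRUE) > 0
    vals[!msk] <- NA_real_
    return(new("ADCMap", values = vals, validMask = msk,
               bUsed = volume@bUsed, spacing = as.numeric(targetSpacing)))
  }
  if (is(volume, "ROISet")) {
    lab <- resampleArray(volume@labels + 0, volume@spacing, targetSpacing,
                         nearest = TRUE)
    return(new("ROISet", labels = array(as.integer(lab), dim(lab)),
               labelNames = volume@labelNames,
               organOfLabel = volume@organOfLabel,
               spacing = as.numeric(targetSpacing),
               nominalAreaMm2 = volume@nominalAreaMm2))
  }
  assertThat(!is.null(spacing) && length(spacing) == 3 && all(spacing > 0),
             "positive voxel spacing metadata is required (metadata error)")
  resampleArray(volume, spacing, targetSpacing, nearest = isMask)
}

# Separable center-aligned grid resampling: successive 1D interpolation
# along each axis (trilinear overall), or nearest-neighbor lookup.
resampleArray <- function(a, spacing, target, nearest = FALSE) {
  dims <- dim(a)
  outDims <- pmax(1L, as.integer(round(dims * spacing / target)))
  for (ax in 1:3) {
    ci <- ((seq_len(outDims[ax]) - 0.5) * target[ax]) / spacing[ax] + 0.5
    ci <- pmin(pmax(ci, 1), dims[ax])
    a <- if (ax == 1) interpAxis1(a, ci, nearest)
         else aperm(interpAxis1(aperm(a, switch(ax, NULL, c(2, 1, 3),
                                                c(3, 2, 1))), ci, nearest),
                    switch(ax, NULL, c(2, 1, 3), c(3, 2, 1)))
  }
  attr(a, "spacing") <- as.numeric(target)
  a
}

interpAxis1 <- function(a, ci, nearest) {
  n <- dim(a)[1]
  if (nearest) {
    idx <- pmin(pmax(round(ci), 1), n)
    return(a[idx, , , drop = FALSE])
  }
  i0 <- pmin(pmax(floor(ci), 1), n)
  i1 <- pmin(i0 + 1, n)
  f <- ci - i0
  a[i0, , , drop = FALSE] * (1 - f) + a[i1, , , drop = FALSE] * f
}

#' Landmark-based histogram matching
#'
#' Maps the intensity distribution of a source volume onto a reference
#' volume: foreground voxels (above the volume mean) of each volume are
#' summarized by a fixed-level histogram (default 128 levels); evenly spaced
#' quantile landmarks (default 10) are read off each histogram's CDF, and a
#' monotone piecewise-linear transfer function mapping source landmarks to
#' reference landmarks is applied to all voxels. The transfer is invariant
#' (within one histogram level) to affine intensity distortions of the
#' source, which is what removes vendor gain and offset differences.
#'
#' @param source,reference 3D arrays (or single-volume \code{DWISeries}),
#'   both with positive intensity range.
#' @param matchPoints number of quantile landmarks (default 10).
#' @param levels number of histogram levels (default 128).
#' @return the transformed source (same type as the input).
#' @export
histogramMatch <- function(source, reference, matchPoints = 10,
                           levels = 128) {
  wrap <- NULL
  if (is(source, "DWISeries")) { wrap <- source; source <- source@volumes[[1]] }
  if (is(reference, "DWISeries")) reference <- reference@volumes[[1]]
  assertThat(diff(range(source)) > 0 && diff(range(reference)) > 0,
             "constant volume: histogram matching is degenerate")
  probs <- seq(0, 1, length.out = matchPoints)
  srcL <- histLandmarks(source[source > mean(source)], levels, probs)
  refL <- histLandmarks(reference[reference > mean(reference)], levels, probs)
  # enforce strictly increasing source knots, monotone reference values
  keep <- c(TRUE, diff(srcL) > 0)
  srcL <- srcL[keep]
  refL <- cummax(refL[keep])
  out <- array(piecewiseLinear(as.numeric(source), srcL, refL),
               dim(source))
  if (!is.null(wrap)) {
    wrap@volumes[[1]] <- out
    return(wrap)
  }
  out
}

# Monotone piecewise-linear transfer through (xk, yk) knots; beyond the
# outer knots the end segments are extended linearly (an affine source
# distortion therefore stays corrected in the tails).
piecewiseLinear <- function(x, xk, yk) {
  n <- length(xk)
  if (n == 1) return(rep(yk, length(x)))
  y <- stats::approx(xk, yk, xout = x, rule = 2)$y
  sl1 <- (yk[2] - yk[1]) / (xk[2] - xk[1])
  sln <- (yk[n] - yk[n - 1]) / (xk[n] - xk[n - 1])
  lo <- x < xk[1]; hi <- x > xk[n]
  y[lo] <- yk[1] + (x[lo] - xk[1]) * sl1
  y[hi] <- yk[n] + (x[hi] - xk[n]) * sln
  y
}

# Quantile landmarks of a sample read off a fixed-level histogram CDF.
histLandmarks <- function(v, levels, probs) {
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant foreground: histogram matching is degenerate",
         call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = levels + 1)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1),
              levels)
  cdf <- cumsum(tabulate(bin, levels)) / length(v)
  stats::approx(c(0, cdf), edges, xout = probs, ties = "ordered",
                rule = 2)$y
}

#' Feature extraction configuration
#'
#' @param binCount fixed bin count for intensity discretization of the
#'   entropy/uniformity and co-occurrence features (default 32).
#' @param minVoxels smallest ROI (voxels) for which a row is produced.
#' @param glcm also compute gray-level co-occurrence features.
#' @return a configuration list.
#' @export
featureConfig <- function(binCount = 32, minVoxels = 10, glcm = TRUE) {
  list(binCount = binCount, minVoxels = minVoxels, glcm = glcm)
}

#' Extract first-order and co-occurrence features per ROI
#'
#' Built-in radiomics extractor: for every ROI label it computes 18
#' first-order features (mean, median, SD, variance, skewness, kurtosis,
#' min, max, range, 10th/90th percentiles, interquartile range, energy,
#' root-mean-square, mean absolute deviation, robust MAD, entropy,
#' uniformity; population-variance convention, undefined moments of constant
#' ROIs set to 0) and 8 gray-level co-occurrence features (contrast,
#' dissimilarity, homogeneity, angular second moment, joint entropy,
#' correlation, cluster shade, cluster prominence) on a fixed-bin-count
#' discretization with distance-1 offsets averaged over the 13 unique 3D
#' directions. ROIs smaller than \code{minVoxels} are skipped with a
#' message. External extractors can substitute any table with the same key
#' columns (site, timepoint, roi_label, organ_class).
#'
#' @param volume a 3D array, [ADCMap-class] (valid voxels only) or
#'   single-volume \code{DWISeries}.
#' @param rois an [ROISet-class] on the same grid.
#' @param site,timepoint identifiers copied into the key columns.
#' @param config see [featureConfig()].
#' @return a feature table \code{data.frame}: key columns plus 26 feature
#'   columns; extractor id and parameters are attached as the
#'   \code{"provenance"} attribute.
#' @export
extractFeatures <- function(volume, rois, site = NA_character_,
                            timepoint = NA_character_,
                            config = featureConfig()) {
  if (is(volume, "ADCMap")) {
    vals <- volume@values; ok <- volume@validMask
  } else if (is(volume, "DWISeries")) {
    vals <- volume@volumes[[1]]; ok <- array(TRUE, dim(vals))
  } else {
    vals <- volume; ok <- array(TRUE, dim(vals))
  }
  assertThat(identical(dim(vals), dim(rois@labels)),
             "volume and ROI masks must share one grid")
  labs <- sort(unique(as.integer(rois@labels[rois@labels > 0])))
  rows <- list()
  for (l in labs) {
    m <- rois@labels == l & ok
    v <- vals[m]
    if (length(v) < config$minVoxels) {
      message(sprintf("ROI %d (%s): %d voxels < %d, skipped",
                      l, rois@labelNames[l], length(v), config$minVoxels))
      next
    }
    fo <- firstOrderFeatures(v, config$binCount)
    feats <- if (config$glcm)
      c(fo, glcmFeatures(vals, m, config$binCount)) else fo
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(site = site, timepoint = timepoint, roi_label = l,
                       name = rois@labelNames[l],
                       organ_class = unname(rois@organOfLabel[l]),
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(feats)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- list(extractor = "mcDWI-builtin",
                                  bin_count = config$binCount,
                                  min_voxels = config$minVoxels)
  out
}

#' @rdname extractFeatures
#' @param v numeric vector of ROI voxel intensities.
#' @param binCount fixed bin count for entropy/uniformity.
#' @export
firstOrderFeatures <- function(v, binCount = 32) {
  n <- length(v)
  mu <- mean(v)
  varp <- mean((v - mu)^2)  # population convention
  sdp <- sqrt(varp)
  q <- stats::quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  w <- v[v >= q[1] & v <= q[4]]
  p <- binProbs(v, binCount)
  c(fo_mean = mu,
    fo_median = stats::median(v),
    fo_sd = sdp,
    fo_variance = varp,
    fo_skewness = if (sdp > 0) mean((v - mu)^3) / sdp^3 else 0,
    fo_kurtosis = if (sdp > 0) mean((v - mu)^4) / sdp^4 else 0,
    fo_min = min(v),
    fo_max = max(v),
    fo_range = max(v) - min(v),
    fo_p10 = q[1],
    fo_p90 = q[4],
    fo_iqr = q[3] - q[2],
    fo_energy = sum(v^2),
    fo_rms = sqrt(mean(v^2)),
    fo_mad = mean(abs(v - mu)),
    fo_rmad = mean(abs(w - mean(w))),
    fo_entropy = -sum(p[p > 0] * log2(p[p > 0])),
    fo_uniformity = sum(p^2))
}

binProbs <- function(v, binCount) {
  rng <- range(v)
  if (diff(rng) == 0) return(c(1, rep(0, binCount - 1)))
  edges <- seq(rng[1], rng[2], length.out = binCount + 1)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1),
              binCount)
  tabulate(bin, binCount) / length(v)
}

# The 13 unique distance-1 3D direction offsets (negatives are covered by
# the symmetric co-occurrence accumulation).
glcmOffsets <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

#' @rdname extractFeatures
#' @param vals full 3D intensity array.
#' @param mask logical 3D array selecting the ROI.
#' @export
glcmFeatures <- function(vals, mask, binCount = 32) {
  # crop to the ROI bounding box: co-occurrence pairs never leave it
  bb <- lapply(1:3, function(ax) {
    r <- range(which(apply(mask, ax, any)))
    seq.int(r[1], r[2])
  })
  vals <- vals[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  mask <- mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
  v <- vals[mask]
  rng <- range(v)
  codes <- array(NA_integer_, dim(vals))
  codes[mask] <- if (diff(rng) == 0) 1L else {
    edges <- seq(rng[1], rng[2], length.out = binCount + 1)
    pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
         binCount)
  }
  dims <- dim(vals)
  feats <- matrix(NA_real_, 0, 8)
  offsets <- glcmOffsets()
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    if (any(dims - abs(off) < 1)) next  # offset exceeds the bounding box
    idx <- lapply(1:3, function(ax) {
      if (off[ax] >= 0) seq_len(dims[ax] - off[ax])
      else seq.int(1 - off[ax], dims[ax])
    })
    a <- codes[idx[[1]], idx[[2]], idx[[3]]]
    b <- codes[idx[[1]] + off[1], idx[[2]] + off[2], idx[[3]] + off[3]]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    cnt <- tabulate((a[keep] - 1L) * binCount + b[keep],
                    binCount * binCount)
    P <- matrix(cnt, binCount, binCount, byrow = TRUE)
    P <- P + t(P)  # symmetric accumulation
    feats <- rbind(feats, glcmStats(P / sum(P)))
  }
  out <- colMeans(feats)
  names(out) <- c("glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity",
                  "glcm_asm", "glcm_joint_entropy", "glcm_correlation",
                  "glcm_cluster_shade", "glcm_cluster_prominence")
  out
}

glcmStats <- function(P) {
  nb <- nrow(P)
  i <- row(P); j <- col(P)
  mui <- sum(i * P); muj <- sum(j * P)
  sdi <- sqrt(sum((i - mui)^2 * P)); sdj <- sqrt(sum((j - muj)^2 * P))
  pe <- P[P > 0]
  corr <- if (sdi * sdj > 0) sum((i - mui) * (j - muj) * P) / (sdi * sdj)
          else 1  # degenerate (constant ROI): perfectly correlated
  c(contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    homogeneity = sum(P / (1 + (i - j)^2)),
    asm = sum(P^2),
    joint_entropy = -sum(pe * log2(pe)),
    correlation = corr,
    cluster_shade = sum((i + j - mui - muj)^3 * P),
    cluster_prominence = sum((i + j - mui - muj)^4 * P))
}

#' Cross-site stability filtering of features
#'
#' First selection stage: for each feature, the per-site vectors of feature
#' values indexed by anatomical position (the ROI labels) are correlated
#' between every unordered pair of sites; the stability score is the mean
#' absolute Pearson correlation over site pairs. Features scoring below the
#' threshold are disregarded (the threshold itself survives). A feature with
#' zero variance across ROIs at some site contributes 0 for that site's
#' pairs (with a message). Because Pearson correlation is invariant under
#' per-site affine rescaling, the score tolerates vendor gain differences by
#' design.
#'
#' @param tables either a list of per-site feature tables or one table with
#'   a \code{site} column; each site must cover the same \code{roi_label}s.
#' @param threshold minimum stability score (default 0.75).
#' @return a list: \code{scores} (named numeric, in [0, 1]),
#'   \code{survivors} (feature names with score >= threshold).
#' @export
stabilityFilter <- function(tables, threshold = 0.75) {
  if (is.data.frame(tables)) tables <- split(tables, tables$site)
  assertThat(length(tables) >= 2, "need at least two sites")
  featCols <- featureColumns(tables[[1]])
  labs <- sort(tables[[1]]$roi_label)
  mats <- lapply(tables, function(t) {
    assertThat(setequal(t$roi_label, labs),
               "all sites must cover the same ROI labels")
    as.matrix(t[match(labs, t$roi_label), featCols, drop = FALSE])
  })
  nS <- length(mats)
  pairs <- utils::combn(nS, 2)
  scores <- vapply(featCols, function(f) {
    rs <- apply(pairs, 2, function(p) {
      x <- mats[[p[1]]][, f]; y <- mats[[p[2]]][, f]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        message(sprintf("feature %s: zero variance at a site; |r| set to 0", f))
        0
      } else abs(stats::cor(x, y))
    })
    mean(rs)
  }, numeric(1))
  list(scores = scores,
       survivors = featCols[scores >= threshold],
       threshold = threshold)
}

featureColumns <- function(table) {
  keys <- c("site", "timepoint", "roi_label", "name", "organ_class")
  setdiff(names(table), keys)
}

#' ANOVA F-value feature ranking
#'
#' Second selection stage: one-way ANOVA F statistic of each surviving
#' feature grouped by organ class; the top \code{nSelect} features by F are
#' selected (ties broken lexicographically by feature name). A feature that
#' is constant everywhere gets F = 0. When fewer features survive than
#' requested, all survivors are selected with a warning.
#'
#' @param table a feature table (rows = ROIs, with \code{organ_class}).
#' @param survivors feature names to rank (e.g. from [stabilityFilter()]).
#' @param nSelect number of features to select (default 15).
#' @return a list: \code{f_score} (named, over survivors), \code{selected}
#'   (ordered feature names).
#' @export
anovaSelect <- function(table, survivors = featureColumns(table),
                        nSelect = 15) {
  g <- factor(table$organ_class)
  assertThat(nlevels(g) >= 2, "need at least two organ classes")
  assertThat(min(table(g)) >= 2,
             sprintf("organ class with < 2 samples: %s",
                     paste(names(which(table(g) < 2)), collapse = ", ")))
  f <- vapply(survivors, function(feat) {
    v <- table[[feat]]
    if (stats::var(v) == 0) return(0)
    stats::anova(stats::lm(v ~ g))[["F value"]][1]
  }, numeric(1))
  if (length(survivors) < nSelect)
    warning(sprintf("only %d features survive; selecting all of them",
                    length(survivors)))
  ord <- order(-f, survivors)
  list(f_score = f,
       selected = survivors[ord][seq_len(min(nSelect, length(survivors)))])
}

#' Two-stage feature selection
#'
#' Chains [stabilityFilter()] (cross-site stability, threshold 0.75) and
#' [anovaSelect()] (organ-class ANOVA F ranking, N = 15) into the selection
#' result.
#'
#' @param tables per-site feature tables (list or one table with
#'   \code{site}).
#' @param threshold stability threshold.
#' @param nSelect number of features to keep.
#' @return a list of class \code{"SelectionResult"}: \code{stability_score},
#'   \code{survivors}, \code{f_score}, \code{selected}.
#' @export
selectFeatures <- function(tables, threshold = 0.75, nSelect = 15) {
  stab <- stabilityFilter(tables, threshold)
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  sel <- anovaSelect(tab, stab$survivors, nSelect)
  structure(list(stability_score = stab$scores,
                 survivors = stab$survivors,
                 f_score = sel$f_score,
                 selected = sel$selected),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("Feature selection: %d/%d stable, %d selected\n",
              length(x$survivors), length(x$stability_score),
              length(x$selected)))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
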