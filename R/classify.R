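#' Build feature tables from a generated study
#'
#' Harmonization preprocessing plus feature extraction for every site (and
#' timepoint) of a traveling-volunteer or test-retest study:
#' \enumerate{
#'   \item compute the central ADC map (b >= 100 fit) or take the T2w
#'     gray-value volume,
#'   \item resample volume and ROI masks to isotropic 1 mm,
#'   \item for T2w, histogram-match every site to the reference site
#'     (10 match points, 128 levels); the ADC stream skips matching by
#'     default since ADC is already a quantitative scale,
#'   \item extract the built-in feature set per ROI.
#' }
#'
#' @param study output of [generateStudy()] (scenarios
#'   \code{traveling_volunteer} or \code{test_retest}).
#' @param modality \code{"adc"} or \code{"t2w"}.
#' @param match apply histogram matching (default: only for T2w).
#' @param resample resample to isotropic 1 mm first (default TRUE).
#' @param config see [featureConfig()].
#' @return one feature table (data.frame) with key columns site, timepoint,
#'   roi_label, name, organ_class.
#' @export
studyFeatures <- function(study, modality = c("adc", "t2w"),
                          match = identical(modality, "t2w"),
                          resample = TRUE, config = featureConfig()) {
  modality <- match.arg(modality)
  assertThat(study$scenario %in% c("traveling_volunteer", "test_retest"),
             "studyFeatures needs a volunteer-style study")
  refId <- study$manifest$site_id[study$manifest$is_reference]

  prep <- function(entry) {
    vol <- if (modality == "adc") computeADCMap(entry$dwi, omitB0 = TRUE)
           else entry$t2w
    rois <- entry$rois
    if (resample) {
      vol <- resampleIsotropic(vol)
      rois <- resampleIsotropic(rois)
    }
    list(vol = vol, rois = rois)
  }
  getEntries <- function() {
    if (study$scenario == "traveling_volunteer") {
      lapply(study$sites, function(s)
        list(t1 = list(site = s$site_id, entry = s)))
    } else {
      lapply(study$sites, function(s)
        lapply(s$timepoints, function(tp)
          list(site = s$site_id, entry = tp)))
    }
  }
  entries <- getEntries()
  prepped <- lapply(entries, function(tps) lapply(tps, function(e)
    c(e["site"], prep(e$entry))))
  if (match && modality == "t2w") {
    refVol <- prepped[[refId]][[1]]$vol
    prepped <- lapply(prepped, function(tps) lapply(tps, function(p) {
      p$vol <- histogramMatch(p$vol, refVol)
      p
    }))
  }
  tabs <- list()
  for (sid in names(prepped))
    for (tp in names(prepped[[sid]])) {
      p <- prepped[[sid]][[tp]]
      tabs[[paste(sid, tp)]] <-
        extractFeatures(p$vol, p$rois, site = p$site, timepoint = tp,
                        config = config)
    }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

# Fit a seeded random forest (1000 trees, depth 10) and return per-row
# class probabilities for newdata.
rfFit <- function(train, selected, trees, maxDepth, seed) {
  df <- train[, c("organ_class", selected)]
  df$organ_class <- factor(df$organ_class)
  ranger::ranger(dependent.variable.name = "organ_class", data = df,
                 num.trees = trees, max.depth = maxDepth,
                 probability = TRUE, seed = seed, num.threads = 1)
}

rfPredict <- function(fit, test, selected) {
  stats::predict(fit, data = test[, selected, drop = FALSE],
                 num.threads = 1)$predictions
}

#' Leave-one-site-out cross-validated organ classification
#'
#' For every site, a random forest (default 1000 trees, maximum depth 10) is
#' trained on all other sites' rows and predicts the held-out site's organ
#' classes; the per-site accuracy is the fraction of that site's ROIs
#' classified correctly. The procedure is repeated \code{nRuns} times with
#' distinct sub-seeds (or a shared seed when \code{perRunSeeds = FALSE}, in
#' which case the run-to-run SD is exactly 0).
#'
#' @param features a feature table with \code{site} and \code{organ_class}.
#' @param selected feature column names to use.
#' @param nRuns repeated runs (default 10).
#' @param seed master seed.
#' @param trees,maxDepth forest size and depth.
#' @param perRunSeeds give each run its own sub-seed (default TRUE).
#' @return a list of class \code{"ClassificationReport"}: \code{per_site}
#'   (site, mean and SD of accuracy over runs), \code{overall_accuracy},
#'   \code{accuracy} (site x run matrix), \code{probabilities} (long
#'   data.frame of per-row class probabilities for ROC analysis),
#'   \code{config}.
#' @export
losoCV <- function(features, selected, nRuns = 10, seed = 1,
                   trees = 1000, maxDepth = 10, perRunSeeds = TRUE) {
  sites <- unique(features$site)
  assertThat(length(sites) >= 3, "need at least 3 sites")
  classes <- sort(unique(features$organ_class))
  for (s in sites) {
    missing <- setdiff(classes,
                       unique(features$organ_class[features$site != s]))
    assertThat(length(missing) == 0,
               sprintf("class '%s' missing from the training fold for site %s",
                       paste(missing, collapse = ","), s))
  }
  acc <- matrix(NA_real_, length(sites), nRuns,
                dimnames = list(sites, NULL))
  probs <- list()
  for (r in seq_len(nRuns)) {
    rs <- if (perRunSeeds) subSeed(seed, r) else subSeed(seed, 1L)
    for (s in sites) {
      train <- features[features$site != s, ]
      test <- features[features$site == s, ]
      fit <- rfFit(train, selected, trees, maxDepth, rs)
      pm <- rfPredict(fit, test, selected)
      pred <- colnames(pm)[max.col(pm, ties.method = "first")]
      acc[s, r] <- mean(pred == test$organ_class)
      probs[[length(probs) + 1L]] <-
        cbind(data.frame(run = r, site = s, truth = test$organ_class,
                         stringsAsFactors = FALSE),
              as.data.frame(pm))
    }
  }
  perSite <- data.frame(site = sites,
                        mean_accuracy = rowMeans(acc),
                        sd_accuracy = apply(acc, 1, stats::sd),
                        stringsAsFactors = FALSE)
  structure(list(per_site = perSite,
                 overall_accuracy = mean(acc),
                 accuracy = acc,
                 probabilities = do.call(rbind, probs),
                 config = list(trees = trees, max_depth = maxDepth,
                               n_runs = nRuns, seed = seed,
                               per_run_seeds = perRunSeeds)),
            class = "ClassificationReport")
}

#' Test-retest organ classification
#'
#' Trains on all sites' time-1 rows and predicts the organ class of every
#' time-2 row; repeated over \code{nRuns} seeded runs (default 5) with mean
#' and SD of the overall accuracy reported.
#'
#' @param featuresT1,featuresT2 feature tables for the two timepoints with
#'   matching (site, roi_label) keys.
#' @inheritParams losoCV
#' @return a \code{"ClassificationReport"} with \code{accuracy} a length-
#'   \code{nRuns} vector, \code{mean_accuracy} and \code{sd_accuracy}.
#' @export
testRetestCV <- function(featuresT1, featuresT2, selected, nRuns = 5,
                         seed = 1, trees = 1000, maxDepth = 10,
                         perRunSeeds = TRUE) {
  k1 <- paste(featuresT1$site, featuresT1$roi_label)
  k2 <- paste(featuresT2$site, featuresT2$roi_label)
  assertThat(setequal(k1, k2),
             "timepoints do not share (site, roi_label) keys (pairing error)")
  accs <- numeric(nRuns)
  for (r in seq_len(nRuns)) {
    rs <- if (perRunSeeds) subSeed(seed, r) else subSeed(seed, 1L)
    fit <- rfFit(featuresT1, selected, trees, maxDepth, rs)
    pm <- rfPredict(fit, featuresT2, selected)
    pred <- colnames(pm)[max.col(pm, ties.method = "first")]
    accs[r] <- mean(pred == featuresT2$organ_class)
  }
  structure(list(accuracy = accs, mean_accuracy = mean(accs),
                 sd_accuracy = stats::sd(accs),
                 config = list(trees = trees, max_depth = maxDepth,
                               n_runs = nRuns, seed = seed,
                               per_run_seeds = perRunSeeds)),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  if (!is.null(x$per_site)) {
    cat(sprintf("LOSO classification (%d runs): overall accuracy %.3f\n",
                x$config$n_runs, x$overall_accuracy))
    for (i in seq_len(nrow(x$per_site)))
      cat(sprintf("  site %s: %.2f (%.3g)\n", x$per_site$site[i],
                  x$per_site$mean_accuracy[i], x$per_site$sd_accuracy[i]))
  } else {
    cat(sprintf("Test-retest classification (%d runs): %.3f (%.3g)\n",
                x$config$n_runs, x$mean_accuracy, x$sd_accuracy))
  }
  invisible(x)
}

#' Macro-averaged one-vs-rest ROC curves and AUC
#'
#' For each group (e.g. run x site) and each class, a one-vs-rest ROC curve
#' is computed from the class probability scores, interpolated onto a common
#' grid of 101 false-positive-rate points, and macro-averaged; the AUC is
#' reported as mean +/- SD over all (group, class) combinations. Groups
#' containing a single class are skipped with a message.
#'
#' @param probabilities long data.frame as produced by [losoCV()]
#'   (\code{$probabilities}): grouping columns, a \code{truth} column, and
#'   one probability column per class.
#' @param groupBy names of grouping columns (default \code{c("run",
#'   "site")}).
#' @return a list: \code{mean_auc}, \code{sd_auc}, \code{auc}
#'   (per group x class), \code{mean_curve} (data.frame fpr/tpr),
#'   \code{fpr_grid}.
#' @export
rocAUC <- function(probabilities, groupBy = c("run", "site")) {
  classes <- setdiff(names(probabilities), c(groupBy, "truth"))
  grid <- seq(0, 1, length.out = 101)
  key <- interaction(probabilities[groupBy], drop = TRUE)
  aucs <- numeric(0)
  curves <- matrix(NA_real_, 0, length(grid))
  for (g in levels(key)) {
    sub <- probabilities[key == g, ]
    for (cl in classes) {
      pos <- sub$truth == cl
      if (!any(pos) || all(pos)) {
        message(sprintf("group %s: class %s one-sided, skipped", g, cl))
        next
      }
      r <- pROC::roc(response = pos, predictor = sub[[cl]],
                     levels = c(FALSE, TRUE), direction = "<",
                     quiet = TRUE)
      aucs <- c(aucs, as.numeric(pROC::auc(r)))
      fpr <- 1 - r$specificities
      tpr <- r$sensitivities
      ord <- order(fpr, tpr)
      y <- stats::approx(c(0, fpr[ord], 1), c(0, tpr[ord], 1),
                         xout = grid, ties = max)$y
      y[1] <- 0  # curves are anchored at the origin
      curves <- rbind(curves, y)
    }
  }
  if (length(aucs) == 0)
    return(list(mean_auc = NA_real_, sd_auc = NA_real_, auc = aucs,
                mean_curve = data.frame(fpr = grid, tpr = NA_real_),
                fpr_grid = grid))
  list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs), auc = aucs,
       mean_curve = data.frame(fpr = grid, tpr = colMeans(curves)),
       fpr_grid = grid)
}

#' 2D t-SNE embedding of the selected features
#'
#' Seeded exact t-distributed stochastic neighbor embedding of the feature
#' rows (standardized columns), for qualitative visualization of the organ
#' structure in the selected feature space. The perplexity is shrunk
#' automatically (with a warning) when fewer rows than 3 * perplexity + 1
#' are provided. Output units are arbitrary.
#'
#' @param features feature table or numeric matrix.
#' @param selected feature columns to use (tables only).
#' @param seed integer seed; the same seed yields the same embedding.
#' @param perplexity t-SNE perplexity (default 30, auto-shrunk).
#' @param nIter gradient-descent iterations.
#' @return an n x 2 matrix of embedding coordinates.
#' @export
tsneEmbed <- function(features, selected = NULL, seed = 1,
                      perplexity = 30, nIter = 400) {
  X <- if (is.data.frame(features)) {
    if (is.null(selected)) selected <- featureColumns(features)
    as.matrix(features[, selected, drop = FALSE])
  } else as.matrix(features)
  n <- nrow(X)
  assertThat(n >= 5, "need at least 5 rows")
  if (perplexity > (n - 1) / 3) {
    perplexity <- max(2, floor((n - 1) / 3))
    warning(sprintf("perplexity shrunk to %g for %d rows", perplexity, n))
  }
  sds <- apply(X, 2, stats::sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  D2 <- as.matrix(stats::dist(X))^2
  P <- condProbs(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withSeed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    gains <- matrix(1, n, 2)
    inc <- matrix(0, n, 2)
    for (it in seq_len(nIter)) {
      ex <- if (it <= 100) 12 else 1
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (ex * P - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (it <= 250) 0.5 else 0.8
      gains <- pmax(0.01, ifelse(sign(grad) != sign(inc),
                                 gains + 0.2, gains * 0.8))
      inc <- mom * inc - 200 * gains * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

# Conditional Gaussian neighbor probabilities at a fixed perplexity, per row
# (binary search over precision).
condProbs <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (k in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 }
      else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

#' Empirical first Wasserstein distance between two samples
#'
#' Exact 1-Wasserstein (earth mover's) distance between the empirical
#' distributions of two intensity samples, computed as the integral of the
#' absolute difference of the two empirical CDFs (equivalently, the L1
#' distance between quantile functions).
#'
#' @param x,y non-empty numeric samples.
#' @return the distance (same units as the samples).
#' @examples
#' wasserstein1d(c(0, 0), c(1, 1))  # 1
#' @export
wasserstein1d <- function(x, y) {
  assertThat(length(x) > 0 && length(y) > 0,
             "samples must be non-empty (invalid argument)")
  all <- sort(c(x, y))
  m <- length(all)
  if (m < 2) return(0)
  sx <- sort(x); sy <- sort(y)
  Fx <- findInterval(all[-m], sx) / length(x)
  Fy <- findInterval(all[-m], sy) / length(y)
  sum(abs(Fx - Fy) * diff(all))
}

#' Pairwise Wasserstein distance matrix over ROI intensity samples
#'
#' Computes the first Wasserstein distance between every pair of ROI voxel
#' samples (raw matrix: symmetric, zero diagonal) and a min-max normalized
#' copy scaled to [0, 1] over the off-diagonal entries (diagonal forced to
#' 0). Rows are ordered by organ class, then by name, for heatmap display.
#'
#' @param samples named list of numeric vectors (one intensity sample per
#'   ROI identity); names are used as labels.
#' @param organ optional character vector (same length) used to order the
#'   matrix by organ class.
#' @return a list of class \code{"DistanceMatrix"}: \code{labels},
#'   \code{raw}, \code{normalized}, \code{organ}.
#' @export
wassersteinMatrix <- function(samples, organ = NULL) {
  assertThat(length(samples) >= 2, "need at least two samples")
  assertThat(all(vapply(samples, length, 1L) > 0),
             "empty sample (invalid argument)")
  if (is.null(names(samples)))
    names(samples) <- paste0("roi", seq_along(samples))
  ord <- if (!is.null(organ)) order(organ, names(samples))
         else seq_along(samples)
  samples <- samples[ord]
  organ <- organ[ord]
  n <- length(samples)
  raw <- matrix(0, n, n, dimnames = list(names(samples), names(samples)))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      raw[i, j] <- raw[j, i] <- wasserstein1d(samples[[i]], samples[[j]])
  off <- raw[row(raw) != col(raw)]
  rng <- range(off)
  normalized <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng)
                else raw * 0
  diag(normalized) <- 0
  structure(list(labels = names(samples), raw = raw,
                 normalized = normalized, organ = organ),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat(sprintf("Wasserstein distance matrix: %d ROIs, raw range [%.3g, %.3g]\n",
              length(x$labels), min(x$raw), max(x$raw)))
  invisible(x)
}

#' ROI voxel samples for distance analysis
#'
#' Collects the per-ROI voxel intensity samples of a map (e.g. for
#' [wassersteinMatrix()]).
#'
#' @param map an \code{ADCMap}, \code{DWISeries} or 3D array.
#' @param rois an [ROISet-class].
#' @param prefix label prefix (e.g. the site/timepoint id).
#' @return a named list of numeric vectors with an \code{"organ"} attribute.
#' @export
roiSamples <- function(map, rois, prefix = "") {
  if (is(map, "ADCMap")) {
    vals <- map@values; ok <- map@validMask
  } else if (is(map, "DWISeries")) {
    vals <- map@volumes[[1]]; ok <- array(TRUE, dim(vals))
  } else {
    vals <- map; ok <- array(TRUE, dim(vals))
  }
  labs <- sort(unique(as.integer(rois@labels[rois@labels > 0])))
  out <- lapply(labs, function(l) vals[rois@labels == l & ok])
  names(out) <- paste0(prefix, rois@labelNames[labs])
  attr(out, "organ") <- unname(rois@organOfLabel[labs])
  out
}
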