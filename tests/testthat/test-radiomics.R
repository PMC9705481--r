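test_that("isotropic resampling preserves values, extent and mask binarity", {
  withr::with_seed(3, v <- array(runif(16 * 16 * 8), c(16, 16, 8)))
  # identity grid: values unchanged
  out <- resampleIsotropic(v, spacing = c(1, 1, 1))
  expect_equal(as.numeric(out), as.numeric(v), tolerance = 1e-12)

  # constant 2 mm volume: constant output, each axis dimension doubled
  cv <- array(5, c(10, 10, 4))
  out2 <- resampleIsotropic(cv, spacing = c(2, 2, 2))
  expect_equal(dim(out2), c(20, 20, 8))
  expect_equal(as.numeric(out2), rep(5, 3200))
  # physical extent preserved within one voxel
  expect_lt(max(abs(dim(out2) * 1 - c(10, 10, 4) * 2)), 1 + 1e-9)

  # nearest-neighbor keeps masks binary
  m <- array(0L, c(9, 9, 5)); m[3:6, 3:6, 2:3] <- 1L
  outm <- resampleIsotropic(m, spacing = c(2.6, 2.6, 5), isMask = TRUE)
  expect_setequal(unique(as.numeric(outm)), c(0, 1))

  expect_error(resampleIsotropic(v), "spacing")
})

test_that("histogram matching is idempotent and removes affine distortions", {
  withr::with_seed(5, ref <- array(rgamma(20 * 20 * 6, 4, 1 / 100),
                                   c(20, 20, 6)))
  levelWidth <- diff(range(ref)) / 128
  probs <- seq(0.1, 0.9, by = 0.1)

  self <- histogramMatch(ref, ref)
  expect_lt(max(abs(quantile(self, probs) - quantile(ref, probs))),
            2 * levelWidth)

  src <- 2 * ref
  matched <- histogramMatch(src, ref)
  fg <- matched[src > mean(src)]
  fgRef <- ref[ref > mean(ref)]
  expect_lt(max(abs(quantile(fg, probs) - quantile(fgRef, probs))),
            2 * levelWidth)
  # monotone non-decreasing transfer
  o <- order(as.numeric(src))
  expect_true(all(diff(as.numeric(matched)[o]) >= -1e-9))

  expect_error(histogramMatch(array(1, c(4, 4, 4)), ref), "degenerate")
})

test_that("histogram matching shrinks cross-site gain spread in ROI means", {
  tm <- makeVolunteerTissueMap(seed = 6)
  rois <- makeROIMasks(spacing = tm$spacing, dims = tm$dims)
  gains <- c(0.5, 0.8, 1.2, 1.6, 2)
  vols <- lapply(seq_along(gains), function(i)
    seriesVolumes(simulateT2w(tm, siteRow(gain = gains[i], noise_sigma = 5,
                                          bias_amplitude = 0.1),
                              seed = 10 + i))[[1]])
  refVol <- seriesVolumes(simulateT2w(tm, siteRow(), seed = 9))[[1]]
  liver <- roiLabels(rois) > 0 &
    array(organClasses(rois)[roiLabels(rois)] == "liver", dim(roiLabels(rois)))
  before <- vapply(vols, function(v) mean(v[liver]), numeric(1))
  after <- vapply(vols, function(v)
    mean(histogramMatch(v, refVol)[liver]), numeric(1))
  expect_lt(sd(after), sd(before))
})

test_that("first-order features follow their closed forms", {
  fo <- firstOrderFeatures(c(0, 2))
  expect_equal(unname(fo["fo_mean"]), 1)
  expect_equal(unname(fo["fo_range"]), 2)
  expect_equal(unname(fo["fo_variance"]), 1)  # population convention
  expect_equal(unname(fo["fo_energy"]), 4)
  expect_equal(unname(fo["fo_rms"]), sqrt(2))

  const <- firstOrderFeatures(rep(3, 50))
  expect_equal(unname(const["fo_sd"]), 0)
  expect_equal(unname(const["fo_skewness"]), 0)
  expect_equal(unname(const["fo_uniformity"]), 1)
  expect_equal(unname(const["fo_entropy"]), 0)
})

test_that("feature extraction yields 26 named columns and degenerate GLCM", {
  rois <- makeROIMasks(spacing = c(1, 1, 5), dims = c(140, 140, 10))
  const <- array(42, c(140, 140, 10))
  tab <- extractFeatures(const, rois, site = "A")
  expect_equal(nrow(tab), 11)
  expect_length(setdiff(names(tab), c("site", "timepoint", "roi_label",
                                      "name", "organ_class")), 26)
  expect_equal(tab$glcm_contrast, rep(0, 11))
  expect_equal(tab$glcm_asm, rep(1, 11))
  expect_equal(tab$fo_sd, rep(0, 11))
  featCols <- setdiff(names(tab), c("site", "timepoint", "roi_label",
                                    "name", "organ_class"))
  expect_false(anyNA(tab[, featCols]))
  expect_equal(attr(tab, "provenance")$extractor, "mcDWI-builtin")

  # too-small ROIs are skipped with a message
  small <- rois
  lab <- roiLabels(small)
  keep <- which(lab == 1)[1:5]
  lab[lab == 1] <- 0L
  lab[keep] <- 1L
  small@labels <- lab
  expect_message(tab2 <- extractFeatures(const, small), "skipped")
  expect_equal(nrow(tab2), 10)
})

test_that("stability scores reward cross-site concordance, punish noise", {
  geo <- defaultROIGeometry()
  mkTab <- function(site, f_stable, f_noise) {
    data.frame(site = site, timepoint = "t1", roi_label = geo$label,
               name = geo$name, organ_class = geo$organ_class,
               stable = f_stable, noise = f_noise)
  }
  withr::with_seed(17, {
    base <- rnorm(11)
    tabs <- lapply(LETTERS[1:7], function(s)
      mkTab(s, base * runif(1, 0.5, 2) + runif(1), rnorm(11)))
  })
  res <- stabilityFilter(tabs)
  expect_equal(unname(res$scores["stable"]), 1, tolerance = 1e-12)
  expect_lt(res$scores["noise"], 0.75)
  expect_equal(res$survivors, "stable")

  # sign flips do not hurt: |r| = 1
  two <- list(mkTab("A", base, base), mkTab("B", -base, base))
  expect_equal(unname(stabilityFilter(two)$scores), c(1, 1))

  # zero-variance vectors score 0 for the affected pairs
  zv <- list(mkTab("A", rep(1, 11), base), mkTab("B", base, base))
  expect_message(reszv <- stabilityFilter(zv), "zero variance")
  expect_equal(unname(reszv$scores["stable"]), 0)
})

test_that("ANOVA F scoring matches the SSB/SSW oracle and the worked case", {
  tab <- data.frame(organ_class = c("A", "A", "B", "B"),
                    f = c(1, 2, 3, 4))
  expect_equal(unname(anovaSelect(tab, "f", 1)$f_score), 8)

  oracleF <- function(v, g) {
    gm <- mean(v)
    ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - gm)^2))
    ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
    (ssb / (nlevels(factor(g)) - 1)) / (ssw / (length(v) - nlevels(factor(g))))
  }
  withr::with_seed(23, {
    g <- rep(c("k", "l", "s", "m", "v"), times = c(4, 6, 4, 4, 4))
    tab2 <- data.frame(organ_class = g)
    for (j in 1:20) tab2[[paste0("x", sprintf("%02d", j))]] <-
      rnorm(22) + (j <= 5) * as.integer(factor(g))
    sel <- anovaSelect(tab2, paste0("x", sprintf("%02d", 1:20)), 15)
    for (j in 1:20) {
      f <- paste0("x", sprintf("%02d", j))
      expect_equal(unname(sel$f_score[f]), oracleF(tab2[[f]], g),
                   tolerance = 1e-10)
    }
    expect_length(sel$selected, 15)
  })

  # constant features score 0 and lose to any varying feature
  tab3 <- data.frame(organ_class = rep(c("A", "B"), each = 3),
                     flat = 1, varies = c(1, 2, 3, 7, 8, 9))
  sel3 <- anovaSelect(tab3, c("flat", "varies"), 1)
  expect_equal(unname(sel3$f_score["flat"]), 0)
  expect_equal(sel3$selected, "varies")

  expect_error(anovaSelect(data.frame(organ_class = c("A", "A", "B"),
                                      f = 1:3), "f", 1), "< 2 samples")
})

test_that("selection keeps at most N features and warns when fewer survive", {
  tabs <- separableFeatures()
  expect_warning(sel <- selectFeatures(tabs, nSelect = 15), "2 features")
  expect_setequal(sel$selected, c("f1", "f2"))
  expect_true(all(sel$stability_score >= 0 & sel$stability_score <= 1))
  sel2 <- selectFeatures(tabs, nSelect = 1)
  expect_length(sel2$selected, 1)
})
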