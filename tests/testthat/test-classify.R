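test_that("LOSO classification is perfect and run-stable on separable data", {
  feats <- separableFeatures()
  rep <- losoCV(feats, c("f1", "f2"), nRuns = 2, seed = 1, trees = 200)
  expect_equal(rep$per_site$mean_accuracy, rep(1, 7))
  expect_equal(rep$per_site$sd_accuracy, rep(0, 7))
  expect_equal(rep$overall_accuracy, 1)
  expect_equal(dim(rep$accuracy), c(7, 2))
})

test_that("LOSO validates sites and training-fold class coverage", {
  feats <- separableFeatures(nSites = 2)
  expect_error(losoCV(feats, c("f1", "f2")), "3 sites")
  f3 <- separableFeatures(nSites = 3)
  # drop a class from all but one site: its fold must fail by name
  f3 <- f3[!(f3$site != "A" & f3$organ_class == "spleen"), ]
  expect_error(losoCV(f3, c("f1", "f2")), "spleen")
})

test_that("shared-seed mode removes run-to-run forest randomness", {
  feats <- separableFeatures()
  withr::with_seed(31, feats$f1 <- feats$f1 + rnorm(nrow(feats), 0, 8))
  rep <- losoCV(feats, c("f1", "f2"), nRuns = 3, seed = 2, trees = 100,
                perRunSeeds = FALSE)
  expect_equal(rep$per_site$sd_accuracy, rep(0, 7))
  rep2 <- losoCV(feats, c("f1", "f2"), nRuns = 3, seed = 2, trees = 100)
  expect_identical(rep2$accuracy,
                   losoCV(feats, c("f1", "f2"), nRuns = 3, seed = 2,
                          trees = 100)$accuracy)
})

test_that("test-retest training transfers across timepoints", {
  t1 <- separableFeatures()
  t2 <- separableFeatures(seed = 2)  # same structure, fresh noise
  rep <- testRetestCV(t1, t2, c("f1", "f2"), nRuns = 2, seed = 1,
                      trees = 200)
  expect_equal(rep$mean_accuracy, 1)
  expect_length(rep$accuracy, 2)

  bad <- t2; bad$roi_label <- bad$roi_label + 100
  expect_error(testRetestCV(t1, bad, c("f1", "f2")), "pairing")
})

test_that("ROC/AUC macro-averaging matches concordance arithmetic", {
  probs <- data.frame(run = 1, site = "A",
                      truth = c("pos", "pos", "neg", "neg"),
                      pos = c(0.9, 0.4, 0.8, 0.3))
  probs$neg <- 1 - probs$pos
  res <- rocAUC(probs)
  expect_equal(res$mean_auc, 0.75)  # 3 of 4 concordant pairs, both classes

  perfect <- data.frame(run = 1, site = "A",
                        truth = rep(c("pos", "neg"), each = 3),
                        pos = c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  perfect$neg <- 1 - perfect$pos
  expect_equal(rocAUC(perfect)$mean_auc, 1)

  withr::with_seed(41, {
    nullp <- data.frame(run = 1, site = "A",
                        truth = rep(c("pos", "neg"), each = 250),
                        pos = runif(500))
    nullp$neg <- 1 - nullp$pos
    expect_lt(abs(rocAUC(nullp)$mean_auc - 0.5), 0.1)
  })

  oneSided <- data.frame(run = 1, site = "A", truth = rep("pos", 4),
                         pos = runif(4))
  expect_message(resOS <- rocAUC(oneSided), "skipped")
  expect_true(is.na(resOS$mean_auc))

  # curves live on the fixed 101-point FPR grid
  expect_equal(nrow(res$mean_curve), 101)
  expect_equal(res$mean_curve$tpr[1], 0)
  expect_equal(res$mean_curve$tpr[101], 1)
})

test_that("t-SNE embedding is seeded, finite and separates planted clusters", {
  withr::with_seed(51, {
    X <- rbind(matrix(rnorm(20 * 5), 20, 5),
               matrix(rnorm(20 * 5, mean = 8), 20, 5))
  })
  expect_warning(Y <- tsneEmbed(X, seed = 1, perplexity = 30), "shrunk")
  expect_equal(dim(Y), c(40, 2))
  expect_true(all(is.finite(Y)))
  expect_warning(Y2 <- tsneEmbed(X, seed = 1, perplexity = 30), "shrunk")
  expect_identical(Y, Y2)

  D <- as.matrix(dist(Y))
  within <- mean(D[1:20, 1:20][upper.tri(D[1:20, 1:20])])
  between <- mean(D[1:20, 21:40])
  expect_gt(between, within)  # positive silhouette-style separation
  expect_error(tsneEmbed(X[1:3, ]), "5 rows")
})

test_that("Wasserstein distance matches oracles and metric axioms", {
  expect_equal(wasserstein1d(c(0, 0), c(1, 1)), 1)
  expect_equal(wasserstein1d(c(0, 1), 1), 0.5)
  expect_equal(wasserstein1d(5:1, 1:5), 0)
  withr::with_seed(61, {
    for (i in 1:20) {
      x <- rnorm(37); y <- rnorm(37, 1)
      # equal-size oracle: mean absolute difference of order statistics
      expect_equal(wasserstein1d(x, y), mean(abs(sort(x) - sort(y))),
                   tolerance = 1e-10)
    }
    for (i in 1:10) {
      x <- rnorm(15); y <- runif(25, -2, 2); z <- rexp(9)
      expect_equal(wasserstein1d(x, y), wasserstein1d(y, x),
                   tolerance = 1e-12)
      expect_lte(wasserstein1d(x, z),
                 wasserstein1d(x, y) + wasserstein1d(y, z) + 1e-12)
    }
  })
})

test_that("distance matrices are symmetric, zero-diagonal and normalized", {
  withr::with_seed(71, samples <- list(a = rnorm(30), b = rnorm(30, 2),
                                       c = rnorm(30, 4), d = rnorm(30)))
  dm <- wassersteinMatrix(samples, organ = c("x", "y", "y", "x"))
  expect_equal(dm$raw, t(dm$raw))
  expect_equal(unname(diag(dm$raw)), rep(0, 4))
  expect_true(all(dm$normalized >= 0 & dm$normalized <= 1))
  off <- dm$normalized[row(dm$normalized) != col(dm$normalized)]
  expect_equal(min(off), 0)
  expect_equal(max(off), 1)
  # ordered by organ class
  expect_equal(dm$organ, sort(dm$organ))
  expect_error(wassersteinMatrix(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("study feature tables carry keys and no missing values", {
  fa <- travelingFeaturesADC()
  expect_equal(nrow(fa), 77)
  expect_setequal(unique(fa$site), manifest7()$site_id)
  expect_false(anyNA(fa))
  expect_equal(sort(unique(fa$organ_class)),
               c("kidney", "liver", "muscle", "spleen", "vertebra"))
})
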