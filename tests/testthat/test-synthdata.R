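test_that("site manifest honors its contract and is seeded", {
  m <- generateSiteManifest(7, seed = 1)
  expect_equal(nrow(m), 7)
  expect_equal(sum(m$is_reference), 1)
  expect_equal(sum(m$includes_b0), 1)
  expect_true(all(m$gain > 0))
  expect_true(all(m$bias_amplitude >= 0 & m$bias_amplitude < 1))
  expect_identical(generateSiteManifest(2, seed = 1),
                   generateSiteManifest(2, seed = 1))
  expect_false(all(generateSiteManifest(7, seed = 1)$gain ==
                     generateSiteManifest(7, seed = 2)$gain))
  expect_error(generateSiteManifest(1), "at least 2")
})

test_that("noise-free DWI decays exactly monoexponentially", {
  tm <- flatTissueMap(adc = 1600, s0 = 1000)
  dwi <- simulateDWI(tm, siteRow(), seed = 1)
  v <- seriesVolumes(dwi)
  # S(100)/S(500) = exp((500-100) * 1600e-6) at every voxel
  expect_equal(as.numeric(v[[1]] / v[[2]]), rep(exp(0.64), 1000),
               tolerance = 1e-12)
  lnS <- log(c(mean(v[[1]]), mean(v[[2]]), mean(v[[3]])))
  fit <- lm(lnS ~ bValues(dwi))
  expect_lt(max(abs(residuals(fit))) / abs(lnS[1]), 1e-10)
})

test_that("perfusion fraction inflates b0-inclusive fits", {
  tm <- flatTissueMap(adc = 1000, f = 0.2, dstar = 20000)
  dwi <- simulateDWI(tm, siteRow(), defaultAcquisition(includeB0 = TRUE),
                     seed = 1)
  withB0 <- mean(adcValues(computeADCMap(dwi, omitB0 = FALSE)))
  noB0 <- mean(adcValues(computeADCMap(dwi, omitB0 = TRUE)))
  expect_gt(withB0, noB0)
})

test_that("background magnitude noise has the Rayleigh mean", {
  sigma <- 30
  tm <- flatTissueMap(dims = c(25, 25, 16), s0 = 0)
  dwi <- simulateDWI(tm, siteRow(noise_sigma = sigma), seed = 7)
  bg <- as.numeric(seriesVolumes(dwi)[[1]])  # averages = 1 at b = 100
  expectMean <- sigma * sqrt(pi / 2)
  sem <- sigma * sqrt((4 - pi) / 2) / sqrt(length(bg))
  expect_lt(abs(mean(bg) - expectMean), 4 * sem)
})

test_that("T2w simulation is linear in gain and seeded", {
  tm <- flatTissueMap()
  g1 <- simulateT2w(tm, siteRow(gain = 1), seed = 3)
  g2 <- simulateT2w(tm, siteRow(gain = 2), seed = 3)
  expect_equal(seriesVolumes(g2)[[1]] / seriesVolumes(g1)[[1]],
               array(2, tm$dims), tolerance = 1e-12)
  expect_identical(simulateT2w(tm, siteRow(noise_sigma = 5), seed = 3),
                   simulateT2w(tm, siteRow(noise_sigma = 5), seed = 3))
})

test_that("default volunteer liver T2w gray values sit in the expected regime", {
  tm <- makeVolunteerTissueMap(seed = 2)
  t2w <- simulateT2w(tm, siteRow(), seed = 2)
  rois <- makeROIMasks(spacing = tm$spacing, dims = tm$dims)
  st <- roiStats(t2w, rois)
  liver <- st[st$organ_class == "liver", ]
  sem <- 480 * 0.22 / sqrt(sum(liver$n_voxels))
  expect_lt(abs(mean(liver$mean) - 480), 3 * sem)
})

test_that("ROI masks are 11 disjoint discs of ~250 mm^2", {
  for (sp in list(c(1, 1, 5), c(2, 2, 5), c(2.6, 2.6, 5))) {
    dims <- c(ceiling(140 / sp[1]), ceiling(140 / sp[2]), 10)
    rois <- makeROIMasks(spacing = sp, dims = dims)
    counts <- table(roiLabels(rois)[roiLabels(rois) > 0])
    expect_length(counts, 11)
    areas <- as.numeric(counts) * sp[1] * sp[2]
    expect_true(all(abs(areas - 250) / 250 <= 0.05))
  }
  rois <- makeROIMasks(spacing = c(1, 1, 5), dims = c(140, 140, 10))
  expect_true(all(table(roiLabels(rois)[roiLabels(rois) > 0]) %in% 237:263))
  expect_length(unique(organClasses(rois)), 5)
  # overlapping layout is rejected
  geo <- defaultROIGeometry()
  geo$x_mm[2] <- geo$x_mm[1] + 5
  geo$y_mm[2] <- geo$y_mm[1]
  expect_error(makeROIMasks(geo, c(1, 1, 5), c(140, 140, 10)), "layout")
})

test_that("study scenarios produce the promised structure", {
  ph <- phantomStudy()
  expect_length(ph$sites, 7)
  expect_length(vapply(ph$sites, `[[`, 1, "temperature"), 7)

  tv <- travelingStudy()
  expect_length(tv$sites, 7)
  # one fixed anatomy, different intensities per site
  expect_false(identical(seriesVolumes(tv$sites[["A"]]$dwi)[[1]],
                         seriesVolumes(tv$sites[["C"]]$dwi)[[1]]))
  expect_identical(tv$tissueMap,
                   generateStudy(manifest7(), "traveling_volunteer",
                                 seed = 1)$tissueMap)

  tr <- testRetestStudy()
  s <- tr$sites[[1]]
  expect_named(s$timepoints, c("t1", "t2"))
  expect_false(identical(seriesVolumes(s$timepoints$t1$dwi)[[1]],
                         seriesVolumes(s$timepoints$t2$dwi)[[1]]))
})

test_that("generators are bit-reproducible for a fixed seed", {
  a <- generateStudy(manifest7(), "phantom", seed = 5)
  b <- generateStudy(manifest7(), "phantom", seed = 5)
  expect_identical(a$sites[["D"]]$dwi@volumes, b$sites[["D"]]$dwi@volumes)
})

test_that("a study round-trips through NIfTI + JSON on disk", {
  dir <- file.path(tempdir(), "mcdwi-io")
  m <- generateSiteManifest(2, seed = 3)
  st <- generateStudy(m, "traveling_volunteer", seed = 3, outDir = dir)
  expect_true(file.exists(file.path(dir, "index.json")))
  rt <- readStudy(dir)
  sid <- m$site_id[1]
  expect_equal(seriesVolumes(rt$sites[[sid]]$dwi)[[1]],
               seriesVolumes(st$sites[[sid]]$dwi)[[1]], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(bValues(rt$sites[[sid]]$dwi), c(100, 500, 900))
  expect_identical(roiLabels(rt$sites[[sid]]$rois),
                   roiLabels(st$sites[[sid]]$rois))
  unlink(dir, recursive = TRUE)
})
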