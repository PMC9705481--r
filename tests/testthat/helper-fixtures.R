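# Shared fixtures. Expensive synthetic studies are built once per test run
# and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# a site profile row without manifest bookkeeping
siteRow <- function(gain = 1, noise_sigma = 0, bias_amplitude = 0,
                    includes_b0 = FALSE) {
  data.frame(site_id = "X", gain = gain, noise_sigma = noise_sigma,
             bias_amplitude = bias_amplitude, includes_b0 = includes_b0,
             is_reference = TRUE)
}

# spatially uniform single-tissue map
flatTissueMap <- function(dims = c(10, 10, 10), spacing = c(1, 1, 1),
                          adc = 1600, s0 = 1000, t2w = 480, f = 0,
                          dstar = 20000) {
  list(adc = array(adc, dims), s0 = array(s0, dims),
       t2w = array(t2w, dims), f = array(f, dims),
       dstar = array(dstar, dims), organIndex = array(1L, dims),
       spacing = spacing, dims = dims)
}

manifest7 <- function() cached("manifest7", generateSiteManifest(7, seed = 1))

travelingStudy <- function()
  cached("traveling", generateStudy(manifest7(), "traveling_volunteer",
                                    seed = 1))

testRetestStudy <- function()
  cached("testretest", generateStudy(manifest7(), "test_retest", seed = 1))

phantomStudy <- function()
  cached("phantom", generateStudy(manifest7(), "phantom", seed = 1))

travelingFeaturesADC <- function()
  cached("featADC", studyFeatures(travelingStudy(), "adc"))

travelingFeaturesT2w <- function()
  cached("featT2w", studyFeatures(travelingStudy(), "t2w"))

# linearly separable five-class feature table over nSites sites, 11 ROIs
separableFeatures <- function(nSites = 7, seed = 1) {
  geo <- defaultROIGeometry()
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nSites), function(s) {
      data.frame(site = LETTERS[s], timepoint = "t1",
                 roi_label = geo$label, name = geo$name,
                 organ_class = geo$organ_class,
                 f1 = as.integer(factor(geo$organ_class)) * 10 +
                   rnorm(11, 0, 0.1),
                 f2 = -as.integer(factor(geo$organ_class)) * 5 +
                   rnorm(11, 0, 0.1),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
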