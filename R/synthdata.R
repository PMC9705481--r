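#' Generate a multi-site scanner manifest
#'
#' Creates a seeded table of per-site acquisition profiles emulating the
#' hardware heterogeneity of a multicenter MR consortium: per-site intensity
#' gain, Rician noise scale, smooth bias-field amplitude, and vendor tag.
#' Exactly one site is flagged as the reference site (used as the origin of
#' traveling-volunteer comparisons and as the histogram-matching reference),
#' and - when at least 7 sites are requested - exactly one site is flagged as
#' requiring the b = 0 s/mm^2 volume in its inline ADC computation, emulating
#' a scanner software constraint.
#'
#' @param nSites number of sites (>= 2).
#' @param seed integer seed; the manifest is deterministic given the seed.
#' @return a \code{data.frame} with one row per site and columns
#'   \code{site_id}, \code{vendor_tag}, \code{gain}, \code{noise_sigma},
#'   \code{bias_amplitude}, \code{includes_b0}, \code{is_reference}.
#' @examples
#' generateSiteManifest(7, seed = 1)
#' @export
generateSiteManifest <- function(nSites, seed = 1) {
  assertThat(is.numeric(nSites) && nSites >= 2,
             "nSites must be at least 2 (invalid argument)")
  nSites <- as.integer(nSites)
  withSeed(seed, {
    ids <- make.unique(rep(LETTERS, length.out = nSites), sep = "")
    vendors <- rep(c("A-style", "B-style", "C-style"), length.out = nSites)
    data.frame(
      site_id        = ids,
      vendor_tag     = sample(vendors),
      gain           = stats::runif(nSites, 0.6, 1.8),
      noise_sigma    = stats::runif(nSites, 10, 25),
      bias_amplitude = stats::runif(nSites, 0.02, 0.18),
      includes_b0    = seq_len(nSites) == 2L & nSites >= 7L,
      is_reference   = seq_len(nSites) == min(6L, nSites),
      stringsAsFactors = FALSE
    )
  })
}

#' Validate a site manifest
#'
#' @param manifest a site manifest data.frame
#' @return the manifest, invisibly, if valid; otherwise an error.
#' @export
validateManifest <- function(manifest) {
  req <- c("site_id", "gain", "noise_sigma", "bias_amplitude",
           "includes_b0", "is_reference")
  assertThat(all(req %in% names(manifest)), "manifest is missing columns")
  assertThat(all(manifest$gain > 0), "gain must be positive")
  assertThat(all(manifest$noise_sigma >= 0), "noise_sigma must be >= 0")
  assertThat(all(manifest$bias_amplitude >= 0 & manifest$bias_amplitude < 1),
             "bias_amplitude must be in [0, 1)")
  assertThat(sum(manifest$is_reference) == 1,
             "exactly one site must be the reference")
  invisible(manifest)
}

#' Acquisition specification
#'
#' Describes a DWI (or T2w) acquisition: the b-values and the number of
#' signal averages per b-value. The default emulates a harmonized abdominal
#' DW-EPI protocol with b = 100, 500, 900 s/mm^2 acquired with 1, 6 and 23
#' signal averages; \code{includeB0} prepends a b = 0 volume (1 average).
#'
#' @param bValues strictly increasing non-negative b-values in s/mm^2.
#' @param averages positive integers, one per b-value.
#' @param modality \code{"dwi"} or \code{"t2w"}.
#' @return a list with class \code{"AcquisitionSpec"}.
#' @export
acquisitionSpec <- function(bValues = c(100, 500, 900),
                            averages = c(1, 6, 23),
                            modality = c("dwi", "t2w")) {
  modality <- match.arg(modality)
  assertThat(all(bValues >= 0), "b-values must be non-negative")
  assertThat(length(bValues) < 2 || all(diff(bValues) > 0),
             "b-values must be strictly increasing")
  assertThat(length(averages) == length(bValues),
             "averages must have one entry per b-value")
  assertThat(all(averages >= 1), "averages must be positive")
  structure(list(bValues = as.numeric(bValues),
                 averages = as.numeric(averages),
                 modality = modality),
            class = "AcquisitionSpec")
}

#' @rdname acquisitionSpec
#' @param includeB0 prepend a b = 0 s/mm^2 volume.
#' @export
defaultAcquisition <- function(includeB0 = FALSE) {
  if (includeB0) acquisitionSpec(c(0, 100, 500, 900), c(1, 1, 6, 23))
  else acquisitionSpec()
}

#' Default tissue parameters per organ class
#'
#' One row per organ class with the parameters of the diffusion signal model
#' S(b) = S0 * [(1 - f) exp(-b ADC) + f exp(-b D*)] and a T2w gray-value
#' mean. Liver ADC (965 um^2/s) and liver T2w gray value (480) are set to the
#' regime of healthy upper-abdominal measurements; perfusion fractions and
#' the remaining organ values are documented stipulations chosen to give the
#' five organ classes distinct, realistic contrasts.
#' \code{heterogeneity_sigma} is the fractional voxelwise spread of the true
#' ADC/T2w within an organ (tissue texture, fixed per anatomy, not noise).
#'
#' @return a \code{data.frame} keyed by \code{organ_class}.
#' @export
defaultTissueSpecs <- function() {
  data.frame(
    organ_class = c("kidney", "liver", "spleen", "muscle", "vertebra",
                    "phantom", "background"),
    adc_true    = c(1900, 965, 880, 1500, 550, 1600, 2400),
    s0          = c(1100, 1000, 1050, 900, 700, 1200, 250),
    t2w_mean    = c(620, 480, 560, 210, 400, 300, 80),
    f           = c(0.12, 0.15, 0.05, 0.04, 0.05, 0, 0),
    d_star      = c(20000, 20000, 20000, 20000, 20000, 0, 0),
    heterogeneity_sigma = c(0.10, 0.22, 0.08, 0.10, 0.12, 0, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Default ROI geometry: 11 anatomical positions in 5 organ classes
#'
#' Centers (in mm, from the volume corner) of the 11 circular ROI positions:
#' left/right kidney, liver segments 4/7/8, two spleen locations, left/right
#' quadratus lumborum, and lumbar vertebral bodies 1/2. The layout fits a
#' 135 x 135 x 50 mm synthetic abdomen with two ROI slice planes.
#'
#' @return a \code{data.frame} with columns \code{label}, \code{name},
#'   \code{organ_class}, \code{x_mm}, \code{y_mm}, \code{z_mm}.
#' @export
defaultROIGeometry <- function() {
  data.frame(
    label = 1:11,
    name = c("kidney_left", "kidney_right", "liver_segment4",
             "liver_segment7", "liver_segment8", "spleen_upper",
             "spleen_lower", "quadratus_lumborum_left",
             "quadratus_lumborum_right", "vertebra_L1", "vertebra_L2"),
    organ_class = c("kidney", "kidney", "liver", "liver", "liver",
                    "spleen", "spleen", "muscle", "muscle",
                    "vertebra", "vertebra"),
    x_mm = c(25, 110, 40, 25, 52, 105, 110, 45, 95, 67, 70),
    y_mm = c(100, 100, 40, 65, 72, 45, 65, 110, 110, 95, 118),
    z_mm = c(17.5, 17.5, 17.5, 32.5, 32.5, 17.5, 32.5, 32.5, 32.5,
             17.5, 32.5),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic volunteer tissue map
#'
#' Places one axis-aligned ellipsoid of tissue per ROI position on a
#' background of body-like signal, then draws seeded voxelwise parameter
#' volumes (ADC, S0, T2w gray value, perfusion fraction, pseudo-diffusion)
#' from the organ-class specs with multiplicative heterogeneity. The map is
#' the fixed "anatomy": re-imaging it with different noise seeds emulates
#' test-retest, imaging it under different site profiles emulates a
#' traveling volunteer.
#'
#' @param dims grid size (voxels), default \code{c(52, 52, 10)}.
#' @param spacing voxel spacing in mm, default \code{c(2.6, 2.6, 5)} (5 mm
#'   slices).
#' @param specs tissue parameter table, see [defaultTissueSpecs()].
#' @param geometry ROI/organ layout, see [defaultROIGeometry()].
#' @param seed integer seed for the heterogeneity draws.
#' @param organScale optional named numeric vector of per-organ multiplicative
#'   offsets applied to ADC and T2w means (emulates different volunteers).
#' @return a list with elements \code{adc}, \code{s0}, \code{t2w}, \code{f},
#'   \code{dstar} (3D parameter arrays), \code{organIndex} (integer array,
#'   0 = background), \code{spacing}, \code{dims}.
#' @export
makeVolunteerTissueMap <- function(dims = c(52, 52, 10),
                                   spacing = c(2.6, 2.6, 5),
                                   specs = defaultTissueSpecs(),
                                   geometry = defaultROIGeometry(),
                                   seed = 1,
                                   organScale = NULL) {
  # ellipsoid semi-axes (mm): in-plane large enough that a 250 mm^2 disc
  # (radius 8.92 mm) jittered by up to 3 mm stays inside its organ
  semi <- c(12.5, 12.5, 7)
  co <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing[a])
  organIndex <- array(0L, dim = dims)
  rownames(specs) <- specs$organ_class
  for (i in seq_len(nrow(geometry))) {
    g <- geometry[i, ]
    dx <- (co[[1]] - g$x_mm) / semi[1]
    dy <- (co[[2]] - g$y_mm) / semi[2]
    dz <- (co[[3]] - g$z_mm) / semi[3]
    inside <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= 1
    organIndex[inside & organIndex == 0L] <- i
  }
  classOf <- c("background", geometry$organ_class)[organIndex + 1L]
  par <- specs[classOf, ]
  scl <- rep(1, length(classOf))
  if (!is.null(organScale)) {
    hit <- classOf %in% names(organScale)
    scl[hit] <- organScale[classOf[hit]]
  }
  withSeed(seed, {
    n <- prod(dims)
    het <- function(base) pmax(base * (1 + par$heterogeneity_sigma *
                                         stats::rnorm(n)), 0.05 * base)
    list(
      adc   = array(het(par$adc_true * scl), dims),
      s0    = array(het(par$s0), dims),
      t2w   = array(het(par$t2w_mean * scl), dims),
      f     = array(par$f, dims),
      dstar = array(par$d_star, dims),
      organIndex = organIndex,
      spacing = spacing, dims = dims
    )
  })
}

#' Build a homogeneous spherical phantom tissue map
#'
#' A PVP-solution-like sphere whose true ADC follows the linear temperature
#' model ADC(T) = ADC20 * (1 + alpha (T - 20)); outside the sphere the signal
#' is zero (air).
#'
#' @param dims,spacing grid geometry; defaults give a ~218 x 218 x 80 mm
#'   volume.
#' @param diameter sphere diameter in mm (default 200).
#' @param adc20 ADC of the solution at 20 degrees C, in um^2/s.
#' @param temperature phantom temperature in degrees C.
#' @param alpha fractional ADC change per degree C.
#' @param s0 baseline signal inside the sphere.
#' @param centerOffset optional (x, y, z) mm offset of the sphere center.
#' @return a tissue map list as in [makeVolunteerTissueMap()].
#' @export
makePhantomTissueMap <- function(dims = c(84, 84, 16),
                                 spacing = c(2.6, 2.6, 5),
                                 diameter = 200, adc20 = 1600,
                                 temperature = 20, alpha = 0.024,
                                 s0 = 1200, centerOffset = c(0, 0, 0)) {
  co <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing[a])
  ctr <- dims * spacing / 2 + centerOffset
  r2 <- outer(outer((co[[1]] - ctr[1])^2, (co[[2]] - ctr[2])^2, `+`),
              (co[[3]] - ctr[3])^2, `+`)
  inside <- r2 <= (diameter / 2)^2
  adcT <- adc20 * (1 + alpha * (temperature - 20))
  list(
    adc   = array(ifelse(inside, adcT, 2400), dims),
    s0    = array(ifelse(inside, s0, 0), dims),
    t2w   = array(ifelse(inside, 300, 0), dims),
    f     = array(0, dims),
    dstar = array(0, dims),
    organIndex = array(ifelse(inside, 1L, 0L), dims),
    spacing = spacing, dims = dims
  )
}

#' Simulate a diffusion-weighted series of a tissue map under a site profile
#'
#' Per-voxel noiseless signal
#' \deqn{S(b) = gain \cdot bias(x) \cdot S_0 [(1-f) e^{-b \cdot ADC} +
#'   f e^{-b D^*}]}{S(b) = gain * bias(x) * S0 * ((1-f) exp(-b ADC) + f exp(-b D*))}
#' with ADC and D* in um^2/s (converted internally to mm^2/s), followed by
#' Rician (magnitude) noise of scale \code{noise_sigma / sqrt(averages_b)}
#' per b-value volume. With zero noise, zero perfusion fraction, zero bias
#' amplitude and unit gain the decay is exactly monoexponential.
#'
#' @param tissueMap a tissue map from [makeVolunteerTissueMap()] or
#'   [makePhantomTissueMap()].
#' @param site one manifest row (see [generateSiteManifest()]).
#' @param acq an [acquisitionSpec()] with modality \code{"dwi"}.
#' @param seed integer seed for the noise draws.
#' @return a [DWISeries-class].
#' @export
simulateDWI <- function(tissueMap, site, acq = defaultAcquisition(),
                        seed = 1) {
  assertThat(acq$modality == "dwi", "acquisition modality must be 'dwi'")
  dims <- tissueMap$dims
  assertThat(identical(dim(tissueMap$adc), as.integer(dims)) ||
               identical(dim(tissueMap$adc), dims),
             "tissue map arrays and dims disagree (shape error)")
  bias <- biasField(dims, site$bias_amplitude)
  base <- site$gain * bias * tissueMap$s0
  vols <- vector("list", length(acq$bValues))
  for (k in seq_along(acq$bValues)) {
    b <- acq$bValues[k]
    sig <- base * ((1 - tissueMap$f) * exp(-b * tissueMap$adc * 1e-6) +
                     tissueMap$f * exp(-b * tissueMap$dstar * 1e-6))
    sigma <- site$noise_sigma / sqrt(acq$averages[k])
    vols[[k]] <- withSeed(subSeed(seed, k), ricianNoise(sig, sigma))
  }
  new("DWISeries", volumes = vols, bValues = acq$bValues,
      averages = acq$averages, spacing = tissueMap$spacing,
      modality = "dwi")
}

#' Simulate a single-shot T2w-like gray-value volume
#'
#' Voxel value = gain * bias(x) * t2w_mean(x) + Gaussian noise of scale
#' \code{noise_sigma}; a gray-value surrogate for a fast T2-weighted
#' structural sequence whose intensities are in arbitrary units (which is
#' what makes cross-site histogram matching necessary).
#'
#' @inheritParams simulateDWI
#' @return a [DWISeries-class] with modality \code{"t2w"} and a single
#'   volume.
#' @export
simulateT2w <- function(tissueMap, site, seed = 1) {
  dims <- tissueMap$dims
  bias <- biasField(dims, site$bias_amplitude)
  sig <- site$gain * bias * tissueMap$t2w
  vol <- withSeed(subSeed(seed, 101L), {
    if (site$noise_sigma > 0)
      array(pmax(sig + stats::rnorm(length(sig), 0, site$noise_sigma), 0),
            dims)
    else sig
  })
  new("DWISeries", volumes = list(vol), bValues = 0, averages = 1,
      spacing = tissueMap$spacing, modality = "t2w")
}

#' Rasterize the circular ROI masks
#'
#' Builds the labeled mask volume for a ROI geometry: for each position, a
#' 2D disc of nominal area 250 mm^2 (radius sqrt(250/pi) ~ 8.92 mm) on the
#' slice nearest the configured z. Discs are rasterized as the
#' \code{round(area / pixelArea)} pixel centers nearest the disc center, so
#' the rasterized area stays within half a pixel of the nominal area for any
#' in-plane spacing up to the disc radius.
#'
#' @param geometry ROI layout (see [defaultROIGeometry()]); may carry jitter.
#' @param spacing voxel spacing in mm.
#' @param dims grid size in voxels.
#' @param nominalArea disc area in mm^2 (default 250).
#' @return an [ROISet-class].
#' @export
makeROIMasks <- function(geometry = defaultROIGeometry(),
                         spacing = c(2.6, 2.6, 5),
                         dims = c(52, 52, 10),
                         nominalArea = 250) {
  radius <- sqrt(nominalArea / pi)
  assertThat(max(spacing[1:2]) <= radius,
             "in-plane spacing must not exceed the disc radius")
  # layout check: same-slice centers closer than one diameter overlap
  sl <- round(geometry$z_mm / spacing[3] + 0.5)
  for (s in unique(sl)) {
    g <- geometry[sl == s, , drop = FALSE]
    if (nrow(g) > 1) {
      d <- as.matrix(stats::dist(g[, c("x_mm", "y_mm")]))
      diag(d) <- Inf
      assertThat(min(d) >= 2 * radius,
                 "ROI centers overlap in-plane (layout error)")
    }
  }
  labels <- array(0L, dim = dims)
  xs <- (seq_len(dims[1]) - 0.5) * spacing[1]
  ys <- (seq_len(dims[2]) - 0.5) * spacing[2]
  nPix <- round(nominalArea / (spacing[1] * spacing[2]))
  for (i in seq_len(nrow(geometry))) {
    g <- geometry[i, ]
    k <- max(1L, min(dims[3], as.integer(round(g$z_mm / spacing[3] + 0.5))))
    d2 <- outer((xs - g$x_mm)^2, (ys - g$y_mm)^2, `+`)
    ord <- order(d2)[seq_len(nPix)]
    slice <- labels[, , k]
    assertThat(all(slice[ord] == 0L), "ROI masks overlap (layout error)")
    slice[ord] <- g$label
    labels[, , k] <- slice
  }
  organ <- geometry$organ_class
  names(organ) <- geometry$name
  new("ROISet", labels = labels, labelNames = geometry$name,
      organOfLabel = organ, spacing = spacing,
      nominalAreaMm2 = nominalArea)
}

# In-plane jitter of ROI centers: uniform in a disc of radius maxShift (mm).
jitterGeometry <- function(geometry, maxShift = 3, seed = 1) {
  withSeed(seed, {
    n <- nrow(geometry)
    r <- maxShift * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    geometry$x_mm <- geometry$x_mm + r * cos(th)
    geometry$y_mm <- geometry$y_mm + r * sin(th)
    geometry
  })
}

#' Generate a complete multi-site study
#'
#' Generates the synthetic dataset for one of the three study designs:
#' \describe{
#'   \item{\code{"phantom"}}{one homogeneous-sphere DWI series per site, each
#'     at a seeded site temperature (default spread 18-24 degrees C).}
#'   \item{\code{"test_retest"}}{per site, a site-specific volunteer imaged
#'     twice with independent noise and a small (<= 3 mm) seeded ROI
#'     placement jitter between the two acquisitions.}
#'   \item{\code{"traveling_volunteer"}}{one fixed volunteer tissue map
#'     imaged under every site profile (per-site ROI jitter, reference site
#'     unjittered).}
#' }
#' When \code{outDir} is given, each volume is written as one NIfTI file per
#' b-value plus a JSON dataset index (\code{index.json}) recording b-values,
#' averages, site metadata and temperatures.
#'
#' @param manifest a site manifest (see [generateSiteManifest()]).
#' @param scenario one of \code{"phantom"}, \code{"test_retest"},
#'   \code{"traveling_volunteer"}.
#' @param seed integer master seed.
#' @param outDir optional output directory; created if missing.
#' @param temperatureRange phantom temperature range, degrees C.
#' @param alpha fractional ADC change per degree C used by the phantom.
#' @return a list with the generated objects (\code{manifest},
#'   \code{scenario}, per-site entries in \code{sites}, and for the
#'   traveling scenario the shared \code{tissueMap}); written file paths are
#'   recorded in \code{index} when \code{outDir} is used.
#' @export
generateStudy <- function(manifest, scenario = c("phantom", "test_retest",
                                                 "traveling_volunteer"),
                          seed = 1, outDir = NULL,
                          temperatureRange = c(18, 24), alpha = 0.024) {
  scenario <- match.arg(scenario)
  validateManifest(manifest)
  nS <- nrow(manifest)
  out <- list(scenario = scenario, manifest = manifest, sites = list())

  if (scenario == "phantom") {
    temps <- withSeed(subSeed(seed, 7L),
                      stats::runif(nS, temperatureRange[1],
                                   temperatureRange[2]))
    for (i in seq_len(nS)) {
      site <- manifest[i, ]
      tm <- makePhantomTissueMap(temperature = temps[i], alpha = alpha)
      acq <- defaultAcquisition(includeB0 = site$includes_b0)
      dwi <- simulateDWI(tm, site, acq, seed = subSeed(seed, 100L + i))
      out$sites[[site$site_id]] <- list(site_id = site$site_id,
                                        temperature = temps[i], dwi = dwi)
    }
  } else if (scenario == "test_retest") {
    geo <- defaultROIGeometry()
    for (i in seq_len(nS)) {
      site <- manifest[i, ]
      # a different volunteer per site: +/- ~5% organ-level offsets
      organScale <- withSeed(subSeed(seed, 200L + i), {
        s <- exp(stats::rnorm(5, 0, 0.05))
        names(s) <- c("kidney", "liver", "spleen", "muscle", "vertebra")
        s
      })
      tm <- makeVolunteerTissueMap(seed = subSeed(seed, 300L + i),
                                   organScale = organScale)
      acq <- defaultAcquisition(includeB0 = site$includes_b0)
      tps <- list()
      for (t in 1:2) {
        g <- if (t == 1) geo else jitterGeometry(geo, 3,
                                                 subSeed(seed, 400L + i))
        tps[[paste0("t", t)]] <- list(
          dwi = simulateDWI(tm, site, acq,
                            seed = subSeed(seed, 500L + 10L * i + t)),
          t2w = simulateT2w(tm, site,
                            seed = subSeed(seed, 600L + 10L * i + t)),
          rois = makeROIMasks(g, tm$spacing, tm$dims)
        )
      }
      out$sites[[site$site_id]] <- list(site_id = site$site_id,
                                        timepoints = tps)
    }
  } else {
    geo <- defaultROIGeometry()
    tm <- makeVolunteerTissueMap(seed = subSeed(seed, 42L))
    out$tissueMap <- tm
    for (i in seq_len(nS)) {
      site <- manifest[i, ]
      acq <- defaultAcquisition(includeB0 = site$includes_b0)
      g <- if (site$is_reference) geo
           else jitterGeometry(geo, 3, subSeed(seed, 700L + i))
      out$sites[[site$site_id]] <- list(
        site_id = site$site_id,
        dwi = simulateDWI(tm, site, acq, seed = subSeed(seed, 800L + i)),
        t2w = simulateT2w(tm, site, seed = subSeed(seed, 900L + i)),
        rois = makeROIMasks(g, tm$spacing, tm$dims)
      )
    }
  }
  if (!is.null(outDir)) out$index <- writeStudy(out, outDir)
  out
}

# ---- on-disk layout: one NIfTI per b-value + JSON index --------------------

writeVolume <- function(vol, spacing, path) {
  im <- RNifti::asNifti(vol)
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path)
  path
}

writeSeries <- function(series, dir, stem) {
  files <- character(length(series@bValues))
  for (k in seq_along(series@bValues)) {
    files[k] <- file.path(dir, sprintf("%s_b%d.nii.gz", stem,
                                       as.integer(series@bValues[k])))
    writeVolume(series@volumes[[k]], series@spacing, files[k])
  }
  list(files = basename(files), b_values = series@bValues,
       averages = series@averages, modality = series@modality)
}

#' Write a generated study to disk
#'
#' NIfTI volumes (one file per b-value) plus \code{index.json} with all
#' metadata needed to reload the dataset.
#'
#' @param study output of [generateStudy()].
#' @param outDir output directory (created if needed).
#' @return the index structure, invisibly.
#' @export
writeStudy <- function(study, outDir) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE)
  assertThat(ok && file.access(outDir, 2) == 0,
             sprintf("cannot write to '%s' (I/O error)", outDir))
  idx <- list(scenario = study$scenario,
              manifest = study$manifest, sites = list())
  for (sid in names(study$sites)) {
    s <- study$sites[[sid]]
    sdir <- file.path(outDir, sid)
    dir.create(sdir, showWarnings = FALSE)
    entry <- list(site_id = sid)
    if (!is.null(s$temperature)) entry$temperature <- s$temperature
    if (!is.null(s$dwi)) entry$dwi <- writeSeries(s$dwi, sdir, "dwi")
    if (!is.null(s$t2w)) entry$t2w <- writeSeries(s$t2w, sdir, "t2w")
    if (!is.null(s$rois)) {
      writeVolume(s$rois@labels, s$rois@spacing,
                  file.path(sdir, "rois.nii.gz"))
      entry$rois <- list(file = "rois.nii.gz",
                         label_names = s$rois@labelNames,
                         organ_of_label = unname(s$rois@organOfLabel))
    }
    if (!is.null(s$timepoints)) {
      entry$timepoints <- lapply(names(s$timepoints), function(tp) {
        tdir <- file.path(sdir, tp)
        dir.create(tdir, showWarnings = FALSE)
        e <- list(timepoint = tp,
                  dwi = writeSeries(s$timepoints[[tp]]$dwi, tdir, "dwi"),
                  t2w = writeSeries(s$timepoints[[tp]]$t2w, tdir, "t2w"))
        writeVolume(s$timepoints[[tp]]$rois@labels,
                    s$timepoints[[tp]]$rois@spacing,
                    file.path(tdir, "rois.nii.gz"))
        e$rois <- list(file = "rois.nii.gz",
                       label_names = s$timepoints[[tp]]$rois@labelNames,
                       organ_of_label =
                         unname(s$timepoints[[tp]]$rois@organOfLabel))
        e
      })
      names(entry$timepoints) <- names(s$timepoints)
    }
    idx$sites[[sid]] <- entry
  }
  jsonlite::write_json(idx, file.path(outDir, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(idx)
}

readSeries <- function(dir, meta) {
  vols <- lapply(file.path(dir, meta$files), function(f) {
    v <- RNifti::readNifti(f)
    array(as.numeric(v), dim = dim(v))
  })
  sp <- RNifti::pixdim(RNifti::readNifti(file.path(dir, meta$files[[1]])))
  new("DWISeries", volumes = vols, bValues = as.numeric(meta$b_values),
      averages = as.numeric(meta$averages), spacing = as.numeric(sp[1:3]),
      modality = meta$modality)
}

readROISet <- function(dir, meta) {
  v <- RNifti::readNifti(file.path(dir, meta$file))
  organ <- unlist(meta$organ_of_label)
  names(organ) <- unlist(meta$label_names)
  new("ROISet", labels = array(as.integer(v), dim = dim(v)),
      labelNames = unlist(meta$label_names), organOfLabel = organ,
      spacing = as.numeric(RNifti::pixdim(v)[1:3]), nominalAreaMm2 = 250)
}

#' Read a study written by [writeStudy()]
#'
#' @param dir directory holding \code{index.json}.
#' @return a study list in the same structure as [generateStudy()] output.
#' @export
readStudy <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"))
  out <- list(scenario = idx$scenario,
              manifest = do.call(rbind, lapply(idx$manifest, function(r)
                as.data.frame(r, stringsAsFactors = FALSE))),
              sites = list())
  for (sid in names(idx$sites)) {
    e <- idx$sites[[sid]]
    sdir <- file.path(dir, sid)
    s <- list(site_id = sid)
    if (!is.null(e$temperature)) s$temperature <- e$temperature
    if (!is.null(e$dwi)) s$dwi <- readSeries(sdir, e$dwi)
    if (!is.null(e$t2w)) s$t2w <- readSeries(sdir, e$t2w)
    if (!is.null(e$rois)) s$rois <- readROISet(sdir, e$rois)
    if (!is.null(e$timepoints)) {
      s$timepoints <- lapply(e$timepoints, function(tp) {
        tdir <- file.path(sdir, tp$timepoint)
        list(dwi = readSeries(tdir, tp$dwi),
             t2w = readSeries(tdir, tp$t2w),
             rois = readROISet(tdir, tp$rois))
      })
    }
    out$sites[[sid]] <- s
  }
  out
}
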