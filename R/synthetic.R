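#' Scenario for one synthetic multispectral photograph
#'
#' Describes the generating truth for a rendered scene: the carapace's mean
#' channel reflectances, the pattern's length scale and contrast, sensor
#' noise, the camera's power-law response and the ambient illumination, and
#' the in-frame 40% grey standard. All generators driven by a scenario are
#' seed-deterministic and return their truth record alongside the image.
#'
#' @param width,height raster size in pixels.
#' @param base_quad named vector of mean carapace reflectances `LW`, `MW`,
#'   `SW`, `UV` on the 0--255 value scale (255 = 100% reflectance).
#' @param pattern_scale dominant marking size (spatial period) in pixels.
#' @param pattern_contrast peak-to-peak pattern amplitude on the value
#'   scale; 0 renders a featureless carapace.
#' @param noise_sd Gaussian sensor noise SD on the raw 0--255 scale.
#' @param camera_exponent `g` in the camera response
#'   `value = 255 * radiance^(1/g)`; 1 is a linear sensor, ~2.2 typical.
#' @param illumination global illumination factor relative to the
#'   reference exposure.
#' @param standard_reflectance reflectance of the in-frame grey standard.
#' @param ruler_scale pixels per mm.
#' @param seed integer seed.
#' @return An `image_scenario` list.
#' @export
image_scenario <- function(width = 256, height = 256,
                           base_quad = c(LW = 120, MW = 60, SW = 20, UV = 40),
                           pattern_scale = 16, pattern_contrast = 20,
                           noise_sd = 1, camera_exponent = 2.2,
                           illumination = 1, standard_reflectance = 0.40,
                           ruler_scale = 10, seed = 1) {
  stopifnot(pattern_scale >= 2, pattern_contrast >= 0, noise_sd >= 0,
            camera_exponent > 0, illumination > 0,
            standard_reflectance > 0, standard_reflectance <= 1)
  if (!setequal(names(base_quad), CHANNELS)) {
    stop("base_quad must be named LW, MW, SW, UV", call. = FALSE)
  }
  structure(as.list(environment()), class = "image_scenario")
}

# camera forward model: reflectance fraction -> raw 0-255 value
camera_response <- function(reflectance, scenario) {
  radiance <- pmax(scenario$illumination * reflectance, 0)
  pmin(255 * radiance^(1 / scenario$camera_exponent), 255)
}

add_sensor_noise <- function(raster, noise_sd) {
  if (noise_sd <= 0) return(raster)
  pmin(pmax(raster + stats::rnorm(length(raster), 0, noise_sd), 0), 255)
}

#' Band-limited blob texture
#'
#' Mottled, carapace-like binary texture with a controllable dominant
#' length scale: white noise is band-pass filtered to a half-octave annulus
#' around the target spatial period and thresholded at zero, giving a field
#' of +/- 0.5.
#'
#' @param nrow,ncol raster size.
#' @param scale target spatial period in pixels.
#' @param binary threshold to +/- 0.5 blobs (default) or keep the smooth
#'   band-limited field (unit SD).
#' @return Numeric matrix; zero mean up to discretization.
#' @export
blob_texture <- function(nrow, ncol, scale, binary = TRUE) {
  n <- 2^ceiling(log2(max(nrow, ncol)))
  noise <- matrix(stats::rnorm(n * n), n, n)
  freq <- fft_radial_freq(n)
  keep <- freq > 1 / (scale * 2^0.25) & freq <= 1 / (scale / 2^0.25)
  ft <- stats::fft(noise)
  ft[!keep] <- 0
  field <- Re(stats::fft(ft, inverse = TRUE)) / length(ft)
  field <- field[seq_len(nrow), seq_len(ncol), drop = FALSE]
  field <- field / stats::sd(field)
  if (binary) ifelse(field >= 0, 0.5, -0.5) else field
}

ladder_reflectances <- function() c(0.02, 0.05, 0.10, 0.20, 0.40, 0.60, 0.80, 0.99)

#' Render a calibration scene with an embedded grey-standard ladder
#'
#' A flat background with eight neutral grey patches spanning 2--99%
#' reflectance plus the 40% working standard, passed through the
#' scenario's camera nonlinearity, illumination and sensor noise. The
#' ladder table is *measured from the rendered image* (mean raw value per
#' patch and channel), exactly as it would be from a real calibration
#' photograph.
#'
#' @param scenario an [image_scenario()].
#' @return List with `raw` (a [msimage]), `ladder` (tibble `channel`,
#'   `reflectance`, `measured_value`), `patch_rois` (list of logical
#'   matrices, one per ladder step) and `truth` (generating parameters).
#' @export
make_calibration_scene <- function(scenario = image_scenario()) {
  stopifnot(inherits(scenario, "image_scenario"))
  set.seed(scenario$seed)
  refl <- ladder_reflectances()
  patch <- 24L
  gap <- 8L
  ncol_img <- length(refl) * (patch + gap) + gap
  nrow_img <- 3L * (patch + gap) + gap
  base <- matrix(0.20, nrow_img, ncol_img)
  patch_rois <- vector("list", length(refl))
  for (k in seq_along(refl)) {
    rows <- gap + seq_len(patch)
    cols <- gap + (k - 1L) * (patch + gap) + seq_len(patch)
    base[rows, cols] <- refl[k]
    roi <- matrix(FALSE, nrow_img, ncol_img)
    roi[rows, cols] <- TRUE
    patch_rois[[k]] <- roi
  }
  std_rows <- 2L * gap + patch + seq_len(patch)
  std_cols <- gap + seq_len(patch)
  standard_roi <- matrix(FALSE, nrow_img, ncol_img)
  standard_roi[std_rows, std_cols] <- TRUE
  base[std_rows, std_cols] <- scenario$standard_reflectance
  channels <- lapply(CHANNELS, function(ch) {
    add_sensor_noise(camera_response(base, scenario), scenario$noise_sd)
  })
  names(channels) <- CHANNELS
  raw <- msimage(channels, standard_roi = standard_roi,
                 ruler_scale = scenario$ruler_scale)
  ladder <- purrr::map_dfr(CHANNELS, function(ch) {
    tibble::tibble(
      channel = ch, reflectance = refl,
      measured_value = vapply(patch_rois, function(roi) {
        mean(raw$channels[[ch]][roi])
      }, numeric(1))
    )
  })
  list(raw = raw, ladder = ladder, patch_rois = patch_rois,
       truth = list(reflectances = refl, scenario = scenario))
}

#' Render one synthetic crab photograph
#'
#' An elliptical "carapace" filled with blob texture at the scenario's
#' length scale and contrast over the base channel reflectances, on a plain
#' background with the grey standard in one corner. The truth record holds
#' the expected colour metrics (from the base quad) and the dominant
#' marking size.
#'
#' @param scenario an [image_scenario()].
#' @return List with `raw` (a [msimage]), `roi_mask` (logical matrix) and
#'   `truth` (expected brightness, saturation, hue1, hue2, marking size,
#'   carapace width in mm, and the scenario).
#' @export
make_crab_image <- function(scenario = image_scenario()) {
  stopifnot(inherits(scenario, "image_scenario"))
  set.seed(scenario$seed)
  nr <- scenario$height
  nc <- scenario$width
  cy <- nr / 2; cx <- nc / 2
  a <- 0.36 * nr; b <- 0.30 * nc   # ellipse semi-axes (rows, cols)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  roi_mask <- ((rr - cy) / a)^2 + ((cc - cx) / b)^2 <= 1
  if (scenario$pattern_scale > 2 * min(a, b)) {
    warning("pattern length scale exceeds the carapace; ",
            "dominant marking size is unresolvable")
  }
  tex <- blob_texture(nr, nc, scenario$pattern_scale)
  pat <- matrix(0, nr, nc)
  pat[roi_mask] <- scenario$pattern_contrast * tex[roi_mask]
  std <- 16L
  standard_roi <- matrix(FALSE, nr, nc)
  standard_roi[4:(3 + std), 4:(3 + std)] <- TRUE
  channels <- lapply(CHANNELS, function(ch) {
    refl <- matrix(0.15 * 255, nr, nc)          # background
    refl[roi_mask] <- scenario$base_quad[[ch]]
    refl <- refl + pat                          # achromatic pattern
    refl[standard_roi] <- scenario$standard_reflectance * 255
    add_sensor_noise(camera_response(pmax(refl, 0) / 255, scenario),
                     scenario$noise_sd)
  })
  names(channels) <- CHANNELS
  raw <- msimage(channels, standard_roi = standard_roi,
                 ruler_scale = scenario$ruler_scale)
  q <- tibble::as_tibble(as.list(scenario$base_quad))
  cm <- colour_metrics(q)
  truth <- list(
    brightness = cm$brightness, saturation = cm$saturation,
    hue1 = cm$hue1, hue2 = cm$hue2,
    marking_size = scenario$pattern_scale,
    pattern_resolvable = scenario$pattern_contrast > 0 &&
      scenario$pattern_scale <= 2 * min(a, b),
    carapace_width_mm = 2 * b / scenario$ruler_scale,
    scenario = scenario
  )
  list(raw = raw, roi_mask = roi_mask, truth = truth)
}

#' Scenario for a synthetic cohort of crabs
#'
#' Emulates the structure of the field dataset: one row per crab with site
#' (4 levels), shore zone (3 levels), sex, carapace width in mm, and the
#' six appearance metrics, with site- and life-stage-dependent means and
#' stage-dependent variance (juveniles more variable than adults).
#' Defaults mirror the field design: about three times as many juveniles
#' as adults per site, juveniles brighter, more saturated, with higher
#' proportion energy and smaller markings than adults, and a juvenile SD
#' inflation of 1.5.
#'
#' @param n_juvenile,n_adult crabs per site and stage.
#' @param sites,zones factor levels.
#' @param base_means named mean vector of the six metrics for adults at
#'   the reference site.
#' @param sds named per-metric SDs (adults).
#' @param juvenile_sd_inflation multiplier on SDs for juveniles.
#' @param site_effect_adult,site_effect_juvenile multipliers on the
#'   per-site mean offsets (in adult-SD units) for each stage; 0 makes all
#'   site means equal for that stage.
#' @param stage_shift named per-metric juvenile minus adult mean shift in
#'   adult-SD units.
#' @return A `cohort_scenario` list.
#' @export
cohort_scenario <- function(n_juvenile = 120, n_adult = 42,
                            sites = paste0("S", 1:4),
                            zones = c("low", "middle", "upper"),
                            base_means = c(hue = 1.10, saturation = 0.060,
                                           brightness = 60, marking_size = 20,
                                           total_energy = 150,
                                           proportion_energy = 0.25),
                            sds = c(hue = 0.15, saturation = 0.015,
                                    brightness = 10, marking_size = 6,
                                    total_energy = 40,
                                    proportion_energy = 0.05),
                            juvenile_sd_inflation = 1.5,
                            site_effect_adult = 1,
                            site_effect_juvenile = 1,
                            stage_shift = c(hue = 0.3, saturation = 1.2,
                                            brightness = 1.2,
                                            marking_size = -1.3,
                                            total_energy = 0.5,
                                            proportion_energy = 1.1)) {
  stopifnot(n_juvenile >= 2, n_adult >= 2, length(sites) >= 2,
            juvenile_sd_inflation > 0, all(sds > 0))
  stopifnot(setequal(names(base_means), PHENOTYPE_METRICS),
            setequal(names(sds), PHENOTYPE_METRICS),
            setequal(names(stage_shift), PHENOTYPE_METRICS))
  structure(as.list(environment()), class = "cohort_scenario")
}

# per-site mean offsets in SD units, one distinct direction per site
site_patterns <- function(n_sites) {
  base <- rbind(
    c( 0,  0,  0,  0,  0,  0),
    c( 1,  0, -1,  0,  1,  0),
    c(-1,  1,  0,  1,  0, -1),
    c( 0, -1,  1, -1, -1,  1)
  ) * 0.5
  base[rep_len(seq_len(nrow(base)), n_sites), , drop = FALSE]
}

#' Generate a synthetic cohort table with known ground truth
#'
#' Draws each site x stage cell from a multivariate normal (diagonal
#' covariance) around the scenario's cell means, clips metrics to their
#' physical ranges (non-negative energies, saturation at most the vertex
#' distance, proportion energy in (0, 1]), and draws carapace widths per
#' stage so the 25-mm rule separates juveniles from adults. Zone and sex
#' are assigned at random.
#'
#' @param scenario a [cohort_scenario()].
#' @param seed integer seed.
#' @return List with `cohort` (tibble: `id`, `site`, `zone`, `sex`,
#'   `carapace_width_mm`, `stage`, and the six metrics) and `truth`
#'   (tibble of generating cell means and SDs, plus the scenario).
#' @export
make_cohort <- function(scenario = cohort_scenario(), seed = 1) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  set.seed(seed)
  mets <- PHENOTYPE_METRICS
  sdv <- scenario$sds[mets]
  pat <- site_patterns(length(scenario$sites))
  cells <- tidyr::expand_grid(site = scenario$sites,
                              stage = c("adult", "juvenile"))
  rows <- list(); truth_rows <- list()
  for (i in seq_len(nrow(cells))) {
    site <- cells$site[i]; stage <- cells$stage[i]
    si <- match(site, scenario$sites)
    eff <- if (stage == "adult") scenario$site_effect_adult else
      scenario$site_effect_juvenile
    mu <- scenario$base_means[mets] + eff * pat[si, ] * sdv
    if (stage == "juvenile") mu <- mu + scenario$stage_shift[mets] * sdv
    sd_cell <- sdv * if (stage == "juvenile") scenario$juvenile_sd_inflation else 1
    n <- if (stage == "juvenile") scenario$n_juvenile else scenario$n_adult
    m <- sapply(seq_along(mets), function(j) stats::rnorm(n, mu[j], sd_cell[j]))
    colnames(m) <- mets
    m[, "hue"] <- pmax(m[, "hue"], 1e-3)
    m[, "saturation"] <- pmin(pmax(m[, "saturation"], 0), 0.75)
    m[, "brightness"] <- pmax(m[, "brightness"], 1e-3)
    m[, "marking_size"] <- pmax(m[, "marking_size"], 2)
    m[, "total_energy"] <- pmax(m[, "total_energy"], 1e-3)
    m[, "proportion_energy"] <- pmin(pmax(m[, "proportion_energy"], 1e-3), 1)
    cw <- if (stage == "adult") {
      pmin(pmax(stats::rnorm(n, 35, 7), 25), 60)
    } else {
      pmin(pmax(stats::rnorm(n, 15, 5), 5), 24.9)
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(site = site,
                     zone = sample(scenario$zones, n, replace = TRUE),
                     sex = sample(c("F", "M"), n, replace = TRUE),
                     carapace_width_mm = cw,
                     stage = stage),
      tibble::as_tibble(m)
    )
    truth_rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(site = site, stage = stage, n = n),
      tibble::as_tibble(as.list(stats::setNames(mu, paste0("mean_", mets)))),
      tibble::as_tibble(as.list(stats::setNames(sd_cell, paste0("sd_", mets))))
    )
  }
  cohort <- dplyr::bind_rows(rows)
  cohort$id <- sprintf("crab%04d", seq_len(nrow(cohort)))
  cohort$stage <- factor(cohort$stage, levels = c("adult", "juvenile"))
  cohort <- dplyr::relocate(cohort, "id")
  list(cohort = cohort,
       truth = list(cells = dplyr::bind_rows(truth_rows),
                    scenario = scenario, seed = seed))
}
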