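#' Fit the camera linearization curve from a grey-standard ladder
#'
#' Cameras respond nonlinearly to light, so raw image values must be mapped
#' back to a linear (reflectance-proportional) scale before any colour
#' measurement. The mapping is fitted per channel from photographs of a
#' ladder of grey standards of known reflectance (nominally eight Spectralon
#' standards spanning 2--99%) as a monotone power law
#' `value = a * reflectance^b`, by least squares on the log-log scale.
#'
#' @param ladder data frame with columns `channel` (LW/MW/SW/UV),
#'   `reflectance` (fraction in (0, 1]) and `measured_value` (mean raw pixel
#'   value, 0--255).
#' @return A `response_curve`: a tibble with one row per channel and columns
#'   `channel`, `a`, `b`, `r_squared` (R^2 of linearized value against
#'   reflectance) and `rmse` (residual summary on the raw scale).
#' @examples
#' r <- c(0.02, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 0.99)
#' ladder <- tidyr::expand_grid(channel = c("LW", "MW", "SW", "UV"),
#'                              reflectance = r)
#' ladder$measured_value <- 255 * ladder$reflectance^(1 / 2.2)
#' fit_linearization(ladder)
#' @export
fit_linearization <- function(ladder) {
  stopifnot(all(c("channel", "reflectance", "measured_value") %in% names(ladder)))
  fits <- ladder |>
    dplyr::group_by(.data$channel) |>
    dplyr::arrange(.data$reflectance, .by_group = TRUE) |>
    dplyr::group_modify(~ fit_one_channel(.x)) |>
    dplyr::ungroup()
  structure(fits, class = c("response_curve", class(fits)))
}

fit_one_channel <- function(pts, saturation_limit = 250) {
  if (nrow(pts) < 3L) {
    stop("need at least 3 ladder points per channel", call. = FALSE)
  }
  if (any(diff(pts$reflectance) <= 0)) {
    stop("ladder reflectances must be strictly increasing", call. = FALSE)
  }
  if (any(pts$measured_value < 0)) {
    stop("measured ladder values must be non-negative", call. = FALSE)
  }
  # points near the 8-bit ceiling are clipped (overexposed) and carry no
  # response information; zero points carry none on the log scale
  unsat <- pts$measured_value < saturation_limit
  if (any(diff(pts$measured_value[unsat]) < -2.55)) {
    stop("ladder is non-monotone: measured values decrease with reflectance ",
         "by more than 1% of scale; re-photograph the standards or check ",
         "channel assignment", call. = FALSE)
  }
  use <- pts$measured_value > 0 & unsat
  if (sum(use) < 3L) {
    stop("too few unsaturated positive ladder values to fit", call. = FALSE)
  }
  fit <- stats::lm(log(measured_value) ~ log(reflectance), data = pts[use, ])
  b <- unname(stats::coef(fit)[2])
  a <- exp(unname(stats::coef(fit)[1]))
  if (b <= 0) stop("fitted response is non-increasing", call. = FALSE)
  lin <- linearize_values(pts$measured_value[use], a, b)
  r2 <- stats::cor(lin, pts$reflectance[use])^2
  pred <- a * pts$reflectance[use]^b
  tibble::tibble(a = a, b = b, r_squared = r2,
                 rmse = sqrt(mean((pts$measured_value[use] - pred)^2)))
}

# invert value = a * r^b; returns 255 * r_hat (linear 0-255 scale)
linearize_values <- function(v, a, b) {
  255 * (pmax(v, 0) / a)^(1 / b)
}

#' @export
print.response_curve <- function(x, ...) {
  cat("<response_curve> value = a * reflectance^b per channel\n")
  NextMethod()
}

#' Map a raw multispectral image through its fitted response curve
#'
#' Each pixel is passed through its channel's inverse response so that the
#' output is proportional to scene radiance (and, after equalization,
#' reflectance). Pixel ordering is preserved per channel. Raw values at the
#' 8-bit ceiling (255) are flagged as saturated and later excluded from ROI
#' means, the numeric analogue of avoiding specular highlights.
#'
#' @param raw a [msimage] in the raw camera domain.
#' @param curve a `response_curve` from [fit_linearization()].
#' @return A [msimage] in the linear domain with a `saturated` attribute
#'   (logical matrix).
#' @export
linearize <- function(raw, curve) {
  stopifnot(inherits(raw, "msimage"), inherits(curve, "response_curve"))
  if (isTRUE(raw$linear)) stop("image is already linearized", call. = FALSE)
  rng <- range(unlist(lapply(raw$channels, range)))
  if (rng[1] < 0 || rng[2] > 255) {
    stop("raw values outside [0, 255]", call. = FALSE)
  }
  if (!setequal(curve$channel, CHANNELS)) {
    stop("response curve must cover all four channels", call. = FALSE)
  }
  saturated <- Reduce(`|`, lapply(raw$channels, function(m) m >= 255))
  channels <- lapply(CHANNELS, function(ch) {
    row <- curve[curve$channel == ch, ]
    linearize_values(raw$channels[[ch]], row$a, row$b)
  })
  names(channels) <- CHANNELS
  out <- msimage(channels, standard_roi = raw$standard_roi,
                 ruler_scale = raw$ruler_scale, linear = TRUE)
  attr(out, "saturated") <- saturated
  out
}

#' Equalize to the grey standard and scale to reflectance
#'
#' Rescales each linearized channel so that the mean over the in-frame grey
#' standard equals its known reflectance on the 0--255 scale (a 40% standard
#' reads 0.40 x 255 = 102). This removes ambient-illumination differences
#' between photographs: the calibrated image reports the physical
#' reflectance of the scene.
#'
#' @param linear a linear-domain [msimage] (or a `calibrated_msimage`, in
#'   which case the operation is idempotent).
#' @param standard_reflectance reflectance of the in-frame standard,
#'   fraction (default 0.40).
#' @param roi_mask optional logical matrix marking the carapace region.
#' @return A `calibrated_msimage`.
#' @export
equalize_and_scale <- function(linear, standard_reflectance = 0.40,
                               roi_mask = NULL) {
  if (inherits(linear, "calibrated_msimage")) {
    channels <- linear$channels
    standard_roi <- linear$standard_roi
    mm_per_pixel <- linear$mm_per_pixel
    saturated <- linear$saturated
    if (is.null(roi_mask)) roi_mask <- linear$roi_mask
  } else {
    stopifnot(inherits(linear, "msimage"))
    if (!isTRUE(linear$linear)) {
      stop("equalize_and_scale() expects a linearized image; run linearize()",
           call. = FALSE)
    }
    channels <- linear$channels
    standard_roi <- linear$standard_roi
    mm_per_pixel <- if (is.null(linear$ruler_scale)) NA_real_ else
      1 / linear$ruler_scale
    saturated <- attr(linear, "saturated")
  }
  stopifnot(standard_reflectance > 0, standard_reflectance <= 1)
  if (is.null(standard_roi) || !any(standard_roi)) {
    stop("standard_roi is empty; cannot equalize", call. = FALSE)
  }
  target <- standard_reflectance * 255
  channels <- lapply(channels, function(m) {
    std_mean <- mean(m[standard_roi])
    if (!is.finite(std_mean) || std_mean <= 0) {
      stop("grey-standard region is black in one channel; failed photograph?",
           call. = FALSE)
    }
    m * (target / std_mean)
  })
  new_calibrated_msimage(channels, mm_per_pixel = mm_per_pixel,
                         roi_mask = roi_mask, standard_roi = standard_roi,
                         saturated = saturated)
}

#' Resize a calibrated image to the common spatial scale
#'
#' All crabs are brought to the same pixels-per-mm scale (default 10 px/mm)
#' using the ruler photographed in each frame, so that marking sizes are
#' comparable across individuals.
#'
#' @param img a `calibrated_msimage`.
#' @param target_mm_per_pixel target scale in mm per pixel (default 0.1,
#'   i.e. 10 px/mm).
#' @return A `calibrated_msimage` at the target scale.
#' @export
rescale_to_common_scale <- function(img, target_mm_per_pixel = 0.1) {
  stopifnot(inherits(img, "calibrated_msimage"), target_mm_per_pixel > 0)
  if (is.null(img$mm_per_pixel) || !is.finite(img$mm_per_pixel)) {
    stop("image has no ruler scale; cannot resize", call. = FALSE)
  }
  fac <- img$mm_per_pixel / target_mm_per_pixel
  if (abs(fac - 1) < 1e-9) return(img)
  d <- dim(img$channels$LW)
  nr <- max(2L, round(d[1] * fac))
  nc <- max(2L, round(d[2] * fac))
  resize_num <- function(m) EBImage::resize(m, w = nr, h = nc)
  resize_bool <- function(m) {
    if (is.null(m)) return(NULL)
    EBImage::resize(m * 1, w = nr, h = nc, filter = "none") > 0.5
  }
  new_calibrated_msimage(
    lapply(img$channels, resize_num),
    mm_per_pixel = target_mm_per_pixel,
    roi_mask = resize_bool(img$roi_mask),
    standard_roi = resize_bool(img$standard_roi),
    saturated = resize_bool(img$saturated)
  )
}

#' Measure the carapace region of interest
#'
#' Returns the per-channel mean reflectance over the carapace mask (the
#' `ChannelQuad` feeding the colour metrics) and the pattern raster: the
#' per-pixel brightness image with pixels outside the mask set to the masked
#' mean, ready for granularity analysis. Saturated pixels are excluded from
#' the channel means.
#'
#' @param img a `calibrated_msimage` with a non-empty `roi_mask`.
#' @param crop crop the pattern raster to the mask bounding box (default
#'   TRUE).
#' @return A list with `quad` (one-row tibble `LW`, `MW`, `SW`, `UV`),
#'   `pattern` (numeric matrix) and `mm_per_pixel`.
#' @export
extract_roi <- function(img, crop = TRUE) {
  stopifnot(inherits(img, "calibrated_msimage"))
  mask <- img$roi_mask
  if (is.null(mask) || !any(mask)) stop("ROI mask is empty", call. = FALSE)
  good <- mask
  if (!is.null(img$saturated)) good <- good & !img$saturated
  if (!any(good)) stop("every ROI pixel is saturated", call. = FALSE)
  quad <- tibble::as_tibble(lapply(img$channels, function(m) mean(m[good])))
  bright <- (img$channels$LW + img$channels$MW +
               img$channels$SW + img$channels$UV) / 4
  fill <- mean(bright[mask])
  pattern <- bright
  pattern[!mask] <- fill
  if (crop) {
    idx <- which(mask, arr.ind = TRUE)
    pattern <- pattern[min(idx[, 1]):max(idx[, 1]),
                       min(idx[, 2]):max(idx[, 2]), drop = FALSE]
  }
  list(quad = quad, pattern = pattern, mm_per_pixel = img$mm_per_pixel)
}

#' One-call calibration: linearize, equalize, rescale
#'
#' @param raw a raw-domain [msimage].
#' @param curve a `response_curve`.
#' @param standard_reflectance reflectance of the in-frame standard.
#' @param roi_mask optional carapace mask.
#' @param target_mm_per_pixel common scale; `NULL` to skip resizing.
#' @return A `calibrated_msimage`.
#' @export
calibrate_image <- function(raw, curve, standard_reflectance = 0.40,
                            roi_mask = NULL, target_mm_per_pixel = NULL) {
  cal <- equalize_and_scale(linearize(raw, curve),
                            standard_reflectance = standard_reflectance,
                            roi_mask = roi_mask)
  if (!is.null(target_mm_per_pixel)) {
    cal <- rescale_to_common_scale(cal, target_mm_per_pixel)
  }
  cal
}
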