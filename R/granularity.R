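#' Build the log-spaced ladder of marking-size bands
#'
#' The granularity analysis decomposes a pattern into spatial-scale bands
#' whose nominal marking sizes follow a half-octave geometric sequence:
#' starting at 2 px and multiplying by sqrt(2) (printed as 1.414) up to
#' 4096 px, sizes are `2 * 2^(k/2)` rounded to three significant figures,
#' giving 23 bands with the defaults. A "marking size of s pixels" means a
#' spatial period of s pixels.
#'
#' @param min_size smallest marking size in pixels (>= 2).
#' @param multiplier geometric step between sizes (> 1); 1.414 is treated
#'   as exactly sqrt(2) so the ladder terminates at `max_size`.
#' @param max_size largest marking size in pixels.
#' @return A `band_ladder`: list with `sizes` (pixels) and `period_edges`
#'   (length `length(sizes) + 1`; geometric midpoints between neighbouring
#'   sizes, open at both ends so the bands partition the whole spectrum).
#' @examples
#' build_ladder()$sizes
#' @export
build_ladder <- function(min_size = 2, multiplier = 1.414, max_size = 4096) {
  stopifnot(min_size >= 2, max_size > min_size)
  if (multiplier <= 1) stop("multiplier must be > 1", call. = FALSE)
  if (abs(multiplier - sqrt(2)) < 2e-3) multiplier <- sqrt(2)
  k <- 0:ceiling(log(max_size / min_size) / log(multiplier) + 1e-9)
  raw <- min_size * multiplier^k
  # whole-number sizes (the even half-octave steps: 2, 4, ..., 4096) stay
  # exact; intermediate sizes are rounded to 3 significant figures
  sizes <- ifelse(abs(raw - round(raw)) < 1e-6, round(raw), signif(raw, 3))
  sizes <- sizes[sizes <= max_size * (1 + 1e-9)]
  edges <- c(0, sqrt(sizes[-length(sizes)] * sizes[-1]), Inf)
  structure(list(sizes = sizes, period_edges = edges,
                 min_size = min_size, multiplier = multiplier,
                 max_size = max_size),
            class = "band_ladder")
}

#' @export
print.band_ladder <- function(x, ...) {
  cat(sprintf("<band_ladder> %d bands, %g to %g px (x%.4g)\n",
              length(x$sizes), min(x$sizes), max(x$sizes), x$multiplier))
  invisible(x)
}

# pad raster with its mean to a power-of-two square (preserves the mean, so
# the DC term and per-pixel variance bookkeeping stay exact)
pad_square_pow2 <- function(raster) {
  d <- dim(raster)
  n <- 2^ceiling(log2(max(d)))
  if (d[1] == n && d[2] == n) return(raster)
  out <- matrix(mean(raster), n, n)
  out[seq_len(d[1]), seq_len(d[2])] <- raster
  out
}

# radial spatial frequency (cycles/pixel) of each FFT bin of an n x n raster
fft_radial_freq <- function(n) {
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
  fx <- matrix(f, n, n)
  sqrt(fx^2 + t(fx)^2)
}

band_mask <- function(freq, ladder, band) {
  e <- ladder$period_edges
  lo_p <- e[band]       # smaller period bound (higher frequency edge)
  hi_p <- e[band + 1]
  f_hi <- if (lo_p == 0) Inf else 1 / lo_p
  f_lo <- if (is.infinite(hi_p)) 0 else 1 / hi_p
  freq > f_lo & freq <= f_hi & freq > 0
}

#' Band-pass filter a raster into one granularity band
#'
#' Ideal annular band-pass in the Fourier domain: only spatial periods
#' between the band's edges (geometric midpoints to the neighbouring ladder
#' sizes) are kept; the DC term is always removed, so the output is
#' zero-mean and constant rasters map to zero. The raster is first padded
#' with its mean to a power-of-two square; the returned raster has the
#' padded dimensions so that [band_energy()] of the output matches
#' [granularity_spectrum()] exactly.
#'
#' @param raster numeric matrix.
#' @param band band index into `ladder$sizes` (smallest size = 1).
#' @param ladder a `band_ladder`.
#' @return Zero-mean filtered matrix (padded dimensions).
#' @export
bandpass <- function(raster, band, ladder) {
  stopifnot(inherits(ladder, "band_ladder"),
            band >= 1, band <= length(ladder$sizes))
  if (any(!is.finite(raster))) stop("raster has non-finite pixels", call. = FALSE)
  x <- pad_square_pow2(raster)
  n <- nrow(x)
  ft <- stats::fft(x)
  keep <- band_mask(fft_radial_freq(n), ladder, band)
  ft[!keep] <- 0
  Re(stats::fft(ft, inverse = TRUE)) / length(ft)
}

#' Pattern energy of a filtered raster
#'
#' Energy is the sum of squared pixel values divided by the number of
#' pixels -- the variance contributed by the band's spatial scales.
#'
#' @param filtered matrix from [bandpass()].
#' @return Scalar energy.
#' @export
band_energy <- function(filtered) {
  if (length(filtered) == 0) stop("empty raster", call. = FALSE)
  sum(filtered^2) / length(filtered)
}

#' Granularity spectrum of a pattern raster
#'
#' One energy per ladder band, reported against marking size in pixels
#' (size, not spatial frequency, on the axis). Energies are computed in the
#' Fourier domain of the mean-padded square raster; by Parseval's theorem
#' this equals [band_energy()] of each [bandpass()] output, and because the
#' annuli partition the spectrum the energies sum exactly to the padded
#' raster's pixel variance.
#'
#' @param raster numeric matrix (the masked, mean-filled carapace
#'   brightness image).
#' @param ladder a `band_ladder` (default [build_ladder()]).
#' @param mm_per_pixel optional scale, carried into the result so marking
#'   sizes convert to mm.
#' @return A `granularity_spectrum`: tibble with columns `size` (px) and
#'   `energy`, plus attributes `mm_per_pixel` and `raster_variance`.
#' @export
granularity_spectrum <- function(raster, ladder = build_ladder(),
                                 mm_per_pixel = NA_real_) {
  stopifnot(inherits(ladder, "band_ladder"))
  if (any(!is.finite(raster))) stop("raster has non-finite pixels", call. = FALSE)
  x <- pad_square_pow2(raster)
  n <- nrow(x)
  pw <- Mod(stats::fft(x))^2 / length(x)^2   # per-pixel power by Parseval
  freq <- fft_radial_freq(n)
  energy <- vapply(seq_along(ladder$sizes), function(b) {
    sum(pw[band_mask(freq, ladder, b)])
  }, numeric(1))
  out <- tibble::tibble(size = ladder$sizes, energy = energy)
  attr(out, "mm_per_pixel") <- mm_per_pixel
  attr(out, "raster_variance") <- mean((x - mean(x))^2)
  class(out) <- c("granularity_spectrum", class(out))
  out
}

#' Summary pattern metrics of a granularity spectrum
#'
#' * `marking_size`: size of the maximum-energy band (dominant marking
#'   size), in pixels (and mm when the scale is known);
#' * `total_energy`: sum over bands -- overall pattern contrast;
#' * `proportion_energy`: maximum band energy / total -- how strongly one
#'   marking size dominates.
#'
#' @param spectrum a `granularity_spectrum`.
#' @return One-row tibble with `marking_size`, `marking_size_mm`,
#'   `total_energy`, `proportion_energy`.
#' @export
spectrum_metrics <- function(spectrum) {
  stopifnot(inherits(spectrum, "granularity_spectrum"))
  tot <- sum(spectrum$energy)
  if (tot <= 0) {
    stop("all-zero granularity spectrum: pattern metrics undefined for a ",
         "featureless image", call. = FALSE)
  }
  i <- which.max(spectrum$energy)
  mmpp <- attr(spectrum, "mm_per_pixel")
  tibble::tibble(
    marking_size = spectrum$size[i],
    marking_size_mm = if (is.null(mmpp)) NA_real_ else spectrum$size[i] * mmpp,
    total_energy = tot,
    proportion_energy = spectrum$energy[i] / tot
  )
}

#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.granularity_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Marking size (px)", y = "Pattern energy",
                  title = "Granularity spectrum") +
    ggplot2::theme_minimal()
}
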