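#' Multispectral image containers
#'
#' A `msimage` holds the four camera channels (LW, MW, SW, UV) of one
#' photograph as numeric matrices on the 0--255 raw scale, together with the
#' pixel region of the in-frame grey reflectance standard and the spatial
#' scale measured from the ruler in the frame. A `calibrated_msimage` is the
#' reflectance-scaled result of [calibrate_image()], where a value of 255
#' means 100% reflectance.
#'
#' @param channels named list of four numeric matrices (`LW`, `MW`, `SW`,
#'   `UV`), identical dimensions, values in `[0, 255]`.
#' @param standard_roi logical matrix marking the grey-standard pixels, same
#'   dimensions as the channels (or `NULL` if no standard is in frame).
#' @param ruler_scale pixels per mm, from the ruler in the image.
#' @param linear logical; `TRUE` once the camera response has been inverted.
#' @return An object of class `msimage`.
#' @export
msimage <- function(channels, standard_roi = NULL, ruler_scale = NULL,
                    linear = FALSE) {
  stopifnot(is.list(channels))
  if (!setequal(names(channels), CHANNELS)) {
    stop("channels must be named LW, MW, SW, UV", call. = FALSE)
  }
  channels <- channels[CHANNELS]
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) {
    stop("all four channel rasters must have identical dimensions", call. = FALSE)
  }
  rng <- range(unlist(lapply(channels, range)))
  if (!linear && (rng[1] < 0 || rng[2] > 255)) {
    stop("raw channel values must lie in [0, 255]", call. = FALSE)
  }
  if (!is.null(standard_roi)) {
    stopifnot(is.logical(standard_roi), identical(dim(standard_roi), dims[[1]]))
  }
  if (!is.null(ruler_scale)) stopifnot(ruler_scale > 0)
  structure(
    list(channels = channels, standard_roi = standard_roi,
         ruler_scale = ruler_scale, linear = linear),
    class = "msimage"
  )
}

CHANNELS <- c("LW", "MW", "SW", "UV")

#' @export
print.msimage <- function(x, ...) {
  d <- dim(x$channels$LW)
  cat(sprintf("<msimage> %d x %d px, %s domain%s\n", d[1], d[2],
              if (isTRUE(x$linear)) "linear" else "raw",
              if (is.null(x$ruler_scale)) "" else
                sprintf(", %.3g px/mm", x$ruler_scale)))
  invisible(x)
}

new_calibrated_msimage <- function(channels, mm_per_pixel, roi_mask = NULL,
                                   standard_roi = NULL, saturated = NULL) {
  structure(
    list(channels = channels, mm_per_pixel = mm_per_pixel,
         roi_mask = roi_mask, standard_roi = standard_roi,
         saturated = saturated),
    class = "calibrated_msimage"
  )
}

#' @export
print.calibrated_msimage <- function(x, ...) {
  d <- dim(x$channels$LW)
  cat(sprintf("<calibrated_msimage> %d x %d px, %.4g mm/px\n",
              d[1], d[2], x$mm_per_pixel))
  invisible(x)
}

#' Read and write multispectral images as per-channel TIFF files
#'
#' Channels are stored as single-page greyscale TIFFs named
#' `<stem>_LW.tif`, ..., `<stem>_UV.tif` plus a `<stem>.yaml` sidecar holding
#' the ruler scale and the grey-standard bounding box. TIFF values are
#' written on a 0--1 scale and mapped back to 0--255 on read.
#'
#' @param img a [msimage].
#' @param stem path stem (no extension).
#' @return `write_msimage()` returns `stem` invisibly; `read_msimage()`
#'   returns a [msimage].
#' @export
write_msimage <- function(img, stem) {
  stopifnot(inherits(img, "msimage"))
  for (ch in CHANNELS) {
    tiff::writeTIFF(pmin(pmax(img$channels[[ch]] / 255, 0), 1),
                    paste0(stem, "_", ch, ".tif"), bits.per.sample = 16L)
  }
  meta <- list(ruler_scale = img$ruler_scale, linear = isTRUE(img$linear))
  if (!is.null(img$standard_roi)) {
    idx <- which(img$standard_roi, arr.ind = TRUE)
    meta$standard_box <- as.integer(c(min(idx[, 1]), max(idx[, 1]),
                                      min(idx[, 2]), max(idx[, 2])))
  }
  yaml::write_yaml(meta, paste0(stem, ".yaml"))
  invisible(stem)
}

#' @rdname write_msimage
#' @export
read_msimage <- function(stem) {
  meta <- yaml::read_yaml(paste0(stem, ".yaml"))
  channels <- lapply(CHANNELS, function(ch) {
    m <- tiff::readTIFF(paste0(stem, "_", ch, ".tif"))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * 255
  })
  names(channels) <- CHANNELS
  standard_roi <- NULL
  if (!is.null(meta$standard_box)) {
    b <- meta$standard_box
    standard_roi <- matrix(FALSE, nrow(channels$LW), ncol(channels$LW))
    standard_roi[b[1]:b[2], b[3]:b[4]] <- TRUE
  }
  msimage(channels, standard_roi = standard_roi,
          ruler_scale = meta$ruler_scale, linear = isTRUE(meta$linear))
}
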