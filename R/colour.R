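#' Tetrahedral colour-space vertices
#'
#' Vertex coordinates of the regular tetrahedron used for saturation, one
#' vertex per channel in the order UV, SW, MW, LW, each at distance 0.75
#' from the achromatic origin (the convention of the tetrahedral colour
#' space literature). Equal channel proportions map to the origin, so
#' saturation is the Euclidean distance from the achromatic point.
#'
#' @param vertex_distance distance of each vertex from the origin.
#' @return A 4 x 3 matrix with rows UV, SW, MW, LW.
#' @export
tetra_vertices <- function(vertex_distance = 0.75) {
  k <- 2 * sqrt(2) / 3
  ang <- 2 * pi * (0:2) / 3 + pi / 2
  v <- rbind(
    UV = c(0, 0, 1),
    SW = c(k * cos(ang[1]), k * sin(ang[1]), -1 / 3),
    MW = c(k * cos(ang[2]), k * sin(ang[2]), -1 / 3),
    LW = c(k * cos(ang[3]), k * sin(ang[3]), -1 / 3)
  )
  vertex_distance * v
}

quad_cols <- function(df) {
  if (!all(CHANNELS %in% names(df))) {
    stop("expected columns LW, MW, SW, UV", call. = FALSE)
  }
  m <- as.matrix(df[, CHANNELS])
  if (any(m < 0) || any(!is.finite(m))) {
    stop("channel values must be finite and non-negative", call. = FALSE)
  }
  m
}

#' Colour metrics from carapace channel means
#'
#' Computes the achromatic and chromatic descriptors used throughout the
#' analysis from per-crab mean channel reflectances (`LW`, `MW`, `SW`, `UV`
#' on the calibrated 0--255 scale):
#'
#' * `brightness` = (LW + MW + SW + UV) / 4;
#' * `saturation` = distance from the achromatic centre of the tetrahedral
#'   colour space, computed on channel proportions so it is independent of
#'   overall brightness;
#' * `hue1` = UV / ((LW + MW + SW) / 3), a UV-versus-rest ratio;
#' * `hue2` = (LW + UV) / (MW + SW), a longwave+UV versus mediumwave ratio.
#'
#' Equal channels give saturation 0 and both hues exactly 1 (the achromatic
#' point). `hue1` correlates strongly with saturation in practice and is
#' reported but excluded from downstream statistics by default; `hue2` is
#' the "hue" of the six-metric phenotype.
#'
#' @param quads data frame with columns `LW`, `MW`, `SW`, `UV`; any other
#'   columns are carried through.
#' @param vertex_distance tetrahedron vertex distance (default 0.75).
#' @return The input tibble with `brightness`, `saturation`, `hue1`, `hue2`
#'   appended.
#' @examples
#' colour_metrics(tibble::tibble(LW = 120, MW = 60, SW = 20, UV = 40))
#' @export
colour_metrics <- function(quads, vertex_distance = 0.75) {
  m <- quad_cols(quads)
  if (any(rowSums(m) == 0)) stop("all-zero channel quad", call. = FALSE)
  p <- channel_proportions(quads)
  out <- tibble::as_tibble(quads)
  out$brightness <- rowMeans(m)
  out$saturation <- tetra_saturation(p, vertex_distance = vertex_distance)
  h <- hues(quads)
  out$hue1 <- h$hue1
  out$hue2 <- h$hue2
  out
}

#' Channel proportions
#'
#' Standardizes a channel quad to proportions of the channel total,
#' removing absolute brightness variation.
#'
#' @inheritParams colour_metrics
#' @return Tibble with columns `pLW`, `pMW`, `pSW`, `pUV` summing to 1.
#' @export
channel_proportions <- function(quads) {
  m <- quad_cols(quads)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("channel sums must be positive", call. = FALSE)
  p <- m / tot
  colnames(p) <- paste0("p", CHANNELS)
  tibble::as_tibble(p)
}

#' Tetrahedral saturation
#'
#' @param props data frame with proportion columns `pLW`, `pMW`, `pSW`,
#'   `pUV` (from [channel_proportions()]).
#' @param vertex_distance tetrahedron vertex distance (default 0.75).
#' @return Numeric vector of distances from the achromatic centre.
#' @export
tetra_saturation <- function(props, vertex_distance = 0.75) {
  pc <- paste0("p", CHANNELS)
  stopifnot(all(pc %in% names(props)))
  p <- as.matrix(props[, c("pUV", "pSW", "pMW", "pLW")])
  xyz <- p %*% tetra_vertices(vertex_distance)
  sqrt(rowSums(xyz^2))
}

#' Hue ratios
#'
#' @inheritParams colour_metrics
#' @return Tibble with columns `hue1`, `hue2`.
#' @export
hues <- function(quads) {
  m <- quad_cols(quads)
  d1 <- (m[, "LW"] + m[, "MW"] + m[, "SW"]) / 3
  d2 <- m[, "MW"] + m[, "SW"]
  if (any(d1 <= 0) || any(d2 <= 0)) {
    stop("hue denominators must be positive (LW+MW+SW and MW+SW)",
         call. = FALSE)
  }
  tibble::tibble(hue1 = unname(m[, "UV"] / d1),
                 hue2 = unname((m[, "LW"] + m[, "UV"]) / d2))
}

#' PCA screen of channel proportions
#'
#' Principal component analysis of the covariance matrix of the
#' proportional channel data across a cohort. Used as a diagnostic to
#' confirm that the two fixed hue ratios capture the main axes of colour
#' variation; it does not redefine them. Proportions sum to 1, so the
#' covariance has rank at most 3 and the fourth component is null.
#'
#' @param quads data frame of channel quads, one row per crab (>= 3 rows).
#' @return A list with `loadings` (4 x 4 matrix), `variance_explained`
#'   (percent per PC, summing to 100) and `sdev`.
#' @export
pca_colour_screen <- function(quads) {
  if (nrow(quads) < 3L) stop("need at least 3 individuals for PCA", call. = FALSE)
  p <- channel_proportions(quads)
  fit <- stats::prcomp(as.matrix(p), center = TRUE, scale. = FALSE)
  ve <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  list(loadings = fit$rotation, variance_explained = ve, sdev = fit$sdev)
}

#' Screen candidate metrics for collinearity
#'
#' Pairwise Pearson correlations over candidate appearance metrics; pairs
#' at or above the threshold are flagged for exclusion from multivariate
#' analyses (in the crab data, saturation and hue1 flag each other, which
#' is why hue1 is dropped by default).
#'
#' @param metrics data frame of numeric metric columns.
#' @param cols columns to screen; default all numeric columns.
#' @param threshold absolute correlation at which a pair is flagged
#'   (default 0.7).
#' @return Tibble with columns `metric_a`, `metric_b`, `r`, `flagged`;
#'   pairs involving a constant column get `r = NA` and a note.
#' @export
correlation_screen <- function(metrics, cols = NULL, threshold = 0.7) {
  if (is.null(cols)) {
    cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  }
  if (nrow(metrics) < 3L) stop("need at least 3 rows", call. = FALSE)
  m <- as.matrix(metrics[, cols])
  constant <- apply(m, 2, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(m))
  pairs <- utils::combn(cols, 2)
  out <- tibble::tibble(
    metric_a = pairs[1, ], metric_b = pairs[2, ],
    r = r[cbind(pairs[1, ], pairs[2, ])]
  )
  out$note <- ifelse(constant[out$metric_a] | constant[out$metric_b],
                     "constant column: correlation undefined", "")
  out$flagged <- !is.na(out$r) & abs(out$r) >= threshold
  out
}
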