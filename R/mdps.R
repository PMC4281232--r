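PHENOTYPE_METRICS <- c("hue", "saturation", "brightness",
                       "marking_size", "total_energy", "proportion_energy")

#' Standardize phenotype metrics to the dataset maximum
#'
#' Each of the six appearance metrics is rescaled as a proportion of its
#' maximum over the entire dataset, putting all axes of the
#' multidimensional phenotypic space on a common 0--1 scale. The maximum is
#' always taken over the full cohort, never per group, so groups remain
#' comparable. Idempotent: standardizing twice changes nothing.
#'
#' @param cohort data frame, one row per crab.
#' @param metrics metric columns to standardize (default the six phenotype
#'   metrics).
#' @return The cohort tibble with the metric columns rescaled.
#' @export
standardize_metrics <- function(cohort, metrics = PHENOTYPE_METRICS) {
  stopifnot(all(metrics %in% names(cohort)))
  out <- tibble::as_tibble(cohort)
  for (m in metrics) {
    mx <- max(out[[m]], na.rm = TRUE)
    if (!is.finite(mx) || mx <= 0) {
      stop("metric '", m, "' has non-positive maximum; cannot standardize",
           call. = FALSE)
    }
    out[[m]] <- out[[m]] / mx
  }
  out
}

group_mdps_one <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(list(value = NA_real_, indiv = rep(NA_real_, n)))
  d <- as.matrix(stats::dist(m))
  indiv <- rowSums(d) / (n - 1)
  list(value = mean(indiv), indiv = indiv)
}

#' Diversity in the multidimensional phenotypic space (MDPS)
#'
#' For each group (site x life stage by default), every crab's mean
#' Euclidean distance to all other crabs of the group is computed over the
#' standardized phenotype metrics; the group MDPS is the mean of these
#' individual means. Larger values mean the group's crabs are more spread
#' out in phenotype space, i.e. more variable in appearance.
#'
#' @param cohort standardized cohort table (see [standardize_metrics()]).
#' @param groups character vector of grouping columns (default
#'   `c("site", "stage")`).
#' @param metrics metric columns defining the space.
#' @return A `mdps_result` tibble: one row per group with `n` and `mdps`
#'   (`NA` for singleton groups); the per-individual mean distances are in
#'   `attr(, "individual")`.
#' @export
mdps <- function(cohort, groups = c("site", "stage"),
                 metrics = PHENOTYPE_METRICS) {
  stopifnot(all(groups %in% names(cohort)), all(metrics %in% names(cohort)))
  cohort <- tibble::as_tibble(cohort)
  key <- interaction(cohort[groups], drop = TRUE, lex.order = TRUE)
  pieces <- split(seq_len(nrow(cohort)), key)
  rows <- purrr::map(pieces, function(idx) {
    res <- group_mdps_one(as.matrix(cohort[idx, metrics]))
    g <- cohort[idx[1], groups]
    dplyr::bind_cols(g, tibble::tibble(n = length(idx), mdps = res$value))
  })
  indiv <- purrr::map2(pieces, rows, function(idx, r) {
    dplyr::bind_cols(cohort[idx, groups, drop = FALSE],
                     tibble::tibble(row = idx,
                                    mean_distance = group_mdps_one(
                                      as.matrix(cohort[idx, metrics]))$indiv))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "individual") <- dplyr::bind_rows(indiv)
  class(out) <- c("mdps_result", class(out))
  out
}

#' Resampled MDPS controlling for sample size
#'
#' Larger samples can appear more diverse simply because they contain more
#' individuals, so each group's MDPS is recomputed over repeated random
#' subsamples of a common size (by default the smallest group's n, the
#' reference group), drawn without replacement. The mean and standard
#' deviation over 99 resamples are reported alongside the full-sample
#' value.
#'
#' @inheritParams mdps
#' @param subsample_n subsample size; default `min` group size.
#' @param reps number of random subsamples (default 99).
#' @param seed integer seed; resampling is reproducible given the seed.
#' @return Tibble with one row per group: `n`, `subsample_n`, `reps`,
#'   `mdps` (full sample), `mdps_resampled`, `resampled_sd`, and
#'   `reference` marking the group(s) whose n equals `subsample_n`.
#' @export
resample_mdps <- function(cohort, groups = c("site", "stage"),
                          metrics = PHENOTYPE_METRICS,
                          subsample_n = NULL, reps = 99, seed = 1) {
  full <- mdps(cohort, groups = groups, metrics = metrics)
  if (is.null(subsample_n)) subsample_n <- min(full$n)
  if (subsample_n < 2L) stop("subsample_n must be at least 2", call. = FALSE)
  if (subsample_n > min(full$n)) {
    stop("subsample_n exceeds the smallest group size", call. = FALSE)
  }
  key <- interaction(tibble::as_tibble(cohort)[groups],
                     drop = TRUE, lex.order = TRUE)
  pieces <- split(seq_len(nrow(cohort)), key)
  set.seed(seed)
  res <- purrr::map(pieces, function(idx) {
    m <- as.matrix(tibble::as_tibble(cohort)[idx, metrics])
    vals <- vapply(seq_len(reps), function(i) {
      group_mdps_one(m[sample(nrow(m), subsample_n), , drop = FALSE])$value
    }, numeric(1))
    c(mean = mean(vals), sd = stats::sd(vals))
  })
  out <- full
  stats_m <- do.call(rbind, res)
  out$subsample_n <- as.integer(subsample_n)
  out$reps <- as.integer(reps)
  out$mdps_resampled <- unname(stats_m[, "mean"])
  out$resampled_sd <- unname(stats_m[, "sd"])
  out$reference <- out$n == min(out$n)
  attr(out, "seed") <- seed
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.mdps_result <- function(object, ...) {
  groups <- setdiff(names(object),
                    c("n", "mdps", "subsample_n", "reps", "mdps_resampled",
                      "resampled_sd", "reference"))
  object$group <- interaction(as.data.frame(object)[groups], sep = " / ")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$mdps)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = NULL, y = "Mean pairwise distance (MDPS)",
                  title = "Phenotypic diversity by group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("mdps_resampled" %in% names(object)) {
    p <- p + ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$mdps_resampled,
                   ymin = .data$mdps_resampled - .data$resampled_sd,
                   ymax = .data$mdps_resampled + .data$resampled_sd))
  }
  p
}
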