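#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a LOOCV classification result
#'
#' @param x a `classification_result` from [lda_loocv()].
#' @param ... unused.
#' @return Per-group tibble: `group`, `n`, `correct`, `proportion_correct`.
#' @exportS3Method generics::tidy
tidy.classification_result <- function(x, ...) x$per_group

#' @rdname tidy.classification_result
#' @return `glance()`: one-row tibble with `overall`, `n`, `n_groups`.
#' @exportS3Method generics::glance
glance.classification_result <- function(x, ...) {
  tibble::tibble(overall = x$overall, n = sum(x$per_group$n),
                 n_groups = nrow(x$per_group))
}

#' Tidy a stepwise fixed-effects model
#'
#' @param x a `glm_stepwise` object.
#' @param ... unused.
#' @return `tidy()`: the final Type-II ANOVA table (`term`, `sum_sq`, `df`,
#'   `df_residual`, `F`, `p`).
#' @exportS3Method generics::tidy
tidy.glm_stepwise <- function(x, ...) x$anova

#' @rdname tidy.glm_stepwise
#' @return `glance()`: one-row tibble with fit summaries and the number of
#'   removed interactions.
#' @exportS3Method generics::glance
glance.glm_stepwise <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    sigma = s$sigma, df_residual = x$model$df.residual,
    n_removed = nrow(x$removed),
    boxcox_power = if (is.null(x$boxcox_power)) NA_real_ else x$boxcox_power
  )
}

#' Tidy a fitted camera response curve
#'
#' @param x a `response_curve` from [fit_linearization()].
#' @param ... unused.
#' @return Tibble with one row per channel: `channel`, `a`, `b`,
#'   `r_squared`, `rmse`.
#' @exportS3Method generics::tidy
tidy.response_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
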