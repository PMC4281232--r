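#' Assign life-stage / maturity classes from carapace width
#'
#' Two size-based criteria are supported:
#'
#' * `"cw25"` (the default used downstream): adults are crabs with carapace
#'   width of 25 mm or more, juveniles below 25 mm, regardless of sex;
#' * `"maturity"`: sex-specific maturity sizes -- females mature from 28 mm
#'   carapace width, males above 21 mm; smaller individuals are immature.
#'
#' @param cohort data frame with `carapace_width_mm` (and `sex`, coded
#'   `"F"`/`"M"`, when `criterion = "maturity"`).
#' @param criterion `"cw25"` or `"maturity"`.
#' @return The cohort with a `stage` factor appended: `adult`/`juvenile`
#'   for `"cw25"`, `mature`/`immature` for `"maturity"`.
#' @export
assign_age <- function(cohort, criterion = c("cw25", "maturity")) {
  criterion <- match.arg(criterion)
  cw <- cohort$carapace_width_mm
  if (is.null(cw) || any(is.na(cw)) || any(cw <= 0)) {
    stop("carapace_width_mm must be present and positive for every crab",
         call. = FALSE)
  }
  out <- tibble::as_tibble(cohort)
  if (criterion == "cw25") {
    out$stage <- factor(ifelse(cw >= 25, "adult", "juvenile"),
                        levels = c("adult", "juvenile"))
  } else {
    sex <- toupper(substr(as.character(cohort$sex), 1, 1))
    if (is.null(cohort$sex) || any(!sex %in% c("F", "M"))) {
      stop("the maturity criterion needs sex coded F/M for every crab",
           call. = FALSE)
    }
    mature <- ifelse(sex == "F", cw >= 28, cw > 21)
    out$stage <- factor(ifelse(mature, "mature", "immature"),
                        levels = c("mature", "immature"))
  }
  out
}

#' Jackknifed (leave-one-out) discriminant classification
#'
#' Linear discriminant analysis with leave-one-out cross-validation: each
#' crab is classified by a discriminant function fitted on all the others,
#' so the classification is independent of the held-out sample. Priors are
#' proportional to group sizes; within-group covariances are pooled
#' (linear, not quadratic, discriminants).
#'
#' @param cohort data frame.
#' @param features character vector of predictor columns (default the six
#'   phenotype metrics).
#' @param label grouping column name (e.g. `"site"` or `"stage"`).
#' @return A `classification_result`: list with `confusion` (true x
#'   predicted counts), `per_group` tibble of proportions correct, and
#'   `overall` proportion correct.
#' @export
lda_loocv <- function(cohort, features = PHENOTYPE_METRICS, label) {
  stopifnot(all(features %in% names(cohort)), label %in% names(cohort))
  x <- as.matrix(cohort[, features])
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  g <- factor(cohort[[label]])
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes <= length(features))) {
    warning("some groups have n <= number of features; ",
            "LOOCV estimates may be unstable")
  }
  fit <- tryCatch(
    MASS::lda(x, grouping = g, CV = TRUE),
    error = function(e) {
      stop("discriminant fit failed (singular within-group covariance, ",
           "often collinear features): ", conditionMessage(e), call. = FALSE)
    }
  )
  confusion <- table(true = g, predicted = fit$class)
  per_group <- tibble::tibble(
    group = levels(g),
    n = as.integer(sizes),
    correct = as.integer(diag(confusion)),
    proportion_correct = diag(confusion) / as.integer(sizes)
  )
  structure(
    list(confusion = confusion, per_group = per_group,
         overall = sum(diag(confusion)) / length(g),
         label = label, features = features),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> LOOCV LDA on '%s': %.3f correct overall\n",
              x$label, x$overall))
  print(x$confusion)
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.classification_result <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("LOOCV classification by %s (%.1f%% correct)",
                                  object$label, 100 * object$overall)) +
    ggplot2::theme_minimal()
}

#' Spearman rank correlation of an appearance metric against size
#'
#' Rank correlation (midranks for ties) of a metric against continuous
#' carapace width, with the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' An exact permutation p-value is used for very small samples when
#' requested.
#'
#' @param cohort data frame.
#' @param metric metric column name.
#' @param size size column (default `"carapace_width_mm"`).
#' @param exact use the exact permutation distribution when `n <= 10`.
#' @return One-row tibble: `metric`, `n`, `rho`, `t`, `df`, `p`.
#' @export
spearman_vs_size <- function(cohort, metric, size = "carapace_width_mm",
                             exact = FALSE) {
  x <- cohort[[size]]
  y <- cohort[[metric]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    return(tibble::tibble(metric = metric, n = n, rho = NA_real_,
                          t = NA_real_, df = n - 2L, p = NA_real_))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    tval <- sign(rho) * Inf
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  if (exact && n <= 10) {
    perms <- perm_all(n)
    ry <- rank(y)
    rstats <- apply(perms, 1, function(ix) stats::cor(rank(x), ry[ix]))
    p <- mean(abs(rstats) >= abs(rho) - 1e-12)
  }
  tibble::tibble(metric = metric, n = n, rho = rho, t = tval,
                 df = n - 2L, p = p)
}

perm_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Box-Cox power transform
#'
#' `(v^lambda - 1) / lambda` for `lambda != 0`, `log(v)` for `lambda = 0`.
#' When `lambda` is omitted it is estimated by profile maximum likelihood
#' over a grid on `[-3, 3]` (step 0.001) for the constant-mean model.
#'
#' @param values positive numeric vector.
#' @param lambda power; `NULL` to estimate.
#' @return Transformed vector with the power used in `attr(, "lambda")`.
#' @export
boxcox_transform <- function(values, lambda = NULL) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("Box-Cox requires finite positive values", call. = FALSE)
  }
  if (is.null(lambda)) lambda <- boxcox_lambda(values)
  out <- if (abs(lambda) < 1e-12) log(values) else (values^lambda - 1) / lambda
  attr(out, "lambda") <- lambda
  out
}

#' @rdname boxcox_transform
#' @param grid candidate powers for the profile likelihood.
#' @export
boxcox_lambda <- function(values, grid = seq(-3, 3, by = 0.001)) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("Box-Cox requires finite positive values", call. = FALSE)
  }
  n <- length(values)
  lv <- log(values)
  slv <- sum(lv)
  ll <- vapply(grid, function(l) {
    z <- if (abs(l) < 1e-12) lv else (values^l - 1) / l
    s2 <- mean((z - mean(z))^2)
    -n / 2 * log(s2) + (l - 1) * slv
  }, numeric(1))
  grid[which.max(ll)]
}

#' Fixed-effects model with stepwise removal of non-significant interactions
#'
#' Ordinary least squares on a (optionally Box-Cox transformed) response
#' with the fixed factors and all listed two-way interactions. Marginal
#' (Type II) F tests are computed; the interaction with the largest
#' p-value at or above `alpha` is removed and the model refitted, one term
#' at a time, until every remaining interaction is significant. Main
#' effects are never removed.
#'
#' @param cohort data frame.
#' @param response response column name.
#' @param fixed main-effect factor columns (default site, zone, stage).
#' @param interactions candidate two-way interactions as `"a:b"` strings;
#'   default all pairs of `fixed`.
#' @param alpha removal threshold (default 0.05).
#' @param boxcox_power Box-Cox power applied to the response before
#'   fitting; `NULL` for no transform, `"mle"` to estimate.
#' @return A `glm_stepwise` object: list with `anova` (tibble of term, F,
#'   df pair, p for the final model), `removed` (removal trace, in order),
#'   `model` (the final `lm`), `alpha`, `boxcox_power`.
#' @export
glm_stepwise <- function(cohort, response, fixed = c("site", "zone", "stage"),
                         interactions = NULL, alpha = 0.05,
                         boxcox_power = NULL) {
  stopifnot(response %in% names(cohort), all(fixed %in% names(cohort)))
  dat <- as.data.frame(cohort)
  for (f in fixed) dat[[f]] <- factor(dat[[f]])
  if (is.null(interactions) && length(fixed) >= 2) {
    interactions <- utils::combn(fixed, 2, paste, collapse = ":")
  }
  lambda <- NULL
  y <- dat[[response]]
  if (!is.null(boxcox_power)) {
    lambda <- if (identical(boxcox_power, "mle")) boxcox_lambda(y) else
      boxcox_power
    dat[[response]] <- as.numeric(boxcox_transform(y, lambda))
  }
  inter_active <- interactions
  removed <- tibble::tibble(term = character(), p = numeric(),
                            step = integer())
  step <- 0L
  repeat {
    fml <- stats::reformulate(c(fixed, inter_active), response = response)
    fit <- stats::lm(fml, data = dat)
    if (any(is.na(stats::coef(fit)))) {
      stop("rank-deficient design: some factor combinations are empty or ",
           "aliased", call. = FALSE)
    }
    an <- anova_type2(fit)
    if (length(inter_active) == 0) break
    pvals <- an$p[match(normalize_terms(inter_active), an$term)]
    worst <- which.max(pvals)
    if (pvals[worst] < alpha) break
    step <- step + 1L
    removed <- dplyr::bind_rows(removed,
      tibble::tibble(term = inter_active[worst], p = pvals[worst],
                     step = step))
    inter_active <- inter_active[-worst]
  }
  structure(
    list(anova = an, removed = removed, model = fit, alpha = alpha,
         boxcox_power = lambda, response = response),
    class = "glm_stepwise"
  )
}

normalize_terms <- function(terms) {
  vapply(strsplit(terms, ":"), function(p) paste(sort(p), collapse = ":"),
         character(1))
}

anova_type2 <- function(fit) {
  an <- car::Anova(fit, type = 2)
  df_res <- an$Df[rownames(an) == "Residuals"]
  keep <- rownames(an) != "Residuals"
  tibble::tibble(
    term = normalize_terms(rownames(an)[keep]),
    sum_sq = an$`Sum Sq`[keep],
    df = an$Df[keep],
    df_residual = df_res,
    F = an$`F value`[keep],
    p = an$`Pr(>F)`[keep]
  )
}

#' @export
print.glm_stepwise <- function(x, ...) {
  cat(sprintf("<glm_stepwise> response '%s'%s; %d interaction(s) removed\n",
              x$response,
              if (is.null(x$boxcox_power)) "" else
                sprintf(" (Box-Cox power %.3f)", x$boxcox_power),
              nrow(x$removed)))
  print(x$anova)
  invisible(x)
}
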