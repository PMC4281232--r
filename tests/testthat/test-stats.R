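test_that("age criteria classify carapace widths as documented", {
  co <- tibble::tibble(
    sex = c("F", "F", "M", "M", "F"),
    carapace_width_mm = c(30, 27, 22, 21, 28)
  )
  a <- assign_age(co, "maturity")
  expect_equal(as.character(a$stage),
               c("mature", "immature", "mature", "immature", "mature"))

  b <- assign_age(tibble::tibble(sex = "M", carapace_width_mm = c(24, 25, 25.1)),
                  "cw25")
  expect_equal(as.character(b$stage), c("juvenile", "adult", "adult"))

  expect_error(assign_age(tibble::tibble(sex = "F", carapace_width_mm = NA)),
               "carapace_width_mm")
})

test_that("jackknifed LDA separates distinct groups and degrades to chance", {
  co <- sim_groups(100, sep = 10 / sqrt(6))  # ~10 pooled SD overall
  res <- lda_loocv(co, label = "grp")
  expect_gte(res$overall, 0.99)
  expect_equal(sum(res$confusion), 200)
  expect_equal(unname(rowSums(res$confusion)), res$per_group$n)

  # permuted labels: no better than chance (LOOCV is pessimistically biased
  # under the null, so accuracy may fall below 0.5 but must not exceed it
  # beyond binomial noise)
  set.seed(9)
  chance <- vapply(1:10, function(i) {
    perm <- co; perm$grp <- sample(perm$grp)
    lda_loocv(perm, label = "grp")$overall
  }, numeric(1))
  expect_true(all(chance < 0.5 + 2.576 * sqrt(0.25 / 200)))
  expect_true(all(chance > 0.25))

  # deterministic on identical input
  expect_identical(lda_loocv(co, label = "grp")$confusion, res$confusion)

  # the held-out point is never used to fit its own classifier: a strong
  # single-feature outlier leaves every other prediction unchanged on a
  # well-separated set
  base <- sim_groups(30, sep = 8, seed = 3)
  out <- base
  out$hue[1] <- out$hue[1] + 50
  p_out <- lda_loocv(out, label = "grp")
  expect_equal(unname(p_out$confusion["b", ]),
               unname(lda_loocv(base, label = "grp")$confusion["b", ]))
  expect_gte(p_out$confusion["a", "a"], 29)  # at most its own flip

  one <- sim_groups(3, sep = 0)
  w <- capture_warnings(lda_loocv(one, label = "grp"))
  expect_true(any(grepl("unstable", w)))
})

test_that("Spearman correlation matches a count-based midrank oracle", {
  co <- tibble::tibble(carapace_width_mm = 1:20, m = (1:20)^3)
  expect_equal(spearman_vs_size(co, "m")$rho, 1)
  co$m <- -co$m
  expect_equal(spearman_vs_size(co, "m")$rho, -1)

  # ties handled with midranks, t and df as printed conventions
  set.seed(13)
  co2 <- tibble::tibble(carapace_width_mm = sample(rep(1:6, 4)),
                        m = sample(rep(c(2, 2, 5, 9), 6)))
  res <- spearman_vs_size(co2, "m")
  rho <- spearman_oracle(co2$carapace_width_mm, co2$m)
  expect_equal(res$rho, rho, tolerance = 1e-12)
  expect_equal(res$df, nrow(co2) - 2L)
  expect_equal(res$t, rho * sqrt((24 - 2) / (1 - rho^2)))

  # invariant under strictly monotone transforms of either variable
  co3 <- tibble::tibble(carapace_width_mm = runif(30, 1, 50), m = rnorm(30))
  r0 <- spearman_vs_size(co3, "m")$rho
  co3$carapace_width_mm <- exp(co3$carapace_width_mm / 10)
  co3$m <- co3$m^3
  expect_equal(spearman_vs_size(co3, "m")$rho, r0)

  # exact permutation p for tiny n agrees with enumeration
  co4 <- tibble::tibble(carapace_width_mm = c(1, 2, 3, 4, 5),
                        m = c(2, 1, 4, 3, 5))
  pe <- spearman_vs_size(co4, "m", exact = TRUE)$p
  expect_gte(pe, 0); expect_lte(pe, 1)
  expect_equal(pe, mean(abs(apply(carapacer:::perm_all(5), 1, function(ix)
    cor(1:5, c(2, 1, 4, 3, 5)[ix], method = "spearman"))) >=
      abs(cor(co4$carapace_width_mm, co4$m, method = "spearman")) - 1e-12))

  const <- tibble::tibble(carapace_width_mm = 1:10, m = rep(3, 10))
  expect_true(is.na(spearman_vs_size(const, "m")$rho))
})

test_that("Box-Cox transform and its profile-likelihood estimate behave", {
  v <- c(1, 2, 5, 10)
  expect_equal(boxcox_transform(v, 1), v - 1, ignore_attr = TRUE)
  expect_equal(boxcox_transform(v, 0), log(v), ignore_attr = TRUE)
  # order preserved for any power
  for (l in c(-1.124, -0.45, 0.113, 0.562)) {
    expect_true(all(diff(boxcox_transform(v, l)) > 0))
  }
  # log-normal data: MLE power near zero
  set.seed(31)
  x <- exp(rnorm(1000))
  expect_lt(abs(boxcox_lambda(x)), 0.1)
  # agreement with the MASS profile on the same model
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-1, 1, 0.001), plotit = FALSE)
  expect_lt(abs(boxcox_lambda(x) - bc$x[which.max(bc$y)]), 0.01)
  expect_error(boxcox_transform(c(1, -2)), "positive")
})

test_that("stepwise interaction removal follows the alpha rule and Type II F values", {
  set.seed(17)
  n <- 240
  co <- tibble::tibble(
    site = sample(paste0("S", 1:4), n, replace = TRUE),
    zone = sample(c("low", "middle", "upper"), n, replace = TRUE),
    stage = sample(c("adult", "juvenile"), n, replace = TRUE)
  )
  co$y <- rnorm(n) + 2 * (co$site == "S2" & co$stage == "juvenile")

  keep_all <- glm_stepwise(co, "y", alpha = 1)
  expect_equal(nrow(keep_all$removed), 0)
  expect_setequal(keep_all$anova$term,
                  c("site", "zone", "stage", "site:zone", "site:stage",
                    "stage:zone"))

  none <- glm_stepwise(co, "y", alpha = 0)
  expect_equal(nrow(none$removed), 3)
  expect_setequal(none$anova$term, c("site", "zone", "stage"))

  # a real site x stage interaction survives; noise interactions go
  fit <- glm_stepwise(co, "y", alpha = 0.05)
  expect_true("site:stage" %in% fit$anova$term)
  expect_false(any(c("site:zone", "stage:zone") %in% fit$anova$term))
  expect_true(all(diff(fit$removed$step) == 1))

  # balanced 2x2: F values match the closed-form two-way ANOVA oracle
  set.seed(23)
  toy <- tidyr::expand_grid(site = c("A", "B"), stage = c("ad", "juv"),
                            rep = 1:6)
  toy$y <- rnorm(24) + (toy$site == "A") * 0.8 + (toy$stage == "juv") * 0.5
  got <- glm_stepwise(toy, "y", fixed = c("site", "stage"), alpha = 1)$anova
  orc <- anova2_oracle(toy$y, toy$site, toy$stage)
  expect_equal(got$F[got$term == "site"], orc$F_a, tolerance = 1e-10)
  expect_equal(got$F[got$term == "stage"], orc$F_b, tolerance = 1e-10)
  expect_equal(got$F[got$term == "site:stage"], orc$F_ab, tolerance = 1e-10)

  # Box-Cox power recorded when requested
  co$ypos <- exp(co$y / 4)
  fit2 <- glm_stepwise(co, "ypos", alpha = 0.05, boxcox_power = "mle")
  expect_true(is.numeric(fit2$boxcox_power))
  expect_equal(glance(fit2)$boxcox_power, fit2$boxcox_power)

  # rank-deficient designs are rejected with a diagnostic
  bad <- co; bad$zone <- bad$site
  expect_error(glm_stepwise(bad, "y"), "rank-deficient|aliased")
})
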