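# shared fixtures: all generated in code, nothing on disk

# ladder table rendered through a power-law camera value = 255 * r^(1/g)
power_law_ladder <- function(exponent = 2.2,
                             refl = c(0.02, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 0.99)) {
  tidyr::expand_grid(channel = c("LW", "MW", "SW", "UV"),
                     reflectance = refl) |>
    dplyr::mutate(measured_value = 255 * reflectance^(1 / exponent))
}

# linear-domain msimage with a uniform value and a square standard patch
uniform_linear_image <- function(value, std_value = value, n = 32) {
  ch <- matrix(value, n, n)
  std <- matrix(FALSE, n, n)
  std[2:9, 2:9] <- TRUE
  for (i in which(std)) ch[i] <- std_value
  msimage(list(LW = ch, MW = ch, SW = ch, UV = ch),
          standard_roi = std, ruler_scale = 10, linear = TRUE)
}

# horizontal sinusoidal grating, amplitude a, period p pixels
grating <- function(n, period, amplitude = 1) {
  matrix(amplitude * sin(2 * pi * seq_len(n) / period), n, n, byrow = TRUE)
}

# exhaustive pairwise-distance oracle for the group MDPS
mdps_oracle <- function(m) {
  n <- nrow(m)
  indiv <- vapply(seq_len(n), function(i) {
    mean(vapply(setdiff(seq_len(n), i), function(j) {
      sqrt(sum((m[i, ] - m[j, ])^2))
    }, numeric(1)))
  }, numeric(1))
  mean(indiv)
}

# midranks computed from first principles (count-based), then Pearson on them
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# textbook balanced two-way ANOVA with interaction (closed-form sums)
anova2_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y); gm <- mean(y)
  cell <- tapply(y, list(a, b), mean)
  am <- tapply(y, a, mean); bm <- tapply(y, b, mean)
  r <- n / (nlevels(a) * nlevels(b))   # replicates per cell
  ss_a <- r * nlevels(b) * sum((am - gm)^2)
  ss_b <- r * nlevels(a) * sum((bm - gm)^2)
  ss_ab <- r * sum((outer(am - gm, bm - gm, `+`) + gm - cell)^2)
  ss_e <- sum((y - cell[cbind(a, b)])^2)
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_e <- n - nlevels(a) * nlevels(b)
  list(F_a = (ss_a / df_a) / (ss_e / df_e),
       F_b = (ss_b / df_b) / (ss_e / df_e),
       F_ab = (ss_ab / df_ab) / (ss_e / df_e))
}

# two Gaussian groups separated by `sep` SD on every axis
sim_groups <- function(n, sep, p = 6, seed = 1)  {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, mean = sep), n, p))
  colnames(x) <- c("hue", "saturation", "brightness", "marking_size",
                   "total_energy", "proportion_energy")
  dplyr::bind_cols(tibble::tibble(grp = rep(c("a", "b"), each = n)),
                   tibble::as_tibble(x))
}
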