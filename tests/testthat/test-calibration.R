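test_that("power-law fit recovers the camera response from a grey-standard ladder", {
  # linear sensor: curve is identity up to scale and essentially exact
  lin <- power_law_ladder(exponent = 1)
  curve <- fit_linearization(lin)
  expect_true(all(curve$r_squared >= 0.999))
  expect_true(all(abs(curve$b - 1) < 1e-6))
  expect_true(all(abs(curve$a - 255) < 1e-3))

  # gamma-like response: the linearization exponent 1/b recovers 2.2 within 2%
  gam <- power_law_ladder(exponent = 2.2)
  curve <- fit_linearization(gam)
  expect_true(all(abs(1 / curve$b - 2.2) / 2.2 < 0.02))
  expect_true(all(curve$r_squared >= 0.999))

  # a flat segment (repeated measured value) is tolerated, curve stays monotone
  flat <- power_law_ladder(exponent = 1)
  flat$measured_value[flat$channel == "LW"][3] <-
    flat$measured_value[flat$channel == "LW"][2]
  curve <- fit_linearization(flat)
  v <- seq(0, 255, by = 1)
  row <- curve[curve$channel == "LW", ]
  mapped <- carapacer:::linearize_values(v, row$a, row$b)
  expect_true(all(diff(mapped) >= 0))
  expect_identical(mapped[1], 0)

  # decreasing measured values or too few points are rejected
  bad <- power_law_ladder(exponent = 1)
  bad$measured_value[2] <- bad$measured_value[1] - 5
  expect_error(fit_linearization(bad), "non-monotone")
  expect_error(fit_linearization(power_law_ladder(refl = c(0.1, 0.5))),
               "at least 3")
})

test_that("linearize inverts the camera response pixel-wise and preserves order", {
  curve <- fit_linearization(power_law_ladder(exponent = 2.2))
  refl <- matrix(runif(64 * 64, 0.02, 0.95), 64, 64)
  raw_vals <- 255 * refl^(1 / 2.2)
  std <- matrix(FALSE, 64, 64); std[1:8, 1:8] <- TRUE
  raw <- msimage(rep(list(raw_vals), 4) |> setNames(c("LW", "MW", "SW", "UV")),
                 standard_roi = std, ruler_scale = 10)
  lin <- linearize(raw, curve)
  expect_true(isTRUE(lin$linear))
  # proportional to scene reflectance within 1%
  expect_lt(max(abs(lin$channels$MW / 255 - refl) / refl), 0.01)
  # order preserved
  expect_true(all(order(lin$channels$LW) == order(raw$channels$LW)))

  # identity curve: output equals input; constant image stays constant
  idc <- fit_linearization(power_law_ladder(exponent = 1))
  raw2 <- msimage(rep(list(matrix(80, 8, 8)), 4) |>
                    setNames(c("LW", "MW", "SW", "UV")),
                  standard_roi = matrix(TRUE, 8, 8))
  lin2 <- linearize(raw2, idc)
  expect_equal(lin2$channels$UV, matrix(80, 8, 8), tolerance = 1e-6)
  expect_error(linearize(lin2, idc), "already linearized")
})

test_that("equalization pins the standard region to its reflectance and is idempotent", {
  # standard at 120 with a 40% standard: scale 102/120 = 0.85
  img <- uniform_linear_image(value = 120)
  cal <- equalize_and_scale(img, standard_reflectance = 0.40)
  expect_equal(mean(cal$channels$LW[cal$standard_roi]), 102)
  expect_equal(cal$channels$LW[20, 20], 102)   # whole image scaled by 0.85

  # idempotence: equalizing a calibrated image changes nothing
  cal2 <- equalize_and_scale(cal, standard_reflectance = 0.40)
  expect_equal(cal2$channels$SW, cal$channels$SW, tolerance = 1e-12)

  # illumination invariance: x0.5 to x2 exposure gives identical output
  base <- uniform_linear_image(value = 60, std_value = 90)
  outs <- lapply(c(0.5, 1, 2), function(k) {
    scaled <- base
    scaled$channels <- lapply(base$channels, function(m) m * k)
    equalize_and_scale(scaled, 0.40)$channels$LW
  })
  expect_lt(max(abs(outs[[1]] - outs[[2]]) / outs[[2]]), 0.005)
  expect_lt(max(abs(outs[[3]] - outs[[2]]) / outs[[2]]), 0.005)

  # black standard region signals a failed photograph
  dark <- uniform_linear_image(value = 50, std_value = 0)
  expect_error(equalize_and_scale(dark), "black")
})

test_that("rescaling to the common scale preserves physical dimensions", {
  n <- 128
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  disc <- (rr - 64)^2 + (cc - 64)^2 <= 50^2
  ch <- matrix(10, n, n); ch[disc] <- 100
  cal <- carapacer:::new_calibrated_msimage(
    rep(list(ch), 4) |> setNames(c("LW", "MW", "SW", "UV")),
    mm_per_pixel = 0.1, roi_mask = disc)

  # no-op when already at the target scale
  same <- rescale_to_common_scale(cal, 0.1)
  expect_identical(same$channels$LW, cal$channels$LW)

  # 2x downscale: the 100-px disc becomes ~50 px wide
  half <- rescale_to_common_scale(cal, 0.2)
  expect_equal(dim(half$channels$LW), c(64, 64))
  width_px <- max(colSums(half$channels$LW > 55))
  expect_lt(abs(width_px - 50), 2)
  expect_equal(half$mm_per_pixel, 0.2)

  # grating of period 16 downscaled 2x has period 8 by FFT peak
  g <- carapacer:::new_calibrated_msimage(
    rep(list(grating(n, 16, 40) + 50), 4) |> setNames(c("LW", "MW", "SW", "UV")),
    mm_per_pixel = 0.1)
  g2 <- rescale_to_common_scale(g, 0.2)
  row <- g2$channels$LW[32, ]
  spec <- Mod(fft(row - mean(row)))[2:32]
  expect_equal(which.max(spec) + 1, 64 / 8 + 1)  # 8 cycles over 64 px

  cal$mm_per_pixel <- NA_real_
  expect_error(rescale_to_common_scale(cal, 0.1), "ruler")
})

test_that("ROI extraction averages over the mask and fills outside with the mean", {
  n <- 32
  mask <- matrix(FALSE, n, n); mask[9:24, 9:24] <- TRUE
  ch <- matrix(80, n, n)
  cal <- carapacer:::new_calibrated_msimage(
    rep(list(ch), 4) |> setNames(c("LW", "MW", "SW", "UV")),
    mm_per_pixel = 0.1, roi_mask = mask)
  r <- extract_roi(cal)
  expect_equal(unlist(r$quad), c(LW = 80, MW = 80, SW = 80, UV = 80))

  # two halves at 60 and 100 average to 80; fill value equals the masked mean
  ch2 <- matrix(0, n, n); ch2[, 1:16] <- 60; ch2[, 17:32] <- 100
  cal2 <- carapacer:::new_calibrated_msimage(
    rep(list(ch2), 4) |> setNames(c("LW", "MW", "SW", "UV")),
    mm_per_pixel = 0.1, roi_mask = mask)
  r2 <- extract_roi(cal2, crop = FALSE)
  expect_equal(r2$quad$LW, 80)
  expect_equal(r2$pattern[1, 1], 80)

  # saturated pixels are excluded from the channel means
  sat <- matrix(FALSE, n, n); sat[9:24, 9:16] <- TRUE
  cal3 <- cal2; cal3$saturated <- sat
  expect_equal(extract_roi(cal3)$quad$LW, 100)

  cal$roi_mask <- NULL
  expect_error(extract_roi(cal), "empty")
})
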