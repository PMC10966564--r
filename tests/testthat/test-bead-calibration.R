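test_that("a noiseless Gaussian blob is localized to better than 0.05 px", {
  x0 <- 50.25; y0 <- 71.75
  cols <- 0:127; rows <- 0:127
  img <- 200 + 1500 * exp(-(outer((rows - y0)^2, (cols - x0)^2, `+`)) / (2 * 3^2))
  ctr <- fit_bead_center(img)
  expect_lt(abs(ctr$center_xy_px[["x"]] - x0), 0.05)
  expect_lt(abs(ctr$center_xy_px[["y"]] - y0), 0.05)
  expect_gt(ctr$amplitude_counts, 1000)
})

test_that("Poisson-noise bead images are localized within 0.5 px on every seed", {
  for (seed in 1:20) {
    g <- generate_bead_image(d_p_true_nm = 80, peak_counts = 2.5e3,
                             noise = noise_model(seed = seed))
    ctr <- fit_bead_center(g$stack)
    expect_lt(abs(ctr$center_xy_px[["x"]] - g$truth$center_px$x), 0.5)
    expect_lt(abs(ctr$center_xy_px[["y"]] - g$truth$center_px$y), 0.5)
  }
})

test_that("a blank frame raises a localization failure", {
  expect_error(fit_bead_center(matrix(0, 64, 64)),
               class = "photonstim_localization_failure")
  flat <- withr::with_seed(1, matrix(rpois(64 * 64, 100), 64, 64))
  expect_error(fit_bead_center(flat),
               class = "photonstim_localization_failure")
})

test_that("sphere geometry maps lateral distance to height correctly", {
  bead <- bead_spec(diameter_um = 7.38) # R = 3.69 um
  # pixel size chosen so columns hit exact fractions of R
  px <- 3.69 * 0.1
  hm <- pixel_heights(c(x = 0, y = 0), bead, px, c(1L, 15L))
  expect_equal(hm$heights_nm[1, 1], 0)              # contact point
  expect_equal(hm$heights_nm[1, 7], (3.69 - sqrt(3.69^2 - (0.6 * 3.69)^2)) * 1e3)
  expect_equal(hm$heights_nm[1, 7], 0.2 * 3690)     # closed-form: y(0.6R) = 0.2R
  expect_false(hm$valid[1, 11])                     # r = R masked invalid
  expect_true(is.na(hm$heights_nm[1, 11]))
  # just inside the equator the height approaches R
  hm2 <- pixel_heights(c(x = 0, y = 0), bead, 3.69 * 0.0999, c(1L, 12L))
  expect_gt(hm2$heights_nm[1, 11], 0.95 * 3690)
  expect_error(pixel_heights(c(x = 0, y = 0), bead, 0, c(4L, 4L)),
               class = "photonstim_invalid_input")
})

test_that("noiseless exponential data are recovered to 1e-6 relative", {
  h <- seq(0, 400, length.out = 200)
  z <- 1800 * exp(-h / 57) + 120
  fit <- fit_penetration_depth(h, z)
  expect_equal(fit$d_p_nm, 57, tolerance = 1e-6)
  expect_equal(fit$amplitude_counts, 1800, tolerance = 1e-6)
  expect_equal(fit$background_counts, 120, tolerance = 1e-4)
  expect_true(fit$reliable)
})

test_that("the fitted depth is permutation invariant in the pixel order", {
  h <- seq(0, 400, length.out = 123)
  z <- 2000 * exp(-h / 80) + 90 + sin(seq_along(h)) # deterministic perturbation
  p <- sample(seq_along(h))
  f1 <- fit_penetration_depth(h, z)
  f2 <- fit_penetration_depth(h[p], z[p])
  expect_equal(f2$d_p_nm, f1$d_p_nm, tolerance = 1e-9)
})

test_that("Poisson noise at 2.5e3 peak counts recovers d_p within 10% on >= 18/20 seeds", {
  ok <- 0L
  for (seed in 1:20) {
    g <- generate_bead_image(d_p_true_nm = 80, peak_counts = 2.5e3,
                             noise = noise_model(seed = seed))
    bf <- run_bead_calibration(g$stack, medium_index = 1.340)
    ok <- ok + (abs(bf$d_p_measured_nm - 80) / 80 < 0.10)
  }
  expect_gte(ok, 18L)
})

test_that("degenerate constant counts are flagged or refused", {
  h <- seq(0, 400, length.out = 100)
  res <- tryCatch(fit_penetration_depth(h, rep(1000, 100)),
                  photonstim_fit_failure = function(e) e)
  if (inherits(res, "dp_fit")) expect_false(res$reliable)
  expect_error(fit_penetration_depth(h[1:10], rep(1, 10)),
               class = "photonstim_invalid_input")
})

test_that("estimator bias vanishes as the noise level shrinks", {
  err <- vapply(c(100, 10, 1), function(sd) {
    e <- vapply(1:5, function(seed) {
      g <- generate_bead_image(
        d_p_true_nm = 57, peak_counts = 2.5e3,
        noise = noise_model(shot_noise = FALSE, read_noise_sd_counts = sd,
                            offset_counts = 0, seed = seed))
      abs(run_bead_calibration(g$stack, medium_index = 1.340,
                               n_water = 1.340)$d_p_measured_nm - 57)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[3], 0.5)
})

test_that("the full chain recovers both reference depths from noiseless images", {
  # waveguide excitation measured in index-matched sucrose, converted to water
  d_suc <- convert_penetration_depth(57, 1.340, 1.450, 491)$d_p_nm
  g <- generate_bead_image(d_p_true_nm = d_suc, noise = noiseless())
  bf <- run_bead_calibration(g$stack, medium_index = 1.450)
  expect_equal(bf$d_p_water_nm, 57, tolerance = 0.05)
  expect_equal(bf$d_p_measured_nm, d_suc, tolerance = 0.05)
  # conversion must never change the medium-frame fit
  expect_equal(bf$d_p_measured_nm, bf$fit$d_p_nm)
  # objective-TIRF case in water (80 nm water-referred)
  g2 <- generate_bead_image(d_p_true_nm = 80, noise = noiseless())
  bf2 <- run_bead_calibration(g2$stack, medium_index = 1.340)
  expect_equal(bf2$d_p_water_nm, 80, tolerance = 0.05)
})

test_that("a stripe-restricted (elliptical) excitation does not bias the fit", {
  stripe <- list(center_row_px = 63.3, width_um = 2.0)
  g <- generate_bead_image(d_p_true_nm = 90, excitation_stripe = stripe,
                           center_px = c(x = 63.8, y = 63.3),
                           noise = noiseless())
  frame <- matrix(g$stack$data[1, , ], 128, 128)
  # excited region is laterally wider than tall: elliptical footprint
  lit <- which(frame > 1, arr.ind = TRUE)
  expect_gt(diff(range(lit[, 2])), 1.3 * diff(range(lit[, 1])))
  mask <- matrix(FALSE, 128, 128)
  mask[unique(lit[, 1]), ] <- TRUE
  bf <- run_bead_calibration(g$stack, medium_index = 1.450, stripe_mask = mask)
  expect_equal(bf$d_p_measured_nm, 90, tolerance = 0.01)
})

test_that("stage errors carry the stage identity", {
  err <- tryCatch(run_bead_calibration(matrix(0, 64, 64), pixel_size_um = 0.129),
                  photonstim_localization_failure = function(e) e)
  expect_match(conditionMessage(err), "fit_bead_center")
  blank <- optical_stack(matrix(0, 64, 64))
  expect_error(run_bead_calibration(blank),
               class = "photonstim_missing_metadata")
})
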