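test_that("generators are bit-reproducible under a fixed seed", {
  a <- generate_bead_image(noise = noise_model(seed = 42))
  b <- generate_bead_image(noise = noise_model(seed = 42))
  expect_identical(a$stack$data, b$stack$data)
  c <- generate_bead_image(noise = noise_model(seed = 43))
  expect_false(identical(a$stack$data, c$stack$data))

  lay <- small_scene(seed = 9)
  m1 <- generate_calcium_movie(lay, noise = noise_model(seed = 9))
  m2 <- generate_calcium_movie(lay, noise = noise_model(seed = 9))
  expect_identical(m1$movie$data, m2$movie$data)

  d1 <- generate_cutback_data(seed = 5)
  d2 <- generate_cutback_data(seed = 5)
  expect_identical(d1$data$transmission_dB, d2$data$transmission_dB)
  expect_false(identical(d1$data$transmission_dB,
                         generate_cutback_data(seed = 6)$data$transmission_dB))
})

test_that("generator calls do not disturb the global RNG stream", {
  withr::with_seed(123, {
    before <- runif(1)
  })
  withr::with_seed(123, {
    invisible(generate_cutback_data(seed = 99))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("the noiseless bead image follows the hemisphere model exactly", {
  ctr <- c(x = 64, y = 64) # integer centre: the contact pixel is exact
  g <- generate_bead_image(d_p_true_nm = 57, peak_counts = 2000,
                           center_px = ctr, noise = noiseless())
  frame <- matrix(g$stack$data[1, , ], 128, 128)
  expect_equal(frame[65, 65], 2000) # r = 0: expected counts = peak
  # a pixel at lateral distance r: counts = peak * exp(-y(r)/d_p)
  r_um <- 10 * 0.129
  y_nm <- (3.69 - sqrt(3.69^2 - r_um^2)) * 1e3
  expect_equal(frame[65, 75], 2000 * exp(-y_nm / 57), tolerance = 1e-12)
  # outside the projected disc the frame is dark
  expect_identical(frame[1, 1], 0)
  expect_identical(g$truth$d_p_true_nm, 57)
  expect_error(generate_bead_image(bead = bead_spec(diameter_um = 30),
                                   noise = noiseless()),
               class = "photonstim_invalid_input")
})

test_that("the waveguide responder mask is exactly the stripe-hit cells", {
  lay <- small_scene(seed = 10)
  g <- generate_calcium_movie(lay, stimulation_mode = "waveguide",
                              noise = noiseless())
  hit_cells <- sort(unique(lay$cell_mask[lay$cell_mask > 0 & lay$waveguide_mask]))
  expect_gt(length(hit_cells), 0)
  expect_identical(g$responder_mask,
                   matrix(lay$cell_mask %in% hit_cells & lay$cell_mask > 0,
                          64, 64))
  # responders are cells; everything outside cells is quiet
  expect_true(all(lay$cell_mask[g$responder_mask] > 0))
})

test_that("zero transient amplitude reduces to a flat baseline movie", {
  g <- generate_calcium_movie(small_scene(seed = 11),
                              transient_amplitude_frac = 0,
                              baseline_counts = 1234, noise = noiseless())
  expect_true(all(g$movie$data == 1234))
})

test_that("noiseless movies realise the generative transient model exactly", {
  lay <- small_scene(seed = 12)
  g <- generate_calcium_movie(lay, stimulation_mode = "full_field",
                              noise = noiseless())
  p <- which(g$responder_mask, arr.ind = TRUE)[1, ]
  expected <- protocol_trace(amp = 5000 * 0.3, tau = 0.5, baseline = 5000)
  expect_equal(g$movie$data[, p[1], p[2]], expected, tolerance = 1e-12)
})

test_that("cut-back generation is an exact line at zero noise", {
  g <- generate_cutback_data(noise_sd_dB = 0)
  expect_equal(g$data$transmission_dB, -0.9 * g$data$length_cm - 13.4)
  expect_identical(g$truth$slope_true, -0.9)
  expect_error(generate_cutback_data(noise_sd_dB = -1),
               class = "photonstim_invalid_input")
})

test_that("every ground-truth record carries its seed", {
  expect_identical(generate_bead_image(noise = noise_model(seed = 3))$truth$seed, 3L)
  expect_identical(generate_calcium_movie(small_scene(),
                                          noise = noise_model(seed = 4))$truth$seed, 4L)
  expect_identical(generate_cutback_data(seed = 5)$truth$seed, 5L)
})
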