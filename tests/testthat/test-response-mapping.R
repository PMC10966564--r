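test_that("window extraction is half-open and frame-exact", {
  mv <- optical_stack(array(seq_len(600 * 4), c(600, 2, 2)))
  win <- extract_window(mv, 21, 31)
  expect_identical(dim(win$data)[1], 100L)
  expect_equal(win$t0_s, 21)
  expect_equal(win$data[1, , ], mv$data[211, , ]) # frame at t = 21.0 s is kept
  full <- extract_window(mv, 0, 60)
  expect_identical(full$data, mv$data)
  expect_error(extract_window(mv, 59, 61), class = "photonstim_invalid_input")
  expect_error(extract_window(mv, 10, 10), class = "photonstim_invalid_input")
  expect_warning(extract_window(mv, 21, 30.5, f_stim_hz = 1),
                 class = "photonstim_offgrid_window")
})

test_that("harmonic score reproduces the forced single-bin value and DC exclusion", {
  t <- (0:99) / 10
  expect_equal(harmonic_response_score(cos(2 * pi * t), 10, 1), 50) # N/2
  expect_equal(harmonic_response_score(rep(7, 100), 10, 1), 0)
  # adding any constant never changes the score (DC bin excluded); only
  # floating-point rounding of the transform remains
  tr <- protocol_trace(amp = 3, baseline = 50)[211:310]
  for (c0 in c(-50, 13.7, 1e4)) {
    expect_equal(harmonic_response_score(tr + c0, 10, 1),
                 harmonic_response_score(tr, 10, 1), tolerance = 1e-9)
  }
})

test_that("off-bin and super-Nyquist harmonics are refused by name", {
  tr <- rnorm(100)
  expect_error(harmonic_response_score(tr[1:99], 10, 1),
               class = "photonstim_invalid_input")
  err <- tryCatch(harmonic_response_score(tr[1:99], 10, 1), error = identity)
  expect_match(conditionMessage(err), "bin")
  expect_error(harmonic_response_score(tr, 10, 1, harmonics = 1:6),
               class = "photonstim_invalid_input")
  expect_error(harmonic_response_score(tr, 10, 1, harmonics = c(0, 1)),
               class = "photonstim_invalid_input")
})

test_that("the score equals a brute-force DFT oracle on a protocol transient train", {
  tr <- protocol_trace(amp = 1, tau = 0.5, baseline = 100)[211:310]
  oracle <- sum(vapply(1:5, function(k) dft_mag_brute(tr, 10 * k), numeric(1)))
  expect_equal(harmonic_response_score(tr, 10, 1), oracle, tolerance = 1e-9)
  # and the fft path agrees too
  oracle_fft <- sum(Mod(fft(tr))[10 * (1:5) + 1])
  expect_equal(harmonic_response_score(tr, 10, 1), oracle_fft, tolerance = 1e-9)
})

test_that("the response map is the pixel-wise score, scale invariant, zero-safe", {
  g <- generate_calcium_movie(small_scene(seed = 2), noise = noise_model(seed = 2))
  map <- response_map(g$movie)
  win <- extract_window(g$movie, 21, 31)
  px <- rbind(c(5L, 9L), c(32L, 32L), c(60L, 13L))
  raw <- apply(px, 1, function(p) {
    harmonic_response_score(win$data[, p[1], p[2]], 10, 1)
  })
  expect_equal(map$scores[px], raw / map$raw_max_score, tolerance = 1e-12)
  # scaling every trace by c > 0 leaves the normalized map unchanged
  scaled <- g$movie
  scaled$data <- scaled$data * 3.7
  expect_equal(response_map(scaled)$scores, map$scores, tolerance = 1e-12)
  zero <- optical_stack(array(0, c(600, 4, 4)))
  zmap <- response_map(zero)
  expect_true(all(zmap$scores == 0))
  expect_identical(zmap$raw_max_score, 0)
})

test_that("waveguide stimulation confines high scores to stripe-adjacent cells", {
  for (seed in 1:3) {
    g <- generate_calcium_movie(small_scene(seed = seed),
                                stimulation_mode = "waveguide",
                                noise = noise_model(seed = seed))
    map <- response_map(g$movie)
    resp <- g$responder_mask
    expect_gt(sum(resp), 0)
    expect_gte(mean(map$scores[resp] > 0.5), 0.95)
    expect_gte(mean(map$scores[!resp] < 0.1), 0.99)
  }
})

test_that("full-field stimulation lights up every soma in the field of view", {
  lay <- small_scene(seed = 4)
  g <- generate_calcium_movie(lay, stimulation_mode = "full_field",
                              noise = noise_model(seed = 4))
  map <- response_map(g$movie)
  expect_true(all(map$scores[lay$cell_mask > 0] > 0.5))
})

test_that("noiseless responses concentrate their energy in harmonic bins", {
  g <- generate_calcium_movie(small_scene(seed = 5), noise = noiseless())
  win <- extract_window(g$movie, 21, 31)
  p <- which(g$responder_mask, arr.ind = TRUE)[1, ]
  spec <- Mod(fft(win$data[, p[1], p[2]]))^2
  non_dc <- spec[2:51]
  in_harm <- sum(non_dc[10 * (1:5)])
  expect_gte(in_harm / sum(non_dc), 0.90)
})

test_that("a pure-noise movie is indistinguishable from its frame-permutation null", {
  noise_movie <- generate_calcium_movie(small_scene(seed = 6),
                                        transient_amplitude_frac = 0,
                                        noise = noise_model(seed = 6))
  map <- response_map(noise_movie$movie)
  expect_identical(max(map$scores), 1) # normalization forces a maximum
  # frame-order permutation oracle: scrambling time destroys nothing in pure
  # noise, so the raw score distribution must be unchanged
  perm <- noise_movie$movie
  perm$data <- perm$data[withr::with_seed(6, sample(dim(perm$data)[1])), , ]
  map_null <- response_map(perm)
  raw <- as.vector(map$scores) * map$raw_max_score
  raw_null <- as.vector(map_null$scores) * map_null$raw_max_score
  expect_equal(median(raw), median(raw_null), tolerance = 0.05)
  expect_equal(quantile(raw, 0.99), quantile(raw_null, 0.99),
               tolerance = 0.10, ignore_attr = TRUE)
  # and a real responder movie scores far outside this null distribution
  resp_movie <- generate_calcium_movie(small_scene(seed = 6),
                                       noise = noise_model(seed = 6))
  resp_map <- response_map(resp_movie$movie)
  raw_resp <- resp_map$scores[resp_movie$responder_mask] * resp_map$raw_max_score
  expect_gt(min(raw_resp), max(raw_null))
})

test_that("ROI averaging is exact and resolves the ten pulse-locked peaks", {
  g <- generate_calcium_movie(small_scene(seed = 7), noise = noise_model(seed = 7))
  one <- matrix(FALSE, 64, 64); one[11, 23] <- TRUE
  tr <- roi_average_trace(g$movie, one)
  expect_identical(tr$mean_counts, g$movie$data[, 11, 23])
  resp <- roi_average_trace(g$movie, g$responder_mask)
  bg_mean <- mean(resp$mean_counts[resp$time_s < 20])
  bg_sd <- sd(resp$mean_counts[resp$time_s < 20])
  # a clear peak right after each of the 10 pulses
  for (tp in 21:30) {
    seg <- resp$mean_counts[resp$time_s >= tp & resp$time_s < tp + 0.3]
    expect_gt(max(seg), bg_mean + 5 * bg_sd)
  }
  # a non-stimulated region stays flat: nothing pulse-locked above background
  qt <- roi_average_trace(g$movie, !g$responder_mask)
  q_mean <- mean(qt$mean_counts[qt$time_s < 20])
  q_sd <- sd(qt$mean_counts[qt$time_s < 20])
  post_pulse <- qt$mean_counts[qt$time_s >= 21 & qt$time_s < 31]
  expect_true(all(post_pulse < q_mean + 4 * q_sd))
  expect_error(roi_average_trace(g$movie, matrix(FALSE, 64, 64)),
               class = "photonstim_invalid_input")
})

test_that("protocol invariants are enforced", {
  expect_error(stim_protocol(pulse_rate_hz = -1), class = "photonstim_invalid_input")
  expect_error(stim_protocol(pulse_width_s = 1.2), class = "photonstim_invalid_input")
  expect_error(stim_protocol(background_s = 55), class = "photonstim_invalid_input")
  expect_equal(pulse_times(stim_protocol()), 21:30)
})
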