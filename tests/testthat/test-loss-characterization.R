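test_that("a noiseless line is recovered exactly with zero standard errors", {
  L <- c(1.2, 2.5, 4.0, 5.5, 7.0, 8.1)
  f <- cutback_fit(cutback_dataset(L, -0.9 * L - 13.4))
  expect_equal(f$propagation_dB_per_cm, -0.9, tolerance = 1e-12)
  expect_equal(f$intercept_dB, -13.4, tolerance = 1e-12)
  expect_lt(f$propagation_se, 1e-10)
  expect_null(f$flag)
})

test_that("the fit is equivariant under a constant transmission offset", {
  g <- generate_cutback_data(seed = 11)
  f0 <- cutback_fit(g$data)
  shifted <- g$data
  shifted$transmission_dB <- shifted$transmission_dB + 3.25
  f1 <- cutback_fit(shifted)
  expect_equal(f1$propagation_dB_per_cm, f0$propagation_dB_per_cm)
  expect_equal(f1$intercept_dB, f0$intercept_dB + 3.25)
  expect_equal(f1$propagation_se, f0$propagation_se)
})

test_that("95% t-intervals cover the true slope at roughly the nominal rate", {
  # n = 6 devices leaves 4 residual df, so the interval uses Student's t
  hits <- vapply(1:100, function(seed) {
    f <- cutback_fit(generate_cutback_data(seed = seed)$data)
    abs(f$propagation_dB_per_cm - (-0.9)) <=
      stats::qt(0.975, f$n - 2L) * f$propagation_se
  }, logical(1))
  expect_gte(sum(hits), 90L)
})

test_that("degenerate datasets are refused or flagged", {
  expect_error(cutback_fit(data.frame(length_cm = 2, transmission_dB = -15)),
               class = "photonstim_invalid_input")
  expect_error(cutback_fit(data.frame(length_cm = c(2, 2, 2),
                                      transmission_dB = c(-15, -15.2, -14.9))),
               class = "photonstim_invalid_input")
  expect_warning(two <- cutback_dataset(c(1.2, 8.1), c(-14.5, -20.7)),
                 class = "photonstim_few_devices")
  f <- cutback_fit(two)
  expect_match(f$flag, "exact interpolation")
  expect_true(is.na(f$propagation_se))
  expect_equal(f$propagation_dB_per_cm, (-20.7 + 14.5) / (8.1 - 1.2))
  expect_warning(cutback_fit(cutback_dataset(1:4, c(-1, -2, -2.5, -1.5) + 1:4)),
                 class = "photonstim_positive_slope")
})

test_that("intercept decomposition is exact arithmetic and round-trips", {
  b <- decompose_intercept(-13.4, -5.5, 2, n_turns = 4)
  expect_identical(b$bend_total_dB, -13.4 - 2 * (-5.5))
  expect_equal(b$bend_total_dB, -2.4)
  expect_equal(b$bend_dB_per_turn, -0.6)
  expect_identical(decompose_intercept(-13.4, 0, 2)$bend_total_dB, -13.4)
  # inverse: intercept = bend + n * coupling
  expect_equal(b$bend_total_dB + b$n_facets * b$coupling_dB_per_facet, -13.4)
  se <- decompose_intercept(-13.4, -5.5, 2, intercept_se = 0.4,
                            coupling_se = 0.3)$bend_total_se
  expect_equal(se, sqrt(0.4^2 + (2 * 0.3)^2))
  expect_error(decompose_intercept(-13.4, -5.5, 0),
               class = "photonstim_invalid_input")
})

test_that("roughness scattering bound vanishes with roughness and scales as sigma^2", {
  expect_equal(as.numeric(payne_lacey_loss(0)), 0)
  a1 <- as.numeric(payne_lacey_loss(2.5))
  a2 <- as.numeric(payne_lacey_loss(5))
  expect_equal(a2 / a1, 4, tolerance = 1e-12)
  # an upper bound must not fall below the measured propagation loss magnitude
  expect_gte(as.numeric(payne_lacey_loss(5)), 0.9)
  expect_identical(attr(payne_lacey_loss(5), "estimate_type"),
                   "order-of-magnitude upper bound")
  expect_error(payne_lacey_loss(5, correlation_length_nm = 0),
               class = "photonstim_invalid_input")
})
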