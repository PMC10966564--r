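test_that("index contrast reproduces the polymer/water values and edge cases", {
  expect_equal(round(index_contrast(1.566, 1.340), 3), 0.144)
  expect_equal(round(index_contrast(1.527, 1.340), 3), 0.122)
  for (n in c(1.0, 1.34, 2.5)) expect_identical(index_contrast(n, n), 0)
  expect_error(index_contrast(0, 1.3), class = "photonstim_invalid_input")
  expect_error(index_contrast(-1.5, 1.3), class = "photonstim_invalid_input")
})

test_that("penetration depth formula round-trips through an independent root finder", {
  dp <- penetration_depth_from_neff(1.5109, 1.340, 491)
  expect_s3_class(dp, "penetration_depth")
  # independent oracle: recover n_eff from d_p by bracketed root finding
  n_back <- uniroot(function(n) {
    491 / (4 * pi * sqrt(n^2 - 1.340^2)) - dp$d_p_nm
  }, c(1.3401, 3), tol = 1e-12)$root
  expect_equal(n_back, 1.5109, tolerance = 1e-9)
  expect_equal(dp$d_p_nm, 56, tolerance = 0.01)
})

test_that("penetration depth is strictly decreasing in n_eff and has the forced limits", {
  ns <- seq(1.36, 3, length.out = 50)
  dps <- vapply(ns, function(n) penetration_depth_from_neff(n, 1.34, 491)$d_p_nm,
                numeric(1))
  expect_true(all(diff(dps) < 0))
  expect_lt(penetration_depth_from_neff(100, 1.34, 491)$d_p_nm, 0.5)
  # algebraic forcing: n_eff^2 - n_clad^2 = (lambda/4pi)^2 (nm^2) => d_p = 1 nm
  lam <- 491
  n_forced <- sqrt((lam / (4 * pi))^2 + 1.34^2)
  expect_equal(penetration_depth_from_neff(n_forced, 1.34, lam)$d_p_nm, 1)
  expect_error(penetration_depth_from_neff(1.2, 1.34, 491),
               class = "photonstim_no_evanescent")
})

test_that("TIRF depth matches the n_eff parameterization and diverges at the critical angle", {
  for (th in c(70, 80, 89.9)) {
    n_eff <- 1.463 * sin(th * pi / 180)
    expect_equal(tirf_penetration_depth(th, 1.463, 1.340, 488)$d_p_nm,
                 penetration_depth_from_neff(n_eff, 1.340, 488)$d_p_nm)
  }
  expect_equal(tirf_penetration_depth(90, 1.463, 1.340, 488)$d_p_nm,
               488 / (4 * pi * sqrt(1.463^2 - 1.340^2)))
  th_c <- asin(1.340 / 1.463) * 180 / pi
  expect_gt(tirf_penetration_depth(th_c + 1e-4, 1.463, 1.340, 488)$d_p_nm, 1e4)
  expect_error(tirf_penetration_depth(th_c - 0.1, 1.463, 1.340, 488),
               class = "photonstim_no_evanescent")
  angles <- seq(th_c + 0.5, 90, length.out = 30)
  dps <- vapply(angles,
                function(a) tirf_penetration_depth(a, 1.463, 1.340, 488)$d_p_nm,
                numeric(1))
  expect_true(all(diff(dps) < 0))
})

test_that("threshold height has the 1/e anchors and exact log-linearity", {
  expect_identical(threshold_height(5, 5, 56), 0)
  expect_equal(threshold_height(exp(1) * 5, 5, 56), 56)
  # doubling the surface intensity adds exactly d_p * ln 2
  for (I in c(10, 1e3, 3.3e5)) {
    expect_equal(threshold_height(2 * I, 5, 56) - threshold_height(I, 5, 56),
                 56 * log(2))
  }
  expect_warning(h <- threshold_height(1, 5, 56),
                 class = "photonstim_threshold_unreached")
  expect_true(is.na(h))
  expect_true(attr(h, "never_reached"))
})

test_that("channelrhodopsin threshold height from the printed surface intensity", {
  h <- threshold_height(3.3e5, 5, 56)
  expect_equal(h, 56 * log(3.3e5 / 5))
  expect_equal(h, 610, tolerance = 0.05) # printed inputs are rounded
})

test_that("minimum input power scales linearly with the threshold", {
  i_per_mW <- 3.3e5
  expect_equal(min_input_power_mW(5, i_per_mW), 5 / 3.3e5)
  expect_equal(min_input_power_mW(10, i_per_mW), 2 * min_input_power_mW(5, i_per_mW))
})

test_that("cladding conversion keeps the tangential wavevector invariant", {
  # hand-computed oracle for the sucrose -> water case
  beta <- sqrt((491 / (4 * pi * 92))^2 + 1.45^2)
  d_expected <- 491 / (4 * pi * sqrt(beta^2 - 1.340^2))
  conv <- convert_penetration_depth(92, 1.45, 1.340, 491)
  expect_equal(conv$d_p_nm, d_expected)
  expect_equal(conv$d_p_nm, 56, tolerance = 0.01)
  expect_equal(conv$n_eff, beta)
  # identity and monotonicity
  expect_equal(convert_penetration_depth(92, 1.45, 1.45, 491)$d_p_nm, 92)
  targets <- c(1.30, 1.34, 1.38, 1.42)
  dps <- vapply(targets,
                function(n) convert_penetration_depth(92, 1.45, n, 491)$d_p_nm,
                numeric(1))
  expect_true(all(diff(dps) > 0))
  expect_error(convert_penetration_depth(200, 1.34, 1.52, 491),
               class = "photonstim_no_evanescent")
})

test_that("conversion round-trips A -> B -> A to 1e-9 relative", {
  cases <- expand.grid(dp = c(30, 57, 92, 150), nA = c(1.34, 1.45),
                       nB = c(1.0, 1.34))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      there <- convert_penetration_depth(dp, nA, nB, 491)$d_p_nm
      back <- convert_penetration_depth(there, nB, nA, 491)$d_p_nm
      expect_equal(back, dp, tolerance = 1e-9)
    })
  }
})
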