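#' Fluorescent calibration bead description
#'
#' @param diameter_um bead diameter in um (default 7.38, the silica
#'   calibration beads used for penetration-depth measurements).
#' @param fluorophore_label text label (default "FITC").
#' @return An object of class `bead_spec`.
#' @export
bead_spec <- function(diameter_um = 7.38, fluorophore_label = "FITC") {
  if (diameter_um <= 0) stop_invalid("diameter_um must be positive")
  structure(list(diameter_um = diameter_um,
                 fluorophore_label = fluorophore_label),
            class = "bead_spec")
}

.single_frame <- function(image) {
  if (inherits(image, "optical_stack")) {
    if (dim(image$data)[1] != 1L) {
      stop_invalid("bead images must be single-frame stacks")
    }
    matrix(image$data[1L, , ], dim(image$data)[2], dim(image$data)[3])
  } else if (is.matrix(image)) image else {
    stop_invalid("image must be an optical_stack or a matrix")
  }
}

#' Locate a bead center by 2-D Gaussian fitting
#'
#' The evanescently excited cap of a bead is, near the contact point, an
#' almost perfectly Gaussian spot (`exp(-y(r)/d_p)` with
#' `y(r) ~ r^2 / (2R)`), so a 2-D Gaussian least-squares fit gives a
#' sub-pixel center. Pixel coordinates are 0-based with pixel centres at
#' integer coordinates.
#'
#' @param image single-frame [optical_stack()] or numeric matrix of counts.
#' @param approximate_center_px optional starting `c(x, y)` (0-based); by
#'   default the brightest pixel after 3x3 smoothing.
#' @param window_px half-size of the square fit window around the start
#'   (default 12 px).
#' @return A list of class `bead_center` with `center_xy_px` (named `x`,
#'   `y`), `center_se_px`, `amplitude_counts`, `background_counts`,
#'   `sigma_px`. Fit divergence or an amplitude below 3x the background
#'   noise SD raises a localization-failure error.
#' @export
fit_bead_center <- function(image, approximate_center_px = NULL, window_px = 12L) {
  m <- .single_frame(image)
  if (is.null(approximate_center_px)) {
    sm <- m
    if (all(dim(m) >= 3L)) { # light 3x3 box smoothing to dodge hot pixels
      sm <- (m[c(1, 1:(nrow(m) - 1)), ] + m + m[c(2:nrow(m), nrow(m)), ]) / 3
      sm <- (sm[, c(1, 1:(ncol(m) - 1))] + sm + sm[, c(2:ncol(m), ncol(m))]) / 3
    }
    pk <- which(sm == max(sm), arr.ind = TRUE)[1, ]
    approximate_center_px <- c(x = unname(pk["col"]) - 1, y = unname(pk["row"]) - 1)
  }
  r0 <- round(approximate_center_px[["y"]]) + 1L
  c0 <- round(approximate_center_px[["x"]]) + 1L
  rows <- max(1L, r0 - window_px):min(nrow(m), r0 + window_px)
  cols <- max(1L, c0 - window_px):min(ncol(m), c0 + window_px)
  d <- data.frame(
    z = as.vector(m[rows, cols]),
    x = rep(cols - 1, each = length(rows)),
    y = rep(rows - 1, times = length(cols)))
  bg0 <- stats::median(d$z)
  a0 <- max(d$z) - bg0
  noise_sd <- stats::mad(as.vector(m[m <= stats::quantile(m, 0.5)]))
  if (noise_sd == 0) noise_sd <- stats::sd(d$z[d$z <= bg0]) %||% 0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)) + b,
      data = d,
      start = list(A = a0, x0 = approximate_center_px[["x"]],
                   y0 = approximate_center_px[["y"]], s = 3, b = bg0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop_localization("bead localization failed: Gaussian fit did not converge")
  co <- summary(fit)$coefficients
  A <- co["A", "Estimate"]
  A_se <- co["A", "Std. Error"]
  insignificant <- !is.finite(A_se) || A < 3 * A_se
  if (!is.finite(A) || A <= 0 ||
      (is.finite(noise_sd) && noise_sd > 0 && A < 3 * noise_sd) ||
      insignificant) {
    stop_localization(sprintf(
      "bead localization failed: amplitude %.1f not significant against background noise (SD %.1f)",
      A, noise_sd))
  }
  structure(
    list(center_xy_px = c(x = co["x0", "Estimate"], y = co["y0", "Estimate"]),
         center_se_px = c(x = co["x0", "Std. Error"], y = co["y0", "Std. Error"]),
         amplitude_counts = A, background_counts = co["b", "Estimate"],
         sigma_px = co["s", "Estimate"]),
    class = "bead_center")
}

#' Per-pixel fluorophore heights from sphere geometry
#'
#' A fluorophore on the lower hemisphere of a bead of radius R at lateral
#' distance r from the contact point sits at height
#' \eqn{y(r) = R - \sqrt{R^2 - r^2}} above the surface. Pixels at or beyond
#' the equator projection (r >= R) are masked invalid.
#'
#' @param center_xy_px bead center, 0-based `c(x, y)` pixel coordinates.
#' @param bead a [bead_spec()].
#' @param pixel_size_um pixel size in um (> 0).
#' @param frame_shape rows x cols of the image.
#' @return A list with `heights_nm` (matrix, NA outside the bead), `valid`
#'   (logical matrix) and `r_um` (lateral distance matrix).
#' @export
pixel_heights <- function(center_xy_px, bead, pixel_size_um, frame_shape) {
  stopifnot(inherits(bead, "bead_spec"))
  if (pixel_size_um <= 0) stop_invalid("pixel_size_um must be positive")
  R_um <- bead$diameter_um / 2
  dy <- (seq_len(frame_shape[1]) - 1L - center_xy_px[["y"]]) * pixel_size_um
  dx <- (seq_len(frame_shape[2]) - 1L - center_xy_px[["x"]]) * pixel_size_um
  r_um <- sqrt(outer(dy^2, dx^2, `+`))
  valid <- r_um < R_um
  h <- matrix(NA_real_, frame_shape[1], frame_shape[2])
  h[valid] <- (R_um - sqrt(R_um^2 - r_um[valid]^2)) * 1e3
  list(heights_nm = h, valid = valid, r_um = r_um)
}

#' Fit the evanescent decay to height-resolved bead counts
#'
#' Nonlinear least squares of \eqn{I(y) = A e^{-y/d_p} + b} over pixels with
#' height below `y_max_nm`. Requires at least 30 valid pairs. A fit whose
#' standard error exceeds 50% of the estimate, or whose data span less than
#' twice the fitted decay length, is flagged unreliable.
#'
#' @param heights_nm per-pixel heights in nm (vector or matrix, NA = invalid).
#' @param counts matching camera counts.
#' @param y_max_nm fit-range cap in nm (default 500).
#' @return A list of class `dp_fit` with `d_p_nm`, `d_p_se_nm`,
#'   `amplitude_counts`, `background_counts`, `n_pixels_used`,
#'   `residual_sd`, `reliable` and `flag`.
#' @export
fit_penetration_depth <- function(heights_nm, counts, y_max_nm = 500) {
  y <- as.vector(heights_nm)
  z <- as.vector(counts)
  keep <- is.finite(y) & is.finite(z) & y <= y_max_nm
  y <- y[keep]; z <- z[keep]
  if (length(y) < 30L) {
    stop_invalid(sprintf("only %d valid (height, count) pairs; need >= 30", length(y)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ A * exp(-y / dp) + b,
                      start = list(A = max(z), dp = 100,
                                   b = unname(stats::quantile(z, 0.05))),
                      lower = c(A = 0, dp = 1e-3, b = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) stop_fit_failure("exponential decay fit did not converge")
  co <- summary(fit)$coefficients
  dp <- co["dp", "Estimate"]
  dp_se <- co["dp", "Std. Error"]
  flag <- NULL
  if (!is.finite(dp_se) || dp_se > 0.5 * dp) {
    flag <- "unreliable: d_p standard error exceeds 50% of the estimate"
  } else if (max(y) < 2 * dp) {
    flag <- "unreliable: sampled heights span less than 2 x fitted d_p"
  }
  structure(
    list(d_p_nm = dp, d_p_se_nm = dp_se,
         amplitude_counts = co["A", "Estimate"],
         background_counts = co["b", "Estimate"],
         n_pixels_used = length(y),
         residual_sd = summary(fit)$sigma,
         reliable = is.null(flag), flag = flag),
    class = "dp_fit")
}

#' End-to-end bead calibration of the evanescent penetration depth
#'
#' Chains the full procedure: locate the bead ([fit_bead_center()]), map
#' pixels to heights from the sphere geometry ([pixel_heights()]), fit the
#' exponential decay ([fit_penetration_depth()]), and convert the fitted
#' penetration depth from the measurement medium to water
#' ([convert_penetration_depth()]). Stage errors propagate with the stage
#' name prefixed.
#'
#' @param image single-frame [optical_stack()] with `pixel_size_um` set, or
#'   a matrix (then `pixel_size_um` must be supplied).
#' @param bead a [bead_spec()].
#' @param medium_index refractive index of the immersion medium during the
#'   measurement (default 1.450, an index-matched sucrose solution).
#' @param wavelength_nm excitation vacuum wavelength in nm.
#' @param pixel_size_um pixel size override in um.
#' @param y_max_nm fit-range cap in nm.
#' @param stripe_mask optional logical matrix: pixels outside the excitation
#'   stripe are excluded before fitting (waveguide-edge case).
#' @param n_water refractive index of water used for the conversion.
#' @return A list of class `bead_fit` combining the stage outputs:
#'   `center_xy_px`, `amplitude_counts`, `background_counts`,
#'   `d_p_measured_nm`, `d_p_water_nm`, `medium_index`, `n_water`,
#'   `fit` (the `dp_fit`), `n_pixels_used`.
#' @export
run_bead_calibration <- function(image, bead = bead_spec(), medium_index = 1.450,
                                 wavelength_nm = 491, pixel_size_um = NULL,
                                 y_max_nm = 500, stripe_mask = NULL,
                                 n_water = 1.340) {
  if (inherits(image, "optical_stack")) {
    if (is.null(pixel_size_um)) pixel_size_um <- image$pixel_size_um
  }
  if (is.null(pixel_size_um) || is.na(pixel_size_um)) {
    stop_missing_metadata("pixel_size_um is required for bead calibration")
  }
  stage <- function(name, expr) {
    withCallingHandlers(expr, photonstim_error = function(e) {
      e$message <- sprintf("[%s] %s", name, e$message)
      stop(e)
    })
  }
  m <- .single_frame(image)
  ctr <- stage("fit_bead_center", fit_bead_center(m))
  hm <- stage("pixel_heights",
              pixel_heights(ctr$center_xy_px, bead, pixel_size_um, dim(m)))
  h <- hm$heights_nm
  if (!is.null(stripe_mask)) h[!stripe_mask] <- NA_real_
  dpfit <- stage("fit_penetration_depth",
                 fit_penetration_depth(h, m, y_max_nm = y_max_nm))
  conv <- stage("convert_penetration_depth",
                convert_penetration_depth(dpfit$d_p_nm, medium_index, n_water,
                                          wavelength_nm))
  structure(
    list(center_xy_px = ctr$center_xy_px, center_se_px = ctr$center_se_px,
         amplitude_counts = dpfit$amplitude_counts,
         background_counts = dpfit$background_counts,
         d_p_measured_nm = dpfit$d_p_nm, d_p_water_nm = conv$d_p_nm,
         medium_index = medium_index, n_water = n_water,
         wavelength_nm = wavelength_nm, fit = dpfit,
         n_pixels_used = dpfit$n_pixels_used),
    class = "bead_fit")
}

#' @export
print.bead_fit <- function(x, ...) {
  cat(sprintf(
    "<bead_fit> center (%.2f, %.2f) px; d_p = %.1f nm in medium (n = %.3f), %.1f nm in water (n = %.3f); %d px\n",
    x$center_xy_px[["x"]], x$center_xy_px[["y"]], x$d_p_measured_nm,
    x$medium_index, x$d_p_water_nm, x$n_water, x$n_pixels_used))
  if (!is.null(x$fit$flag)) cat(" flag:", x$fit$flag, "\n")
  invisible(x)
}
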