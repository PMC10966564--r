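#' Rib waveguide cross-section geometry
#'
#' Describes the imprinted polymer rib: a raised strip of width `width_um` and
#' height `core_height_nm` sitting on a thin residual slab of the same
#' material (`slab_height_nm`, a by-product of nanoimprint replication). The
#' low aspect ratio lets neurons grow across the waveguide while keeping the
#' mode pressed against the top surface.
#'
#' @param width_um rib width in um (default 4.5).
#' @param core_height_nm rib height above the residual slab in nm (default 300).
#' @param slab_height_nm residual slab thickness in nm (default 40).
#' @param indices a [material_indices()] object.
#' @return An object of class `waveguide_geometry`.
#' @examples
#' waveguide_geometry()
#' @export
waveguide_geometry <- function(width_um = 4.5, core_height_nm = 300,
                               slab_height_nm = 40,
                               indices = material_indices()) {
  stopifnot(inherits(indices, "material_indices"))
  if (width_um <= 0) stop_invalid("width_um must be positive")
  if (core_height_nm < 0 || slab_height_nm < 0) {
    stop_invalid("heights must be non-negative")
  }
  structure(
    list(width_um = width_um, core_height_nm = core_height_nm,
         slab_height_nm = slab_height_nm, indices = indices),
    class = "waveguide_geometry"
  )
}

#' @export
print.waveguide_geometry <- function(x, ...) {
  cat(sprintf("<waveguide_geometry> w = %.2f um, core = %.0f nm, slab = %.0f nm\n",
              x$width_um, x$core_height_nm, x$slab_height_nm))
  print(x$indices)
  invisible(x)
}

# Area-averaged relative permittivity on the finite-difference grid.
# Interfaces are axis aligned, so the average over a cell is a product of
# 1-D coverage fractions; this restores near second-order accuracy of the
# scalar discretisation at the index steps.
.eps_grid <- function(geometry, x_nm, y_nm, dx, dy) {
  ind <- geometry$indices
  e_core <- ind$n_core^2
  e_sub <- ind$n_substrate^2
  e_clad <- ind$n_cladding^2
  hs <- geometry$slab_height_nm
  ht <- hs + geometry$core_height_nm
  hw <- geometry$width_um * 1e3 / 2

  frac <- function(a, b, lo, hi) pmin(b, hi) - pmax(a, lo)
  y1 <- y_nm - dy / 2; y2 <- y_nm + dy / 2
  f_sub <- pmax(frac(y1, y2, -Inf, 0), 0) / dy
  f_slab <- pmax(frac(y1, y2, 0, hs), 0) / dy
  f_band <- pmax(frac(y1, y2, hs, ht), 0) / dy
  f_top <- pmax(1 - f_sub - f_slab - f_band, 0)

  x1 <- abs(x_nm) - dx / 2; x2 <- abs(x_nm) + dx / 2
  fx <- pmax(pmin(x2, hw) - pmax(x1, -hw), 0) / dx # fraction inside the rib
  fx <- pmin(fx, 1)

  band <- outer(f_band, fx * e_core + (1 - fx) * e_clad)   # ny x nx
  outer(f_sub, rep(1, length(x_nm))) * e_sub +
    outer(f_slab, rep(1, length(x_nm))) * e_core +
    band +
    outer(f_top, rep(1, length(x_nm))) * e_clad
}

.lateral_order <- function(field, row) {
  v <- field[row, ]
  v[abs(v) < 1e-3 * max(abs(v))] <- 0
  s <- sign(v[v != 0])
  sum(diff(s) != 0)
}

#' Solve the guided modes of a rib waveguide cross-section
#'
#' Semi-vectorial scalar-Helmholtz finite-difference solver on a regular
#' cell-centred grid with Dirichlet boundaries. The discretised operator
#' \eqn{\nabla_t^2 + k_0^2\varepsilon(x,y)} is assembled as a sparse
#' symmetric matrix and its largest eigenpairs (the guided modes, with
#' \eqn{\beta^2} just below \eqn{k_0^2 n_{core}^2}) are extracted by
#' shift-invert Lanczos iteration (sparse Cholesky factorisation of
#' \eqn{\sigma I - A}). Polarization is quoted as TE-like
#' (dominant lateral E field); permittivity is area-averaged across
#' interfaces.
#'
#' @param geometry a [waveguide_geometry()] object.
#' @param wavelength_nm vacuum wavelength in nm; defaults to the wavelength of
#'   the geometry's indices.
#' @param grid_spacing_nm length-2 numeric `c(x, y)` cell size in nm
#'   (default 50 x 10). Vertical spacing above 25 nm triggers a warning,
#'   above 50 nm the call is refused.
#' @param n_modes number of guided modes requested.
#' @param window_um length-2 numeric `c(x, y)` computational window in um
#'   (default 9 x 4, with 1.5 um of substrate below the slab). The window
#'   must pad the rib by at least 2 um laterally and 1.5 um vertically.
#' @return A list of `mode_solution` objects sorted by descending effective
#'   index, each with elements `n_eff`, `intensity` (mW/mm2 at 1 mW guided
#'   power, rows = y, cols = x), `field` (real scalar field, unit L2 norm in
#'   mW), `x_nm`, `y_nm`, `mode_label`, `surface_peak_density_per_mW`,
#'   `d_p_nm`, `wavelength_nm`, `geometry`. If no guided mode exists an empty
#'   list is returned with a `diagnostic` attribute.
#' @export
solve_modes <- function(geometry, wavelength_nm = geometry$indices$wavelength_nm,
                        grid_spacing_nm = c(50, 10), n_modes = 3L,
                        window_um = c(9, 4)) {
  stopifnot(inherits(geometry, "waveguide_geometry"))
  dx <- grid_spacing_nm[[1]]
  dy <- grid_spacing_nm[[length(grid_spacing_nm)]]
  if (dy > 50) stop_invalid("vertical grid spacing above 50 nm is too coarse; refused")
  if (dx > 250) stop_invalid("lateral grid spacing above 250 nm is too coarse; refused")
  if (dy > 25) {
    warn_photonstim("vertical grid spacing above 25 nm near the core is coarser than recommended",
                    "photonstim_coarse_grid")
  }
  wx <- window_um[[1]] * 1e3
  wy <- window_um[[2]] * 1e3
  sub_pad <- 1500
  rib_w <- geometry$width_um * 1e3
  h_top <- geometry$slab_height_nm + geometry$core_height_nm
  if ((wx - rib_w) / 2 < 2000) {
    stop_invalid("window must pad the rib by at least 2 um laterally")
  }
  if (wy - sub_pad - h_top < 1500) {
    stop_invalid("window must pad the rib top by at least 1.5 um vertically")
  }

  nx <- round(wx / dx)
  ny <- round(wy / dy)
  x_nm <- (seq_len(nx) - (nx + 1) / 2) * dx
  y_nm <- -sub_pad + (seq_len(ny) - 0.5) * dy
  k0 <- 2 * pi / wavelength_nm
  eps <- .eps_grid(geometry, x_nm, y_nm, dx, dy)

  N <- nx * ny
  idx <- function(iy, ix) iy + (ix - 1L) * ny
  diag_val <- as.numeric(-2 / dx^2 - 2 / dy^2 + k0^2 * eps)
  # vertical neighbours (within a column)
  iy <- rep(seq_len(ny - 1L), nx)
  ix <- rep(seq_len(nx), each = ny - 1L)
  i_v <- idx(iy, ix); j_v <- idx(iy + 1L, ix)
  # horizontal neighbours
  iy2 <- rep(seq_len(ny), nx - 1L)
  ix2 <- rep(seq_len(nx - 1L), each = ny)
  i_h <- idx(iy2, ix2); j_h <- idx(iy2, ix2 + 1L)

  A <- Matrix::sparseMatrix(
    i = c(seq_len(N), i_v, j_v, i_h, j_h),
    j = c(seq_len(N), j_v, i_v, j_h, i_h),
    x = c(diag_val, rep(1 / dy^2, 2 * length(i_v)), rep(1 / dx^2, 2 * length(i_h))),
    dims = c(N, N))
  A <- Matrix::forceSymmetric(A)

  sigma <- k0^2 * geometry$indices$n_core^2
  ch <- Matrix::Cholesky(Matrix::Diagonal(N, sigma) - A, LDL = FALSE)
  op <- function(v, extra = NULL) as.numeric(Matrix::solve(ch, v))
  nev <- as.integer(n_modes) + 2L
  res <- igraph::arpack(op, sym = TRUE,
                        options = list(n = N, nev = nev,
                                       ncv = max(4L * nev + 10L, 40L),
                                       which = "LA", maxiter = 5000L))
  beta2 <- sigma - 1 / res$values
  ord <- order(beta2, decreasing = TRUE)
  beta2 <- beta2[ord]
  vecs <- res$vectors[, ord, drop = FALSE]
  n_eff <- sqrt(pmax(beta2, 0)) / k0

  n_guide_min <- max(geometry$indices$n_substrate, geometry$indices$n_cladding)
  guided <- which(n_eff > n_guide_min + 1e-9)
  if (length(guided) == 0L) {
    out <- list()
    attr(out, "diagnostic") <- sprintf(
      "no guided mode: largest effective index %.4f does not exceed %.4f",
      max(n_eff), n_guide_min)
    message(attr(out, "diagnostic"))
    return(out)
  }
  guided <- guided[seq_len(min(length(guided), n_modes))]

  dA_mm2 <- dx * dy * 1e-12 # nm^2 -> mm^2
  modes <- lapply(guided, function(k) {
    psi <- matrix(vecs[, k], nrow = ny, ncol = nx)
    if (psi[which.max(abs(psi))] < 0) psi <- -psi
    nrm <- sum(psi^2) * dA_mm2
    field <- psi / sqrt(nrm)            # L2 norm = 1 mW
    intensity <- field^2                 # mW/mm2 at 1 mW guided power
    row_pk <- which.max(apply(abs(field), 1, max))
    m <- structure(
      list(n_eff = n_eff[k], field = field, intensity = intensity,
           x_nm = x_nm, y_nm = y_nm, dx_nm = dx, dy_nm = dy,
           mode_label = list(family = "TE-like",
                             order = .lateral_order(field, row_pk)),
           wavelength_nm = wavelength_nm, geometry = geometry,
           surface_peak_density_per_mW = NA_real_, d_p_nm = NA_real_),
      class = "mode_solution")
    m$surface_peak_density_per_mW <- surface_intensity(m, 1)
    m$d_p_nm <- penetration_depth_from_neff(
      m$n_eff, geometry$indices$n_cladding, wavelength_nm)$d_p_nm
    m
  })
  modes
}

#' @export
print.mode_solution <- function(x, ...) {
  cat(sprintf(
    "<mode_solution> %s%d%d  n_eff = %.4f  d_p = %.1f nm  I_surf = %.3g mW/mm2 per mW\n",
    if (x$mode_label$family == "TE-like") "TE" else "TM",
    x$mode_label$order, 0L, x$n_eff, x$d_p_nm, x$surface_peak_density_per_mW))
  invisible(x)
}

# index of the first grid row lying entirely in the cladding above the rib top
.first_cladding_row <- function(mode) {
  h_top <- mode$geometry$slab_height_nm + mode$geometry$core_height_nm
  which(mode$y_nm - mode$dy_nm / 2 >= h_top - 1e-9)[1]
}

#' Peak power density on the waveguide top surface
#'
#' The maximum of the mode's power-density profile along the horizontal line
#' at the rib top surface, scaled linearly by the guided power. Because grid
#' values live at cell centres, the value in the first pure-cladding row is
#' extrapolated back to the interface with the mode's own evanescent decay
#' constant.
#'
#' @param mode a `mode_solution` from [solve_modes()].
#' @param input_power_mW guided power in mW.
#' @return Peak surface power density in mW/mm2.
#' @export
surface_intensity <- function(mode, input_power_mW = 1) {
  stopifnot(inherits(mode, "mode_solution"))
  if (input_power_mW <= 0) stop_invalid("input_power_mW must be positive")
  h_top <- mode$geometry$slab_height_nm + mode$geometry$core_height_nm
  r0 <- .first_cladding_row(mode)
  d_p <- penetration_depth_from_neff(
    mode$n_eff, mode$geometry$indices$n_cladding, mode$wavelength_nm)$d_p_nm
  line <- mode$intensity[r0, ]
  offset <- mode$y_nm[r0] - h_top
  max(line) * exp(offset / d_p) * input_power_mW
}

#' Penetration depth of a solved mode from its intensity tail
#'
#' Fits the exponential decay of the mode's power density above the rib top
#' surface (log-linear least squares along the vertical line through the
#' surface intensity maximum) and cross-checks the fitted decay length
#' against the closed form \eqn{\lambda/(4\pi\sqrt{n_{eff}^2 - n_c^2})}.
#' Disagreement beyond 10%, or a tail fit with R2 < 0.99, attaches a
#' diagnostic warning.
#'
#' @param mode a `mode_solution` from [solve_modes()].
#' @param fit_range_nm vertical extent above the surface used for the fit
#'   (default 400 nm, skipping the first interface cell).
#' @return A `penetration_depth` object whose `d_p_nm` is the fitted decay
#'   length, with attributes `d_p_formula_nm` and `r_squared`.
#' @export
mode_penetration_depth <- function(mode, fit_range_nm = 400) {
  stopifnot(inherits(mode, "mode_solution"))
  h_top <- mode$geometry$slab_height_nm + mode$geometry$core_height_nm
  r0 <- .first_cladding_row(mode)
  col <- which.max(mode$intensity[r0, ])
  rows <- which(mode$y_nm >= mode$y_nm[r0] + mode$dy_nm / 2 &
                  mode$y_nm <= h_top + fit_range_nm)
  y <- mode$y_nm[rows]
  I <- mode$intensity[rows, col]
  if (any(I <= 0) || length(rows) < 4L) {
    stop_fit_failure("intensity tail above the surface is not positive/long enough to fit")
  }
  fit <- stats::lm(log(I) ~ y)
  d_fit <- -1 / stats::coef(fit)[["y"]]
  r2 <- summary(fit)$r.squared
  d_formula <- penetration_depth_from_neff(
    mode$n_eff, mode$geometry$indices$n_cladding, mode$wavelength_nm)$d_p_nm
  if (r2 < 0.99) {
    warn_photonstim(sprintf("non-exponential tail: fit R2 = %.4f < 0.99", r2),
                    "photonstim_nonexponential_tail")
  }
  if (abs(d_fit - d_formula) / d_formula > 0.10) {
    warn_photonstim(sprintf(
      "fitted decay length %.1f nm deviates from the closed form %.1f nm by > 10%%",
      d_fit, d_formula), "photonstim_dp_mismatch")
  }
  out <- new_penetration_depth(d_fit, mode$n_eff,
                               mode$geometry$indices$n_cladding,
                               mode$wavelength_nm)
  attr(out, "d_p_formula_nm") <- d_formula
  attr(out, "r_squared") <- r2
  out
}
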