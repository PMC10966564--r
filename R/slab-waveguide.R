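#' Effective index of a three-layer asymmetric slab waveguide
#'
#' Solves the standard dispersion relation of a planar film of index `n_core`
#' between `n_substrate` and `n_cladding`:
#' \deqn{k_0 d \sqrt{n_1^2 - N^2} = m\pi +
#'   \arctan\!\left(\rho_2\sqrt{\frac{N^2-n_2^2}{n_1^2-N^2}}\right) +
#'   \arctan\!\left(\rho_3\sqrt{\frac{N^2-n_3^2}{n_1^2-N^2}}\right)}
#' with \eqn{\rho_i = 1} for TE and \eqn{\rho_i = (n_1/n_i)^2} for TM. The
#' root is bracketed on \eqn{N \in (\max(n_2,n_3), n_1)} over 1000 initial
#' intervals and refined by bisection to 1e-9 in `N` — fully deterministic.
#'
#' @param indices a [material_indices()] object.
#' @param thickness_nm film thickness in nm.
#' @param polarization `"TE"` or `"TM"`.
#' @param mode_index integer mode order m >= 0.
#' @return The effective index as a numeric scalar, or `NA` (with attribute
#'   `status = "cut off"`) when the requested mode is not guided.
#' @examples
#' slab_neff(material_indices(), thickness_nm = 340)
#' @export
slab_neff <- function(indices, thickness_nm, polarization = c("TE", "TM"),
                      mode_index = 0L) {
  stopifnot(inherits(indices, "material_indices"))
  polarization <- match.arg(polarization)
  if (thickness_nm <= 0) stop_invalid("thickness_nm must be positive")
  if (mode_index < 0 || mode_index != round(mode_index)) {
    stop_invalid("mode_index must be a non-negative integer")
  }
  n1 <- indices$n_core
  n2 <- indices$n_substrate
  n3 <- indices$n_cladding
  if (n1 <= max(n2, n3)) stop_invalid("core index must exceed substrate and cladding")
  k0 <- 2 * pi / indices$wavelength_nm
  rho2 <- if (polarization == "TM") (n1 / n2)^2 else 1
  rho3 <- if (polarization == "TM") (n1 / n3)^2 else 1
  m <- as.integer(mode_index)

  disp <- function(N) {
    kap <- sqrt(pmax(n1^2 - N^2, 0))
    g2 <- sqrt(pmax(N^2 - n2^2, 0))
    g3 <- sqrt(pmax(N^2 - n3^2, 0))
    k0 * thickness_nm * kap - m * pi -
      atan2(rho2 * g2, kap) - atan2(rho3 * g3, kap)
  }

  lo <- max(n2, n3)
  hi <- n1
  eps <- 1e-12 * (hi - lo)
  grid <- seq(lo + eps, hi - eps, length.out = 1001L)
  f <- disp(grid)
  # dispersion is monotone decreasing in N; find the sign change
  idx <- which(f[-length(f)] > 0 & f[-1L] <= 0)
  if (length(idx) == 0L) {
    if (all(f < 0)) {
      return(structure(NA_real_, status = "cut off"))
    }
    # root pinned inside the last interval (f>0 throughout except endpoint)
    idx <- length(grid) - 1L
  }
  root <- stats::uniroot(disp, lower = grid[idx[1L]], upper = grid[idx[1L] + 1L],
                         tol = 1e-9)$root
  root
}

#' Effective-index-method estimate for a rib waveguide
#'
#' Classic two-step reduction of a rib cross-section: the vertical slab
#' problem is solved (TE) at the rib thickness and at the residual slab
#' thickness, then the resulting effective indices form a lateral slab of
#' width `width_um` that is solved with the orthogonal (TM) polarization.
#' When the thin residual slab is below cutoff, the lateral cladding falls
#' back to the larger of substrate and cladding index.
#'
#' Used as an independent cross-check of the finite-difference solver.
#'
#' @param geometry a [waveguide_geometry()] object.
#' @param lateral_mode integer lateral mode order (0 for the fundamental).
#' @return Effective index estimate (numeric), or `NA` if unguided.
#' @export
effective_index_method <- function(geometry, lateral_mode = 0L) {
  stopifnot(inherits(geometry, "waveguide_geometry"))
  ind <- geometry$indices
  n_core_slab <- slab_neff(ind, geometry$core_height_nm + geometry$slab_height_nm,
                           polarization = "TE", mode_index = 0L)
  if (is.na(n_core_slab)) return(structure(NA_real_, status = "cut off"))
  n_side <- if (geometry$slab_height_nm > 0) {
    slab_neff(ind, geometry$slab_height_nm, polarization = "TE", mode_index = 0L)
  } else NA_real_
  if (is.na(n_side)) n_side <- max(ind$n_substrate, ind$n_cladding)
  lateral <- material_indices(
    n_core = n_core_slab, n_substrate = n_side, n_cladding = n_side,
    wavelength_nm = ind$wavelength_nm)
  slab_neff(lateral, geometry$width_um * 1e3, polarization = "TM",
            mode_index = lateral_mode)
}
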