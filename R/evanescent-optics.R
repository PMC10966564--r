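#' Material refractive indices for a waveguide system
#'
#' Bundles the refractive indices of the core, substrate and cladding together
#' with the vacuum wavelength they refer to. Defaults describe the hybrid
#' polymer OrmoClear on fused silica with a water cladding at 491 nm, the
#' low-index-contrast system used for evanescent-field stimulation of neurons.
#'
#' @param n_core core refractive index (OrmoClear: 1.566 at 491 nm;
#'   OrmoComp: 1.527).
#' @param n_substrate substrate refractive index (fused silica: 1.463 at
#'   491 nm, Malitson dispersion).
#' @param n_cladding cladding refractive index (water: 1.340 at 491 nm).
#' @param wavelength_nm vacuum wavelength in nm.
#' @return An object of class `material_indices`.
#' @examples
#' material_indices()
#' @export
material_indices <- function(n_core = 1.566, n_substrate = 1.463,
                             n_cladding = 1.340, wavelength_nm = 491) {
  if (!all(is.finite(c(n_core, n_substrate, n_cladding, wavelength_nm)))) {
    stop_invalid("all indices and the wavelength must be finite numbers")
  }
  if (n_core <= 1 || n_substrate <= 1 || n_cladding <= 1) {
    stop_invalid("refractive indices must exceed 1")
  }
  if (n_core <= max(n_substrate, n_cladding)) {
    stop_invalid("guidance requires n_core > max(n_substrate, n_cladding)")
  }
  if (wavelength_nm <= 0) stop_invalid("wavelength_nm must be positive")
  structure(
    list(n_core = n_core, n_substrate = n_substrate,
         n_cladding = n_cladding, wavelength_nm = wavelength_nm),
    class = "material_indices"
  )
}

#' @export
print.material_indices <- function(x, ...) {
  cat(sprintf(
    "<material_indices> n_core = %.4f, n_substrate = %.4f, n_cladding = %.4f @ %.1f nm\n",
    x$n_core, x$n_substrate, x$n_cladding, x$wavelength_nm))
  invisible(x)
}

#' Relative index contrast of a waveguide core against its cladding
#'
#' The contrast \eqn{\Delta = (n_{core} - n_{clad})/n_{core}} controls how
#' strongly a guided mode overlaps the cladding: polymer-on-glass systems in
#' water are low contrast (OrmoClear/water: 0.144; OrmoComp/water: 0.122),
#' which pushes the mode towards the top surface where cells sit.
#'
#' @param n_core core refractive index.
#' @param n_cladding cladding refractive index.
#' @return Dimensionless contrast `(n_core - n_cladding) / n_core`.
#' @examples
#' index_contrast(1.566, 1.340) # 0.144
#' @export
index_contrast <- function(n_core, n_cladding) {
  if (!is.numeric(n_core) || !is.numeric(n_cladding) || anyNA(c(n_core, n_cladding))) {
    stop_invalid("indices must be numeric and non-missing")
  }
  if (any(n_core <= 0)) stop_invalid("n_core must be positive")
  (n_core - n_cladding) / n_core
}

new_penetration_depth <- function(d_p_nm, n_eff, cladding_index, wavelength_nm) {
  structure(
    list(d_p_nm = d_p_nm, n_eff = n_eff, cladding_index = cladding_index,
         wavelength_nm = wavelength_nm),
    class = "penetration_depth"
  )
}

#' @export
print.penetration_depth <- function(x, ...) {
  cat(sprintf("<penetration_depth> d_p = %.2f nm (n_eff = %.4f, n_clad = %.4f, lambda = %.1f nm)\n",
              x$d_p_nm, x$n_eff, x$cladding_index, x$wavelength_nm))
  invisible(x)
}

#' Evanescent 1/e intensity penetration depth from an effective index
#'
#' For a guided mode of effective index \eqn{n_{eff}} bounded by a cladding of
#' index \eqn{n_c}, the intensity above the surface decays as
#' \eqn{I(y) = I_0 e^{-y/d_p}} with
#' \deqn{d_p = \frac{\lambda}{4\pi\sqrt{n_{eff}^2 - n_c^2}}.}
#' (The factor 4\eqn{\pi} rather than 2\eqn{\pi} makes this an intensity,
#' not field, decay length.)
#'
#' @param n_eff effective index of the guided mode.
#' @param n_cladding cladding refractive index.
#' @param wavelength_nm vacuum wavelength in nm.
#' @return A `penetration_depth` object with elements `d_p_nm`, `n_eff`,
#'   `cladding_index`, `wavelength_nm`.
#' @examples
#' penetration_depth_from_neff(1.5109, 1.340, 491)$d_p_nm # ~56 nm
#' @export
penetration_depth_from_neff <- function(n_eff, n_cladding, wavelength_nm) {
  if (wavelength_nm <= 0) stop_invalid("wavelength_nm must be positive")
  if (n_eff <= n_cladding) {
    stop_no_evanescent(sprintf(
      "no evanescent regime: n_eff (%.4f) must exceed n_cladding (%.4f)",
      n_eff, n_cladding))
  }
  d_p <- wavelength_nm / (4 * pi * sqrt(n_eff^2 - n_cladding^2))
  new_penetration_depth(d_p, n_eff, n_cladding, wavelength_nm)
}

#' TIRF penetration depth versus incidence angle
#'
#' In objective-type TIRF the evanescent layer above the glass/water interface
#' has \eqn{d_p = \lambda / (4\pi\sqrt{n_i^2\sin^2\theta - n_c^2})}, the same
#' expression as [penetration_depth_from_neff()] with
#' \eqn{n_{eff} = n_i \sin\theta}. The depth diverges at the critical angle
#' and shrinks monotonically towards grazing incidence.
#'
#' @param theta_deg incidence angle at the interface, in degrees.
#' @param n_incident refractive index of the incidence medium (e.g. fused
#'   silica, 1.463).
#' @param n_cladding refractive index of the low-index medium (water, 1.340).
#' @param wavelength_nm vacuum wavelength in nm.
#' @return A `penetration_depth` object.
#' @examples
#' tirf_penetration_depth(75, 1.463, 1.340, 488)
#' @export
tirf_penetration_depth <- function(theta_deg, n_incident, n_cladding, wavelength_nm) {
  if (theta_deg <= 0 || theta_deg > 90) {
    stop_invalid("theta_deg must lie in (0, 90] degrees")
  }
  n_eff <- n_incident * sin(theta_deg * pi / 180)
  if (n_eff <= n_cladding) {
    stop_no_evanescent(sprintf(
      "angle %.2f deg is at or below the critical angle (%.2f deg)",
      theta_deg, asin(min(n_cladding / n_incident, 1)) * 180 / pi))
  }
  penetration_depth_from_neff(n_eff, n_cladding, wavelength_nm)
}

#' Height at which the evanescent intensity crosses a threshold
#'
#' Given the intensity at the waveguide surface and an activation threshold
#' (e.g. the ~5 mW/mm2 irradiance needed to trigger channelrhodopsin-2), the
#' exponential decay crosses the threshold at
#' \eqn{y^\ast = d_p \ln(I_{surf}/I_{th})}.
#'
#' @param I_surface intensity at the surface, mW/mm2.
#' @param I_threshold threshold intensity, mW/mm2.
#' @param d_p_nm penetration depth in nm.
#' @return Height in nm at which the intensity falls to `I_threshold`.
#'   If `I_surface < I_threshold` the threshold is never reached: the return
#'   value is `NA` carrying attribute `never_reached = TRUE`, with a warning.
#' @examples
#' threshold_height(3.3e5, 5, 56) # ~621 nm
#' @export
threshold_height <- function(I_surface, I_threshold, d_p_nm) {
  if (I_threshold <= 0) stop_invalid("I_threshold must be positive")
  if (d_p_nm <= 0) stop_invalid("d_p_nm must be positive")
  if (I_surface < I_threshold) {
    warn_photonstim("threshold intensity is never reached at the surface",
                    "photonstim_threshold_unreached")
    return(structure(NA_real_, never_reached = TRUE))
  }
  d_p_nm * log(I_surface / I_threshold)
}

#' Minimum guided power for a surface intensity to reach a threshold
#'
#' Surface intensity scales linearly with the guided power, so the smallest
#' input power at which the surface just reaches `I_threshold` is
#' `I_threshold / surface_density_per_mW`.
#'
#' @param I_threshold threshold intensity, mW/mm2.
#' @param surface_density_per_mW surface intensity per 1 mW guided power,
#'   mW/mm2 per mW.
#' @return Minimum input power in mW.
#' @export
min_input_power_mW <- function(I_threshold, surface_density_per_mW) {
  if (I_threshold <= 0 || surface_density_per_mW <= 0) {
    stop_invalid("intensities must be positive")
  }
  I_threshold / surface_density_per_mW
}

#' Convert a penetration depth between cladding media
#'
#' A penetration depth measured with one cladding (e.g. an index-matched
#' sucrose solution) can be restated for another (water). The tangential
#' wavevector of the guided or totally reflected wave,
#' \eqn{\beta/k_0 = \sqrt{(\lambda/4\pi d_p)^2 + n_{c,meas}^2}}, does not
#' depend on which medium is being probed; holding it fixed gives
#' \eqn{d_p' = \lambda / (4\pi\sqrt{\beta^2/k_0^2 - n_{c,target}^2})}.
#'
#' @param d_p_measured_nm measured penetration depth in nm.
#' @param n_cladding_measured cladding index during the measurement.
#' @param n_cladding_target cladding index to convert to.
#' @param wavelength_nm vacuum wavelength in nm.
#' @return A `penetration_depth` object for the target cladding; its `n_eff`
#'   element is the invariant tangential index \eqn{\beta/k_0}.
#' @examples
#' convert_penetration_depth(92, 1.45, 1.340, 491)$d_p_nm # ~56 nm
#' @export
convert_penetration_depth <- function(d_p_measured_nm, n_cladding_measured,
                                      n_cladding_target, wavelength_nm) {
  if (d_p_measured_nm <= 0) stop_invalid("d_p_measured_nm must be positive")
  if (wavelength_nm <= 0) stop_invalid("wavelength_nm must be positive")
  beta <- sqrt((wavelength_nm / (4 * pi * d_p_measured_nm))^2 + n_cladding_measured^2)
  if (beta <= n_cladding_target) {
    stop_no_evanescent(sprintf(
      "no evanescent regime in the target medium: beta/k0 = %.4f <= n_target = %.4f",
      beta, n_cladding_target))
  }
  penetration_depth_from_neff(beta, n_cladding_target, wavelength_nm)
}
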