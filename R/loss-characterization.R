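#' Cut-back transmission dataset
#'
#' Total transmission (dB, losses negative) of a set of otherwise identical
#' waveguide devices whose straight-segment lengths differ — the input to the
#' cut-back propagation-loss regression.
#'
#' @param lengths_cm straight-segment lengths in cm (positive, not all equal).
#' @param transmissions_dB measured total transmission per device in dB.
#' @param wavelength_nm measurement wavelength in nm.
#' @return An object of class `cutback_dataset` (also a data.frame with
#'   columns `length_cm`, `transmission_dB`).
#' @export
cutback_dataset <- function(lengths_cm, transmissions_dB, wavelength_nm = 489) {
  if (length(lengths_cm) != length(transmissions_dB)) {
    stop_invalid("lengths and transmissions must have equal length")
  }
  if (any(lengths_cm <= 0)) stop_invalid("lengths must be strictly positive")
  if (length(unique(lengths_cm)) < 2L) {
    stop_invalid("lengths must not all be equal")
  }
  if (length(lengths_cm) < 3L) {
    warn_photonstim("fewer than 3 devices: slope uncertainty will be unreliable",
                    "photonstim_few_devices")
  }
  structure(
    data.frame(length_cm = lengths_cm, transmission_dB = transmissions_dB),
    wavelength_nm = wavelength_nm,
    class = c("cutback_dataset", "data.frame")
  )
}

#' Cut-back regression of transmission versus length
#'
#' Ordinary least squares of total transmission (dB) on straight-waveguide
#' length (cm). The slope is the propagation loss in dB/cm; the intercept
#' collects the length-independent contributions (facet coupling and bends).
#' Standard errors come from the residual variance. A positive slope (gain)
#' triggers a warning; a fit with zero residual degrees of freedom is
#' returned with `NA` standard errors and a flag.
#'
#' @param data a [cutback_dataset()] (or data.frame with `length_cm` and
#'   `transmission_dB` columns).
#' @return A list of class `cutback_fit` with elements
#'   `propagation_dB_per_cm`, `propagation_se`, `intercept_dB`,
#'   `intercept_se`, `n`, `flag` (NULL or a message) and the underlying `lm`
#'   fit in `model`.
#' @examples
#' d <- cutback_dataset(c(1.2, 4, 8.1), -0.9 * c(1.2, 4, 8.1) - 13.4)
#' cutback_fit(d)
#' @export
cutback_fit <- function(data) {
  if (!all(c("length_cm", "transmission_dB") %in% names(data))) {
    stop_invalid("data must contain length_cm and transmission_dB")
  }
  if (nrow(data) < 2L) stop_invalid("at least 2 measurements are required")
  if (length(unique(data$length_cm)) < 2L) {
    stop_invalid("zero length variance: lengths must differ")
  }
  fit <- stats::lm(transmission_dB ~ length_cm, data = data)
  # suppressWarnings: summary.lm warns on the designed noiseless-recovery case
  co <- suppressWarnings(summary(fit))$coefficients
  flag <- NULL
  if (fit$df.residual == 0L) {
    flag <- "exact interpolation: no residual degrees of freedom, standard errors undefined"
    se_slope <- NA_real_
    se_int <- NA_real_
  } else {
    se_slope <- co["length_cm", "Std. Error"]
    se_int <- co["(Intercept)", "Std. Error"]
  }
  slope <- stats::coef(fit)[["length_cm"]]
  if (slope > 0) {
    warn_photonstim("positive slope: transmission increases with length",
                    "photonstim_positive_slope")
  }
  structure(
    list(propagation_dB_per_cm = slope, propagation_se = se_slope,
         intercept_dB = stats::coef(fit)[["(Intercept)"]], intercept_se = se_int,
         n = nrow(data), flag = flag, model = fit),
    class = "cutback_fit")
}

#' @export
print.cutback_fit <- function(x, ...) {
  cat(sprintf("<cutback_fit> propagation %.3f +/- %.3f dB/cm, intercept %.2f +/- %.2f dB (n = %d)\n",
              x$propagation_dB_per_cm, x$propagation_se, x$intercept_dB,
              x$intercept_se, x$n))
  if (!is.null(x$flag)) cat(" flag:", x$flag, "\n")
  invisible(x)
}

#' Decompose a cut-back intercept into coupling and bend losses
#'
#' The length-independent intercept of the cut-back fit is the sum of the
#' facet coupling losses and the total bend loss:
#' `bend_total = intercept - n_facets * coupling`. All quantities are signed
#' dB with losses negative. If standard errors are supplied they are
#' propagated in quadrature.
#'
#' @param intercept_dB cut-back intercept in dB.
#' @param coupling_dB_per_facet measured coupling loss per facet in dB.
#' @param n_facets number of facets (>= 1, default 2).
#' @param n_turns optional number of full 360-degree turns in the device; if
#'   given, the per-turn bend loss is also reported.
#' @param intercept_se,coupling_se optional standard errors.
#' @return A list of class `loss_budget` with `bend_total_dB`, optional
#'   `bend_dB_per_turn`, `bend_total_se`, and the inputs.
#' @examples
#' decompose_intercept(-13.4, -5.5, 2, n_turns = 4)
#' @export
decompose_intercept <- function(intercept_dB, coupling_dB_per_facet,
                                n_facets = 2L, n_turns = NULL,
                                intercept_se = NA_real_, coupling_se = NA_real_) {
  if (n_facets < 1L || n_facets != round(n_facets)) {
    stop_invalid("n_facets must be a positive integer")
  }
  bend <- intercept_dB - n_facets * coupling_dB_per_facet
  se <- if (is.na(intercept_se) && is.na(coupling_se)) NA_real_ else {
    sqrt(ifelse(is.na(intercept_se), 0, intercept_se^2) +
           (n_facets * ifelse(is.na(coupling_se), 0, coupling_se))^2)
  }
  out <- list(intercept_dB = intercept_dB,
              coupling_dB_per_facet = coupling_dB_per_facet,
              n_facets = as.integer(n_facets),
              bend_total_dB = bend, bend_total_se = se)
  if (!is.null(n_turns)) {
    if (n_turns <= 0) stop_invalid("n_turns must be positive")
    out$n_turns <- n_turns
    out$bend_dB_per_turn <- bend / n_turns
  }
  structure(out, class = "loss_budget")
}

#' @export
print.loss_budget <- function(x, ...) {
  cat(sprintf("<loss_budget> intercept %.2f dB = %d x %.2f dB/facet + bends %.2f dB\n",
              x$intercept_dB, x$n_facets, x$coupling_dB_per_facet, x$bend_total_dB))
  if (!is.null(x$bend_dB_per_turn)) {
    cat(sprintf(" bend loss per 360 degrees: %.2f dB (%g turns)\n",
                x$bend_dB_per_turn, x$n_turns))
  }
  invisible(x)
}

#' Payne-Lacey upper bound on roughness scattering loss
#'
#' Order-of-magnitude estimate of the propagation loss a rough-walled slab of
#' the rib's core thickness can radiate. The Payne-Lacey analysis bounds the
#' scattering loss of a planar waveguide of half-thickness d by
#' \deqn{\alpha_{max} = \kappa\,\frac{\sigma^2}{k_0\, d^4\, n_1}}
#' with \eqn{\kappa} close to unity for practical geometries; the bound is
#' the maximum over roughness correlation lengths, so it does not depend on
#' the supplied correlation length (which is validated and recorded for
#' provenance). The result is an upper bound, tagged as an
#' order-of-magnitude estimate; real devices with finite correlation length
#' and partially coherent sidewalls lose much less.
#'
#' @param rms_roughness_nm RMS surface roughness sigma in nm.
#' @param correlation_length_nm roughness autocorrelation length in nm
#'   (exponential autocorrelation assumed; default 50).
#' @param geometry a [waveguide_geometry()]; the slab thickness is the rib
#'   core height plus the residual slab.
#' @param wavelength_nm vacuum wavelength in nm.
#' @return Loss upper bound in dB/cm (a positive magnitude), with attributes
#'   `estimate_type = "order-of-magnitude upper bound"` and
#'   `correlation_length_nm`.
#' @export
payne_lacey_loss <- function(rms_roughness_nm, correlation_length_nm = 50,
                             geometry = waveguide_geometry(),
                             wavelength_nm = geometry$indices$wavelength_nm) {
  if (rms_roughness_nm < 0) stop_invalid("rms_roughness_nm must be non-negative")
  if (correlation_length_nm <= 0) stop_invalid("correlation_length_nm must be positive")
  k0 <- 2 * pi / wavelength_nm              # 1/nm
  d <- (geometry$core_height_nm + geometry$slab_height_nm) / 2 # half-thickness, nm
  alpha_per_nm <- rms_roughness_nm^2 / (k0 * d^4 * geometry$indices$n_core)
  alpha_dB_cm <- 10 / log(10) * alpha_per_nm * 1e7 # field^2 attenuation -> dB/cm
  structure(alpha_dB_cm,
            estimate_type = "order-of-magnitude upper bound",
            correlation_length_nm = correlation_length_nm)
}
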