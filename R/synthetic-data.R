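#' Camera noise model for synthetic images
#'
#' Shot noise (Poisson on the expected photon counts), Gaussian read noise
#' and a constant camera offset. A given seed reproduces the output bit for
#' bit. Defaults emulate an sCMOS camera at short exposure: read noise SD 5
#' counts, offset 100 counts.
#'
#' @param shot_noise apply Poisson noise to the expected counts?
#' @param read_noise_sd_counts Gaussian read noise SD in counts (>= 0).
#' @param offset_counts constant camera baseline in counts (>= 0).
#' @param seed integer RNG seed recorded in every ground-truth record.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(shot_noise = TRUE, read_noise_sd_counts = 5,
                        offset_counts = 100, seed = 1L) {
  if (read_noise_sd_counts < 0 || offset_counts < 0) {
    stop_invalid("read noise SD and offset must be non-negative")
  }
  structure(list(shot_noise = isTRUE(shot_noise),
                 read_noise_sd_counts = read_noise_sd_counts,
                 offset_counts = offset_counts, seed = as.integer(seed)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> shot = %s, read SD = %g, offset = %g, seed = %d\n",
              x$shot_noise, x$read_noise_sd_counts, x$offset_counts, x$seed))
  invisible(x)
}

#' Noise-free synthetic output
#'
#' Convenience constructor: no shot noise, no read noise, no offset.
#' @param seed unused but recorded, for provenance symmetry.
#' @rdname noise_model
#' @export
noiseless <- function(seed = 1L) {
  noise_model(shot_noise = FALSE, read_noise_sd_counts = 0, offset_counts = 0,
              seed = seed)
}

# Expected counts -> observed camera counts under the noise model.
# Deterministic (and unrounded) when no stochastic component is active.
.apply_noise <- function(expected, noise) {
  stochastic <- noise$shot_noise || noise$read_noise_sd_counts > 0
  if (!stochastic) return(expected + noise$offset_counts)
  withr::with_seed(noise$seed, {
    out <- if (noise$shot_noise) {
      stats::rpois(length(expected), as.vector(expected))
    } else as.vector(expected)
    if (noise$read_noise_sd_counts > 0) {
      out <- out + stats::rnorm(length(out), 0, noise$read_noise_sd_counts)
    }
    out <- pmax(round(out + noise$offset_counts), 0)
    array(out, dim = dim(expected) %||% length(expected))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic fluorescent bead image under evanescent excitation
#'
#' Emulates a FITC-covered silica bead resting on the chip surface, excited
#' by an exponentially decaying evanescent field: a fluorophore at lateral
#' distance r from the contact point sits at height
#' \eqn{y(r) = R - \sqrt{R^2 - r^2}} on the lower hemisphere, so its
#' expected signal is `peak_counts * exp(-y(r)/d_p_true_nm)` inside the
#' projected disc. An optional excitation stripe (a waveguide of finite
#' width) masks the excitation laterally, which makes the excited region
#' elliptical, as observed for beads on the waveguide edge.
#'
#' @param bead a [bead_spec()].
#' @param d_p_true_nm true penetration depth in the surrounding medium, nm.
#' @param peak_counts expected counts at the contact point (default 2.5e3,
#'   the observed center-of-bead count level).
#' @param pixel_size_um pixel size in um (default 0.129, a 132 um field of
#'   view on a 1024 px sensor).
#' @param frame_shape rows x cols of the frame.
#' @param center_px bead center as 0-based `c(x, y)` pixel coordinates;
#'   default slightly off the frame center so sub-pixel recovery is
#'   non-trivial.
#' @param excitation_stripe optional `list(center_row_px =, width_um =)`
#'   horizontal stripe restricting the excitation.
#' @param noise a [noise_model()].
#' @return A list with `stack` (a 1-frame [optical_stack()]) and `truth`
#'   (ground-truth record: all parameters plus the seed).
#' @export
generate_bead_image <- function(bead = bead_spec(), d_p_true_nm = 57,
                                peak_counts = 2.5e3, pixel_size_um = 0.129,
                                frame_shape = c(128L, 128L), center_px = NULL,
                                excitation_stripe = NULL,
                                noise = noise_model()) {
  stopifnot(inherits(bead, "bead_spec"), inherits(noise, "noise_model"))
  if (d_p_true_nm <= 0 || peak_counts <= 0) {
    stop_invalid("d_p_true_nm and peak_counts must be positive")
  }
  R_um <- bead$diameter_um / 2
  if (2 * R_um >= min(frame_shape) * pixel_size_um) {
    stop_invalid("bead is larger than the frame")
  }
  if (is.null(center_px)) {
    center_px <- c(x = (frame_shape[2] - 1) / 2 + 0.3,
                   y = (frame_shape[1] - 1) / 2 - 0.2)
  }
  rows <- seq_len(frame_shape[1]) - 1L # 0-based pixel centres
  cols <- seq_len(frame_shape[2]) - 1L
  dy <- (rows - center_px[["y"]]) * pixel_size_um
  dx <- (cols - center_px[["x"]]) * pixel_size_um
  r_um <- sqrt(outer(dy^2, dx^2, `+`))
  inside <- r_um < R_um
  h_nm <- matrix(0, frame_shape[1], frame_shape[2])
  h_nm[inside] <- (R_um - sqrt(R_um^2 - r_um[inside]^2)) * 1e3
  expected <- matrix(0, frame_shape[1], frame_shape[2])
  expected[inside] <- peak_counts * exp(-h_nm[inside] / d_p_true_nm)
  if (!is.null(excitation_stripe)) {
    half_px <- excitation_stripe$width_um / 2 / pixel_size_um
    in_stripe <- abs(rows - excitation_stripe$center_row_px) <= half_px
    expected[!in_stripe, ] <- 0
  }
  observed <- .apply_noise(array(expected, dim = c(1L, dim(expected))), noise)
  list(
    stack = optical_stack(observed, frame_interval_s = 0.1, exposure_s = 0.1,
                          pixel_size_um = pixel_size_um),
    truth = list(kind = "bead_image", d_p_true_nm = d_p_true_nm,
                 center_px = as.list(center_px), peak_counts = peak_counts,
                 bead_diameter_um = bead$diameter_um,
                 pixel_size_um = pixel_size_um,
                 excitation_stripe = excitation_stripe,
                 noise = unclass(noise), seed = noise$seed))
}

#' Scene layout for synthetic calcium movies
#'
#' Places elliptical somata (optionally overlapping a horizontal waveguide
#' stripe) in the frame. Cell positions, radii and orientations are drawn
#' reproducibly from `seed`.
#'
#' @param frame_shape rows x cols in pixels (default 128 x 128, the fast
#'   test-scale counterpart of a 1200 x 1200 field of view).
#' @param pixel_size_um pixel size in um (default 0.5).
#' @param n_cells number of somata.
#' @param soma_radius_um range of ellipse semi-axes in um.
#' @param waveguide `list(center_row_px =, width_um =)` horizontal stimulation
#'   stripe (default: mid-frame, 4.5 um wide), or `NULL` for none.
#' @param seed RNG seed.
#' @return An object of class `scene_layout` with `cell_regions`,
#'   `cell_mask` (integer matrix, 0 = background, i = cell i) and
#'   `waveguide_mask` (logical matrix or NULL).
#' @export
scene_layout <- function(frame_shape = c(128L, 128L), pixel_size_um = 0.5,
                         n_cells = 8L, soma_radius_um = c(3, 6),
                         waveguide = list(center_row_px = (frame_shape[1] - 1) / 2,
                                          width_um = 4.5),
                         seed = 1L) {
  if (!is.null(waveguide) && waveguide$width_um <= 0) {
    stop_invalid("waveguide stripe width must be positive")
  }
  draw_cells <- function() {
    lapply(seq_len(n_cells), function(i) {
      a <- stats::runif(1, soma_radius_um[1], soma_radius_um[2])
      b <- stats::runif(1, soma_radius_um[1], soma_radius_um[2])
      marg <- max(a, b) / pixel_size_um + 1
      list(center_px = c(x = stats::runif(1, marg, frame_shape[2] - 1 - marg),
                         y = stats::runif(1, marg, frame_shape[1] - 1 - marg)),
           radii_um = c(a = a, b = b),
           theta = stats::runif(1, 0, pi))
    })
  }
  # the waveguide-stimulation experiment has neurons growing on the
  # waveguide; redraw (deterministically, within the seeded stream) until at
  # least one soma can straddle the stripe
  cells <- withr::with_seed(seed, {
    for (try in 1:100) {
      cand <- draw_cells()
      if (is.null(waveguide)) break
      reach <- vapply(cand, function(cl) {
        abs(cl$center_px[["y"]] - waveguide$center_row_px) * pixel_size_um <
          min(cl$radii_um)
      }, logical(1))
      if (any(reach)) break
    }
    cand
  })
  rows <- seq_len(frame_shape[1]) - 1L
  cols <- seq_len(frame_shape[2]) - 1L
  mask <- matrix(0L, frame_shape[1], frame_shape[2])
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    dx <- outer(rep(1, frame_shape[1]), cols - cl$center_px[["x"]]) * pixel_size_um
    dy <- outer(rows - cl$center_px[["y"]], rep(1, frame_shape[2])) * pixel_size_um
    u <- dx * cos(cl$theta) + dy * sin(cl$theta)
    v <- -dx * sin(cl$theta) + dy * cos(cl$theta)
    mask[(u / cl$radii_um[["a"]])^2 + (v / cl$radii_um[["b"]])^2 <= 1] <- i
  }
  wg_mask <- NULL
  if (!is.null(waveguide)) {
    half_px <- waveguide$width_um / 2 / pixel_size_um
    wg_mask <- matrix(abs(rows - waveguide$center_row_px) <= half_px,
                      frame_shape[1], frame_shape[2])
  }
  structure(list(frame_shape = as.integer(frame_shape),
                 pixel_size_um = pixel_size_um, cell_regions = cells,
                 cell_mask = mask, waveguide = waveguide,
                 waveguide_mask = wg_mask, seed = as.integer(seed)),
            class = "scene_layout")
}

#' Synthetic calcium-imaging movie with stimulation-locked transients
#'
#' Generates a recording that follows the stimulation protocol: a flat
#' baseline for `background_s`, then each pulse at time \eqn{t_i} adds an
#' exponentially decaying calcium transient
#' `baseline * transient_amplitude_frac * exp(-(t - t_i)/tau)` to every
#' responder pixel. In `full_field` mode every cell responds; in
#' `waveguide` mode only cells whose soma intersects the stimulation stripe
#' do (evanescent excitation reaches only cells touching the waveguide).
#' Noise follows the supplied [noise_model()].
#'
#' @param layout a [scene_layout()].
#' @param protocol a [stim_protocol()].
#' @param transient_amplitude_frac peak transient amplitude as a fraction of
#'   baseline (Delta F / F0, default 0.3, a typical Rhod-3 scale).
#' @param decay_tau_s calcium decay time constant in s (default 0.5).
#' @param baseline_counts baseline fluorescence in counts (default 5000).
#' @param stimulation_mode `"full_field"` or `"waveguide"`.
#' @param frame_interval_s sampling interval in s (default 0.1 = 10 Hz).
#' @param spontaneous_rate_hz rate of Poisson-timed spontaneous transients
#'   added to every cell (default 0: none).
#' @param noise a [noise_model()].
#' @return A list with `movie` (an [optical_stack()]), `responder_mask`
#'   (logical matrix) and `truth` (ground-truth record).
#' @export
generate_calcium_movie <- function(layout = scene_layout(),
                                   protocol = stim_protocol(),
                                   transient_amplitude_frac = 0.3,
                                   decay_tau_s = 0.5, baseline_counts = 5000,
                                   stimulation_mode = c("full_field", "waveguide"),
                                   frame_interval_s = 0.1,
                                   spontaneous_rate_hz = 0,
                                   noise = noise_model()) {
  stopifnot(inherits(layout, "scene_layout"), inherits(protocol, "stim_protocol"),
            inherits(noise, "noise_model"))
  stimulation_mode <- match.arg(stimulation_mode)
  if (transient_amplitude_frac < 0 || decay_tau_s <= 0 || baseline_counts <= 0) {
    stop_invalid("amplitude fraction must be >= 0, tau and baseline positive")
  }
  if (stimulation_mode == "waveguide" && is.null(layout$waveguide_mask)) {
    stop_invalid("waveguide stimulation requires a layout with a waveguide stripe")
  }
  n_frames <- round(protocol$total_s / frame_interval_s)
  t <- (seq_len(n_frames) - 1L) * frame_interval_s

  transient <- function(event_times) {
    s <- numeric(n_frames)
    for (ti in event_times) {
      on <- t >= ti
      s[on] <- s[on] + exp(-(t[on] - ti) / decay_tau_s)
    }
    s * baseline_counts * transient_amplitude_frac
  }
  s_t <- transient(pulse_times(protocol))

  responders <- if (stimulation_mode == "full_field") {
    layout$cell_mask > 0L
  } else {
    hit <- sort(unique(layout$cell_mask[layout$cell_mask > 0L & layout$waveguide_mask]))
    matrix(layout$cell_mask %in% hit & layout$cell_mask > 0L,
           nrow(layout$cell_mask), ncol(layout$cell_mask))
  }

  n_px <- prod(layout$frame_shape)
  expected <- matrix(baseline_counts, n_frames, n_px) +
    outer(s_t, as.numeric(as.vector(responders)))
  if (spontaneous_rate_hz > 0) {
    spont <- withr::with_seed(noise$seed + 1L, {
      lapply(seq_along(layout$cell_regions), function(i) {
        k <- stats::rpois(1, spontaneous_rate_hz * protocol$total_s)
        sort(stats::runif(k, 0, protocol$total_s))
      })
    })
    for (i in seq_along(spont)) {
      if (length(spont[[i]]) == 0) next
      sel <- which(as.vector(layout$cell_mask == i))
      expected[, sel] <- expected[, sel] + transient(spont[[i]])
    }
  }
  observed <- .apply_noise(array(expected, c(n_frames, layout$frame_shape)), noise)
  list(
    movie = optical_stack(observed, frame_interval_s = frame_interval_s,
                          exposure_s = 0.01,
                          pixel_size_um = layout$pixel_size_um),
    responder_mask = responders,
    truth = list(kind = "calcium_movie", stimulation_mode = stimulation_mode,
                 transient_amplitude_frac = transient_amplitude_frac,
                 decay_tau_s = decay_tau_s, baseline_counts = baseline_counts,
                 frame_interval_s = frame_interval_s,
                 pulse_times_s = pulse_times(protocol),
                 spontaneous_rate_hz = spontaneous_rate_hz,
                 layout_seed = layout$seed, noise = unclass(noise),
                 seed = noise$seed))
}

#' Synthetic cut-back transmission data
#'
#' Straight-line transmission versus length with Gaussian measurement noise:
#' `T = slope * L + intercept + N(0, noise_sd)`, reproducible by seed.
#' Default lengths span the measured devices (1.2 to 8.1 cm).
#'
#' @param slope_true propagation loss in dB/cm (negative for loss).
#' @param intercept_true length-independent loss in dB.
#' @param lengths_cm device lengths in cm.
#' @param noise_sd_dB Gaussian noise SD in dB (>= 0).
#' @param seed RNG seed.
#' @return A list with `data` (a [cutback_dataset()]) and `truth`.
#' @export
generate_cutback_data <- function(slope_true = -0.9, intercept_true = -13.4,
                                  lengths_cm = c(1.2, 2.5, 4.0, 5.5, 7.0, 8.1),
                                  noise_sd_dB = 0.3, seed = 1L) {
  if (noise_sd_dB < 0) stop_invalid("noise_sd_dB must be non-negative")
  tr <- slope_true * lengths_cm + intercept_true
  if (noise_sd_dB > 0) {
    tr <- tr + withr::with_seed(seed, stats::rnorm(length(lengths_cm), 0, noise_sd_dB))
  }
  list(data = cutback_dataset(lengths_cm, tr),
       truth = list(kind = "cutback", slope_true = slope_true,
                    intercept_true = intercept_true, noise_sd_dB = noise_sd_dB,
                    seed = as.integer(seed)))
}
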