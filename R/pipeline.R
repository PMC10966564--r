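#' @keywords internal
.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null",
                       pretty = TRUE)
  path
}

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop_invalid(sprintf("unknown key(s) in %s: %s", where,
                         paste(unknown, collapse = ", ")))
  }
}

.protocol_from <- function(p) {
  if (is.null(p)) return(stim_protocol())
  .check_keys(p, c("background_s", "n_pulses", "pulse_rate_hz",
                   "pulse_width_s", "total_s"), "protocol")
  do.call(stim_protocol, p)
}

.noise_from <- function(n, default_seed) {
  if (is.null(n)) return(noise_model(seed = default_seed))
  .check_keys(n, c("shot_noise", "read_noise_sd_counts", "offset_counts",
                   "seed"), "noise")
  if (is.null(n$seed)) n$seed <- default_seed
  do.call(noise_model, n)
}

# stage registry: validate() runs before any execution, run() does the work
.stages <- list(
  simulate_cutback = list(
    keys = c("slope_true", "intercept_true", "lengths_cm", "noise_sd_dB"),
    validate = function(p, seed) {
      if (!is.null(p$noise_sd_dB) && p$noise_sd_dB < 0) {
        stop_invalid("noise_sd_dB must be non-negative")
      }
    },
    run = function(p, ctx) {
      g <- generate_cutback_data(
        slope_true = p$slope_true %||% -0.9,
        intercept_true = p$intercept_true %||% -13.4,
        lengths_cm = unlist(p$lengths_cm) %||% c(1.2, 2.5, 4.0, 5.5, 7.0, 8.1),
        noise_sd_dB = p$noise_sd_dB %||% 0.3, seed = ctx$seed)
      csv <- file.path(ctx$outdir, "cutback.csv")
      utils::write.csv(as.data.frame(g$data), csv, row.names = FALSE)
      truth <- .write_json(g$truth, file.path(ctx$outdir, "cutback_truth.json"))
      list(product = g$data, outputs = c(csv, truth),
           summary = list(n_devices = nrow(g$data)))
    }),
  cutback_fit = list(
    keys = c("input", "coupling_dB_per_facet", "coupling_se", "n_facets",
             "n_turns"),
    validate = function(p, seed) {
      if (!is.null(p$n_facets) && p$n_facets < 1) stop_invalid("n_facets must be >= 1")
    },
    run = function(p, ctx) {
      dat <- .resolve_input(p$input, ctx, "simulate_cutback")
      if (is.character(dat)) {
        df <- utils::read.csv(dat)
        dat <- cutback_dataset(df$length_cm, df$transmission_dB)
      }
      fit <- cutback_fit(dat)
      budget <- decompose_intercept(
        fit$intercept_dB, p$coupling_dB_per_facet %||% -5.5,
        n_facets = p$n_facets %||% 2L, n_turns = p$n_turns,
        intercept_se = fit$intercept_se,
        coupling_se = p$coupling_se %||% NA_real_)
      out <- .write_json(
        list(propagation_dB_per_cm = fit$propagation_dB_per_cm,
             propagation_se = fit$propagation_se,
             intercept_dB = fit$intercept_dB, intercept_se = fit$intercept_se,
             loss_budget = unclass(budget), units = "dB (losses negative)"),
        file.path(ctx$outdir, "loss_budget.json"))
      list(product = list(fit = fit, budget = budget), outputs = out,
           summary = list(propagation_dB_per_cm = fit$propagation_dB_per_cm))
    }),
  simulate_beads = list(
    keys = c("d_p_water_nm", "medium_index", "peak_counts", "pixel_size_um",
             "frame_shape", "bead_diameter_um", "wavelength_nm", "noise"),
    validate = function(p, seed) {
      if (!is.null(p$d_p_water_nm) && p$d_p_water_nm <= 0) {
        stop_invalid("d_p_water_nm must be positive")
      }
      .noise_from(p$noise, seed)
    },
    run = function(p, ctx) {
      lam <- p$wavelength_nm %||% 491
      n_med <- p$medium_index %||% 1.450
      d_med <- convert_penetration_depth(p$d_p_water_nm %||% 57, 1.340, n_med,
                                         lam)$d_p_nm
      g <- generate_bead_image(
        bead = bead_spec(p$bead_diameter_um %||% 7.38),
        d_p_true_nm = d_med, peak_counts = p$peak_counts %||% 2.5e3,
        pixel_size_um = p$pixel_size_um %||% 0.129,
        frame_shape = unlist(p$frame_shape) %||% c(128L, 128L),
        noise = .noise_from(p$noise, ctx$seed))
      tif <- file.path(ctx$outdir, "bead.tif")
      write_stack(g$stack, tif)
      g$truth$d_p_water_nm <- p$d_p_water_nm %||% 57
      g$truth$medium_index <- n_med
      truth <- .write_json(g$truth, file.path(ctx$outdir, "bead_truth.json"))
      list(product = g$stack, outputs = c(tif, paste0(tif, ".json"), truth),
           summary = list(d_p_true_medium_nm = d_med))
    }),
  calibrate_beads = list(
    keys = c("input", "bead_diameter_um", "medium_index", "wavelength_nm",
             "y_max_nm"),
    validate = function(p, seed) {
      if (!is.null(p$y_max_nm) && p$y_max_nm <= 0) stop_invalid("y_max_nm must be positive")
    },
    run = function(p, ctx) {
      stk <- .resolve_input(p$input, ctx, "simulate_beads")
      if (is.character(stk)) stk <- read_stack(stk)
      bf <- run_bead_calibration(
        stk, bead = bead_spec(p$bead_diameter_um %||% 7.38),
        medium_index = p$medium_index %||% 1.450,
        wavelength_nm = p$wavelength_nm %||% 491,
        y_max_nm = p$y_max_nm %||% 500)
      hm <- pixel_heights(bf$center_xy_px, bead_spec(p$bead_diameter_um %||% 7.38),
                          stk$pixel_size_um, dim(stk$data)[2:3])
      keep <- which(hm$valid)
      csv <- file.path(ctx$outdir, "bead_heights_counts.csv")
      utils::write.csv(
        data.frame(height_nm = hm$heights_nm[keep],
                   counts = matrix(stk$data[1, , ],
                                   dim(stk$data)[2], dim(stk$data)[3])[keep]),
        csv, row.names = FALSE)
      rep <- .write_json(
        list(center_xy_px = as.list(bf$center_xy_px),
             d_p_measured_nm = bf$d_p_measured_nm,
             d_p_water_nm = bf$d_p_water_nm, medium_index = bf$medium_index,
             n_water = bf$n_water, n_pixels_used = bf$n_pixels_used,
             units = "nm"),
        file.path(ctx$outdir, "bead_fit.json"))
      list(product = bf, outputs = c(rep, csv),
           summary = list(d_p_water_nm = bf$d_p_water_nm))
    }),
  simulate_movie = list(
    keys = c("stimulation_mode", "n_cells", "frame_shape", "pixel_size_um",
             "protocol", "noise", "transient_amplitude_frac", "decay_tau_s",
             "baseline_counts", "frame_interval_s", "layout_seed"),
    validate = function(p, seed) {
      .protocol_from(p$protocol)
      .noise_from(p$noise, seed)
      if (!is.null(p$stimulation_mode) &&
          !p$stimulation_mode %in% c("full_field", "waveguide")) {
        stop_invalid("stimulation_mode must be full_field or waveguide")
      }
    },
    run = function(p, ctx) {
      fs <- unlist(p$frame_shape) %||% c(128L, 128L)
      layout <- scene_layout(frame_shape = fs,
                             pixel_size_um = p$pixel_size_um %||% 0.5,
                             n_cells = p$n_cells %||% 8L,
                             seed = p$layout_seed %||% ctx$seed)
      g <- generate_calcium_movie(
        layout, protocol = .protocol_from(p$protocol),
        transient_amplitude_frac = p$transient_amplitude_frac %||% 0.3,
        decay_tau_s = p$decay_tau_s %||% 0.5,
        baseline_counts = p$baseline_counts %||% 5000,
        stimulation_mode = p$stimulation_mode %||% "waveguide",
        frame_interval_s = p$frame_interval_s %||% 0.1,
        noise = .noise_from(p$noise, ctx$seed))
      tif <- file.path(ctx$outdir, "movie.tif")
      write_stack(g$movie, tif)
      g$truth$responder_mask <- unname(apply(g$responder_mask, 1, as.integer,
                                             simplify = FALSE))
      truth <- .write_json(g$truth, file.path(ctx$outdir, "movie_truth.json"))
      list(product = g, outputs = c(tif, paste0(tif, ".json"), truth),
           summary = list(n_responder_px = sum(g$responder_mask)))
    }),
  map_response = list(
    keys = c("input", "window_s", "harmonics", "protocol",
             "responder_threshold"),
    validate = function(p, seed) {
      .protocol_from(p$protocol)
      thr <- p$responder_threshold %||% 0.5
      if (thr <= 0 || thr >= 1) stop_invalid("responder_threshold must lie in (0, 1)")
    },
    run = function(p, ctx) {
      mv <- .resolve_input(p$input, ctx, "simulate_movie")
      if (is.list(mv) && !inherits(mv, "optical_stack")) mv <- mv$movie
      if (is.character(mv)) mv <- read_stack(mv)
      map <- response_map(mv, protocol = .protocol_from(p$protocol),
                          window_s = unlist(p$window_s) %||% c(21, 31),
                          harmonics = unlist(p$harmonics) %||% 1:5)
      tif <- file.path(ctx$outdir, "response_map.tif")
      write_response_map(map, tif)
      thr <- p$responder_threshold %||% 0.5
      list(product = map, outputs = c(tif, paste0(tif, ".json")),
           summary = list(raw_max_score = map$raw_max_score,
                          responder_threshold = thr,
                          n_above_threshold = sum(classify_responders(map, thr))))
    }),
  solve_modes = list(
    keys = c("width_um", "core_height_nm", "slab_height_nm", "n_core",
             "n_substrate", "n_cladding", "wavelength_nm", "n_modes",
             "grid_spacing_nm"),
    validate = function(p, seed) {
      material_indices(p$n_core %||% 1.566, p$n_substrate %||% 1.463,
                       p$n_cladding %||% 1.340, p$wavelength_nm %||% 491)
    },
    run = function(p, ctx) {
      geo <- waveguide_geometry(
        width_um = p$width_um %||% 4.5,
        core_height_nm = p$core_height_nm %||% 300,
        slab_height_nm = p$slab_height_nm %||% 40,
        indices = material_indices(p$n_core %||% 1.566, p$n_substrate %||% 1.463,
                                   p$n_cladding %||% 1.340,
                                   p$wavelength_nm %||% 491))
      modes <- solve_modes(geo, n_modes = p$n_modes %||% 3L,
                           grid_spacing_nm = unlist(p$grid_spacing_nm) %||% c(50, 10))
      out <- .write_json(
        lapply(modes, function(m) list(
          family = m$mode_label$family, order = m$mode_label$order,
          n_eff = m$n_eff, d_p_nm = m$d_p_nm,
          surface_peak_density_mW_mm2_per_mW = m$surface_peak_density_per_mW)),
        file.path(ctx$outdir, "modes.json"))
      list(product = modes, outputs = out,
           summary = list(n_modes = length(modes)))
    })
)

.resolve_input <- function(input, ctx, default_stage) {
  if (is.null(input)) input <- default_stage
  if (is.character(input) && input %in% names(ctx$products)) {
    return(ctx$products[[input]])
  }
  if (is.character(input)) {
    if (!file.exists(input)) {
      stop_invalid(sprintf("stage input is neither an earlier stage nor a file: %s", input))
    }
    ctx$hashes[[input]] <- unname(tools::md5sum(input))
    return(input)
  }
  input
}

#' Validate a pipeline configuration
#'
#' Checks the whole configuration before anything runs: unknown keys are
#' rejected at every level, stage names must exist, and stage parameters are
#' type- and range-checked (protocols, noise models and material indices are
#' actually constructed, so e.g. a negative pulse rate fails here).
#'
#' @param config a list, or path to a YAML file.
#' @return The normalized configuration list, invisibly on success.
#' @export
validate_config <- function(config) {
  src <- NULL
  if (is.character(config)) {
    src <- config
    config <- yaml::read_yaml(config)
  }
  .check_keys(config, c("seed", "output_dir", "verbosity", "stages"), "config")
  if (is.null(config$stages) || length(config$stages) == 0L) {
    stop_invalid("config must declare at least one stage")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$verbosity <- config$verbosity %||% 1L
  config$output_dir <- config$output_dir %||% "photonstim_run"
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$stage) || !st$stage %in% names(.stages)) {
      stop_invalid(sprintf("stage %d: unknown stage '%s' (known: %s)", i,
                           st$stage %||% "<missing>",
                           paste(names(.stages), collapse = ", ")))
    }
    reg <- .stages[[st$stage]]
    .check_keys(st[setdiff(names(st), "stage")], reg$keys,
                sprintf("stage %d (%s)", i, st$stage))
    reg$validate(st, config$seed)
  }
  attr(config, "source") <- src
  invisible(config)
}

#' Run a multi-stage analysis pipeline from a configuration
#'
#' Executes the declared stages in order. Every run writes the resolved
#' configuration (`config_resolved.json`) and a provenance report
#' (`report.json`: stage outputs, seed, package version, input file hashes)
#' next to the outputs; rerunning with the same configuration and seed
#' produces byte-identical reports. Stage failures abort with the stage
#' identity in the message; outputs of completed stages are preserved.
#'
#' @param config a list, or path to a YAML file; see [validate_config()].
#' @return The report, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  outdir <- config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ctx <- new.env(parent = emptyenv())
  ctx$seed <- config$seed
  ctx$outdir <- outdir
  ctx$products <- list()
  ctx$hashes <- list()
  verbose <- (config$verbosity %||% 1L) >= 1L
  .write_json(config, file.path(outdir, "config_resolved.json"))

  report_stages <- list()
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (verbose) message(sprintf("[photonstim] stage %d/%d: %s",
                                 i, length(config$stages), st$stage))
    res <- withCallingHandlers(
      .stages[[st$stage]]$run(st, ctx),
      error = function(e) {
        if (!inherits(e, "photonstim_stage_annotated")) {
          e$message <- sprintf("stage %d (%s) failed: %s", i, st$stage,
                               conditionMessage(e))
          class(e) <- unique(c("photonstim_stage_annotated", class(e)))
          stop(e)
        }
      })
    ctx$products[[st$stage]] <- res$product
    report_stages[[i]] <- list(stage = st$stage,
                               outputs = as.list(res$outputs),
                               summary = res$summary)
  }
  report <- list(
    package = "photonstim",
    package_version = as.character(utils::packageVersion("photonstim")),
    seed = config$seed,
    input_hashes = ctx$hashes,
    stages = report_stages)
  .write_json(report, file.path(outdir, "report.json"))
  if (verbose) message(sprintf("[photonstim] done: %s", file.path(outdir, "report.json")))
  invisible(report)
}
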