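#' Write an optical stack as multi-page TIFF plus JSON sidecar
#'
#' Counts are stored losslessly as 16-bit TIFF pages (integer counts up to
#' 65535); acquisition metadata goes to a JSON sidecar `<path>.json`.
#'
#' @param stack an [optical_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "optical_stack"))
  d <- stack$data
  if (any(d != round(d))) {
    warn_photonstim("non-integer counts rounded for 16-bit TIFF storage",
                    "photonstim_lossy_write")
    d <- round(d)
  }
  if (max(d) > 65535) stop_invalid("counts exceed the 16-bit TIFF range")
  pages <- lapply(seq_len(dim(d)[1]), function(i) {
    matrix(d[i, , ], dim(d)[2], dim(d)[3]) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(frame_interval_s = stack$frame_interval_s,
               exposure_s = stack$exposure_s,
               pixel_size_um = stack$pixel_size_um, t0_s = stack$t0_s,
               n_frames = dim(d)[1], dtype = "uint16")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an optical stack written by [write_stack()]
#'
#' Counts are restored exactly; metadata comes from the JSON sidecar. A
#' missing sidecar or missing `frame_interval_s` is an error — frame timing
#' is never silently defaulted.
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return An [optical_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop_missing_metadata(sprintf("metadata sidecar not found: %s", sidecar))
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$frame_interval_s)) {
    stop_missing_metadata("sidecar lacks required field frame_interval_s")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- round(pages[[i]] * 65535)
  optical_stack(arr, frame_interval_s = as.numeric(meta$frame_interval_s),
                exposure_s = as.numeric(meta$exposure_s %||% NA_real_),
                pixel_size_um = as.numeric(meta$pixel_size_um %||% NA_real_),
                t0_s = as.numeric(meta$t0_s %||% 0))
}

#' Write a response map as 32-bit float TIFF plus JSON metadata
#'
#' @param map a [response_map()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_response_map <- function(map, path) {
  stopifnot(inherits(map, "response_map"))
  tiff::writeTIFF(map$scores, path, bits.per.sample = 32L)
  meta <- list(window_s = map$window_s, harmonics = map$harmonics,
               f_stim_hz = map$f_stim_hz, raw_max_score = map$raw_max_score)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
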