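#' @keywords internal
stop_photonstim <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "photonstim_error"), call = call))
}

stop_invalid <- function(msg) stop_photonstim(msg, "photonstim_invalid_input")
stop_no_evanescent <- function(msg) stop_photonstim(msg, "photonstim_no_evanescent")
stop_localization <- function(msg) stop_photonstim(msg, "photonstim_localization_failure")
stop_fit_failure <- function(msg) stop_photonstim(msg, "photonstim_fit_failure")
stop_missing_metadata <- function(msg) stop_photonstim(msg, "photonstim_missing_metadata")

warn_photonstim <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "photonstim_warning")))
}
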