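# shared fixtures, all generated in code

# the default rib geometry is solved once per test run and cached
.mode_cache <- new.env(parent = emptyenv())

default_modes <- function() {
  if (is.null(.mode_cache$modes)) {
    .mode_cache$modes <- solve_modes(waveguide_geometry(), n_modes = 3)
  }
  .mode_cache$modes
}

# brute-force unnormalized DFT magnitude at one bin (independent oracle,
# direct summation, no fft)
dft_mag_brute <- function(trace, bin) {
  n <- length(trace)
  tt <- seq_len(n) - 1L
  Mod(sum(trace * exp(-2i * pi * bin * tt / n)))
}

# ideal protocol trace: baseline + pulse-locked exponential transients,
# evaluated directly from the generative model
protocol_trace <- function(protocol = stim_protocol(), amp = 1, tau = 0.5,
                           fs = 10, baseline = 0) {
  t <- seq(0, protocol$total_s - 1 / fs, by = 1 / fs)
  s <- rep(baseline, length(t))
  for (ti in pulse_times(protocol)) {
    on <- t >= ti
    s[on] <- s[on] + amp * exp(-(t[on] - ti) / tau)
  }
  s
}

# small waveguide-stimulation scene for movie tests
small_scene <- function(seed = 1L, frame = c(64L, 64L)) {
  scene_layout(frame_shape = frame, pixel_size_um = 0.5, n_cells = 5L,
               seed = seed)
}
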