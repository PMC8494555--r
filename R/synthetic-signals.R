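#' Specification for a synthetic grass-wave signal
#'
#' Grass waves are the low-amplitude clutter class of ultrasound signal:
#' long piecewise-constant runs (quiet intervals and clutter plateaus)
#' interrupted by sparse high-amplitude spike "burrs". The class is only
#' described qualitatively in the CEUS literature, so this parameterisation
#' is a stand-in: run levels alternate between exact zero (quiet intervals,
#' probability `quiet_prob`) and small uniform amplitudes, which gives the
#' byte stream the long literal runs that run-length coding exploits.
#'
#' @param length number of samples (> 0).
#' @param baseline_amp clutter amplitude scale (a.u.); run levels are drawn
#'   uniformly from `[-baseline_amp, baseline_amp]`.
#' @param run_length_mean mean run length in samples (>= 1).
#' @param spike_rate expected spikes per 1000 samples (>= 0).
#' @param spike_amp spike amplitude scale (a.u.).
#' @param quiet_prob probability that a run sits at exactly zero.
#' @return object of class `grass_wave_spec`.
#' @export
grass_wave_spec <- function(length = 8192L, baseline_amp = 40,
                            run_length_mean = 20, spike_rate = 1,
                            spike_amp = 1500, quiet_prob = 0.6) {
  length <- as.integer(length)
  if (is.na(length) || length <= 0L)
    abort_ceus("invalid_spec", "length must be a positive integer")
  if (run_length_mean < 1)
    abort_ceus("invalid_spec", "run_length_mean must be >= 1")
  if (spike_rate < 0) abort_ceus("invalid_spec", "spike_rate must be >= 0")
  if (quiet_prob < 0 || quiet_prob > 1)
    abort_ceus("invalid_spec", "quiet_prob must be in [0, 1]")
  structure(list(length = length, baseline_amp = baseline_amp,
                 run_length_mean = run_length_mean, spike_rate = spike_rate,
                 spike_amp = spike_amp, quiet_prob = quiet_prob),
            class = "grass_wave_spec")
}

#' Specification for a synthetic defect-wave signal
#'
#' Defect waves are the wide-amplitude echo class: a small number of
#' carrier-modulated echo pulses with Gaussian envelopes over additive
#' Gaussian noise. Successive samples are strongly correlated (the carrier
#' period is long relative to the sampling step), which is what makes the
#' difference transform shrink the amplitude alphabet.
#'
#' @param length number of samples (> 0).
#' @param n_echoes number of echo pulses (>= 0).
#' @param echo_amp_range length-2 numeric, min < max echo amplitude (a.u.).
#' @param pulse_width nominal full width of one echo envelope, in samples.
#' @param noise_sd standard deviation of additive Gaussian noise (a.u.).
#' @param carrier_period carrier wavelength in samples.
#' @return object of class `defect_wave_spec`.
#' @export
defect_wave_spec <- function(length = 8192L, n_echoes = 12L,
                             echo_amp_range = c(2000, 28000),
                             pulse_width = 200, noise_sd = 20,
                             carrier_period = 32) {
  length <- as.integer(length)
  if (is.na(length) || length <= 0L)
    abort_ceus("invalid_spec", "length must be a positive integer")
  if (length(echo_amp_range) != 2L || echo_amp_range[1] >= echo_amp_range[2])
    abort_ceus("invalid_spec", "echo_amp_range must satisfy min < max")
  if (n_echoes < 0) abort_ceus("invalid_spec", "n_echoes must be >= 0")
  if (noise_sd < 0) abort_ceus("invalid_spec", "noise_sd must be >= 0")
  structure(list(length = length, n_echoes = as.integer(n_echoes),
                 echo_amp_range = echo_amp_range, pulse_width = pulse_width,
                 noise_sd = noise_sd, carrier_period = carrier_period),
            class = "defect_wave_spec")
}

#' Generate a grass-wave signal
#'
#' Piecewise-constant runs (geometric-plus-one run lengths with the requested
#' mean) at integer clutter levels, with isolated spikes superimposed at the
#' requested rate. Deterministic for a given (spec, seed) pair.
#'
#' @param spec a [grass_wave_spec()].
#' @param seed integer seed; identical seeds give identical signals.
#' @return a [us_signal()] with `kind = "grass"`.
#' @export
generate_grass_wave <- function(spec, seed) {
  if (!inherits(spec, "grass_wave_spec"))
    abort_ceus("invalid_spec", "spec must be a grass_wave_spec")
  with_seed(seed, {
    n <- spec$length
    # run lengths: 1 + Geometric with mean run_length_mean
    p <- if (spec$run_length_mean > 1) 1 / spec$run_length_mean else 1
    x <- integer(0)
    while (length(x) < n) {
      k <- min(50L * ceiling(n / spec$run_length_mean) + 50L, 1e6L)
      lens <- 1L + stats::rgeom(k, p)
      quiet <- runif(k) < spec$quiet_prob
      lvls <- ifelse(quiet, 0L,
                     as.integer(round(runif(k, -spec$baseline_amp,
                                            spec$baseline_amp))))
      x <- c(x, rep(lvls, lens))
    }
    x <- x[seq_len(n)]
    n_spikes <- rbinom(1L, n, min(1, spec$spike_rate / 1000))
    if (n_spikes > 0) {
      pos <- sample.int(n, n_spikes)
      amp <- as.integer(round(spec$spike_amp *
                                runif(n_spikes, 0.5, 1) *
                                sample(c(-1L, 1L), n_spikes, TRUE)))
      x[pos] <- x[pos] + amp
    }
    x <- pmax(pmin(x, 32767L), -32768L)
    us_signal(x, kind = "grass", source_id = sprintf("grass-seed%d", seed))
  })
}

#' Generate a defect-wave signal
#'
#' `n_echoes` carrier-modulated Gaussian-envelope pulses at random positions,
#' with envelope amplitudes drawn uniformly from `echo_amp_range`, plus
#' additive Gaussian noise. Deterministic for a given (spec, seed) pair.
#'
#' @param spec a [defect_wave_spec()].
#' @param seed integer seed.
#' @return a [us_signal()] with `kind = "defect"`.
#' @export
generate_defect_wave <- function(spec, seed) {
  if (!inherits(spec, "defect_wave_spec"))
    abort_ceus("invalid_spec", "spec must be a defect_wave_spec")
  with_seed(seed, {
    n <- spec$length
    y <- numeric(n)
    if (spec$n_echoes > 0) {
      centers <- sort(runif(spec$n_echoes, spec$pulse_width,
                            n - spec$pulse_width))
      amps <- runif(spec$n_echoes, spec$echo_amp_range[1],
                    spec$echo_amp_range[2])
      phases <- runif(spec$n_echoes, 0, 2 * pi)
      t <- seq_len(n)
      sdw <- spec$pulse_width / 4
      for (k in seq_len(spec$n_echoes)) {
        env <- amps[k] * exp(-(t - centers[k])^2 / (2 * sdw^2))
        y <- y + env * sin(2 * pi * (t - centers[k]) / spec$carrier_period +
                             phases[k])
      }
    }
    if (spec$noise_sd > 0) y <- y + rnorm(n, 0, spec$noise_sd)
    x <- pmax(pmin(round(y), 32767), -32768)
    us_signal(x, kind = "defect", source_id = sprintf("defect-seed%d", seed))
  })
}
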