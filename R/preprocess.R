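#' Smooth burrs out of a grass-wave signal
#'
#' Scans left to right and removes spike "burrs". A *peak* is a local
#' extremum whose absolute deviation from the median of a 9-sample centred
#' window exceeds `peak_threshold`. Peaks are processed in order of
#' appearance ("appear first, process first"): each detected peak is replaced
#' by linear interpolation between the nearest flanking non-peak samples and
#' detection resumes at the repaired position, so that when two adjacent
#' peaks have opposite signs, repairing the earlier one can make the later
#' one disappear. Passes repeat until no peak remains, which makes the
#' operation idempotent; the signal length never changes.
#'
#' Smoothing lowers the empirical symbol entropy of the signal because spike
#' values are rare, isolated symbols; with fewer burrs the run structure the
#' byte-level codecs rely on is cleaner.
#'
#' @param signal a grass-kind [us_signal()].
#' @param peak_threshold deviation threshold (a.u.); defaults to 4 times the
#'   signal's median absolute deviation (robust, parameter-light).
#' @return a [us_signal()], same length and kind.
#' @export
smooth_grass_wave <- function(signal, peak_threshold = NULL) {
  check_nonempty(signal)
  x <- as.numeric(signal$samples)
  n <- length(x)
  if (is.null(peak_threshold)) {
    peak_threshold <- 4 * stats::mad(x)
    if (peak_threshold == 0) peak_threshold <- 4  # all-constant fallback
  }
  if (peak_threshold <= 0)
    abort_ceus("invalid_input", "peak_threshold must be > 0")
  if (n < 3L)
    return(us_signal(x, kind = signal$kind,
                     sample_width_bits = signal$sample_width_bits,
                     source_id = signal$source_id))

  win_median <- function(i) {
    lo <- max(1L, i - 4L); hi <- min(n, i + 4L)
    median(x[lo:hi])
  }
  is_peak <- function(i) {
    if (i <= 1L || i >= n) return(FALSE)
    d <- x[i] - win_median(i)
    if (abs(d) <= peak_threshold) return(FALSE)
    # local extremum in the direction of the deviation
    if (d > 0) x[i] >= x[i - 1L] && x[i] >= x[i + 1L]
    else x[i] <= x[i - 1L] && x[i] <= x[i + 1L]
  }

  for (pass in 1:100) {
    repaired <- FALSE
    i <- 2L
    while (i < n) {
      if (is_peak(i)) {
        L <- i - 1L
        while (L > 1L && is_peak(L)) L <- L - 1L
        R <- i + 1L
        while (R < n && is_peak(R)) R <- R + 1L
        idx <- (L + 1L):(R - 1L)
        x[idx] <- x[L] + (x[R] - x[L]) * (idx - L) / (R - L)
        repaired <- TRUE
        i <- max(2L, L)  # resume from the repaired position
      }
      i <- i + 1L
    }
    if (!repaired) break
  }
  us_signal(round(x), kind = signal$kind,
            sample_width_bits = signal$sample_width_bits,
            source_id = signal$source_id)
}

#' First-difference transform of a signal
#'
#' Converts amplitude information into amplitude-change information:
#' the first output sample equals the first input sample, and every later
#' output sample is the difference between consecutive input samples.
#' The result is declared 32-bit wide so that differences of 16-bit samples
#' never wrap, keeping downstream fidelity metrics meaningful. Exactly
#' inverted by [inverse_difference()].
#'
#' @param signal a non-empty [us_signal()].
#' @return a [us_signal()] of equal length, `sample_width_bits = 32`.
#' @export
difference_transform <- function(signal) {
  check_nonempty(signal)
  x <- signal$samples
  out <- c(x[1L], diff(x))
  us_signal(out, kind = signal$kind, sample_width_bits = 32L,
            source_id = signal$source_id)
}

#' Invert the first-difference transform
#'
#' Cumulative sum of the differenced stream; exact integer reconstruction.
#'
#' @param signal a non-empty differenced [us_signal()].
#' @param target_width_bits declared width of the reconstruction (16 or 32).
#' @return a [us_signal()] of equal length.
#' @export
inverse_difference <- function(signal, target_width_bits = 16L) {
  check_nonempty(signal)
  out <- cumsum(as.numeric(signal$samples))
  lim <- 2^(target_width_bits - 1)
  if (any(out < -lim | out > lim - 1))
    abort_ceus("reconstruction",
               "reconstructed samples overflow the declared %d-bit width",
               target_width_bits)
  us_signal(out, kind = signal$kind, sample_width_bits = target_width_bits,
            source_id = signal$source_id)
}

#' Shannon entropy of the empirical sample-value distribution
#'
#' Symbols are the distinct sample values of the signal (not bytes): these
#' are sampled amplitudes, and the compressibility argument concerns the
#' amplitude alphabet. Entropy is
#' \deqn{S = -\sum_i P(X_i)\,\log_2 P(X_i)}
#' with `P` the empirical symbol frequency; zero-probability terms
#' contribute nothing.
#'
#' @param signal a non-empty [us_signal()].
#' @return list of class `entropy_report` with `entropy_bits` (bits per
#'   symbol), `n_symbols` (sample count) and `alphabet_size` (distinct
#'   values).
#' @export
information_entropy <- function(signal) {
  check_nonempty(signal)
  p <- tabulate(factor(signal$samples))
  p <- p / sum(p)
  structure(list(entropy_bits = -sum(p * log2(p)),
                 n_symbols = length(signal$samples),
                 alphabet_size = length(p)),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("<entropy_report> %.4f bits/symbol over %d symbols (alphabet %d)\n",
              x$entropy_bits, x$n_symbols, x$alphabet_size))
  invisible(x)
}
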