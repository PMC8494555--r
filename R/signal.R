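#' Construct a sampled ultrasound signal
#'
#' A `us_signal` holds an ordered sequence of signed integer amplitudes
#' together with its class tag and declared sample width. Two signal classes
#' are distinguished throughout the package: *grass waves* (low-amplitude
#' clutter with sparse spike "burrs" and long constant runs) and *defect
#' waves* (wide-amplitude echo pulses).
#'
#' @param samples integer vector of amplitudes (arbitrary units).
#' @param kind one of `"grass"`, `"defect"`, `"other"`.
#' @param sample_width_bits declared width of one sample; 16 for raw signals,
#'   32 after widening transforms such as [difference_transform()].
#' @param source_id free-text provenance tag.
#' @return object of class `us_signal`.
#' @export
us_signal <- function(samples, kind = c("other", "grass", "defect"),
                      sample_width_bits = 16L, source_id = "") {
  kind <- match.arg(kind)
  if (!is.numeric(samples))
    abort_ceus("invalid_input", "samples must be numeric")
  samples <- as.integer(round(samples))
  if (anyNA(samples))
    abort_ceus("invalid_input", "samples contain NA or out-of-range values")
  sample_width_bits <- as.integer(sample_width_bits)
  if (!sample_width_bits %in% c(16L, 32L))
    abort_ceus("invalid_input", "sample_width_bits must be 16 or 32")
  if (sample_width_bits == 16L && length(samples) &&
      (min(samples) < -32768L || max(samples) > 32767L))
    abort_ceus("invalid_input", "samples exceed declared 16-bit width")
  structure(
    list(samples = samples, kind = kind,
         sample_width_bits = sample_width_bits, source_id = source_id),
    class = "us_signal")
}

#' @export
print.us_signal <- function(x, ...) {
  cat(sprintf("<us_signal> kind=%s n=%d width=%d bits", x$kind,
              length(x$samples), x$sample_width_bits))
  if (nzchar(x$source_id)) cat(" source=", x$source_id, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.us_signal <- function(x) length(x$samples)

is_us_signal <- function(x) inherits(x, "us_signal")

check_nonempty <- function(signal) {
  if (!is_us_signal(signal)) abort_ceus("invalid_input", "not a us_signal")
  if (length(signal$samples) == 0L)
    abort_ceus("empty_input", "signal has no samples")
  invisible(signal)
}

#' Serialize signal samples to a little-endian byte stream
#'
#' Samples are packed as signed little-endian integers of the signal's
#' declared width (2 or 4 bytes per sample). This byte stream is the unit of
#' accounting for all compression-ratio figures.
#'
#' @param signal a [us_signal()].
#' @return raw vector.
#' @export
signal_to_bytes <- function(signal) {
  if (!is_us_signal(signal)) abort_ceus("invalid_input", "not a us_signal")
  writeBin(signal$samples, raw(), size = signal$sample_width_bits %/% 8L,
           endian = "little")
}

#' Rebuild a signal from a little-endian byte stream
#'
#' @param bytes raw vector, length a multiple of `sample_width_bits / 8`.
#' @inheritParams us_signal
#' @return a [us_signal()].
#' @export
bytes_to_signal <- function(bytes, kind = "other", sample_width_bits = 16L,
                            source_id = "") {
  bpw <- as.integer(sample_width_bits) %/% 8L
  if (length(bytes) %% bpw != 0L)
    abort_ceus("corrupt_stream", "byte count not a multiple of sample width")
  n <- length(bytes) %/% bpw
  samples <- readBin(bytes, integer(), n = n, size = bpw, signed = TRUE,
                     endian = "little")
  us_signal(samples, kind = kind, sample_width_bits = sample_width_bits,
            source_id = source_id)
}
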