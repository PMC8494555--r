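#' Compression ratio in percent
#'
#' `CR = 100 * N_after / N_before`: compressed size as a percentage of the
#' original size, so lower is better and values above 100 represent
#' expansion.
#'
#' @param n_after compressed size in bytes.
#' @param n_before original size in bytes (> 0).
#' @return percent.
#' @export
compression_ratio <- function(n_after, n_before) {
  if (any(n_before <= 0))
    abort_ceus("invalid_input", "n_before must be > 0")
  100 * n_after / n_before
}

#' Relative root-mean-squared error between original and restored signals
#'
#' \deqn{R^2MSE = 100\sqrt{\sum_i (X_i - X'_i)^2 / \sum_i X_i^2}}
#' computed over all samples. Zero for every lossless round trip.
#'
#' @param original,restored [us_signal()]s or numeric vectors of equal
#'   length; `original` must not be all-zero.
#' @return percent.
#' @export
relative_rmse <- function(original, restored) {
  x <- if (is_us_signal(original)) original$samples else original
  y <- if (is_us_signal(restored)) restored$samples else restored
  if (length(x) != length(y))
    abort_ceus("invalid_input", "signals differ in length (%d vs %d)",
               length(x), length(y))
  den <- sum(as.numeric(x)^2)
  if (den == 0)
    abort_ceus("undefined_metric", "R2MSE undefined for an all-zero original")
  100 * sqrt(sum((as.numeric(x) - as.numeric(y))^2) / den)
}

#' Fidelity correlation between original and restored signals
#'
#' Pearson correlation
#' \deqn{r = \frac{E[XX'] - E[X]E[X']}{\sqrt{D[X]\,D[X']}}}
#' between restored and raw data; 1 for any lossless round trip with
#' nonconstant data. (The printed form of this definition in parts of the
#' literature omits the square root in the denominator; the standard Pearson
#' coefficient is the only consistent reading and is what is computed here.)
#'
#' @param original,restored [us_signal()]s or numeric vectors, equal length
#'   >= 2, both with nonzero variance.
#' @return correlation in `[-1, 1]`.
#' @export
fidelity_correlation <- function(original, restored) {
  x <- if (is_us_signal(original)) original$samples else original
  y <- if (is_us_signal(restored)) restored$samples else restored
  if (length(x) != length(y))
    abort_ceus("invalid_input", "signals differ in length")
  if (length(x) < 2L)
    abort_ceus("invalid_input", "need at least 2 samples")
  if (var(as.numeric(x)) == 0 || var(as.numeric(y)) == 0)
    abort_ceus("undefined_metric",
               "correlation undefined for a constant signal")
  cor(as.numeric(x), as.numeric(y))
}

#' Platform-aware codec selection policy
#'
#' On a PC platform, DEFLATE (best compression ratio) is selected for both
#' signal classes. On an embedded platform DEFLATE's compression speed is
#' the limiting factor, so a balanced combination is used: RLE for grass
#' waves (whose long byte runs RLE compresses cheaply) and DEFLATE for
#' defect waves.
#'
#' @param platform `"PC"` or `"embedded"`.
#' @param kind `"grass"` or `"defect"`.
#' @return algorithm name: `"RLE"`, `"HUFFMAN"` or `"DEFLATE"`.
#' @export
select_algorithm <- function(platform, kind) {
  if (!platform %in% c("PC", "embedded"))
    abort_ceus("invalid_input", "unknown platform '%s'", platform)
  if (!kind %in% c("grass", "defect"))
    abort_ceus("invalid_input", "unknown signal kind '%s'", kind)
  if (platform == "PC") "DEFLATE"
  else if (kind == "grass") "RLE" else "DEFLATE"
}

#' Benchmark codecs over a set of signals
#'
#' For each (signal, algorithm) pair: serialize the signal to its byte
#' stream, apply the configured preprocessing, encode, decode, undo the
#' preprocessing, and score the reconstruction against the *original*
#' pre-preprocessing samples with CR, R2MSE and r, so that preprocessing
#' invertibility is covered by the same numbers. Wall-clock compression and
#' decompression speeds are reported for context only; they depend on the
#' host and are not part of any correctness contract.
#'
#' @param signals list of [us_signal()]s.
#' @param algorithms character vector of algorithm names.
#' @param preprocessing named list mapping signal kind to one of `"none"`,
#'   `"difference"` (invertible; undone before scoring) or `"smooth"`
#'   (burr removal; lossy, so R2MSE then measures the smoothing loss).
#'   Kinds not listed get `"none"`.
#' @return data frame with one row per (signal, algorithm):
#'   `signal_id, kind, algorithm, CR_pct, R2MSE_pct, r, comp_Bps, decomp_Bps`.
#' @export
benchmark <- function(signals, algorithms = c("RLE", "HUFFMAN", "DEFLATE"),
                      preprocessing = list(defect = "difference")) {
  if (length(signals) == 0L || length(algorithms) == 0L)
    abort_ceus("invalid_input", "need at least one signal and one algorithm")
  if (is_us_signal(signals)) signals <- list(signals)
  rows <- list()
  for (sig in signals) {
    prep <- preprocessing[[sig$kind]]
    if (is.null(prep)) prep <- "none"
    pre <- switch(prep,
      none = sig,
      difference = difference_transform(sig),
      smooth = smooth_grass_wave(sig),
      abort_ceus("invalid_input", "unknown preprocessing '%s'", prep))
    raw_bytes <- signal_to_bytes(sig)
    pre_bytes <- signal_to_bytes(pre)
    for (alg in algorithms) {
      t_c <- system.time(blk <- compress_bytes(pre_bytes, alg))[["elapsed"]]
      t_d <- system.time(dec <- decompress_bytes(blk))[["elapsed"]]
      post <- bytes_to_signal(dec, kind = pre$kind,
                              sample_width_bits = pre$sample_width_bits)
      restored <- switch(prep,
        none = post,
        difference = inverse_difference(post,
                        target_width_bits = sig$sample_width_bits),
        smooth = post)
      rows[[length(rows) + 1L]] <- data.frame(
        signal_id = sig$source_id, kind = sig$kind, algorithm = alg,
        CR_pct = compression_ratio(length(blk$payload), length(raw_bytes)),
        R2MSE_pct = relative_rmse(sig, restored),
        r = fidelity_correlation(sig, restored),
        comp_Bps = if (t_c > 0) length(pre_bytes) / t_c else NA_real_,
        decomp_Bps = if (t_d > 0) length(pre_bytes) / t_d else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
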