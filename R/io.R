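# Minimal binary formats for 1-D research signals and compressed payloads.
# A 16-byte signal header keeps the codecs' byte accounting unambiguous:
#   "USIG" | version u8 | kind u8 (0 grass, 1 defect, 2 other) | width u8 |
#   reserved u8 | sample_count u64 LE
# and a 17-byte container header:
#   "UQZ1" | algorithm u8 (0 RLE, 1 HUFFMAN, 2 DEFLATE) | original_length
#   u64 LE | crc32 u32 LE
# followed by the payload to end of file.

KIND_CODES <- c(grass = 0L, defect = 1L, other = 2L)
ALGO_CODES <- c(RLE = 0L, HUFFMAN = 1L, DEFLATE = 2L)

write_u64le <- function(con, x) {
  x <- as.numeric(x)
  bytes <- as.raw((x %/% 2^(8 * (0:7))) %% 256)
  writeBin(bytes, con)
}

read_u64le <- function(bytes) {
  sum(as.numeric(bytes) * 2^(8 * (0:7)))
}

write_u32le <- function(con, x) {
  x <- as.numeric(x)
  writeBin(as.raw((x %/% 2^(8 * (0:3))) %% 256), con)
}

#' Write a signal to disk
#'
#' Paths ending in `.txt` or `.csv` get the delimited-text form (a `# kind=`
#' comment line then one sample per line); anything else gets the 16-byte
#' binary header plus little-endian samples. Both round-trip bit-exactly
#' through [read_signal()].
#'
#' @param signal a [us_signal()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  if (!is_us_signal(signal)) abort_ceus("invalid_input", "not a us_signal")
  if (grepl("\\.(txt|csv)$", path, ignore.case = TRUE)) {
    writeLines(c(sprintf("# kind=%s width=%d", signal$kind,
                         signal$sample_width_bits),
                 as.character(signal$samples)), path)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("USIG"), con)
  writeBin(as.raw(c(1L, KIND_CODES[[signal$kind]],
                    signal$sample_width_bits, 0L)), con)
  write_u64le(con, length(signal$samples))
  writeBin(signal$samples, con, size = signal$sample_width_bits %/% 8L,
           endian = "little")
  invisible(path)
}

#' Read a signal from disk
#'
#' @param path file written by [write_signal()] (binary or text form,
#'   detected by extension).
#' @return a [us_signal()].
#' @export
read_signal <- function(path) {
  if (grepl("\\.(txt|csv)$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    kind <- "other"; width <- 16L
    hdr <- grepl("^#", lines)
    m <- regmatches(lines[hdr], regexec("kind=(\\w+) width=(\\d+)", lines[hdr]))
    if (length(m) && length(m[[1]]) == 3L) {
      kind <- m[[1]][2]; width <- as.integer(m[[1]][3])
    }
    return(us_signal(as.integer(lines[!hdr]), kind = kind,
                     sample_width_bits = width, source_id = basename(path)))
  }
  if (!file.exists(path)) abort_ceus("format", "no such file: %s", path)
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 16L)
    abort_ceus("format", "truncated signal file (%d bytes, header needs 16)",
               length(bytes))
  if (!identical(bytes[1:4], charToRaw("USIG")))
    abort_ceus("format", "bad magic at byte offset 0")
  kind <- names(KIND_CODES)[match(as.integer(bytes[6]), KIND_CODES)]
  if (is.na(kind)) abort_ceus("format", "unknown kind code at byte offset 5")
  width <- as.integer(bytes[7])
  n <- read_u64le(bytes[9:16])
  bpw <- width %/% 8L
  if (length(bytes) != 16L + n * bpw)
    abort_ceus("format",
               "payload truncated at byte offset %d (declared %d samples)",
               length(bytes), n)
  samples <- readBin(bytes[-(1:16)], integer(), n = n, size = bpw,
                     signed = TRUE, endian = "little")
  us_signal(samples, kind = kind, sample_width_bits = width,
            source_id = basename(path))
}

#' Write a compressed block to disk
#'
#' @param block a [compressed_block()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path) {
  stopifnot(inherits(block, "compressed_block"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("UQZ1"), con)
  writeBin(as.raw(ALGO_CODES[[block$algorithm]]), con)
  write_u64le(con, block$original_length)
  write_u32le(con, block$checksum)
  writeBin(block$payload, con)
  invisible(path)
}

#' Read a compressed block from disk
#'
#' @param path file written by [write_block()].
#' @return a [compressed_block()].
#' @export
read_block <- function(path) {
  if (!file.exists(path)) abort_ceus("format", "no such file: %s", path)
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 17L)
    abort_ceus("format", "truncated container (%d bytes, header needs 17)",
               length(bytes))
  if (!identical(bytes[1:4], charToRaw("UQZ1")))
    abort_ceus("format", "bad magic at byte offset 0")
  algo <- names(ALGO_CODES)[match(as.integer(bytes[5]), ALGO_CODES)]
  if (is.na(algo)) abort_ceus("format", "unknown algorithm code at offset 4")
  n <- read_u64le(bytes[6:13])
  crc <- read_u64le(c(bytes[14:17], as.raw(rep(0L, 4))))
  compressed_block(algo, bytes[-(1:17)], n, crc)
}

#' Write a time-intensity curve as two-column delimited text
#'
#' One `time,intensity` header line, then one `t,I` row per sample.
#'
#' @param curve a [tic_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tic_curve <- function(curve, path) {
  stopifnot(inherits(curve, "tic_curve"))
  writeLines(c("time,intensity",
               sprintf("%.10g,%.10g", curve$times, curve$intensities)), path)
  invisible(path)
}

#' Read a time-intensity curve from two-column delimited text
#'
#' @param path file with a `time,intensity` header line.
#' @param roi_id label; defaults to the file name.
#' @param window observation window (s).
#' @return a [tic_curve()].
#' @export
read_tic_curve <- function(path, roi_id = basename(path), window = 120) {
  df <- read.csv(path, comment.char = "#")
  if (ncol(df) < 2L)
    abort_ceus("format", "expected two columns time,intensity")
  tic_curve(df[[1]], df[[2]], roi_id = roi_id,
            window = max(window, max(df[[1]])))
}

#' Read a pipeline configuration file
#'
#' YAML with nested sections; numeric values carry the units documented on
#' the corresponding constructor arguments (seconds, a.u., samples).
#' Recognised sections: `grass_wave`, `defect_wave` (generator specs),
#' `cohort` (with `groups:` of gamma-variate parameters, `n_per_group`,
#' `between_subject_cv`, `noise_sd`) and `benchmark`
#' (`algorithms`, `preprocessing`).
#'
#' @param path YAML file.
#' @return named list of configuration sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_ceus("format", "config file not found: %s", path)
  yaml::read_yaml(path)
}

cohort_spec_from_config <- function(cfg, seed) {
  groups <- lapply(cfg$groups, function(g) do.call(perfusion_params, g))
  npg <- unlist(cfg$n_per_group)
  cohort_spec(group_param_means = groups,
              n_per_group = npg[names(groups)],
              between_subject_cv = cfg$between_subject_cv %||% 0.15,
              noise_sd = cfg$noise_sd %||% 2,
              seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Delimited table with a provenance footer comment (version, seed, config
# digest) so result files are self-describing.
write_table_footer <- function(df, path, seed = NA, config_path = NULL) {
  write.csv(df, path, row.names = FALSE)
  digest <- if (!is.null(config_path) && file.exists(config_path))
    sprintf("%.0f", cpp_crc32(readBin(config_path, raw(),
                                      n = file.size(config_path))))
  else "none"
  cat(sprintf("# ceusflate %s seed=%s config_crc32=%s\n",
              as.character(utils::packageVersion("ceusflate")),
              as.character(seed), digest),
      file = path, append = TRUE)
  invisible(path)
}
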