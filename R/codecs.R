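#' Compressed block container
#'
#' In-memory container produced by every codec: the algorithm tag, the
#' bit-packed payload, the original byte count and a CRC-32 of the original
#' data (standard reflected polynomial, as in common archive formats).
#' Decoding must reproduce exactly `original_length` bytes whose CRC-32
#' matches `checksum`.
#'
#' @param algorithm one of `"RLE"`, `"HUFFMAN"`, `"DEFLATE"`.
#' @param payload raw vector holding the encoded stream.
#' @param original_length original size in bytes.
#' @param checksum CRC-32 of the original bytes (double, unsigned range).
#' @return object of class `compressed_block`.
#' @export
compressed_block <- function(algorithm, payload, original_length, checksum) {
  algorithm <- match.arg(algorithm, c("RLE", "HUFFMAN", "DEFLATE"))
  if (!is.raw(payload)) abort_ceus("invalid_input", "payload must be raw")
  structure(list(algorithm = algorithm, payload = payload,
                 original_length = as.numeric(original_length),
                 checksum = as.numeric(checksum)),
            class = "compressed_block")
}

#' @export
print.compressed_block <- function(x, ...) {
  cat(sprintf("<compressed_block> %s: %d -> %d bytes (CR %.2f%%) crc32=%.0f\n",
              x$algorithm, x$original_length, length(x$payload),
              if (x$original_length > 0)
                100 * length(x$payload) / x$original_length else NA_real_,
              x$checksum))
  invisible(x)
}

#' CRC-32 checksum of a raw vector
#'
#' @param data raw vector.
#' @return checksum as a double in `[0, 2^32)`.
#' @export
crc32 <- function(data) {
  if (!is.raw(data)) abort_ceus("invalid_input", "data must be raw")
  cpp_crc32(data)
}

# ------------------------------------------------------------------ RLE ----

#' Run-length encode a byte stream
#'
#' The payload is a flat sequence of `(count, value)` byte pairs with counts
#' in 1..255; runs longer than 255 are split across pairs. Inverted exactly
#' by [rle_decode()]. Best suited to grass-wave byte streams, whose quiet
#' intervals serialize to long zero runs.
#'
#' @param data raw vector (may be empty).
#' @return a [compressed_block()] with `algorithm = "RLE"`.
#' @export
rle_encode <- function(data) {
  if (!is.raw(data)) abort_ceus("invalid_input", "data must be raw")
  if (length(data) == 0L)
    return(compressed_block("RLE", raw(0), 0, cpp_crc32(data)))
  r <- rle(as.integer(data))
  # split runs > 255
  nfull <- r$lengths %/% 255L
  rem <- r$lengths %% 255L
  counts <- unlist(mapply(function(f, rm) c(rep(255L, f), if (rm > 0L) rm),
                          nfull, rem, SIMPLIFY = FALSE), use.names = FALSE)
  values <- rep(r$values, nfull + (rem > 0L))
  payload <- as.raw(as.vector(rbind(counts, values)))
  compressed_block("RLE", payload, length(data), cpp_crc32(data))
}

#' Decode a run-length encoded block
#'
#' @param block a [compressed_block()] with `algorithm = "RLE"`.
#' @return raw vector, the exact original bytes (CRC-verified).
#' @export
rle_decode <- function(block) {
  stopifnot(inherits(block, "compressed_block"))
  if (block$algorithm != "RLE")
    abort_ceus("invalid_input", "block algorithm is %s, not RLE", block$algorithm)
  p <- block$payload
  if (length(p) == 0L) {
    verify_block(block, raw(0))
    return(raw(0))
  }
  if (length(p) %% 2L != 0L)
    abort_ceus("corrupt_stream", "corrupt-stream: RLE payload has odd byte count")
  counts <- as.integer(p[c(TRUE, FALSE)])
  if (any(counts == 0L))
    abort_ceus("corrupt_stream", "corrupt-stream: RLE pair with zero count")
  out <- rep(p[c(FALSE, TRUE)], counts)
  verify_block(block, out)
  out
}

# -------------------------------------------------------------- Huffman ----

#' Build an optimal canonical Huffman table from symbol frequencies
#'
#' Standard Huffman construction on the nonzero-frequency symbols, with the
#' resulting lengths converted to canonical codes (shorter codes first, ties
#' broken by symbol index). A single-symbol alphabet is assigned code length
#' 1 so the code stays decodable. Code lengths are capped at 30 bits; the cap
#' can only bind for pathological near-Fibonacci frequency profiles far
#' outside anything a sampled signal produces, and the table remains a valid
#' prefix code if it does.
#'
#' @param frequencies numeric vector of per-symbol counts, indexed by symbol
#'   value + 1; at least one entry must be positive.
#' @return object of class `huffman_table` with `code_lengths` and canonical
#'   `codes` (both indexed like `frequencies`).
#' @export
huffman_build <- function(frequencies) {
  if (!is.numeric(frequencies) || length(frequencies) == 0L)
    abort_ceus("invalid_input", "frequencies must be a numeric vector")
  if (any(frequencies < 0))
    abort_ceus("invalid_input", "frequencies must be non-negative")
  if (all(frequencies == 0))
    abort_ceus("invalid_input", "at least one frequency must be positive")
  lens <- cpp_huffman_lengths(as.numeric(frequencies), 30L)
  codes <- cpp_canonical_codes(lens)
  kraft <- sum(2^(-lens[lens > 0]))
  structure(list(code_lengths = lens, codes = codes, kraft_sum = kraft),
            class = "huffman_table")
}

#' @export
print.huffman_table <- function(x, ...) {
  used <- which(x$code_lengths > 0)
  cat(sprintf("<huffman_table> %d symbols, lengths %d..%d, Kraft sum %.4f\n",
              length(used), min(x$code_lengths[used]),
              max(x$code_lengths[used]), x$kraft_sum))
  invisible(x)
}

# pad or validate a table for the byte alphabet
byte_table_lengths <- function(table) {
  lens <- table$code_lengths
  if (length(lens) > 256L)
    abort_ceus("invalid_input", "table alphabet larger than the byte alphabet")
  c(lens, integer(256L - length(lens)))
}

#' Huffman-encode a byte stream with a prebuilt table
#'
#' @param data raw vector; every byte present must have a code in `table`.
#' @param table a [huffman_table()] over (a subset of) the byte alphabet.
#' @return a [compressed_block()] with `algorithm = "HUFFMAN"`. The payload
#'   carries only the bitstream; the exact bit length is kept in the block's
#'   `n_bits` field.
#' @export
huffman_encode <- function(data, table) {
  if (!is.raw(data)) abort_ceus("invalid_input", "data must be raw")
  if (!inherits(table, "huffman_table"))
    abort_ceus("invalid_input", "table must be a huffman_table")
  enc <- cpp_huffman_encode(data, byte_table_lengths(table))
  blk <- compressed_block("HUFFMAN", enc$payload, length(data), cpp_crc32(data))
  blk$n_bits <- enc$n_bits
  blk
}

#' Decode a Huffman block with its table
#'
#' @param block a [compressed_block()] with `algorithm = "HUFFMAN"`.
#' @param table the [huffman_table()] used at encode time.
#' @return raw vector, the exact original bytes (CRC-verified).
#' @export
huffman_decode <- function(block, table) {
  stopifnot(inherits(block, "compressed_block"))
  if (block$algorithm != "HUFFMAN")
    abort_ceus("invalid_input", "block algorithm is %s, not HUFFMAN",
               block$algorithm)
  n_bits <- if (!is.null(block$n_bits)) block$n_bits
            else 8 * length(block$payload)
  out <- cpp_huffman_decode(block$payload, n_bits, byte_table_lengths(table),
                            block$original_length)
  verify_block(block, out)
  out
}

# ----------------------------------------------------------------- LZ77 ----

#' Tokenize a byte stream with LZ77 sliding-window matching
#'
#' Greedy longest-match search over a 32768-byte window with a 3-byte
#' hash-chain index; matches are 3..258 bytes long. Tokens reconstruct the
#' input exactly under copy-back semantics (overlapping copies allowed).
#' These are the literal/length/distance elements that feed the DEFLATE
#' entropy-coding stage.
#'
#' @param data raw vector.
#' @return data frame with columns `tag` (`"literal"`/`"match"`), `literal`
#'   (byte value 0..255, `NA` for matches), `length` and `distance`
#'   (`NA` for literals).
#' @export
lz77_tokenize <- function(data) {
  if (!is.raw(data)) abort_ceus("invalid_input", "data must be raw")
  tk <- cpp_lz77_tokenize(data)
  is_match <- tk$tag == 1L
  data.frame(
    tag = ifelse(is_match, "match", "literal"),
    literal = ifelse(is_match, NA_integer_, as.integer(tk$literal)),
    length = ifelse(is_match, tk$length, NA_integer_),
    distance = ifelse(is_match, tk$distance, NA_integer_),
    stringsAsFactors = FALSE)
}

#' Reconstruct a byte stream from LZ77 tokens
#'
#' @param tokens a token data frame as produced by [lz77_tokenize()].
#' @return raw vector.
#' @export
lz77_detokenize <- function(tokens) {
  tag <- as.integer(tokens$tag == "match")
  lit <- as.raw(ifelse(is.na(tokens$literal), 0L, tokens$literal))
  len <- as.integer(ifelse(is.na(tokens$length), 0L, tokens$length))
  dist <- as.integer(ifelse(is.na(tokens$distance), 0L, tokens$distance))
  cpp_lz77_detokenize(tag, lit, len, dist)
}

# -------------------------------------------------------------- DEFLATE ----

#' DEFLATE-compress a byte stream (raw RFC 1951)
#'
#' Produces a raw DEFLATE stream using a dynamic-Huffman block: LZ77 tokens
#' are entropy-coded with per-block literal/length and distance trees, the
#' trees' code-length sequences are themselves run-length coded over the
#' 0-18 code-length alphabet, and the code-length-code lengths are emitted
#' in the standard permuted order. A stored-block fallback is used whenever
#' the dynamic block would expand the data, so the output never exceeds the
#' input by more than 5 bytes per 65535-byte chunk. The stream is decodable
#' by any conformant raw-inflate implementation.
#'
#' @param data raw vector (may be empty).
#' @return a [compressed_block()] with `algorithm = "DEFLATE"`.
#' @export
deflate_encode <- function(data) {
  if (!is.raw(data)) abort_ceus("invalid_input", "data must be raw")
  compressed_block("DEFLATE", cpp_deflate(data), length(data), cpp_crc32(data))
}

#' Decode a raw DEFLATE stream
#'
#' Supports stored, fixed-Huffman and dynamic-Huffman blocks. Malformed
#' streams (invalid block type, over-subscribed code lengths, distances
#' reaching before the output start, truncation) raise a corrupt-stream
#' error naming the defect; the CRC of the reconstruction is verified
#' against the block checksum.
#'
#' @param block a [compressed_block()] with `algorithm = "DEFLATE"`.
#' @return raw vector, the exact original bytes.
#' @export
inflate_decode <- function(block) {
  stopifnot(inherits(block, "compressed_block"))
  if (block$algorithm != "DEFLATE")
    abort_ceus("invalid_input", "block algorithm is %s, not DEFLATE",
               block$algorithm)
  out <- cpp_inflate(block$payload)
  verify_block(block, out)
  out
}

verify_block <- function(block, out) {
  if (length(out) != block$original_length)
    abort_ceus("corrupt_stream",
               "corrupt-stream: decoded %d bytes, expected %d",
               length(out), block$original_length)
  if (cpp_crc32(out) != block$checksum)
    abort_ceus("corrupt_stream", "corrupt-stream: CRC-32 mismatch")
  invisible(TRUE)
}

# ------------------------------------------------------- high-level API ----

#' Compress a byte stream with a named algorithm
#'
#' Convenience front end used by the benchmark harness and the command-line
#' tools. `"HUFFMAN"` blocks are made self-contained by prefixing the payload
#' with the 256 code lengths (one byte each) of a table built from the
#' input's byte frequencies.
#'
#' @param data raw vector.
#' @param algorithm `"RLE"`, `"HUFFMAN"` or `"DEFLATE"`.
#' @return a [compressed_block()].
#' @export
compress_bytes <- function(data, algorithm = c("DEFLATE", "RLE", "HUFFMAN")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    RLE = rle_encode(data),
    DEFLATE = deflate_encode(data),
    HUFFMAN = {
      if (length(data) == 0L)
        return(compressed_block("HUFFMAN", raw(0), 0, cpp_crc32(data)))
      tab <- huffman_build(tabulate(as.integer(data) + 1L, 256L))
      blk <- huffman_encode(data, tab)
      blk$payload <- c(as.raw(byte_table_lengths(tab)), blk$payload)
      blk
    })
}

#' Decompress a self-contained block
#'
#' Inverse of [compress_bytes()]; verifies length and CRC-32.
#'
#' @param block a [compressed_block()].
#' @return raw vector.
#' @export
decompress_bytes <- function(block) {
  stopifnot(inherits(block, "compressed_block"))
  switch(block$algorithm,
    RLE = rle_decode(block),
    DEFLATE = inflate_decode(block),
    HUFFMAN = {
      if (block$original_length == 0L) {
        verify_block(block, raw(0))
        return(raw(0))
      }
      if (length(block$payload) < 256L)
        abort_ceus("corrupt_stream", "corrupt-stream: missing Huffman table")
      lens <- as.integer(block$payload[1:256])
      body <- block$payload[-(1:256)]
      out <- cpp_huffman_decode(body, 8 * length(body), lens,
                                block$original_length)
      verify_block(block, out)
      out
    })
}
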