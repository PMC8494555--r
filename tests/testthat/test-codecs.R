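# -- RLE --------------------------------------------------------------------

test_that("RLE emits (count, value) pairs with runs split at 255", {
  blk <- rle_encode(as.raw(c(rep(65, 7), rep(66, 3))))
  expect_identical(as.integer(blk$payload), c(7L, 65L, 3L, 66L))
  expect_equal(blk$original_length, 10)

  long <- as.raw(rep(1, 600))
  blk2 <- rle_encode(long)
  expect_identical(as.integer(blk2$payload), c(255L, 1L, 255L, 1L, 90L, 1L))
  expect_identical(rle_decode(blk2), long)

  empty <- rle_encode(raw(0))
  expect_length(empty$payload, 0L)
  expect_equal(empty$original_length, 0)
  expect_identical(rle_decode(empty), raw(0))
})

test_that("worst-case RLE input expands to exactly 200%", {
  x <- as.raw(rep(c(0, 1), 500))
  blk <- rle_encode(x)
  expect_length(blk$payload, 2000L)
  expect_equal(compression_ratio(length(blk$payload), 1000), 200)
  expect_identical(rle_decode(blk), x)
})

test_that("malformed RLE payloads raise corrupt-stream errors", {
  blk <- rle_encode(as.raw(c(1, 1, 2)))
  bad <- blk; bad$payload <- blk$payload[-1]
  expect_error(rle_decode(bad), "odd byte count")
  crc <- blk; crc$payload[2] <- as.raw(9)
  expect_error(rle_decode(crc), "CRC-32 mismatch")
})

# -- Huffman ----------------------------------------------------------------

test_that("huffman_build reproduces textbook code lengths", {
  tab <- huffman_build(c(2, 1, 1))
  expect_identical(tab$code_lengths, c(1L, 2L, 2L))
  # mean code length equals the entropy of this dyadic distribution
  p <- c(2, 1, 1) / 4
  expect_equal(sum(p * tab$code_lengths), -sum(p * log2(p)))
  single <- huffman_build(c(0, 5))
  expect_identical(single$code_lengths, c(0L, 1L))
  expect_equal(single$kraft_sum, 0.5)
  expect_error(huffman_build(c(0, 0)), class = "ceusflate_invalid_input")
})

test_that("huffman codes are optimal among all prefix codes (alphabet <= 4)", {
  # brute-force oracle: minimal cost over every length assignment satisfying
  # the Kraft inequality (lengths 1..8 are enough at these sizes)
  best_prefix_cost <- function(freq) {
    k <- length(freq)
    grid <- do.call(expand.grid, rep(list(1:8), k))
    ok <- rowSums(2^(-grid)) <= 1 + 1e-12
    min(as.matrix(grid[ok, , drop = FALSE]) %*% freq)
  }
  withr::with_seed(7, {
    for (rep in 1:20) {
      k <- sample(2:4, 1)
      freq <- sample(1:50, k, replace = TRUE)
      tab <- huffman_build(freq)
      expect_equal(sum(freq * tab$code_lengths), best_prefix_cost(freq))
    }
  })
})

test_that("huffman mean code length respects the source-coding bound", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      k <- sample(2:20, 1)
      freq <- sample(1:100, k, replace = TRUE)
      p <- freq / sum(freq)
      tab <- huffman_build(freq)
      mean_len <- sum(p * tab$code_lengths)
      H <- -sum(p * log2(p))
      expect_gte(mean_len, H - 1e-9)
      expect_lt(mean_len, H + 1)
    }
  })
})

test_that("canonical codes are prefix-free and ordered", {
  tab <- huffman_build(c(10, 1, 1, 3, 3, 8))
  used <- which(tab$code_lengths > 0)
  bits <- mapply(function(code, len)
    paste(rev(as.integer(intToBits(code))[seq_len(len)]), collapse = ""),
    tab$codes[used], tab$code_lengths[used])
  for (i in seq_along(bits))
    for (j in seq_along(bits))
      if (i != j) expect_false(startsWith(bits[[j]], bits[[i]]))
  expect_lte(sum(2^(-tab$code_lengths[used])), 1)
})

test_that("huffman encode/decode round-trips with exact bit accounting", {
  withr::with_seed(9, {
    for (rep in 1:50) {
      x <- as.raw(sample(0:3, sample(0:200, 1), replace = TRUE))
      freq <- tabulate(as.integer(x) + 1L, 256L)
      if (all(freq == 0)) freq[1] <- 1
      tab <- huffman_build(freq)
      blk <- huffman_encode(x, tab)
      expect_identical(huffman_decode(blk, tab), x)
      # payload bit length = sum over data symbols of freq * code length
      freq_data <- tabulate(as.integer(x) + 1L, 256L)
      expect_equal(blk$n_bits, sum(freq_data * tab$code_lengths))
    }
  })
  expect_length(huffman_encode(raw(0), huffman_build(c(1)))$payload, 0L)
})

test_that("huffman coding rejects symbols without codes", {
  tab <- huffman_build(c(5, 5))  # codes only for symbols 0 and 1
  expect_error(huffman_encode(as.raw(c(0, 7)), tab), "no code")
  blk <- huffman_encode(as.raw(c(0, 1, 0)), tab)
  trunc <- blk; trunc$payload <- raw(0); trunc$n_bits <- 0
  expect_error(huffman_decode(trunc, tab), "corrupt-stream")
})

# -- LZ77 -------------------------------------------------------------------

test_that("lz77 tokenization matches the hand-traced greedy parse", {
  tk <- lz77_tokenize(charToRaw("abcabcabc"))
  expect_identical(tk$tag, c("literal", "literal", "literal", "match"))
  expect_identical(tk$literal[1:3], as.integer(charToRaw("abc")))
  expect_equal(tk$length[4], 6L)   # overlapping copy-back
  expect_equal(tk$distance[4], 3L)
})

test_that("all-distinct input yields literals only", {
  tk <- lz77_tokenize(as.raw(0:99))
  expect_true(all(tk$tag == "literal"))
  expect_identical(lz77_detokenize(tk), as.raw(0:99))
})

test_that("lz77 detokenize inverts tokenize on random and fixture inputs", {
  corpus <- make_byte_corpus(200, seed = 10)
  for (x in corpus) expect_identical(lz77_detokenize(lz77_tokenize(x)), x)
  dw <- signal_to_bytes(generate_defect_wave(defect_wave_spec(length = 2000), 1))
  expect_identical(lz77_detokenize(lz77_tokenize(dw)), dw)
  bad <- data.frame(tag = "match", literal = NA, length = 5L, distance = 3L)
  expect_error(lz77_detokenize(bad), "distance beyond output start")
})

# -- DEFLATE ----------------------------------------------------------------

test_that("deflate self round trip is exact, including the empty stream", {
  expect_identical(inflate_decode(deflate_encode(raw(0))), raw(0))
  corpus <- make_byte_corpus(300, seed = 12)
  for (x in corpus) expect_identical(inflate_decode(deflate_encode(x)), x)
})

test_that("deflate streams interoperate with the reference zlib coder", {
  corpus <- make_byte_corpus(300, seed = 13)
  for (x in corpus) {
    blk <- deflate_encode(x)
    expect_identical(reference_inflate(blk$payload, x), x)
    ref <- reference_deflate(x)
    rblk <- compressed_block("DEFLATE", ref, length(x),
                             ceusflate:::cpp_crc32(x))
    expect_identical(inflate_decode(rblk), x)
  }
})

test_that("long repeated input compresses below 2%", {
  x <- as.raw(rep(170, 1e5))
  blk <- deflate_encode(x)
  expect_lt(compression_ratio(length(blk$payload), length(x)), 2)
  expect_identical(inflate_decode(blk), x)
})

test_that("stored-block fallback bounds worst-case expansion", {
  withr::with_seed(14, {
    x <- as.raw(sample(0:255, 200000, replace = TRUE))
    blk <- deflate_encode(x)
    chunks <- ceiling(length(x) / 65535)
    expect_lte(length(blk$payload), length(x) + 5 * chunks + 16)
    expect_identical(inflate_decode(blk), x)
  })
})

test_that("malformed deflate streams raise categorised corrupt-stream errors", {
  make_block <- function(payload, orig = raw(1)) {
    compressed_block("DEFLATE", payload, length(orig),
                     ceusflate:::cpp_crc32(orig))
  }
  # reserved block type 11
  expect_error(inflate_decode(make_block(as.raw(0x07))), "invalid block type")
  # fixed-Huffman block whose first symbol is a match: any distance then
  # reaches before the output start. Hand-built bit stream (LSB-first
  # packing): BFINAL=1, BTYPE=01, length symbol 257 (7-bit code 0000001,
  # MSB first), distance symbol 0 (5-bit code 00000), padding.
  bits <- c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0)
  bytes <- packBits(as.integer(bits), type = "raw")
  expect_error(inflate_decode(make_block(bytes, as.raw(c(0, 0, 0)))),
               "distance beyond output start")
  # truncated stream
  good <- deflate_encode(as.raw(sample(0:255, 100, replace = TRUE)))
  trunc <- good; trunc$payload <- good$payload[1:3]
  expect_error(inflate_decode(trunc), "corrupt-stream")
  # CRC mismatch survives structural validity
  tam <- deflate_encode(as.raw(1:50)); tam$checksum <- 12345
  expect_error(inflate_decode(tam), "CRC-32 mismatch")
})

test_that("inflate handles stored blocks from the reference coder", {
  # incompressible input forces zlib (and our encoder) toward stored blocks
  withr::with_seed(15, {
    x <- as.raw(sample(0:255, 70000, replace = TRUE))
    ref <- reference_deflate(x)
    expect_identical(inflate_decode(compressed_block("DEFLATE", ref,
      length(x), ceusflate:::cpp_crc32(x))), x)
  })
})

# -- container round trips --------------------------------------------------

test_that("every codec satisfies decode(encode(x)) = x on a mixed corpus", {
  corpus <- make_byte_corpus(300, seed = 16)
  for (alg in c("RLE", "HUFFMAN", "DEFLATE"))
    for (x in corpus)
      expect_identical(decompress_bytes(compress_bytes(x, alg)), x)
})
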