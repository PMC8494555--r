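# Shared fixtures and independent oracles for the codec and TIC tests.

# Wrap a raw DEFLATE stream in a zlib (RFC 1950) frame so base R's inflater
# can act as the independent decoder.
zlib_wrap <- function(raw_deflate, original) {
  ad <- ceusflate:::cpp_adler32(original)
  trailer <- as.raw(c(ad %/% 2^24, (ad %/% 2^16) %% 256,
                      (ad %/% 256) %% 256, ad %% 256))
  c(as.raw(c(0x78, 0x01)), raw_deflate, trailer)
}

# Reference raw-DEFLATE stream for `x` from base R's zlib compressor
# (strip the 2-byte zlib header and 4-byte Adler-32 trailer).
reference_deflate <- function(x) {
  z <- memCompress(x, type = "gzip")
  z[3:(length(z) - 4L)]
}

reference_inflate <- function(raw_deflate, original) {
  as.raw(memDecompress(zlib_wrap(raw_deflate, original), type = "gzip"))
}

# Mixed corpus of byte inputs: empty, single-byte, all-equal, small-alphabet,
# uniform-random and periodic (match-rich) cases.
make_byte_corpus <- function(n_cases, seed = 1, sizes = c(0:50, 100, 300, 1000)) {
  withr::with_seed(seed, {
    lapply(seq_len(n_cases), function(i) {
      n <- sample(sizes, 1)
      switch(sample(4, 1),
        as.raw(sample(0:255, n, TRUE)),
        as.raw(rep(sample(0:255, 1), n)),
        as.raw(sample(0:3, n, TRUE)),
        {
          p <- as.raw(sample(0:255, max(1, n %/% 5), TRUE))
          head(rep(p, 6), n)
        })
    })
  })
}

# Standard gamma-variate fixture used across the TIC tests (fine sampling so
# discretisation error stays well under the recovery tolerance).
gv_fixture_params <- function(dt = 0.1) {
  perfusion_params(t0 = 10, alpha = 2, beta = 5, A = 1, baseline = 10,
                   duration = 120, dt = dt)
}

# A flat-topped "shifted triangle" curve: zero baseline until t_on, linear
# rise to height over rise_s, linear fall to zero over fall_s. Closed-form
# indicator values are simple chords and areas.
triangle_curve <- function(t_on = 12, rise_s = 10, fall_s = 20, height = 100,
                           dt = 0.01, window = 120) {
  t <- seq(0, window, by = dt)
  y <- numeric(length(t))
  up <- t > t_on & t <= t_on + rise_s
  dn <- t > t_on + rise_s & t <= t_on + rise_s + fall_s
  y[up] <- height * (t[up] - t_on) / rise_s
  y[dn] <- height * (1 - (t[dn] - t_on - rise_s) / fall_s)
  tic_curve(t, y, roi_id = "triangle", window = window)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
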