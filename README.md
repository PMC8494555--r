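# ceusflate

Lossless compression of 1-D sampled ultrasound signals, and quantitative
analysis of contrast-enhanced ultrasound (CEUS) time–intensity curves
(TICs), in one tested R package.

## Who this is for

Two audiences meet here. Engineers working on ultrasound data handling get
from-scratch, verifiable lossless codecs — run-length encoding, canonical
Huffman, and a raw DEFLATE (RFC 1951) encoder/decoder — with the evaluation
metrics and the platform-aware selection policy used to choose between
them. Imaging scientists get nonparametric CEUS TIC quantification (TTP,
AUC, wash-in gradient, rise time, mean transit time, peak intensity, chord
slopes K_UP/K_DOWN), cohort-level group comparisons and diagnostic test
metrics, plus synthetic-data generators with closed-form oracles that make
every estimator testable without patient data.

## The core methods

**Compression.** Signals come in two qualitative classes: *grass waves*
(low-amplitude clutter with long constant runs and sparse spike "burrs")
and *defect waves* (wide-amplitude echo pulses). Grass waves are smoothed
(burr removal by local-median peak detection and interpolation); defect
waves are differenced, `M_i = A_i − A_{i−1}`, converting amplitude into
amplitude-change information. Compressibility is tracked by the empirical
symbol entropy `S = −Σ P(X_i) log2 P(X_i)`. Codecs are scored by

- compression ratio `CR = 100 · N_after / N_before` (%; lower is better),
- relative error `R²MSE = 100 · sqrt(Σ(X−X′)² / ΣX²)` (%), and
- the Pearson fidelity correlation `r`,

with `R²MSE = 0` and `r = 1` demanded of every lossless round trip. The
DEFLATE implementation is bit-compatible with RFC 1951 (dynamic-Huffman
blocks with run-length-coded code-length sequences, stored-block fallback)
and is tested for interoperability against an independent zlib inflater in
both directions. The platform policy selects DEFLATE everywhere on a PC,
and RLE (grass) / DEFLATE (defect) on embedded targets where DEFLATE's
encoding speed is the bottleneck.

**TIC quantification.** Bolus transit is modelled by the gamma-variate
`I(t) = baseline + A (t−t0)^α exp(−(t−t0)/β)`, whose peak is closed-form
(`TTP = t0 + αβ`), giving an analytic oracle for recovery tests. Sampled
curves are quantified under explicit conventions (median baseline from the
first 10% of samples, interpolated 10% arrival threshold, 5-point
smoothing, 50% half-descent for K_DOWN). Group comparisons use Welch's t
test; 2×2 tables use Pearson's chi-square; diagnostic metrics are the
standard confusion-matrix ratios.

## Worked example

```r
library(ceusflate)

g <- generate_grass_wave(grass_wave_spec(), seed = 1)
d <- generate_defect_wave(defect_wave_spec(), seed = 1)
benchmark(list(g, d), c("RLE", "HUFFMAN", "DEFLATE"), preprocessing = list())
#>      signal_id   kind algorithm CR_pct R2MSE_pct r
#> 1  grass-seed1  grass       RLE  62.11         0 1
#> 2  grass-seed1  grass   HUFFMAN  27.78         0 1
#> 3  grass-seed1  grass   DEFLATE   4.02         0 1
#> 4 defect-seed1 defect       RLE 195.73         0 1
#> 5 defect-seed1 defect   HUFFMAN  77.37         0 1
#> 6 defect-seed1 defect   DEFLATE  76.71         0 1
```

Every row is a full encode/decode round trip: `R2MSE_pct = 0` and `r = 1`
certify losslessness; `CR_pct` shows DEFLATE winning on both classes (and
RLE expanding the echo-rich defect class, which is why the embedded policy
only uses it for grass waves):

```r
compress_bytes(signal_to_bytes(d), select_algorithm("embedded", "defect"))
#> <compressed_block> DEFLATE: 16384 -> 12568 bytes (CR 76.71%) crc32=3175157177
```

Quantifying a noiseless model curve recovers the closed-form indicators
(TTP = t0 + αβ = 20 s; AUC = 250 a.u.·s here):

```r
pp <- perfusion_params(t0 = 10, alpha = 2, beta = 5, A = 1,
                       baseline = 10, dt = 0.1)
quantify(perfusion_curve(pp))
#> <tic_parameters>
#>   baseline     10
#>   arrival_time 11.3237
#>   RT           8.67631
#>   TTP          20
#>   mTT          13.7139
#>   I_max        23.5308
#>   Grad         2.30248
#>   AUC          250
#>   K_UP         1.55951
#>   K_DOWN       0.627463
```

A synthetic benign/malignant cohort (52/74 subjects) reproduces the
expected clinical effect direction — malignant lesions peak earlier:

```r
qc <- quantify_cohort(generate_cohort(default_cohort_spec(seed = 1)))
compare_groups(qc, "TTP")
#>   parameter group1    group2 mean1  sd1 n1 mean2  sd2 n2 statistic   df  p_value direction
#> 1       TTP benign malignant    26 2.95 52  17.6 1.71 74      18.5 75.1 1.01e-29         1
```

Mean TTP is 26 s in the benign group versus 17.6 s in the malignant group
(`direction = 1`: first group higher), with a Welch t of 18.5. Diagnostic
performance of any binary call is summarised from its confusion matrix:

```r
diagnostic_metrics(TP = 68, FP = 7, TN = 45, FN = 6)
#> <diagnostic_metrics> sens 91.89%  spec 86.54%  acc 89.68%  PPV 90.67%  NPV 88.24%
```

A command-line front end (`inst/cli/ceusflate`) exposes the same pipeline
as `simulate-signal`, `simulate-cohort`, `compress`, `decompress`,
`benchmark`, `tic`, `compare` and `power` subcommands.

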