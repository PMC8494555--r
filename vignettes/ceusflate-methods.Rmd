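---
title: "Methods: lossless ultrasound compression and CEUS TIC quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lossless ultrasound compression and CEUS TIC quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceusflate)
```

# Scope

`ceusflate` couples two stages that arise together in contrast-enhanced
ultrasound (CEUS) workflows: lossless compression of the 1-D sampled
amplitude signals an ultrasound front end produces, and quantitative
analysis of the time–intensity curves (TICs) a CEUS examination yields.
Because no patient data are available, the package carries first-class
synthetic-data generators whose statistical structure matches what the
downstream stages assume, together with closed-form oracles that make the
estimators testable.

# Signal classes and their generators

Two qualitative classes of ultrasound signal are distinguished:

* **Grass waves** — low-amplitude clutter: long piecewise-constant runs
  (quiet intervals and clutter plateaus) interrupted by sparse spike
  "burrs". Generated as runs with geometric(+1) lengths of mean
  `run_length_mean` (default 20 samples), levels that are exactly zero with
  probability 0.6 and otherwise uniform in ±`baseline_amp` (default 40
  a.u.), plus isolated spikes at `spike_rate` per 1000 samples (default 1)
  with amplitude ~`spike_amp` (default 1500 a.u.).
* **Defect waves** — wide-amplitude echo trains: `n_echoes` (default 12)
  carrier-modulated Gaussian-envelope pulses with envelope amplitudes drawn
  from `echo_amp_range` (default 2000–28000 a.u.), carrier period 32
  samples, pulse width 200 samples, plus Gaussian noise (default SD 20
  a.u.).

These classes are described only qualitatively in the CEUS literature, so
the parameterisation is a stand-in and is flagged as such. Two choices
matter and deserve their rationale:

* *Quiet intervals at exactly zero.* Signals serialize to little-endian
  16-bit byte streams, and byte-level run-length coding only sees runs
  where consecutive bytes repeat. A constant nonzero level like 37
  serializes to the alternating pair `25 00 25 00 …`, which RLE doubles
  rather than compresses. Zero-valued quiet intervals (`00 00 00 …`) are
  what make the grass class RLE-compressible, as its role in the embedded
  compression policy requires. Physically these are the receive intervals
  with no backscatter above the digitiser floor.
* *Long carrier period.* With the carrier sampled ~32× per cycle,
  consecutive samples are strongly correlated, so the first-difference
  transform shrinks the amplitude alphabet — the property the
  defect-wave preprocessing is designed to exploit.

All generators are pure functions of `(spec, seed)`: RNG state is saved,
seeded, and restored around every draw, so identical calls are bit-identical
and the caller's stream is never disturbed.

# Preprocessing

**Burr smoothing** (grass waves). A *peak* is a local extremum whose
absolute deviation from the median of a 9-sample centred window exceeds a
threshold (default 4× the signal's median absolute deviation; an absolute
fallback of 4 a.u. guards the all-constant case). Scanning left to right,
each peak is replaced by linear interpolation between the nearest flanking
non-peak samples and detection resumes at the repaired position — so when
two adjacent peaks point in opposite directions, repairing the earlier one
usually removes the later one ("appear first, process first"). Passes repeat
to a fixed point, which makes the operation idempotent. Spike values are
rare, isolated symbols, so removing them lowers the empirical symbol
entropy; this is asserted on generated fixtures, not claimed universally.

**Difference transform** (defect waves). `M[1] = A[1]`,
`M[i] = A[i] − A[i−1]`, with the output declared 32-bit so differences of
16-bit samples never wrap; `inverse_difference()` (cumulative sum) is an
exact inverse, property-tested over random inputs. Differencing converts
amplitude information into amplitude-change information and reduces the
16-bit *symbol* entropy on the packaged fixtures (≈9.2 → ≈8.9 bits). Note a
subtlety the benchmark makes visible: because the differenced stream is
serialized at 4 bytes/sample, the *byte-level* DEFLATE ratio can be
slightly worse than on the raw 2-byte stream even though the sample
alphabet shrank. Both preprocessing modes are therefore exposed in the
benchmark configuration rather than hard-wired.

**Entropy.** `information_entropy()` computes
$S = -\sum_i P(X_i)\log_2 P(X_i)$ over the distinct *sample values* (not
bytes): the compressibility argument concerns the amplitude alphabet of a
sampled signal.

# Codecs

Three lossless codecs share a container (`compressed_block`: algorithm tag,
payload, original length, CRC-32 of the original).

* **RLE** — `(count, value)` byte pairs, counts 1–255, longer runs split.
* **Canonical Huffman** — optimal code lengths by the standard
  construction; canonical codes (shorter first, ties by symbol index);
  single-symbol alphabets get length 1 so the code stays decodable. Lengths
  are capped at 30 bits (the bit writer is 32-bit); the cap can bind only
  for near-Fibonacci frequency profiles no sampled signal produces.
  Optimality is tested exhaustively against all Kraft-feasible prefix codes
  for alphabets up to 4, and against the source-coding bound
  $H \le \bar L < H + 1$ on random distributions.
* **DEFLATE** — a raw RFC 1951 stream. LZ77 tokenization uses greedy
  longest-match search (3-byte hash chains, 32 KiB window, matches 3–258);
  no lazy matching — greedy is the simplest conformant choice. Dynamic
  Huffman blocks carry the literal/length and distance trees; the trees'
  code-length sequences are run-length coded over the 0–18 code-length
  alphabet and the code-length-code lengths are emitted in the standard
  permuted order. When a dynamic block would expand the data, stored blocks
  are emitted instead, bounding worst-case expansion at 5 bytes per
  65535-byte chunk. The inflater supports stored, fixed-Huffman and
  dynamic-Huffman blocks and classifies malformed streams (invalid block
  type, over-subscribed codes, distance before output start, truncation).

Whether the compression stage described in the source setting is
RFC-conformant is unstated there; bit-exact RFC 1951 conformance is this
package's own decision, because it makes the encoder testable against an
independent oracle: every stream must round-trip through base R's zlib
implementation in both directions (re-framed as RFC 1950 with a
hand-computed Adler-32).

# Evaluation metrics and platform policy

* `CR = 100·N_after/N_before` (%; lower is better, >100 = expansion),
  always accounted against the raw pre-preprocessing byte stream.
* `R²MSE = 100·√(Σ(X−X′)²/ΣX²)` (%) over all samples.
* `r` — Pearson correlation between original and restored samples. (One
  printed form of this definition in the literature drops the square root
  in the denominator and garbles the expectation term; the standard Pearson
  coefficient is the only consistent reading.)

For lossless codecs every round trip must give `R²MSE = 0` and `r = 1`;
the benchmark computes both against the original signal after undoing any
invertible preprocessing, so preprocessing invertibility is covered by the
same numbers. When the lossy smoothing mode is selected, `R²MSE` then
measures the smoothing loss — deliberately.

Compression/decompression speeds are measured and reported for context but
excluded from all tests: they are hardware properties.

The platform policy encodes the operational trade-off: on a PC, DEFLATE
(best CR) for both classes; on an embedded platform, where DEFLATE's
encoding cost is the bottleneck, RLE for grass waves and DEFLATE for defect
waves.

# The TIC model and indicator conventions

Bolus transit is modelled by the gamma-variate,
$$I(t) = \mathrm{baseline} + A\,(t-t_0)^{\alpha} e^{-(t-t_0)/\beta},
\qquad t > t_0,$$
the standard first-pass CEUS bolus shape, chosen because its peak is
closed-form: $\mathrm{TTP} = t_0 + \alpha\beta$,
$I_{\max} = \mathrm{baseline} + A(\alpha\beta)^{\alpha}e^{-\alpha}$. The
remaining oracle indicators come from root-finding and trapezoidal
quadrature on the continuous model at ≥100× the sampling resolution; a
convergence test requires two resolutions to agree within 0.1%.

The indicators have no single operational definition in the field (vendor
packages differ), so the package fixes explicit conventions, shared by the
sampled-curve estimators and the oracle (`tic_conventions()`):

| convention | default | units |
|---|---|---|
| baseline window | first 10% of samples (median) | – |
| arrival threshold | 10% of peak enhancement, interpolated | – |
| half-descent level | 50% of peak enhancement | – |
| smoothing for peak/slopes | 5-point centred moving average | samples |

From these: `RT = TTP − arrival`; `mTT` = first moment of
baseline-subtracted enhancement (clamped at 0) about arrival; `AUC` =
trapezoidal integral of clamped enhancement over the window; `Grad` = max
smoothed first-difference slope on `[arrival, TTP]`; `K_UP` = base-to-peak
chord `(I_max − baseline)/RT`; `K_DOWN` = absolute chord from peak to the
first post-peak half-descent crossing. `Grad` and `K_UP` are deliberately
both reported: the steepest instantaneous wash-in slope and the chord slope
are distinct "slope"-type quantities that the source vocabulary does not
disambiguate. Curves that never fall to half-enhancement inside the window
get `K_DOWN` flagged absent (`missing_washout`) and are dropped from
group statistics with an accounted count; flat curves get every enhancement
indicator flagged rather than raising an error. Clamping enhancement at
zero for AUC/mTT prevents noise below baseline from cancelling enhancement.

One interaction worth knowing: at fixed `A`, raising `beta` (slower
washout) also raises peak enhancement (∝ β^α), so `K_DOWN` ∝ β^(α−1) can
*grow* with `beta`. The monotonicity test therefore renormalises `A` to
hold peak enhancement fixed, isolating the washout-stretch effect.

# Synthetic cohorts

`default_cohort_spec()` emulates a benign/malignant cohort with the
clinically reported group sizes (52/74) and effect directions — malignant
lesions wash in earlier (lower TTP) with larger and steeper enhancement
(higher AUC, Grad). Group mean curves: benign `t0 12 s, α 2.2, β 6.5 s,
A 1.2`; malignant `t0 8 s, α 2.0, β 5.0 s, A 12`; baseline 5 a.u.; 120 s
window at `dt = 0.25 s` (a 4 Hz contrast frame rate). Subjects draw
parameters log-normally (mean-preserving) around the group means with CV
0.15 — log-normal keeps every parameter positive. The shape `α` varies at
CV/3: curve shape is more conserved across subjects than timing or
amplitude, and because AUC ∝ β^{α+1}Γ(α+1) is exponentially sensitive to
`α`, a full-CV shape would swamp amplitude effects that the emulated
findings describe as clearly separated. Measurement noise (SD 2 a.u.) is
added to each sampled curve and clipped at zero. Configurations that
violate the expected effect directions generate a warning, not an error.

These choices were fixed by design-stage effect-size calculation, before
any acceptance measurement; the package emulates the *directions* of the
findings, not patient values.

# Statistics

Group comparisons use Welch's t (no variance-homogeneity assumption —
the source states only "t-test"), two-sided, with no multiple-testing
correction by default to match the per-comparison P < 0.05 convention
(`p.adjust` can always be applied downstream). Degenerate inputs are
explicit: two constant equal samples give statistic 0, p = 1; constant
unequal samples are flagged with p = 0. The paired test treats all-zero
differences the same way. The chi-square test is Pearson without continuity
correction by default (correction available). Diagnostic metrics are the
plain confusion-matrix ratios with zero denominators raising an error that
names the undefined metric.

`power_simulation()` is an *indicator-level* parametric power analysis:
group means come from the closed-form oracle, subject values are drawn
normally with SD = CV × group mean, and Welch tests are run per replicate.
Working at the endpoint level (standard practice in study design) keeps the
sampling model transparent enough that closed-form noncentral-t power is a
valid independent check, which full-curve regeneration would blur through
estimator noise and log-normal skew.

# Numerical choices

* Differences widened to 32-bit rather than wrapped modulo 2^16, keeping
  fidelity metrics on the transformed stream meaningful.
* Peak ties resolve to the earliest time; threshold crossings are linearly
  interpolated; a crossing exactly at a sample returns that sample's time.
* Flat-curve detection is exact (`I_max ≤ baseline` after smoothing).
* CRC-32 (standard reflected polynomial) guards every container;
  decode failures are classified corrupt-stream errors.
* All randomness flows from one explicit integer seed per call; no global
  state survives any generator.

# Problem sizes used by the test suite

Fixture signals are 8192 samples; property corpora are 10^4 mixed byte
inputs (empty through 1000 bytes); TIC recovery uses `dt = 0.1 s` fixtures
(1201 samples) with 200 noisy replicates at 20 dB peak SNR; calibration
uses 10^4 null simulations; direction recovery uses 100 replicate cohorts
of 126 subjects. These sizes give Monte-Carlo standard errors comfortably
below the tested tolerances while the whole suite stays fast.

# Limitations

* The signal-class generators are stand-ins; no claim is made that their
  spectra or amplitude statistics match any particular scanner.
* The TIC generator is a bolus-shape model only — no pharmacokinetics, no
  imaging physics, no motion artefacts; passing recovery tests shows the
  estimators are correct under the stated conventions, not that they are
  robust to everything clinical data can do.
* Indicator definitions are conventions; other operationalisations (e.g. a
  different arrival threshold) will give systematically different RT, mTT
  and slope values on the same curves.
* The DEFLATE encoder aims at conformance and reasonable ratios, not parity
  with tuned zlib levels (no lazy matching, single dynamic block).
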