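#' Time-intensity curve for one region of interest
#'
#' A TIC records ROI-mean CEUS intensity over the observation window after
#' contrast injection. Times must be strictly increasing within
#' `[0, window]`; intensities are non-negative arbitrary units.
#'
#' @param times seconds, strictly increasing, length >= 8.
#' @param intensities a.u., non-negative, same length as `times`.
#' @param roi_id region-of-interest label.
#' @param window observation window in seconds (120 by default, the length
#'   of a stored CEUS cine loop).
#' @return object of class `tic_curve`.
#' @export
tic_curve <- function(times, intensities, roi_id = "roi", window = 120) {
  if (length(times) != length(intensities))
    abort_ceus("invalid_input", "times and intensities differ in length")
  if (length(times) < 8L)
    abort_ceus("invalid_input", "a TIC needs at least 8 samples")
  if (any(diff(times) <= 0))
    abort_ceus("invalid_input", "times must be strictly increasing")
  if (any(times < 0) || any(times > window + 1e-9))
    abort_ceus("invalid_input", "times must lie within [0, window]")
  if (any(intensities < 0))
    abort_ceus("invalid_input", "intensities must be non-negative")
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 roi_id = roi_id, window = window),
            class = "tic_curve")
}

#' @export
print.tic_curve <- function(x, ...) {
  cat(sprintf("<tic_curve> %s: %d samples over [%.3g, %.3g] s (window %g s)\n",
              x$roi_id, length(x$times), min(x$times), max(x$times), x$window))
  invisible(x)
}

#' Operational conventions for TIC indicator extraction
#'
#' The TIC indicators have no single operational definition in the
#' literature (vendor packages each use their own); these are the
#' conventions this package applies, chosen to match common CEUS
#' quantification practice and shared by the sampled-curve estimators and
#' the closed-form oracle.
#'
#' @param arrival_frac arrival is the first crossing of
#'   `baseline + arrival_frac * (I_max - baseline)` (default 10%).
#' @param half_frac the descent reference level as a fraction of peak
#'   enhancement (default 50%, the "semi-descent" level for K_DOWN).
#' @param smooth_window moving-average width in samples for peak and slope
#'   detection (default 5).
#' @param baseline_frac fraction of earliest samples whose median estimates
#'   the baseline (default 10%).
#' @return list of class `tic_conventions`.
#' @export
tic_conventions <- function(arrival_frac = 0.10, half_frac = 0.50,
                            smooth_window = 5L, baseline_frac = 0.10) {
  if (arrival_frac <= 0 || arrival_frac >= 1)
    abort_ceus("invalid_input", "arrival_frac must be in (0, 1)")
  if (half_frac <= 0 || half_frac >= 1)
    abort_ceus("invalid_input", "half_frac must be in (0, 1)")
  structure(list(arrival_frac = arrival_frac, half_frac = half_frac,
                 smooth_window = as.integer(smooth_window),
                 baseline_frac = baseline_frac),
            class = "tic_conventions")
}

new_tic_parameters <- function(baseline, arrival_time, RT, TTP, mTT, I_max,
                               Grad, AUC, K_UP, K_DOWN, flags) {
  structure(list(baseline = baseline, arrival_time = arrival_time, RT = RT,
                 TTP = TTP, mTT = mTT, I_max = I_max, Grad = Grad, AUC = AUC,
                 K_UP = K_UP, K_DOWN = K_DOWN, flags = flags),
            class = "tic_parameters")
}

#' @export
print.tic_parameters <- function(x, ...) {
  cat("<tic_parameters>\n")
  for (f in c("baseline", "arrival_time", "RT", "TTP", "mTT", "I_max",
              "Grad", "AUC", "K_UP", "K_DOWN"))
    cat(sprintf("  %-12s %s\n", f,
                if (is.na(x[[f]])) "absent" else format(x[[f]], digits = 6)))
  invisible(x)
}

#' @export
as.data.frame.tic_parameters <- function(x, ...) {
  data.frame(baseline = x$baseline, arrival_time = x$arrival_time, RT = x$RT,
             TTP = x$TTP, mTT = x$mTT, I_max = x$I_max, Grad = x$Grad,
             AUC = x$AUC, K_UP = x$K_UP, K_DOWN = x$K_DOWN)
}

# centred moving average with shrinking windows at the edges
moving_average <- function(y, k) {
  if (k <= 1L) return(y)
  n <- length(y)
  h <- k %/% 2L
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Estimate the pre-arrival baseline of a TIC
#'
#' Median intensity over the earliest `baseline_frac` of samples. The median
#' keeps the estimate honest even when the bolus arrives inside that early
#' segment, as long as most of it is still pre-contrast.
#'
#' @param curve a [tic_curve()].
#' @param conventions a [tic_conventions()].
#' @return baseline intensity (a.u.).
#' @export
estimate_baseline <- function(curve, conventions = tic_conventions()) {
  stopifnot(inherits(curve, "tic_curve"))
  n <- max(1L, ceiling(conventions$baseline_frac * length(curve$times)))
  median(curve$intensities[seq_len(n)])
}

#' Locate the peak of a TIC
#'
#' `I_max` is the maximum of the moving-average-smoothed intensities and TTP
#' the time at which it occurs; ties resolve to the earliest time.
#'
#' @inheritParams estimate_baseline
#' @return list with `TTP` (s) and `I_max` (a.u.).
#' @export
detect_peak <- function(curve, conventions = tic_conventions()) {
  stopifnot(inherits(curve, "tic_curve"))
  ys <- moving_average(curve$intensities, conventions$smooth_window)
  i <- which.max(ys)  # earliest maximum
  list(TTP = curve$times[i], I_max = ys[i])
}

#' Contrast arrival time of a TIC
#'
#' First time the smoothed intensity exceeds
#' `baseline + arrival_frac * (I_max - baseline)`, linearly interpolated
#' between the bracketing samples.
#'
#' @inheritParams estimate_baseline
#' @param baseline,I_max precomputed values; estimated from the curve when
#'   omitted.
#' @return arrival time (s).
#' @export
arrival_time <- function(curve, baseline = NULL, I_max = NULL,
                         conventions = tic_conventions()) {
  stopifnot(inherits(curve, "tic_curve"))
  if (is.null(baseline)) baseline <- estimate_baseline(curve, conventions)
  ys <- moving_average(curve$intensities, conventions$smooth_window)
  if (is.null(I_max)) I_max <- max(ys)
  if (I_max <= baseline)
    abort_ceus("flat_curve", "no enhancement above baseline")
  thr <- baseline + conventions$arrival_frac * (I_max - baseline)
  above <- which(ys >= thr)
  if (length(above) == 0L)
    abort_ceus("flat_curve", "smoothed curve never reaches the arrival threshold")
  i <- above[1L]
  if (i == 1L || ys[i] == thr) return(curve$times[i])
  t0 <- curve$times[i - 1L]; t1 <- curve$times[i]
  y0 <- ys[i - 1L]; y1 <- ys[i]
  t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
}

#' Rise time (arrival to peak)
#'
#' @inheritParams estimate_baseline
#' @return `RT = TTP - arrival_time`, in seconds.
#' @export
rise_time <- function(curve, conventions = tic_conventions()) {
  pk <- detect_peak(curve, conventions)
  pk$TTP - arrival_time(curve, I_max = pk$I_max, conventions = conventions)
}

#' Mean transit time of the enhancement bolus
#'
#' First moment of the baseline-subtracted enhancement
#' `I' = max(I - baseline, 0)` about the arrival time, over samples at or
#' after arrival: `mTT = sum((t - arrival) I') / sum(I')`.
#'
#' @inheritParams estimate_baseline
#' @return mTT in seconds.
#' @export
mean_transit_time <- function(curve, conventions = tic_conventions()) {
  base <- estimate_baseline(curve, conventions)
  arr <- arrival_time(curve, baseline = base, conventions = conventions)
  sel <- curve$times >= arr
  w <- pmax(curve$intensities[sel] - base, 0)
  if (sum(w) == 0) abort_ceus("flat_curve", "no enhancement after arrival")
  sum((curve$times[sel] - arr) * w) / sum(w)
}

#' Area under the baseline-subtracted TIC
#'
#' Trapezoidal integral of `max(I - baseline, 0)` over the sampled window.
#' Clamping at zero keeps noise excursions below baseline from cancelling
#' genuine enhancement.
#'
#' @inheritParams estimate_baseline
#' @return AUC in a.u.*s.
#' @export
auc_trapezoid <- function(curve, conventions = tic_conventions()) {
  base <- estimate_baseline(curve, conventions)
  trapz(curve$times, pmax(curve$intensities - base, 0))
}

#' Wash-in gradient (steepest ascending slope)
#'
#' Maximum first-difference slope of the smoothed curve over the wash-in
#' interval `[arrival, TTP]`.
#'
#' @inheritParams estimate_baseline
#' @return Grad in a.u./s.
#' @export
wash_in_gradient <- function(curve, conventions = tic_conventions()) {
  base <- estimate_baseline(curve, conventions)
  pk <- detect_peak(curve, conventions)
  if (pk$I_max <= base) abort_ceus("flat_curve", "no enhancement above baseline")
  arr <- arrival_time(curve, baseline = base, I_max = pk$I_max,
                      conventions = conventions)
  ys <- moving_average(curve$intensities, conventions$smooth_window)
  slopes <- diff(ys) / diff(curve$times)
  mid <- (head(curve$times, -1) + tail(curve$times, -1)) / 2
  sel <- mid >= arr & mid <= pk$TTP
  if (!any(sel)) sel <- curve$times[-1] >= arr & head(curve$times, -1) <= pk$TTP
  if (!any(sel)) abort_ceus("flat_curve", "empty wash-in interval")
  max(slopes[sel])
}

#' Base-to-peak and semi-descent chord slopes
#'
#' `K_UP = (I_max - baseline) / (TTP - arrival)` is the ascending chord from
#' baseline crossing to peak. `K_DOWN` is the absolute chord slope from the
#' peak down to the first post-peak time the smoothed curve reaches
#' `baseline + half_frac * (I_max - baseline)` (linearly interpolated).
#' When the curve never falls to that level inside the window, `K_DOWN` is
#' reported absent with a `missing_washout` flag.
#'
#' @inheritParams estimate_baseline
#' @return list with `K_UP`, `K_DOWN` (both a.u./s; `K_DOWN` may be `NA`)
#'   and `missing_washout` (logical).
#' @export
slopes_k <- function(curve, conventions = tic_conventions()) {
  base <- estimate_baseline(curve, conventions)
  pk <- detect_peak(curve, conventions)
  if (pk$I_max <= base) abort_ceus("flat_curve", "no enhancement above baseline")
  arr <- arrival_time(curve, baseline = base, I_max = pk$I_max,
                      conventions = conventions)
  K_UP <- (pk$I_max - base) / (pk$TTP - arr)
  ys <- moving_average(curve$intensities, conventions$smooth_window)
  half <- base + conventions$half_frac * (pk$I_max - base)
  post <- which(curve$times > pk$TTP)
  K_DOWN <- NA_real_
  missing_washout <- TRUE
  below <- post[ys[post] <= half]
  if (length(below) > 0L) {
    i <- below[1L]
    t_half <- if (i == 1L || ys[i] == half) curve$times[i] else {
      t0 <- curve$times[i - 1L]; t1 <- curve$times[i]
      y0 <- ys[i - 1L]; y1 <- ys[i]
      t0 + (half - y0) / (y1 - y0) * (t1 - t0)
    }
    K_DOWN <- abs((half - pk$I_max) / (t_half - pk$TTP))
    missing_washout <- FALSE
  }
  list(K_UP = K_UP, K_DOWN = K_DOWN, missing_washout = missing_washout)
}

#' Extract all TIC indicators from one curve
#'
#' Orchestrates baseline estimation, peak and arrival detection, and all
#' derived indicators. A curve with no enhancement above baseline (flat or
#' noise-only) gets its baseline reported and every enhancement indicator
#' flagged absent rather than raising an error. Deterministic: no random
#' element anywhere in the extraction.
#'
#' @inheritParams estimate_baseline
#' @return a `tic_parameters` object; absent indicators are `NA` with the
#'   reason in `flags`.
#' @export
quantify <- function(curve, conventions = tic_conventions()) {
  stopifnot(inherits(curve, "tic_curve"))
  base <- estimate_baseline(curve, conventions)
  pk <- detect_peak(curve, conventions)
  if (pk$I_max <= base) {
    return(new_tic_parameters(
      baseline = base, arrival_time = NA_real_, RT = NA_real_, TTP = NA_real_,
      mTT = NA_real_, I_max = base, Grad = NA_real_, AUC = 0, K_UP = NA_real_,
      K_DOWN = NA_real_, flags = c(flat = TRUE, missing_washout = NA)))
  }
  arr <- arrival_time(curve, baseline = base, I_max = pk$I_max,
                      conventions = conventions)
  ks <- slopes_k(curve, conventions)
  new_tic_parameters(
    baseline = base, arrival_time = arr, RT = pk$TTP - arr, TTP = pk$TTP,
    mTT = mean_transit_time(curve, conventions), I_max = pk$I_max,
    Grad = wash_in_gradient(curve, conventions),
    AUC = auc_trapezoid(curve, conventions),
    K_UP = ks$K_UP, K_DOWN = ks$K_DOWN,
    flags = c(flat = FALSE, missing_washout = ks$missing_washout))
}

#' Quantify every curve in a cohort
#'
#' @param cohort list of subject records from [generate_cohort()].
#' @param conventions a [tic_conventions()].
#' @return data frame with `subject_id`, `group` and one column per
#'   indicator; absent indicators are `NA`.
#' @export
quantify_cohort <- function(cohort, conventions = tic_conventions()) {
  rows <- lapply(cohort, function(rec) {
    cbind(data.frame(subject_id = rec$subject_id, group = rec$group_label,
                     stringsAsFactors = FALSE),
          as.data.frame(quantify(rec$curve, conventions)))
  })
  do.call(rbind, rows)
}
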