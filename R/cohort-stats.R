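#' Diagnostic metrics from a 2x2 confusion matrix
#'
#' With "positive" meaning malignant: sensitivity `100*TP/(TP+FN)`,
#' specificity `100*TN/(TN+FP)`, accuracy `100*(TP+TN)/total`,
#' PPV `100*TP/(TP+FP)`, NPV `100*TN/(TN+FN)`. Any metric whose denominator
#' is zero raises an error naming that metric.
#'
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return list of class `diagnostic_metrics`, percentages.
#' @export
diagnostic_metrics <- function(TP, FP, TN, FN) {
  cts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(cts < 0) || any(cts != round(cts)))
    abort_ceus("invalid_input", "counts must be non-negative integers")
  if (sum(cts) == 0) abort_ceus("invalid_input", "all counts are zero")
  need <- c(sensitivity = TP + FN, specificity = TN + FP,
            PPV = TP + FP, NPV = TN + FN)
  bad <- names(need)[need == 0]
  if (length(bad))
    abort_ceus("undefined_metric", "undefined metric: %s (zero denominator)",
               paste(bad, collapse = ", "))
  structure(list(
    sensitivity = 100 * TP / (TP + FN),
    specificity = 100 * TN / (TN + FP),
    accuracy = 100 * (TP + TN) / sum(cts),
    PPV = 100 * TP / (TP + FP),
    NPV = 100 * TN / (TN + FN),
    counts = cts), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf(
    "<diagnostic_metrics> sens %.2f%%  spec %.2f%%  acc %.2f%%  PPV %.2f%%  NPV %.2f%%\n",
    x$sensitivity, x$specificity, x$accuracy, x$PPV, x$NPV))
  invisible(x)
}

new_group_comparison <- function(parameter, group1, group2, mean1, sd1, n1,
                                 mean2, sd2, n2, test, statistic, df, p_value,
                                 degenerate = FALSE) {
  structure(list(parameter = parameter, group1 = group1, group2 = group2,
                 mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2,
                 test = test, statistic = statistic, df = df,
                 p_value = p_value,
                 direction = sign(mean1 - mean2),
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: %s (%.4g +/- %.4g, n=%d) vs %s (%.4g +/- %.4g, n=%d)\n  %s: statistic %.4g, df %.4g, p = %.4g%s\n",
    x$parameter, x$group1, x$mean1, x$sd1, x$n1, x$group2, x$mean2, x$sd2,
    x$n2, x$test, x$statistic, x$df, x$p_value,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Welch two-sample t test
#'
#' Unequal-variance t test (Welch statistic with Welch-Satterthwaite
#' degrees of freedom, two-sided p). Welch's form is used for all group
#' comparisons because it needs no variance-homogeneity assumption.
#' Samples that are both constant are handled explicitly: equal constants
#' give statistic 0 and p = 1; different constants are flagged degenerate
#' with p = 0.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param parameter label carried into the result.
#' @param group1,group2 group labels.
#' @return a `group_comparison`.
#' @export
welch_t_test <- function(a, b, parameter = "value",
                         group1 = "group1", group2 = "group2") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    abort_ceus("invalid_input", "each sample needs at least 2 observations")
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- mean(a) == mean(b)
    return(new_group_comparison(parameter, group1, group2,
      mean(a), 0, length(a), mean(b), 0, length(b), "Welch t",
      statistic = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
      df = NA_real_, p_value = if (eq) 1 else 0, degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  new_group_comparison(parameter, group1, group2,
    mean(a), sd(a), length(a), mean(b), sd(b), length(b), "Welch t",
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value)
}

#' Paired t test
#'
#' One-sample t test on within-pair differences, two-sided. Zero-variance
#' differences are handled explicitly: all-zero differences give statistic 0
#' and p = 1 (flagged degenerate); constant nonzero differences give an
#' unbounded statistic with p reported as 0 and the degenerate flag set.
#'
#' @param x,y paired numeric samples of equal length >= 2.
#' @inheritParams welch_t_test
#' @return a `group_comparison`.
#' @export
paired_t_test <- function(x, y, parameter = "value",
                          group1 = "x", group2 = "y") {
  if (length(x) != length(y))
    abort_ceus("invalid_input", "paired samples differ in length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L)
    abort_ceus("invalid_input", "need at least 2 complete pairs")
  d <- x - y
  if (sd(d) == 0) {
    zero <- all(d == 0)
    return(new_group_comparison(parameter, group1, group2,
      mean(x), sd(x), length(x), mean(y), sd(y), length(y), "paired t",
      statistic = if (zero) 0 else Inf * sign(d[1]),
      df = length(d) - 1, p_value = if (zero) 1 else 0, degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE)
  new_group_comparison(parameter, group1, group2,
    mean(x), sd(x), length(x), mean(y), sd(y), length(y), "paired t",
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic without continuity correction by default (the
#' correction is available via `correct = TRUE`), df = 1, p from the
#' chi-square distribution.
#'
#' @param tbl 2x2 matrix of non-negative counts.
#' @param correct apply Yates continuity correction.
#' @param parameter label carried into the result.
#' @return a `group_comparison` (means are the two row proportions of the
#'   first column).
#' @export
chi_square_test <- function(tbl, correct = FALSE, parameter = "proportion") {
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == c(2L, 2L)))
    abort_ceus("invalid_input", "table must be 2x2")
  if (any(tbl < 0)) abort_ceus("invalid_input", "counts must be non-negative")
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0))
    abort_ceus("invalid_input", "zero marginal in the 2x2 table")
  ct <- suppressWarnings(chisq.test(tbl, correct = correct))
  p1 <- tbl[1, 1] / sum(tbl[1, ])
  p2 <- tbl[2, 1] / sum(tbl[2, ])
  new_group_comparison(parameter, "row1", "row2",
    p1, NA_real_, sum(tbl[1, ]), p2, NA_real_, sum(tbl[2, ]),
    if (correct) "chi-square (Yates)" else "chi-square",
    statistic = unname(ct$statistic), df = unname(ct$parameter),
    p_value = ct$p.value)
}

#' Pairwise group comparisons of one TIC indicator
#'
#' Runs a Welch t test for every pair of groups in a quantified-cohort
#' table. Rows with the indicator absent (for example missing-washout
#' K_DOWN) are dropped, with the dropped count recorded in the result's
#' `n_dropped` attribute.
#'
#' @param records data frame from [quantify_cohort()] (needs `group` plus
#'   the indicator column).
#' @param parameter indicator column name, e.g. `"TTP"`.
#' @return data frame with one row per group pair: group labels, means,
#'   SDs, Welch statistic, df, p value and direction
#'   (`sign(mean1 - mean2)`).
#' @export
compare_groups <- function(records, parameter) {
  if (!parameter %in% names(records))
    abort_ceus("invalid_input", "no column '%s' in records", parameter)
  keep <- !is.na(records[[parameter]])
  n_dropped <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  groups <- unique(records$group)
  if (length(groups) < 2L)
    abort_ceus("invalid_input", "need at least 2 groups after exclusions")
  sizes <- table(records$group)
  if (any(sizes < 2L))
    abort_ceus("invalid_input", "every group needs >= 2 usable subjects")
  rows <- list()
  for (i in seq_len(length(groups) - 1L)) {
    for (j in seq((i + 1L), length(groups))) {
      g1 <- groups[i]; g2 <- groups[j]
      cmp <- welch_t_test(records[[parameter]][records$group == g1],
                          records[[parameter]][records$group == g2],
                          parameter = parameter, group1 = g1, group2 = g2)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = parameter, group1 = g1, group2 = g2,
        mean1 = cmp$mean1, sd1 = cmp$sd1, n1 = cmp$n1,
        mean2 = cmp$mean2, sd2 = cmp$sd2, n2 = cmp$n2,
        statistic = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
        direction = cmp$direction, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Indicator-level power simulation for a two-group design
#'
#' Parametric power analysis at the endpoint level: for each indicator the
#' group means come from the closed-form oracle applied to the group mean
#' curves, subject values are drawn normally around them with standard
#' deviation `between_subject_cv * group mean`, and a Welch t test is run
#' per replicate. Power is the fraction of replicates with p below `alpha`;
#' the Monte-Carlo standard error `sqrt(power(1-power)/n_reps)` is reported
#' alongside. Working at the indicator level (rather than regenerating whole
#' curves) keeps the sampling model transparent enough to check against
#' closed-form noncentral-t power.
#'
#' @param spec a [cohort_spec()] with exactly 2 groups.
#' @param parameters indicator names to test.
#' @param n_reps number of simulated cohorts (>= 100).
#' @param alpha significance level.
#' @param seed integer seed.
#' @return data frame: `parameter`, `power`, `mc_se`, `n1`, `n2`.
#' @export
power_simulation <- function(spec, parameters = c("TTP", "AUC", "Grad"),
                             n_reps = 1000L, alpha = 0.05, seed = 1L) {
  if (!inherits(spec, "cohort_spec"))
    abort_ceus("invalid_spec", "spec must be a cohort_spec")
  if (n_reps < 100L) abort_ceus("invalid_input", "n_reps must be >= 100")
  gs <- names(spec$group_param_means)
  if (length(gs) != 2L)
    abort_ceus("invalid_input", "power_simulation needs exactly 2 groups")
  m1 <- analytic_tic_parameters(spec$group_param_means[[1]])
  m2 <- analytic_tic_parameters(spec$group_param_means[[2]])
  n1 <- spec$n_per_group[[gs[1]]]
  n2 <- spec$n_per_group[[gs[2]]]
  cv <- spec$between_subject_cv
  with_seed(seed, {
    rows <- lapply(parameters, function(p) {
      mu1 <- m1[[p]]; mu2 <- m2[[p]]
      if (is.na(mu1) || is.na(mu2))
        abort_ceus("invalid_input", "indicator %s absent for a group mean", p)
      s1 <- abs(cv * mu1); s2 <- abs(cv * mu2)
      hits <- vapply(seq_len(n_reps), function(r) {
        a <- rnorm(n1, mu1, s1)
        b <- rnorm(n2, mu2, s2)
        welch_t_test(a, b)$p_value < alpha
      }, logical(1))
      pw <- mean(hits)
      data.frame(parameter = p, power = pw,
                 mc_se = sqrt(pw * (1 - pw) / n_reps),
                 n1 = n1, n2 = n2, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
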