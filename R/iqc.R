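#' Percent coefficient of variation
#'
#' `100 * sd / mean`, the long-term reproducibility metric of the QC
#' program. Exposed directly so printed mean/SD pairs can be checked.
#'
#' @param mean,sd mean and SD on the same scale; `mean` must be nonzero.
#' @return percent CV.
#' @examples
#' cvPercent(30.12, 0.43)  # QC1 palmitic acid long-term CV
#' @export
cvPercent <- function(mean, sd) {
  if (any(mean == 0)) stop("CV undefined for zero mean")
  100 * sd / mean
}

#' Long-term precision of a QC series
#'
#' Mean, sample SD (n-1 denominator) and percent CV of a QC analyte's
#' measurement series across batches.
#'
#' @param values numeric vector of at least 2 percent measurements.
#' @return list with `mean`, `sd`, `cv`.
#' @examples
#' longtermCv(c(1, 3))  # cv = 70.71%
#' @export
longtermCv <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  s <- sd(values)
  list(mean = m, sd = s, cv = cvPercent(m, s))
}

#' Establish a Shewhart individuals chart from baseline batches
#'
#' Computes the centre line (Avg) and control limits (LCL/UCL at
#' `avg +/- k * sd`) from a baseline period of replicated QC results —
#' in routine use, the first 60 successive batches. The sample SD uses
#' the n-1 denominator. A zero-variance baseline yields a degenerate
#' chart (LCL = UCL = Avg) with a warning.
#'
#' @param baseline_values numeric vector of at least 2 baseline percents.
#' @param k sigma multiplier (default 3).
#' @param code analyte code (metadata).
#' @param material `"qc1"` or `"qc2"` (metadata).
#' @return A [ControlChart-class].
#' @examples
#' ch <- establishChart(c(1, 2, 3))
#' c(lcl(ch), avgLine(ch), ucl(ch))  # -1 2 5
#' @export
establishChart <- function(baseline_values, k = 3, code = "analyte",
                           material = "qc1") {
  if (length(baseline_values) < 2L) {
    stop("need at least 2 baseline values to establish a chart")
  }
  s <- sd(baseline_values)
  if (s == 0) {
    warning("zero-variance baseline: LCL = UCL = Avg")
  }
  new("ControlChart", code = code, material = material,
      avg = mean(baseline_values), sd = s, k = k,
      nBaseline = length(baseline_values))
}

#' Evaluate a batch value against a control chart
#'
#' A point is in control iff `LCL <= value <= UCL`, boundary inclusive
#' (the single point-beyond-limit rule).
#'
#' @param chart a [ControlChart-class].
#' @param value percent measurement (vectorised).
#' @param batch_id optional batch identifier(s).
#' @return `data.frame` with columns `batch_id`, `value`, `in_control`.
#' @examples
#' ch <- establishChart(c(1, 2, 3))
#' evaluatePoint(ch, c(2, 5, 5.01))$in_control  # TRUE TRUE FALSE
#' @export
evaluatePoint <- function(chart, value, batch_id = NA_character_) {
  data.frame(
    batch_id = rep_len(as.character(batch_id), length(value)),
    value = value,
    in_control = value >= lcl(chart) & value <= ucl(chart),
    stringsAsFactors = FALSE)
}

#' Summarise grouped QC values
#'
#' Per-label n, mean, sample SD and percent CV — the shape of a monthly
#' stability table. CV is computed from the unrounded mean/SD.
#'
#' @param labels group labels (e.g. month index), same length as `values`.
#' @param values percent measurements.
#' @return `data.frame` with columns `label`, `n`, `mean`, `sd`, `cv`,
#'   in first-appearance order of the labels.
#' @export
groupSummaries <- function(labels, values) {
  stopifnot(length(labels) == length(values))
  labs <- unique(labels)
  out <- do.call(rbind, lapply(labs, function(l) {
    x <- values[labels == l]
    m <- mean(x)
    s <- if (length(x) >= 2L) sd(x) else 0
    data.frame(label = as.character(l), n = length(x), mean = m, sd = s,
               cv = if (m != 0) 100 * s / m else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.checkGroups <- function(groups, min_n = 1L) {
  stopifnot(all(c("n", "mean", "sd") %in% names(groups)),
            nrow(groups) >= 1L)
  if (any(groups$n < min_n)) {
    stop("every group needs n >= ", min_n)
  }
}

#' Sample-size-weighted grand mean of group summaries
#'
#' `sum(n_i * mean_i) / sum(n_i)` — the overall mean recovered from a
#' table of per-group (n, mean) summaries.
#'
#' @param groups `data.frame` with columns `n`, `mean` (and usually `sd`),
#'   one row per group.
#' @return the grand mean.
#' @examples
#' round(weightedGrandMean(qcMonthlySummaries("DHA")), 2)  # 2.15
#' @export
weightedGrandMean <- function(groups) {
  stopifnot(all(c("n", "mean") %in% names(groups)), nrow(groups) >= 1L)
  sum(groups$n * groups$mean) / sum(groups$n)
}

#' Pooled overall percent CV from group summaries
#'
#' Reconstructs the total sum of squares of the underlying raw series from
#' per-group (n, mean, sd) summaries —
#' `SS = sum((n_i - 1) sd_i^2) + sum(n_i (mean_i - grand)^2)` — and
#' reports `100 * sqrt(SS / (N - 1)) / grand`. When the groups partition a
#' raw series this equals [longtermCv()] on the concatenated values
#' exactly.
#'
#' @param groups `data.frame` with columns `n` (all >= 2), `mean`, `sd`.
#' @return percent CV of the pooled series.
#' @examples
#' round(pooledOverallCv(qcMonthlySummaries("DHA")), 1)  # 2.8
#' @export
pooledOverallCv <- function(groups) {
  .checkGroups(groups, min_n = 2L)
  grand <- weightedGrandMean(groups)
  if (grand == 0) stop("CV undefined for zero grand mean")
  n_tot <- sum(groups$n)
  ss <- sum((groups$n - 1) * groups$sd^2) +
    sum(groups$n * (groups$mean - grand)^2)
  100 * sqrt(ss / (n_tot - 1)) / grand
}

#' One-way ANOVA from group summaries
#'
#' Single-factor analysis of variance computed from per-group
#' (n, mean, sd) summaries alone:
#' `MS_between = sum(n_i (mean_i - grand)^2) / (k - 1)`,
#' `MS_within = sum((n_i - 1) sd_i^2) / (N - k)`, `F = MS_between /
#' MS_within`, with the p-value from the upper tail of the F
#' distribution. Identical to a from-raw-data ANOVA whenever the raw data
#' match the summaries.
#'
#' @param groups `data.frame` with columns `n` (all >= 2), `mean`, `sd`;
#'   at least 2 groups.
#' @return list with `f`, `df_between`, `df_within`, `p`.
#' @examples
#' anovaFromSummaries(qcMonthlySummaries("DHA"))$f  # ~1.40
#' @export
anovaFromSummaries <- function(groups) {
  .checkGroups(groups, min_n = 2L)
  k <- nrow(groups)
  if (k < 2L) stop("need at least 2 groups")
  n_tot <- sum(groups$n)
  grand <- weightedGrandMean(groups)
  ss_between <- sum(groups$n * (groups$mean - grand)^2)
  ms_between <- ss_between / (k - 1)
  ms_within <- sum((groups$n - 1) * groups$sd^2) / (n_tot - k)
  if (ms_within == 0) {
    if (ss_between == 0) {
      return(list(f = 0, df_between = k - 1L, df_within = n_tot - k, p = 1))
    }
    warning("zero within-group variance with unequal means: p = 0")
    return(list(f = Inf, df_between = k - 1L, df_within = n_tot - k, p = 0))
  }
  f <- ms_between / ms_within
  list(f = f, df_between = k - 1L, df_within = n_tot - k,
       p = pf(f, k - 1, n_tot - k, lower.tail = FALSE))
}

#' Extract a QC analyte's per-batch series from profiles
#'
#' Pulls one analyte's percent series for one QC material, in batch
#' order, from a list of [FameProfile-class] objects (e.g. the output of
#' [quantifyBatch()] over a study).
#'
#' @param profiles list of [FameProfile-class].
#' @param code analyte code.
#' @param material `"qc1"` or `"qc2"`.
#' @return `data.frame` with columns `batch_id`, `value`.
#' @export
qcSeries <- function(profiles, code, material = "qc1") {
  keep <- vapply(profiles, function(p) vialRole(p) == material, logical(1))
  rows <- lapply(profiles[keep], function(p) {
    d <- profileData(p)
    data.frame(batch_id = batchId(p), value = d$percent[d$code == code],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(batch_id = character(0),
                               value = numeric(0)) else out
}

#' Chart a QC analyte across a study
#'
#' Establishes the Shewhart chart from the first `baseline_batches` values
#' of the analyte's QC series and evaluates every point against it.
#' Baseline points are plotted and flagged as baseline rather than
#' excluded.
#'
#' @param profiles list of [FameProfile-class] from quantifying a study.
#' @param code analyte code to chart.
#' @param material `"qc1"` or `"qc2"`.
#' @param baseline_batches number of leading batches forming the baseline
#'   (default 60).
#' @param k sigma multiplier (default 3).
#' @return list with `chart` ([ControlChart-class]) and `points`
#'   (`data.frame` `batch_id`, `value`, `in_control`, `baseline`).
#' @export
chartQcSeries <- function(profiles, code, material = "qc1",
                          baseline_batches = 60, k = 3) {
  series <- qcSeries(profiles, code, material)
  if (nrow(series) < baseline_batches) {
    stop("need at least ", baseline_batches,
         " batches to establish the baseline; got ", nrow(series))
  }
  chart <- establishChart(series$value[seq_len(baseline_batches)], k = k,
                          code = code, material = material)
  pts <- evaluatePoint(chart, series$value, series$batch_id)
  pts$baseline <- seq_len(nrow(pts)) <= baseline_batches
  list(chart = chart, points = pts)
}
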