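#' Per-analyte summaries for one method group
#'
#' Summarises a group of profiles measured by one sample-preparation
#' method (e.g. manual or automated): per-analyte mean, SD and percent CV
#' across the group's profiles. Analytes whose group mean falls below
#' `min_level` (default 0.1% — the "major fatty acid" cut) are marked for
#' exclusion from downstream agreement statistics.
#'
#' @param profiles list of at least 2 [FameProfile-class] on one panel.
#' @param label method label carried through to outputs.
#' @param min_level percent level below which an analyte is excluded
#'   downstream (default 0.1; use 0 for no exclusion).
#' @return `data.frame` with columns `label`, `code`, `n`, `mean`, `sd`,
#'   `cv`, `major` (logical: mean >= min_level).
#' @export
summarizeMethod <- function(profiles, label = "method", min_level = 0.1) {
  if (length(profiles) < 2L) stop("need at least 2 profiles per group")
  mats <- vapply(profiles, percents,
                 numeric(nrow(profileData(profiles[[1]]))))
  codes <- profileData(profiles[[1]])$code
  m <- rowMeans(mats)
  s <- apply(mats, 1, sd)
  data.frame(label = label, code = codes, n = length(profiles),
             mean = unname(m), sd = unname(s),
             cv = ifelse(m > 0, 100 * s / m, NA_real_),
             major = unname(m) >= min_level,
             stringsAsFactors = FALSE)
}

## Pair two method summaries on their shared major analytes.
.pairSummaries <- function(a, b) {
  shared <- intersect(a$code[a$major], b$code[b$major])
  if (!length(shared)) stop("no shared analytes above min_level")
  ai <- a[match(shared, a$code), ]
  bi <- b[match(shared, b$code), ]
  data.frame(code = shared, meanA = ai$mean, sdA = ai$sd,
             meanB = bi$mean, sdB = bi$sd, stringsAsFactors = FALSE)
}

#' Correlation of per-analyte means between two methods
#'
#' Pearson correlation of the paired per-analyte mean percentages of two
#' method groups, over the shared analytes above the `min_level` cut.
#'
#' @param a,b outputs of [summarizeMethod()].
#' @return Pearson r.
#' @examples
#' \dontrun{correlateMeans(summA, summB)}
#' @export
correlateMeans <- function(a, b) {
  p <- .pairSummaries(a, b)
  if (nrow(p) < 3L) stop("need at least 3 shared analytes")
  if (sd(p$meanA) == 0 || sd(p$meanB) == 0) {
    stop("zero variance in a mean vector")
  }
  stats::cor(p$meanA, p$meanB)
}

#' Bland-Altman agreement between two methods
#'
#' Mean difference of the paired per-analyte means and 95% limits of
#' agreement (`mean(d) +/- 1.96 sd(d)` with `d = meanA - meanB`).
#'
#' @param a,b outputs of [summarizeMethod()].
#' @return list with `mean_difference`, `sd_difference`, `lower`, `upper`,
#'   and the per-analyte `differences`.
#' @export
blandAltman <- function(a, b) {
  p <- .pairSummaries(a, b)
  d <- p$meanA - p$meanB
  s <- if (length(d) >= 2L) sd(d) else 0
  list(mean_difference = mean(d), sd_difference = s,
       lower = mean(d) - 1.96 * s, upper = mean(d) + 1.96 * s,
       differences = setNames(d, p$code))
}

#' Per-analyte precision comparison table
#'
#' The plotting table behind a precision scatter (per-method SD against
#' the analyte mean): one row per shared analyte with the two SDs and the
#' sign of their difference.
#'
#' @param a,b outputs of [summarizeMethod()].
#' @return `data.frame` with columns `code`, `mean` (average of the two
#'   method means), `sdA`, `sdB`, `sd_sign` (`sign(sdA - sdB)`).
#' @export
precisionScatter <- function(a, b) {
  p <- .pairSummaries(a, b)
  data.frame(code = p$code, mean = (p$meanA + p$meanB) / 2,
             sdA = p$sdA, sdB = p$sdB, sd_sign = sign(p$sdA - p$sdB),
             stringsAsFactors = FALSE)
}

#' Per-analyte Welch t-tests between two method groups
#'
#' Optional direct per-analyte comparison of the two methods' percent
#' levels: an unequal-variance (Welch) two-sample t-test from the group
#' summaries.
#'
#' @param a,b outputs of [summarizeMethod()].
#' @return `data.frame` with columns `code`, `t`, `df`, `p`.
#' @export
welchFromSummaries <- function(a, b) {
  p <- .pairSummaries(a, b)
  na <- a$n[match(p$code, a$code)]
  nb <- b$n[match(p$code, b$code)]
  se2a <- p$sdA^2 / na
  se2b <- p$sdB^2 / nb
  tstat <- (p$meanA - p$meanB) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  data.frame(code = p$code, t = tstat, df = df,
             p = 2 * pt(abs(tstat), df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Full two-method agreement analysis
#'
#' Convenience wrapper running [summarizeMethod()] on both groups and
#' collecting the correlation of means, Bland-Altman agreement and
#' precision comparison.
#'
#' @param profiles_a,profiles_b lists of [FameProfile-class].
#' @param labels length-2 method labels.
#' @param min_level percent cut for major analytes (default 0.1).
#' @return list with `summaries` (both groups stacked), `pearson_r`,
#'   `bland_altman`, `precision`.
#' @export
compareMethods <- function(profiles_a, profiles_b,
                           labels = c("manual", "automated"),
                           min_level = 0.1) {
  a <- summarizeMethod(profiles_a, labels[1], min_level)
  b <- summarizeMethod(profiles_b, labels[2], min_level)
  list(summaries = rbind(a, b),
       pearson_r = correlateMeans(a, b),
       bland_altman = blandAltman(a, b),
       precision = precisionScatter(a, b))
}
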