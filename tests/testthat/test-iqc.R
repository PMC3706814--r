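test_that("chart limits follow avg +/- k * sample SD", {
  # hand arithmetic: sample SD of {1,2,3} is 1
  ch <- establishChart(c(1, 2, 3), k = 3)
  expect_equal(avgLine(ch), 2)
  expect_equal(ch@sd, 1)
  expect_equal(lcl(ch), -1)
  expect_equal(ucl(ch), 5)
  # limits satisfy (ucl - avg) = k * sd for any k
  for (k in c(0.5, 2, 3.7)) {
    chk <- establishChart(c(4, 5, 7, 9), k = k)
    expect_equal(ucl(chk) - avgLine(chk), k * sd(c(4, 5, 7, 9)))
  }
  # degenerate baseline
  expect_warning(ch0 <- establishChart(c(10, 10, 10)), "zero-variance")
  expect_equal(c(lcl(ch0), ucl(ch0)), c(10, 10))
  expect_error(establishChart(5), "at least 2")
})

test_that("point evaluation is boundary inclusive", {
  ch <- establishChart(c(1, 2, 3), k = 3)
  pts <- evaluatePoint(ch, c(avgLine(ch), ucl(ch), ucl(ch) + 1e-9,
                             lcl(ch), lcl(ch) - 1e-9))
  expect_identical(pts$in_control, c(TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("long-term CV matches hand arithmetic and printed worked examples", {
  r <- longtermCv(c(1, 3))
  expect_equal(r$mean, 2)
  expect_equal(r$sd, sqrt(2))
  expect_equal(r$cv, 100 * sqrt(2) / 2)
  expect_equal(longtermCv(c(5, 5, 5))$cv, 0)
  expect_error(longtermCv(7), "at least 2")
  # printed long-term QC1 palmitic and QC2 stearic acid mean/SD pairs
  expect_equal(round(cvPercent(30.12, 0.43), 2), 1.43)
  expect_equal(round(cvPercent(30.53, 0.31), 2), 1.02)
})

test_that("group summaries recompute from scratch per group", {
  expect_equal(groupSummaries(rep("a", 4), rep(2.5, 4))$sd, 0)
  set.seed(41)
  labels <- sample(c("m1", "m2", "m3"), 60, replace = TRUE)
  values <- rnorm(60, 10, 1)
  g <- groupSummaries(labels, values)
  expect_equal(sum(g$n), 60)
  for (i in seq_len(nrow(g))) {
    x <- values[labels == g$label[i]]
    expect_equal(g$mean[i], mean(x))
    expect_equal(g$sd[i], sd(x))
    expect_equal(g$cv[i], 100 * sd(x) / mean(x))
  }
})

test_that("weighted grand mean and pooled CV equal concatenated-series statistics", {
  g <- data.frame(n = c(3, 5), mean = c(2, 4), sd = c(0.5, 0.25))
  expect_equal(weightedGrandMean(g), (3 * 2 + 5 * 4) / 8)
  expect_equal(weightedGrandMean(data.frame(n = 7, mean = 1.3, sd = 0)), 1.3)
  # exact identity with the raw series whenever groups partition it
  set.seed(42)
  for (i in 1:10) {
    sizes <- sample(2:8, 3)
    raw <- lapply(sizes, function(n) rnorm(n, runif(1, 5, 15), runif(1, 0.1, 2)))
    g <- do.call(rbind, lapply(raw, function(x) {
      data.frame(n = length(x), mean = mean(x), sd = sd(x))
    }))
    all_values <- unlist(raw)
    expect_equal(weightedGrandMean(g), mean(all_values))
    expect_equal(pooledOverallCv(g), longtermCv(all_values)$cv)
  }
  expect_error(pooledOverallCv(data.frame(n = c(1, 5), mean = 1:2, sd = 0:1)))
})

test_that("summary-statistics ANOVA equals raw-data ANOVA on matching data", {
  # all means equal: F = 0, p = 1
  g0 <- data.frame(n = c(4, 4), mean = c(2, 2), sd = c(0.3, 0.4))
  a0 <- anovaFromSummaries(g0)
  expect_equal(a0$f, 0)
  expect_equal(a0$p, 1)
  # two groups: F = t^2 (pooled two-sample t on the same summaries)
  g2 <- data.frame(n = c(6, 8), mean = c(10, 10.8), sd = c(0.9, 1.1))
  a2 <- anovaFromSummaries(g2)
  sp2 <- ((6 - 1) * 0.9^2 + (8 - 1) * 1.1^2) / (6 + 8 - 2)
  tstat <- (10 - 10.8) / sqrt(sp2 * (1 / 6 + 1 / 8))
  expect_equal(a2$f, tstat^2)
  expect_equal(a2$df_between, 1L)
  expect_equal(a2$df_within, 12L)
  # expansion oracle: raw data constructed to match each (n, mean, sd)
  # exactly give the same F via stats::aov
  set.seed(43)
  for (i in 1:5) {
    k <- sample(3:6, 1)
    g <- data.frame(n = sample(5:20, k, replace = TRUE),
                    mean = runif(k, 5, 10), sd = runif(k, 0.2, 1.5))
    raw <- do.call(rbind, lapply(seq_len(k), function(j) {
      data.frame(grp = factor(j), y = expandSummary(g$n[j], g$mean[j], g$sd[j]))
    }))
    fit <- summary(stats::aov(y ~ grp, data = raw))[[1]]
    a <- anovaFromSummaries(g)
    expect_equal(a$f, fit[["F value"]][1], tolerance = 1e-10)
    expect_equal(a$p, fit[["Pr(>F)"]][1], tolerance = 1e-10)
    expect_equal(a$df_between, fit[["Df"]][1])
    expect_equal(a$df_within, fit[["Df"]][2])
  }
})

test_that("ANOVA is invariant to group order and location shifts", {
  g <- qcMonthlySummaries("DHA")
  a <- anovaFromSummaries(g)
  set.seed(44)
  a_perm <- anovaFromSummaries(g[sample(nrow(g)), ])
  expect_equal(a_perm$f, a$f)
  g_shift <- transform(g, mean = mean + 5)
  expect_equal(anovaFromSummaries(g_shift)$f, a$f)
  # degenerate: zero within-variance with unequal means
  expect_warning(
    az <- anovaFromSummaries(data.frame(n = c(3, 3), mean = c(1, 2), sd = 0)),
    "p = 0")
  expect_equal(az$p, 0)
})

test_that("charts recover generator parameters and flag injected shifts", {
  # parameter recovery within 3 standard errors
  x <- simulateQcMeasurements(2.20, 0.09, 500, seed = 45)
  ch <- establishChart(x, code = "C22:6n3", material = "qc1")
  expect_lt(abs(avgLine(ch) - 2.20), 3 * 0.09 / sqrt(500))
  expect_lt(abs(ch@sd - 0.09), 3 * 0.09 / sqrt(2 * 500))
  # an injected level shift of 5 sigma is flagged
  pts <- evaluatePoint(ch, c(2.20, 2.20 + 5 * 0.09))
  expect_identical(pts$in_control, c(TRUE, FALSE))
})

test_that("QC series extraction and charting across a quantified study", {
  study <- simulateStudy(12, 1, simConfig(seed = 46))
  profiles <- unlist(lapply(study, quantifyBatch, panel = defaultPanel()),
                     recursive = FALSE)
  s <- qcSeries(profiles, "C22:6n3", "qc1")
  expect_equal(nrow(s), 12)
  expect_identical(s$batch_id, sprintf("B%04d", 1:12))
  res <- chartQcSeries(profiles, "C22:6n3", "qc1", baseline_batches = 10)
  expect_equal(res$chart@nBaseline, 10L)
  expect_equal(sum(res$points$baseline), 10)
  expect_error(chartQcSeries(profiles, "C22:6n3", "qc1",
                             baseline_batches = 60), "at least 60")
})
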