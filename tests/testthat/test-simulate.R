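test_that("QC series emulation honours mean, SD, determinism and edge cases", {
  # zero-variance series
  expect_equal(simulateQcMeasurements(2.20, 0, 5, seed = 3), rep(2.20, 5))
  # determinism
  a <- simulateQcMeasurements(30.12, 0.43, 100, seed = 9)
  b <- simulateQcMeasurements(30.12, 0.43, 100, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, simulateQcMeasurements(30.12, 0.43, 100, 10)))
  # moment recovery at n = 10000 within 3 standard errors
  x <- simulateQcMeasurements(30.12, 0.43, 10000, seed = 1)
  se_mean <- 0.43 / sqrt(10000)
  se_sd <- 0.43 / sqrt(2 * 10000)
  expect_lt(abs(mean(x) - 30.12), 3 * se_mean)
  expect_lt(abs(sd(x) - 0.43), 3 * se_sd)
  # errors
  expect_error(simulateQcMeasurements(1, 0.1, 0, seed = 1))
  expect_error(simulateQcMeasurements(1, -0.1, 5, seed = 1))
})

test_that("sample peak tables have the configured areas and noise structure", {
  sim0 <- simConfig(seed = 5, rt_jitter_sd = 0, area_noise_cv = 0)
  p <- defaultPanel()
  # single-analyte composition: one peak, full total area, at expected rt
  pt <- simulateSamplePeakTable(c("C16:0" = 100), sim0, "s1", "sample", p)
  expect_equal(nrow(peaks(pt)), 1)
  expect_equal(peaks(pt)$area, 1e6)
  expect_equal(peaks(pt)$rt,
               analytes(p)$expected_rt[analytes(p)$code == "C16:0"])
  # two analytes 60/40: areas in exact ratio 3:2 at zero noise
  pt2 <- simulateSamplePeakTable(c("C16:0" = 60, "C18:0" = 40), sim0, "s2")
  expect_equal(sort(peaks(pt2)$area, decreasing = TRUE),
               c(6e5, 4e5))
  # empirical area CV close to the configured CV (SE of a CV ~ cv/sqrt(2n))
  simn <- simConfig(seed = 6)
  areas <- vapply(seq_len(1000), function(i) {
    peaks(simulateSamplePeakTable(c("C16:0" = 100), simn, "s", "sample", p,
                                  seed = 1000 + i))$area
  }, numeric(1))
  cv_hat <- sd(areas) / mean(areas)
  expect_lt(abs(cv_hat - 0.02), 3 * 0.02 / sqrt(2 * 1000))
  expect_error(simulateSamplePeakTable(numeric(0), sim0, "s"))
  expect_error(simulateSamplePeakTable(c("C16:0" = 0), sim0, "s"))
})

test_that("blank tables carry only the configured trace", {
  sim0 <- simConfig(seed = 5, rt_jitter_sd = 0, area_noise_cv = 0)
  b <- simulateBlankPeakTable(sim0)
  expect_equal(nrow(peaks(b)), 3)     # trace C14:0, C16:0, C18:0
  expect_identical(vialRole(b), "process_blank")
  # all-zero trace: empty table
  sim_none <- simConfig(seed = 5, blank_trace = c("C16:0" = 0))
  expect_equal(nrow(peaks(simulateBlankPeakTable(sim_none))), 0)
  # single trace analyte, zero noise: area = total_area * x / 100
  sim_one <- simConfig(seed = 5, rt_jitter_sd = 0, area_noise_cv = 0,
                       blank_trace = c("C16:0" = 0.2))
  expect_equal(peaks(simulateBlankPeakTable(sim_one))$area, 1e6 * 0.2 / 100)
})

test_that("calibration series areas scale with volume and stock", {
  sim0 <- simConfig(seed = 8, rt_jitter_sd = 0, area_noise_cv = 0)
  des <- calibrationDesign()
  series <- simulateCalibrationSeries(des, sim0)
  expect_length(series, 5)
  # zero noise: per-analyte areas exactly proportional to level volumes
  a16 <- vapply(series, function(lv) {
    pk <- peaks(lv$table)
    rt16 <- analytes(defaultPanel())$expected_rt[
      analytes(defaultPanel())$code == "C16:0"]
    pk$area[which.min(abs(pk$rt - rt16))]
  }, numeric(1))
  expect_equal(a16 / a16[1], des@levelVolumes / des@levelVolumes[1])
  # doubling stock doubles every area at zero noise
  des2 <- calibrationDesign(stock_amount = 200)
  series2 <- simulateCalibrationSeries(des2, sim0)
  for (i in seq_along(series)) {
    expect_equal(peaks(series2[[i]]$table)$area,
                 2 * peaks(series[[i]]$table)$area)
  }
})

test_that("study layout, determinism and drift recovery", {
  sim <- simConfig(seed = 11)
  study <- simulateStudy(1, samples_per_batch = 29, sim = sim)
  expect_length(vials(study[[1]]), 32)    # 29 + blank + QC1 + QC2
  roles <- vapply(vials(study[[1]]), vialRole, character(1))
  expect_equal(as.integer(table(roles)[c("sample", "process_blank", "qc1", "qc2")]),
               c(29L, 1L, 1L, 1L))
  expect_error(simulateStudy(1, samples_per_batch = 30, sim = sim), "<= 29")
  # seed determinism of the whole study
  s1 <- simulateStudy(2, 3, simConfig(seed = 21))
  s2 <- simulateStudy(2, 3, simConfig(seed = 21))
  expect_equal(s1, s2)
  # zero noise + zero drift: QC1 peak tables identical across batches
  sim0 <- simConfig(seed = 12, rt_jitter_sd = 0, area_noise_cv = 0,
                    composition_qc1 = transform(qcComposition("qc1"), sd = 0),
                    composition_qc2 = transform(qcComposition("qc2"), sd = 0))
  st0 <- simulateStudy(3, 1, sim0)
  qc1_tabs <- lapply(st0, function(b) {
    peaks(vials(b)[[which(vapply(vials(b), vialRole, character(1)) == "qc1")]])
  })
  expect_equal(qc1_tabs[[2]], qc1_tabs[[1]])
  expect_equal(qc1_tabs[[3]], qc1_tabs[[1]])
})

test_that("multiplicative drift is recovered by log-linear regression", {
  p <- defaultPanel()
  sim <- simConfig(seed = 13, drift_per_batch = c("C20:2" = 0.001))
  study <- simulateStudy(100, samples_per_batch = 0, sim = sim)
  profiles <- unlist(lapply(study, quantifyBatch, panel = p),
                     recursive = FALSE)
  s <- qcSeries(profiles, "C20:2", "qc1")
  idx <- seq_len(nrow(s)) - 1
  fit <- lm(log(s$value) ~ idx)
  slope <- coef(fit)[["idx"]]
  se <- summary(fit)$coefficients["idx", "Std. Error"]
  expect_lt(abs(slope - log(1.001)), 3 * se)
})
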