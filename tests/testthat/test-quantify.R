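test_that("peaks at their expected retention times map one-to-one", {
  p <- tinyPanel()
  rts <- analytes(p)$expected_rt
  pt <- peakTable("s", "sample",
                  data.frame(rt = rts, area = c(10, 20, 30, 40)))
  res <- assignPeaks(pt, p)
  expect_equal(unname(res$areas[analytes(p)$code]), c(10, 20, 30, 40))
  expect_equal(nrow(res$unassigned), 0)
})

test_that("peaks beyond tolerance stay unassigned; empty tables warn", {
  p <- tinyPanel()
  pt <- peakTable("s", "sample", data.frame(rt = 7.5, area = 99))
  res <- assignPeaks(pt, p, rt_tolerance = 0.1)
  expect_true(all(res$areas == 0))
  expect_equal(nrow(res$unassigned), 1)
  expect_warning(res0 <- assignPeaks(peakTable("s", "sample"), p), "empty")
  expect_true(all(res0$areas == 0))
})

test_that("assignment equals exhaustive minimum-|dRT| matching on small instances", {
  set.seed(17)
  for (trial in 1:40) {
    n_analyte <- sample(2:5, 1)
    n_peak <- sample(1:6, 1)
    expected <- sort(runif(n_analyte, 0, 10))
    observed <- sort(runif(n_peak, 0, 10))
    tol <- runif(1, 0.3, 2)
    got <- assignmentScore(expected, observed, tol)
    want <- bruteMatch(expected, observed, tol)
    expect_equal(got$matches, want$matches,
                 info = sprintf("trial %d (matches)", trial))
    expect_equal(got$cost, want$cost, tolerance = 1e-12,
                 info = sprintf("trial %d (cost)", trial))
  }
})

test_that("contested peaks resolve to the global optimum, ties to the earlier peak", {
  p <- tinyPanel()   # expected rts 5, 10, 15, 16
  # two peaks compete for C18:0 and C18:1n9c; optimal matching pairs in order
  pt <- peakTable("s", "sample",
                  data.frame(rt = c(15.4, 15.7), area = c(1, 2)))
  res <- assignPeaks(pt, p, rt_tolerance = 1)
  expect_equal(unname(res$areas[c("C18:0", "C18:1n9c")]), c(1, 2))
  # a single peak equidistant from two analytes goes to the earlier analyte
  # only if that minimises cost; with one analyte and two equal-cost peaks,
  # the earlier-eluting peak is consumed
  p2 <- buildPanel(c("C16:0", "C18:0"),
                   expected_rt = c("C16:0" = 10, "C18:0" = 20))
  pt2 <- peakTable("s", "sample",
                   data.frame(rt = c(9.9, 10.1), area = c(7, 8)))
  res2 <- assignPeaks(pt2, p2, rt_tolerance = 0.5)
  expect_equal(unname(res2$areas[["C16:0"]]), 7)
})

test_that("assignment is stable under peak permutation and small uniform shifts", {
  p <- defaultPanel()
  sim <- simConfig(seed = 19)
  pt <- simulateSamplePeakTable(setNames(qcComposition("qc1")$mean,
                                         qcComposition("qc1")$code),
                                sim, "s", "sample", p)
  base <- assignPeaks(pt, p)$areas
  # permuting peak rows changes nothing (peakTable re-sorts)
  pk <- peaks(pt)
  set.seed(20)
  pt_perm <- peakTable("s", "sample", pk[sample(nrow(pk)), ])
  expect_equal(assignPeaks(pt_perm, p)$areas, base)
  # uniform rt shift below tolerance/2 changes nothing
  pk_shift <- transform(pk, rt = rt + 0.04)
  pt_shift <- peakTable("s", "sample", pk_shift)
  expect_equal(assignPeaks(pt_shift, p)$areas, base)
})

test_that("co-elution merge sums areas under the reported code and conserves total", {
  p <- defaultPanel()
  codes <- setdiff(analytes(p)$code, c("C4:0", "C6:0"))
  x <- setNames(numeric(length(codes)), codes)
  x[c("C20:3n3", "C20:4n6")] <- c(10, 90)
  merged <- mergeCoeluting(x, p)
  expect_equal(merged[["C20:4n6"]], 100)
  expect_false("C20:3n3" %in% names(merged))
  expect_equal(sum(merged), sum(x))
  # no groups configured: identity
  p0 <- buildPanel(c("C16:0", "C18:0"))
  y <- c("C16:0" = 3, "C18:0" = 4)
  expect_equal(mergeCoeluting(y, p0), y)
  # 3-member group conserves a + b + c
  p3 <- buildPanel(c("C14:0", "C16:0", "C18:0", "C20:0"),
                   coelution_groups = list("C18:0" = c("C14:0", "C16:0", "C18:0")))
  z <- c("C14:0" = 1, "C16:0" = 2, "C18:0" = 4, "C20:0" = 8)
  m3 <- mergeCoeluting(z, p3)
  expect_equal(m3[["C18:0"]], 7)
  expect_equal(sum(m3), sum(z))
})

test_that("blank subtraction clips at zero and never inflates areas", {
  expect_equal(subtractBlank(c("C16:0" = 1000), c("C16:0" = 50)),
               c("C16:0" = 950))
  s <- c("C14:0" = 5, "C16:0" = 100)
  expect_equal(subtractBlank(s, numeric(0)), s)          # no blank: identity
  expect_equal(subtractBlank(c("C14:0" = 5), c("C14:0" = 9)),
               c("C14:0" = 0))                           # clipped, not negative
  set.seed(21)
  for (i in 1:20) {
    smp <- setNames(runif(6, 0, 100), letters[1:6])
    blk <- setNames(runif(6, 0, 50), letters[1:6])
    corr <- subtractBlank(smp, blk)
    expect_true(all(corr >= 0))
    expect_lte(sum(corr), sum(smp))
  }
})

test_that("percent closure and scale invariance", {
  expect_equal(computePercent(c(A = 50, B = 30, C = 20)),
               c(A = 50, B = 30, C = 20))
  expect_equal(computePercent(c(X = 7)), c(X = 100))
  expect_error(computePercent(c(A = 0, B = 0)), "all-zero")
  set.seed(22)
  for (i in 1:20) {
    v <- setNames(runif(8, 0.01, 10), LETTERS[1:8])
    k <- runif(1, 1e-6, 1e6)
    expect_equal(computePercent(v * k), computePercent(v))
    expect_equal(sum(computePercent(v)), 100, tolerance = 1e-12)
  }
})

test_that("BLOQ flagging is strict at the 0.15% threshold", {
  f <- flagBloq(c(a = 0.149, b = 0.15, c = 30.12), 0.15)
  expect_identical(unname(f), c(TRUE, FALSE, FALSE))
  expect_error(flagBloq(c(a = 1), 0))
})

test_that("batch quantification consumes the blank and matches manual composition", {
  p <- defaultPanel()
  sim <- simConfig(seed = 23)
  study <- simulateStudy(1, samples_per_batch = 29, sim = sim)
  profs <- quantifyBatch(study[[1]], p)
  expect_length(profs, 31)                 # 32 vials minus the blank
  expect_setequal(vapply(profs, vialRole, character(1)),
                  c("sample", "qc1", "qc2"))
  # pipeline equivalence: composing the four operations manually
  batch <- study[[1]]
  roles <- vapply(vials(batch), vialRole, character(1))
  blank_tab <- vials(batch)[[which(roles == "process_blank")]]
  blank_areas <- mergeCoeluting(assignPeaks(blank_tab, p)$areas, p)
  v1 <- vials(batch)[[1]]
  manual_corr <- subtractBlank(
    mergeCoeluting(assignPeaks(v1, p)$areas, p), blank_areas)
  manual_pct <- computePercent(manual_corr)
  auto <- profs[[1]]
  expect_equal(percents(auto), manual_pct[names(percents(auto))])
  expect_equal(profileData(auto)$bloq,
               unname(flagBloq(manual_pct, 0.15)[profileData(auto)$code]))
  # blank errors
  no_blank <- new("FameBatch", batchId = "X",
                  vials = vials(batch)[roles != "process_blank"])
  expect_error(quantifyBatch(no_blank, p), "no process blank")
  two_blank <- new("FameBatch", batchId = "Y",
                   vials = c(vials(batch), blank_tab))
  expect_error(quantifyBatch(two_blank, p), "2 process blanks")
})

test_that("profiles close to 100 percent and blank-corrected areas stay bounded", {
  p <- defaultPanel()
  study <- simulateStudy(2, 3, simConfig(seed = 29))
  for (b in study) {
    for (prof in quantifyBatch(b, p)) {
      d <- profileData(prof)
      expect_equal(sum(d$percent), 100, tolerance = 1e-9)
      expect_true(all(d$percent >= 0))
      expect_true(all(d$corrected_area <= d$assigned_area + 1e-12))
    }
  }
})
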