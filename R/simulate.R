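#' Simulation configuration for the synthetic peak-table generator
#'
#' Bundles every knob of the generator: retention-time jitter,
#' multiplicative detector noise, the nominal total signal of an
#' injection, optional slow multiplicative between-batch drift, the trace
#' contamination carried by the process blank (and, as true contamination,
#' by every vial), and the compositions of the two QC materials.
#'
#' @param seed integer seed; every random draw of the generator is a pure
#'   function of the configuration and this seed.
#' @param rt_jitter_sd SD of Gaussian retention-time jitter in minutes
#'   (default 0.02).
#' @param area_noise_cv CV of multiplicative Gaussian detector noise on
#'   areas (default 0.02).
#' @param total_area total fatty acid signal of a nominal injection
#'   (default 1e6 signal units).
#' @param drift_per_batch fractional multiplicative drift per batch:
#'   either a single number applied to every analyte or a named vector
#'   per analyte code (default 0, no drift).
#' @param blank_trace named numeric of percent-equivalent trace areas in
#'   the process blank; default trace C14:0/C16:0/C18:0.
#' @param composition_qc1,composition_qc2 `data.frame`s (`code`, `mean`,
#'   `sd`, percent) for the QC materials; defaults from
#'   [qcComposition()].
#' @return A validated [SimConfig-class].
#' @examples
#' sim <- simConfig(seed = 1)
#' @export
simConfig <- function(seed = 1L,
                      rt_jitter_sd = 0.02,
                      area_noise_cv = 0.02,
                      total_area = 1e6,
                      drift_per_batch = 0,
                      blank_trace = c("C14:0" = 0.02, "C16:0" = 0.10,
                                      "C18:0" = 0.05),
                      composition_qc1 = qcComposition("qc1"),
                      composition_qc2 = qcComposition("qc2")) {
  new("SimConfig", seed = as.integer(seed), rtJitterSd = rt_jitter_sd,
      areaNoiseCv = area_noise_cv, totalArea = total_area,
      driftPerBatch = drift_per_batch, blankTrace = blank_trace,
      compositionQc1 = composition_qc1, compositionQc2 = composition_qc2)
}

#' Simulate a long-term QC measurement series for one analyte
#'
#' Draws `n` independent measurements from a normal law with the given
#' mean and SD (percent of total signal), floored at zero — a direct
#' emulation of one analyte's measured level in a QC material across many
#' batches. Identical arguments yield identical series.
#'
#' @param mean,sd percent-scale mean and SD (`sd >= 0`).
#' @param n number of batches (>= 1).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @examples
#' x <- simulateQcMeasurements(30.12, 0.43, n = 860, seed = 1)
#' longtermCv(x)
#' @export
simulateQcMeasurements <- function(mean, sd, n, seed) {
  if (n < 1L) stop("n must be >= 1")
  if (sd < 0) stop("sd must be >= 0")
  .withSeed(seed, pmax(rnorm(n, mean, sd), 0))
}

## Run expr under a local RNG state seeded with `seed`; NULL seed draws
## from the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Generate one vial's peak table from a named percent vector. Trace
## contamination (percent-equivalent) is added on the area scale when
## `trace` is non-empty. Draws from the current RNG stream unless `seed`
## is given.
.drawPeakTable <- function(percent, sim, sample_id, role, panel,
                           batch_id = NA_character_,
                           trace = numeric(0), seed = NULL) {
  .withSeed(seed, {
    percent <- percent[percent > 0]
    if (!length(percent) && !length(trace)) {
      return(peakTable(sample_id, role, batch_id = batch_id))
    }
    codes <- union(names(percent), names(trace[trace > 0]))
    base <- setNames(numeric(length(codes)), codes)
    base[names(percent)] <- percent
    contam <- setNames(numeric(length(codes)), codes)
    tr <- trace[trace > 0]
    contam[names(tr)] <- tr
    a <- analytes(panel)
    rt <- setNames(a$expected_rt, a$code)
    missing <- setdiff(codes, names(rt))
    if (length(missing)) {
      stop("no expected retention time for: ", paste(missing, collapse = ", "))
    }
    n <- length(codes)
    noise1 <- 1 + rnorm(n, 0, sim@areaNoiseCv)
    noise2 <- 1 + rnorm(n, 0, sim@areaNoiseCv)
    area <- pmax(sim@totalArea * (base / 100) * noise1, 0) +
      pmax(sim@totalArea * (contam / 100) * noise2, 0)
    jitter <- rnorm(n, 0, sim@rtJitterSd)
    peaks <- data.frame(rt = unname(rt[codes]) + jitter,
                        area = unname(area),
                        height = unname(area) / 10)
    peaks <- peaks[peaks$area > 0 | (base + contam) > 0, , drop = FALSE]
    peakTable(sample_id, role, peaks, batch_id = batch_id)
  })
}

#' Simulate a sample peak table from a known composition
#'
#' Generates one peak per composed analyte at its expected retention time
#' plus Gaussian jitter, with area
#' `total_area * percent/100 * (1 + noise)` floored at zero, where the
#' noise is Gaussian with CV `area_noise_cv`.
#'
#' @param composition named numeric of percents (>= 0, sum > 0); names
#'   are analyte codes present in `panel`.
#' @param sim a [SimConfig-class].
#' @param sample_id,role vial identity (role from [vialRoles()]).
#' @param panel a [FamePanel-class] providing expected retention times.
#' @param batch_id optional batch identifier.
#' @param seed optional seed; `NULL` (default) draws from the current
#'   RNG stream so callers can compose reproducible studies.
#' @return A [PeakTable-class] with peaks sorted by retention time.
#' @examples
#' sim <- simConfig(seed = 1, rt_jitter_sd = 0, area_noise_cv = 0)
#' pt <- simulateSamplePeakTable(c("C16:0" = 100), sim, "s1", "sample")
#' peaks(pt)$area  # exactly total_area
#' @export
simulateSamplePeakTable <- function(composition, sim, sample_id,
                                    role = "sample",
                                    panel = defaultPanel(),
                                    batch_id = NA_character_,
                                    seed = sim@seed) {
  if (!length(composition) || sum(composition) <= 0) {
    stop("composition must contain at least one positive percent")
  }
  if (any(composition < 0)) stop("composition percents must be >= 0")
  .drawPeakTable(composition, sim, sample_id, role, panel, batch_id,
                 seed = seed)
}

#' Simulate a process-blank peak table
#'
#' The blank carries only the configured trace contamination (default
#' trace C14:0, C16:0 and C18:0); an all-zero trace yields an empty peak
#' table.
#'
#' @inheritParams simulateSamplePeakTable
#' @return A [PeakTable-class] with role `"process_blank"`.
#' @examples
#' sim <- simConfig(seed = 1, rt_jitter_sd = 0, area_noise_cv = 0)
#' nrow(peaks(simulateBlankPeakTable(sim)))  # 3 trace peaks
#' @export
simulateBlankPeakTable <- function(sim, sample_id = "blank",
                                   panel = defaultPanel(),
                                   batch_id = NA_character_,
                                   seed = sim@seed) {
  .drawPeakTable(setNames(numeric(0), character(0)), sim, sample_id,
                 "process_blank", panel, batch_id,
                 trace = sim@blankTrace, seed = seed)
}

#' The default 5-level calibration design
#'
#' Relative volumes 0.01, 0.05, 0.1, 0.5 and 1.0 of the working standard
#' per level, with a configurable per-analyte stock amount (ng per unit
#' relative volume; default 100 ng for every quantifiable analyte of the
#' panel).
#'
#' @param level_volumes strictly increasing relative volumes.
#' @param stock_amount named ng-per-unit-volume vector, or a single
#'   number recycled over the panel's quantifiable analytes.
#' @param panel panel supplying the analyte codes when `stock_amount` is
#'   scalar.
#' @return A [CalibrationDesign-class].
#' @export
calibrationDesign <- function(level_volumes = c(0.01, 0.05, 0.1, 0.5, 1.0),
                              stock_amount = 100,
                              panel = defaultPanel()) {
  if (is.null(names(stock_amount))) {
    codes <- quantifiableCodes(panel)
    stock_amount <- setNames(rep_len(stock_amount, length(codes)), codes)
  }
  new("CalibrationDesign", levelVolumes = level_volumes,
      stockAmount = stock_amount)
}

#' Simulate a multi-level calibration series
#'
#' For each level volume `v`, every analyte's nominal on-column amount is
#' `v * stock_amount[code]` and its peak area is
#' `detector_response * amount * (1 + noise)`, so areas are exactly
#' proportional to volume at zero noise.
#'
#' @param design a [CalibrationDesign-class].
#' @param sim a [SimConfig-class] (supplies noise, jitter and seed).
#' @param panel a [FamePanel-class].
#' @param detector_response signal units per ng (default 1000).
#' @return list with one element per level: `list(level =, amount_ng =
#'   named vector, table = PeakTable)`.
#' @examples
#' series <- simulateCalibrationSeries(calibrationDesign(),
#'                                     simConfig(seed = 1))
#' length(series)  # 5 levels
#' @export
simulateCalibrationSeries <- function(design, sim, panel = defaultPanel(),
                                      detector_response = 1000) {
  validObject(design)
  .withSeed(sim@seed, {
    lapply(seq_along(design@levelVolumes), function(i) {
      v <- design@levelVolumes[i]
      amount <- design@stockAmount * v
      n <- length(amount)
      noise <- 1 + rnorm(n, 0, sim@areaNoiseCv)
      area <- pmax(detector_response * amount * noise, 0)
      a <- analytes(panel)
      rt <- setNames(a$expected_rt, a$code)[names(amount)]
      if (anyNA(rt)) {
        stop("stock amounts name analytes missing from the panel")
      }
      peaks <- data.frame(
        rt = unname(rt) + rnorm(n, 0, sim@rtJitterSd),
        area = unname(area), height = unname(area) / 10)
      list(level = v, amount_ng = amount,
           table = peakTable(sprintf("cal_L%d", i), "calibration_standard",
                             peaks))
    })
  })
}

#' Simulate a multi-batch study
#'
#' Emulates routine operation: each batch holds `samples_per_batch` sample
#' vials (plasma-like compositions drawn per vial from the QC1 material's
#' per-analyte normal law) plus one process blank, one QC1 and one QC2
#' vial. The QC vial compositions are redrawn per batch from their
#' material's mean/SD. Per-analyte multiplicative drift
#' `(1 + drift_per_batch)^batch_index` (index starting at 0) is applied to
#' the generated signal, and every vial carries the blank's trace
#' contamination, which the quantification stage removes again via
#' per-batch blank subtraction. The whole study is a pure function of
#' `(sim, n_batches, samples_per_batch)`.
#'
#' @param n_batches number of batches (>= 1).
#' @param samples_per_batch sample vials per batch, at most 29.
#' @param sim a [SimConfig-class].
#' @param panel a [FamePanel-class].
#' @return list of [FameBatch-class] with sequential ids `B0001`, ...
#' @examples
#' study <- simulateStudy(2, samples_per_batch = 3, sim = simConfig(seed = 7))
#' length(vials(study[[1]]))  # 3 + blank + QC1 + QC2
#' @export
simulateStudy <- function(n_batches, samples_per_batch = 29,
                          sim = simConfig(), panel = defaultPanel()) {
  if (n_batches < 1L) stop("n_batches must be >= 1")
  if (samples_per_batch > 29L) {
    stop("samples_per_batch must be <= 29 (32-vial batch layout)")
  }
  qc1 <- sim@compositionQc1
  qc2 <- sim@compositionQc2
  .withSeed(sim@seed, {
    lapply(seq_len(n_batches), function(b) {
      bid <- sprintf("B%04d", b)
      drift <- .driftFactor(sim@driftPerBatch, b - 1L,
                            union(qc1$code, qc2$code))
      draw_comp <- function(comp) {
        x <- pmax(rnorm(nrow(comp), comp$mean, comp$sd), 0)
        setNames(x, comp$code) * drift[comp$code]
      }
      vial_list <- vector("list", samples_per_batch + 3L)
      for (i in seq_len(samples_per_batch)) {
        vial_list[[i]] <- .drawPeakTable(
          draw_comp(qc1), sim, sprintf("%s_S%02d", bid, i), "sample",
          panel, bid, trace = sim@blankTrace)
      }
      vial_list[[samples_per_batch + 1L]] <- .drawPeakTable(
        setNames(numeric(0), character(0)), sim,
        sprintf("%s_blank", bid), "process_blank", panel, bid,
        trace = sim@blankTrace)
      vial_list[[samples_per_batch + 2L]] <- .drawPeakTable(
        draw_comp(qc1), sim, sprintf("%s_QC1", bid), "qc1", panel, bid,
        trace = sim@blankTrace)
      vial_list[[samples_per_batch + 3L]] <- .drawPeakTable(
        draw_comp(qc2), sim, sprintf("%s_QC2", bid), "qc2", panel, bid,
        trace = sim@blankTrace)
      new("FameBatch", batchId = bid, vials = vial_list)
    })
  })
}

## Per-analyte multiplicative drift factor at a 0-based batch index.
.driftFactor <- function(drift, batch_index, codes) {
  f <- setNames(rep(1, length(codes)), codes)
  if (is.null(names(drift))) {
    f[] <- (1 + drift[1]) ^ batch_index
  } else {
    known <- intersect(names(drift), codes)
    f[known] <- (1 + drift[known]) ^ batch_index
  }
  f
}
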