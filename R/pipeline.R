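#' Run the full analysis pipeline
#'
#' Drives simulate -> quantify -> internal QC (and optionally calibration
#' and method comparison) end to end and writes every artifact as CSV:
#' peak tables, batch manifest, profiles, chart definitions, per-batch
#' chart points, monthly-style group summaries with the summary-statistics
#' ANOVA, and a JSON run manifest recording the configuration, seed and
#' package version. Output is a pure function of the configuration, so an
#' identical config and seed reproduces identical files.
#'
#' @param out_dir output directory (created if missing).
#' @param n_batches,samples_per_batch study size (defaults 100 batches of
#'   29 samples).
#' @param sim a [SimConfig-class]; its seed controls the whole run.
#' @param panel a [FamePanel-class].
#' @param chart_codes analyte codes to chart (default DHA and EPA).
#' @param material QC material to chart (default `"qc1"`).
#' @param baseline_batches leading batches used as the chart baseline
#'   (default 60).
#' @param k_sigma Shewhart sigma multiplier (default 3).
#' @param rt_tolerance retention-time matching tolerance, minutes.
#' @param batches_per_group group size for the stability summaries
#'   (default 38, a month of batches).
#' @param with_calibration also run the 5-level calibration diagnostics
#'   (default TRUE).
#' @param verbose print per-stage progress (default TRUE).
#' @return Invisibly, a list with `profiles`, `charts`, `summaries`,
#'   `anova`, `calibration` and the vector of files written.
#' @examples
#' \donttest{
#' res <- runPipeline(tempfile("famerun"), n_batches = 65,
#'                    samples_per_batch = 2, sim = simConfig(seed = 1),
#'                    verbose = FALSE)
#' names(res)
#' }
#' @export
runPipeline <- function(out_dir,
                        n_batches = 100, samples_per_batch = 29,
                        sim = simConfig(), panel = defaultPanel(),
                        chart_codes = c("C22:6n3", "C20:5n3"),
                        material = "qc1",
                        baseline_batches = 60, k_sigma = 3,
                        rt_tolerance = 0.1,
                        batches_per_group = 38,
                        with_calibration = TRUE,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    tmp <- paste0(p, ".tmp")
    writer(tmp)
    file.rename(tmp, p)
    files <<- c(files, p)
    p
  }

  say("simulate: ", n_batches, " batches x ", samples_per_batch + 3,
      " vials (seed ", sim@seed, ")")
  study <- simulateStudy(n_batches, samples_per_batch, sim, panel)
  emit("peaks.csv", function(p) writePeakTables(study, p))
  emit("manifest.csv", function(p) writeManifest(study, p))
  emit("panel.yaml", function(p) writePanelConfig(panel, p))

  say("quantify: per-batch blank subtraction, BLOQ threshold ",
      bloqThreshold(panel), "%")
  profiles <- unlist(lapply(study, quantifyBatch, panel = panel,
                            rt_tolerance = rt_tolerance),
                     recursive = FALSE)
  emit("profiles.csv", function(p) writeProfiles(profiles, p))
  n_bloq <- sum(vapply(profiles, function(p) sum(profileData(p)$bloq),
                       integer(1)))
  say("quantify: ", length(profiles), " profiles, ", n_bloq,
      " BLOQ analyte measurements")

  say("qc: Shewhart charts (baseline ", baseline_batches, " batches, k = ",
      k_sigma, ")")
  charts <- lapply(chart_codes, function(code) {
    chartQcSeries(profiles, code, material, baseline_batches, k_sigma)
  })
  names(charts) <- chart_codes
  emit("charts.csv", function(p) {
    write.csv(do.call(rbind, lapply(charts, function(ch) {
      data.frame(code = ch$chart@code, material = ch$chart@material,
                 avg = ch$chart@avg, sd = ch$chart@sd, k = ch$chart@k,
                 lcl = lcl(ch$chart), ucl = ucl(ch$chart),
                 n_baseline = ch$chart@nBaseline)
    })), p, row.names = FALSE, quote = FALSE)
  })
  emit("chart_points.csv", function(p) {
    write.csv(do.call(rbind, lapply(names(charts), function(code) {
      cbind(code = code, charts[[code]]$points)
    })), p, row.names = FALSE, quote = FALSE)
  })
  out_of_control <- vapply(charts, function(ch) {
    sum(!ch$points$in_control[!ch$points$baseline])
  }, numeric(1))
  say("qc: out-of-control points per chart: ",
      paste(names(charts), out_of_control, sep = "=", collapse = ", "))

  summaries <- lapply(chart_codes, function(code) {
    s <- qcSeries(profiles, code, material)
    grp <- ceiling(seq_len(nrow(s)) / batches_per_group)
    g <- groupSummaries(sprintf("group%02d", grp), s$value)
    g$code <- code
    g
  })
  summaries <- do.call(rbind, summaries)
  emit("group_summaries.csv", function(p) {
    write.csv(summaries, p, row.names = FALSE, quote = FALSE)
  })
  anova_rows <- do.call(rbind, lapply(chart_codes, function(code) {
    g <- summaries[summaries$code == code & summaries$n >= 2, ]
    a <- anovaFromSummaries(g)
    data.frame(code = code, f = a$f, df_between = a$df_between,
               df_within = a$df_within, p = a$p,
               grand_mean = weightedGrandMean(g),
               overall_cv = pooledOverallCv(g))
  }))
  emit("anova.csv", function(p) {
    write.csv(anova_rows, p, row.names = FALSE, quote = FALSE)
  })

  calib <- NULL
  if (with_calibration) {
    say("calibrate: 5-level series, per-analyte linearity and LOD")
    series <- simulateCalibrationSeries(calibrationDesign(panel = panel),
                                        sim, panel)
    calib <- calibrateSeries(series, panel, rt_tolerance)
    emit("calibration.csv", function(p) {
      write.csv(calib, p, row.names = FALSE, quote = FALSE)
    })
  }

  emit("run_manifest.json", function(p) {
    jsonlite::write_json(list(
      package = "fameqc",
      version = as.character(utils::packageVersion("fameqc")),
      seed = sim@seed,
      n_batches = n_batches, samples_per_batch = samples_per_batch,
      rt_tolerance = rt_tolerance, k_sigma = k_sigma,
      baseline_batches = baseline_batches,
      bloq_threshold = bloqThreshold(panel),
      area_noise_cv = sim@areaNoiseCv, rt_jitter_sd = sim@rtJitterSd,
      files = basename(files)
    ), p, auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(list(profiles = profiles, charts = charts,
                 summaries = summaries, anova = anova_rows,
                 calibration = calib, files = files))
}
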