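#' Fit calibration linearity for one analyte
#'
#' Ordinary least-squares fit of peak area against on-column amount over
#' the calibration levels, with `R^2 = 1 - SS_res/SS_tot`.
#'
#' @param levels `data.frame` (or list) with columns/elements `amount`
#'   (ng) and `area`; at least 3 distinct amounts.
#' @return list with `slope` (signal units per ng), `intercept`,
#'   `r_squared`, `n_levels`, and `residual_sd`.
#' @examples
#' fitLinearity(data.frame(amount = 1:5, area = 2 * (1:5)))
#' @export
fitLinearity <- function(levels) {
  amount <- levels$amount
  area <- levels$area
  if (length(unique(amount)) < 3L) {
    stop("need at least 3 distinct calibration amounts")
  }
  fit <- lm(area ~ amount)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((area - mean(area))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n_levels = length(amount),
       residual_sd = sqrt(ss_res / max(length(amount) - 2, 1)))
}

#' Limit of detection from signal-to-noise
#'
#' `LOD = snr * noise_sd / slope`: the on-column amount whose expected
#' signal equals `snr` times the baseline noise, with the conventional
#' 3:1 signal-to-noise criterion as default.
#'
#' @param noise_sd baseline noise SD in signal units (>= 0).
#' @param slope calibration slope in signal units per ng (> 0).
#' @param snr signal-to-noise ratio defining detection (default 3).
#' @return LOD in ng.
#' @examples
#' estimateLod(noise_sd = 1, slope = 1)  # 3 ng
#' @export
estimateLod <- function(noise_sd, slope, snr = 3) {
  if (slope <= 0) stop("slope must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  snr * noise_sd / slope
}

#' Sample-preparation volumetrics for LOQ scaling
#'
#' @param plasma_volume plasma aliquot, microlitres (default 250).
#' @param injection_volume GC injection, microlitres (default 1).
#' @param reconstitution_volume final hexane reconstitution, microlitres
#'   (default 100).
#' @param folch_transfer_fraction fraction of the chloroform layer
#'   recovered after lipid extraction (default 0.8 = 1600/2000).
#' @param hexane_transfer_fraction fraction of the hexane layer recovered
#'   after derivatization (default 0.6 = 600/1000).
#' @param split_ratio split injection ratio (default 20 for 20:1); the
#'   on-column fraction is `1/(split_ratio + 1)`.
#' @return A [LoqContext-class].
#' @export
loqContext <- function(plasma_volume = 250, injection_volume = 1,
                       reconstitution_volume = 100,
                       folch_transfer_fraction = 0.8,
                       hexane_transfer_fraction = 0.6,
                       split_ratio = 20) {
  new("LoqContext", plasmaVolume = plasma_volume,
      injectionVolume = injection_volume,
      reconstitutionVolume = reconstitution_volume,
      folchTransferFraction = folch_transfer_fraction,
      hexaneTransferFraction = hexane_transfer_fraction,
      splitOnColumnFraction = 1 / (split_ratio + 1))
}

#' Convert an on-column detection limit to a plasma-volume LOQ
#'
#' Scales an on-column LOD (ng) to the equivalent plasma concentration by
#' the volume of plasma effectively represented on the column:
#' `plasma_volume * folch_fraction * hexane_fraction *
#' (injection/reconstitution) * split_on_column_fraction` microlitres.
#' Doubling the injection volume therefore exactly compensates for halving
#' the plasma volume.
#'
#' @param lod_ng on-column limit, ng.
#' @param ctx a [LoqContext-class].
#' @return concentration limit in ng per microlitre of plasma.
#' @examples
#' lodToPlasmaLoq(1, loqContext(plasma_volume = 250, injection_volume = 1))
#' @export
lodToPlasmaLoq <- function(lod_ng, ctx) {
  validObject(ctx)
  equiv <- ctx@plasmaVolume * ctx@folchTransferFraction *
    ctx@hexaneTransferFraction *
    (ctx@injectionVolume / ctx@reconstitutionVolume) *
    ctx@splitOnColumnFraction
  if (equiv <= 0) stop("on-column plasma equivalent is zero")
  lod_ng / equiv
}

#' Spike recovery over replicates
#'
#' Per replicate, `recovery% = 100 * (measured_spiked - measured_unspiked)
#' / spike_amount`; summarised as mean recovery and percent CV. Arguments
#' must share one unit (the operation is unit-agnostic).
#'
#' @param measured_spiked,measured_unspiked numeric vectors (recycled to
#'   a common length) of measured amounts with and without the spike.
#' @param spike_amount the known spiked amount (> 0).
#' @return list with `code`-free fields: `recoveries` (%), `mean_recovery`,
#'   `cv` (percent CV over replicates, `NA` for a single replicate).
#' @examples
#' computeRecovery(c(125, 130, 128), 100, 30)
#' @export
computeRecovery <- function(measured_spiked, measured_unspiked,
                            spike_amount) {
  if (spike_amount <= 0) stop("spike_amount must be > 0")
  k <- max(length(measured_spiked), length(measured_unspiked))
  ms <- rep_len(measured_spiked, k)
  mu <- rep_len(measured_unspiked, k)
  rec <- 100 * (ms - mu) / spike_amount
  m <- mean(rec)
  list(recoveries = rec, mean_recovery = m,
       cv = if (k >= 2 && m != 0) 100 * sd(rec) / m else NA_real_)
}

#' Calibration diagnostics for a whole series
#'
#' Fits per-analyte linearity across the levels of a (simulated or
#' measured) calibration series, and derives an on-column LOD per analyte
#' from the fit's residual SD at the lowest level (the package's default
#' noise proxy) plus the plasma LOQ under two volumetric contexts: 250 ul
#' plasma / 1 ul injection (routine) and 125 ul / 2 ul (repeats). The two
#' are equal by construction.
#'
#' @param series output of [simulateCalibrationSeries()], or any list of
#'   `list(level =, amount_ng = named vector, table = PeakTable)`.
#' @param panel a [FamePanel-class].
#' @param rt_tolerance retention-time matching tolerance, minutes.
#' @param snr signal-to-noise criterion for the LOD (default 3).
#' @return `data.frame` per analyte: `code`, `slope`, `intercept`,
#'   `r_squared`, `lod_ng`, `loq_250ul_1ul`, `loq_125ul_2ul`
#'   (ng per microlitre plasma).
#' @examples
#' series <- simulateCalibrationSeries(calibrationDesign(),
#'                                     simConfig(seed = 1))
#' fits <- calibrateSeries(series)
#' min(fits$r_squared)
#' @export
calibrateSeries <- function(series, panel = defaultPanel(),
                            rt_tolerance = 0.1, snr = 3) {
  per_level <- lapply(series, function(lv) {
    assigned <- assignPeaks(lv$table, panel, rt_tolerance)$areas
    merged <- mergeCoeluting(assigned, panel)
    list(amount = lv$amount_ng, area = merged)
  })
  codes <- quantifiableCodes(panel)
  codes <- codes[codes %in% names(per_level[[1]]$amount)]
  ctx_routine <- loqContext(plasma_volume = 250, injection_volume = 1)
  ctx_repeat <- loqContext(plasma_volume = 125, injection_volume = 2)
  rows <- lapply(codes, function(code) {
    amount <- vapply(per_level, function(lv) lv$amount[[code]], numeric(1))
    area <- vapply(per_level, function(lv) lv$area[[code]], numeric(1))
    fit <- fitLinearity(data.frame(amount = amount, area = area))
    lod <- if (fit$slope > 0) {
      estimateLod(fit$residual_sd, fit$slope, snr)
    } else NA_real_
    data.frame(code = code, slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, lod_ng = lod,
               loq_250ul_1ul = if (is.na(lod)) NA_real_ else
                 lodToPlasmaLoq(lod, ctx_routine),
               loq_125ul_2ul = if (is.na(lod)) NA_real_ else
                 lodToPlasmaLoq(lod, ctx_repeat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @importFrom stats residuals
NULL
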