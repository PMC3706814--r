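#' @import methods
#' @importFrom stats rnorm sd var lm coef pf pt qt cor residuals setNames
#' @importFrom utils read.csv write.csv head
NULL

## Closed set of vial roles used throughout the pipeline.
.VIAL_ROLES <- c("sample", "process_blank", "qc1", "qc2", "calibration_standard")

#' Vial roles recognised by the pipeline
#'
#' @return Character vector of the closed set of roles a vial (peak table)
#'   may carry: `"sample"`, `"process_blank"`, `"qc1"`, `"qc2"`,
#'   `"calibration_standard"`.
#' @export
vialRoles <- function() .VIAL_ROLES

#' FamePanel: the FAME quantification panel
#'
#' An S4 class describing the analyte panel of a fatty acid methyl ester
#' (FAME) assay: the retention ladder, the reference analyte, analytes
#' excluded from quantification (e.g. lost under the solvent peak), and
#' co-elution groups that are reported under a single code.
#'
#' @slot analytes `data.frame` with columns `code`, `common_name`,
#'   `expected_rt` (minutes), `source` (`"mix37"` or `"added"`), `notes`;
#'   ordered by `expected_rt`.
#' @slot referenceCode code of the reference analyte (default `"C16:0"`).
#' @slot excludedCodes codes excluded from the quantifiable list.
#' @slot coelutionGroups named list; each element is a character vector of
#'   member codes, the element name is the single reported code.
#' @slot bloqThreshold percent of total signal below which a measurement is
#'   flagged below the limit of quantification (default 0.15).
#'
#' @seealso [buildPanel()], [defaultPanel()], [quantifiableCodes()]
#' @export
setClass("FamePanel",
  slots = c(
    analytes = "data.frame",
    referenceCode = "character",
    excludedCodes = "character",
    coelutionGroups = "list",
    bloqThreshold = "numeric"
  )
)

setValidity("FamePanel", function(object) {
  a <- object@analytes
  msgs <- character()
  need <- c("code", "common_name", "expected_rt", "source", "notes")
  if (!all(need %in% names(a))) {
    return(paste("analytes must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(a$code)) msgs <- c(msgs, "analyte codes must be unique")
  if (any(!is.na(a$expected_rt) & a$expected_rt <= 0)) {
    msgs <- c(msgs, "expected_rt must be strictly positive")
  }
  rts <- a$expected_rt[!is.na(a$expected_rt)]
  if (length(rts) > 1L && any(diff(rts) <= 0)) {
    msgs <- c(msgs, "expected_rt must be strictly increasing along the panel")
  }
  if (length(object@referenceCode) != 1L ||
      !(object@referenceCode %in% a$code)) {
    msgs <- c(msgs, "referenceCode must name one analyte in the panel")
  }
  if (object@referenceCode %in% object@excludedCodes) {
    msgs <- c(msgs, "the reference analyte cannot be excluded")
  }
  if (!all(object@excludedCodes %in% a$code)) {
    msgs <- c(msgs, "excluded codes must be panel analytes")
  }
  for (rep_code in names(object@coelutionGroups)) {
    members <- object@coelutionGroups[[rep_code]]
    if (!(rep_code %in% members)) {
      msgs <- c(msgs, sprintf(
        "co-elution group '%s' must report one of its member codes", rep_code))
    }
    if (!all(members %in% setdiff(a$code, object@excludedCodes))) {
      msgs <- c(msgs, sprintf(
        "co-elution members of '%s' must be non-excluded panel analytes",
        rep_code))
    }
  }
  if (length(object@bloqThreshold) != 1L || object@bloqThreshold <= 0) {
    msgs <- c(msgs, "bloqThreshold must be a single positive percent")
  }
  if (length(msgs)) msgs else TRUE
})

#' PeakTable: an integrated chromatogram for one vial
#'
#' Holds the integrated peaks (retention time, area, height) of a single
#' GC-FID injection together with the vial's identity and role in the batch.
#'
#' @slot sampleId sample identifier.
#' @slot role one of [vialRoles()].
#' @slot batchId batch identifier (may be `NA` for standalone tables).
#' @slot injectionVolume on-column injection volume in microlitres (> 0).
#' @slot peaks `data.frame` with columns `rt` (minutes), `area`, `height`,
#'   sorted ascending by `rt`.
#' @export
setClass("PeakTable",
  slots = c(
    sampleId = "character",
    role = "character",
    batchId = "character",
    injectionVolume = "numeric",
    peaks = "data.frame"
  )
)

setValidity("PeakTable", function(object) {
  msgs <- character()
  if (!(object@role %in% .VIAL_ROLES)) {
    msgs <- c(msgs, paste("role must be one of:",
                          paste(.VIAL_ROLES, collapse = ", ")))
  }
  if (length(object@injectionVolume) != 1L ||
      is.na(object@injectionVolume) || object@injectionVolume <= 0) {
    msgs <- c(msgs, "injectionVolume must be a single positive number")
  }
  p <- object@peaks
  if (!all(c("rt", "area", "height") %in% names(p))) {
    msgs <- c(msgs, "peaks must have columns rt, area, height")
  } else {
    if (any(p$rt <= 0)) msgs <- c(msgs, "peak rt must be > 0")
    if (any(p$area < 0)) msgs <- c(msgs, "peak area must be >= 0")
    if (any(p$height < 0)) msgs <- c(msgs, "peak height must be >= 0")
    if (is.unsorted(p$rt, strictly = FALSE)) {
      msgs <- c(msgs, "peaks must be sorted ascending by rt")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' FameBatch: one analytical batch of vials
#'
#' A batch is the unit of automated preparation and analysis: up to 32 vials
#' comprising dried sample extracts plus one process blank and the two
#' quality-control materials (QC1 pooled human plasma, QC2 pooled horse
#' plasma).
#'
#' @slot batchId batch identifier.
#' @slot vials list of [PeakTable-class] objects, in vial-position order.
#' @export
setClass("FameBatch",
  slots = c(batchId = "character", vials = "list")
)

setValidity("FameBatch", function(object) {
  if (!all(vapply(object@vials, is, logical(1), class2 = "PeakTable"))) {
    return("all vials must be PeakTable objects")
  }
  TRUE
})

#' FameProfile: a blank-corrected relative-percent fatty acid profile
#'
#' Per-analyte result of quantifying one vial: assigned raw area, blank
#' corrected area, percent of the total fatty acid signal, and a BLOQ
#' (below limit of quantification) flag.
#'
#' @slot sampleId sample identifier.
#' @slot batchId batch identifier.
#' @slot role vial role, one of [vialRoles()].
#' @slot referenceCode the panel's reference analyte code.
#' @slot data `data.frame` with columns `code`, `assigned_area`,
#'   `corrected_area`, `percent`, `bloq`.
#' @export
setClass("FameProfile",
  slots = c(
    sampleId = "character",
    batchId = "character",
    role = "character",
    referenceCode = "character",
    data = "data.frame"
  )
)

setValidity("FameProfile", function(object) {
  d <- object@data
  msgs <- character()
  need <- c("code", "assigned_area", "corrected_area", "percent", "bloq")
  if (!all(need %in% names(d))) {
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  }
  if (any(d$percent < 0)) msgs <- c(msgs, "percents must be >= 0")
  tot <- sum(d$percent)
  if (isTRUE(sum(d$corrected_area) > 0) && abs(tot - 100) > 1e-9) {
    msgs <- c(msgs, sprintf("percents must sum to 100 (got %.12f)", tot))
  }
  if (length(msgs)) msgs else TRUE
})

#' ControlChart: Shewhart chart parameters for one QC analyte
#'
#' Centre line and control limits for an individuals Shewhart chart of one
#' analyte in one QC material, estimated from a baseline period of batches.
#' Limits are `avg +/- k * sd` with the sample SD (n-1 denominator).
#'
#' @slot code analyte code.
#' @slot material `"qc1"` or `"qc2"`.
#' @slot avg centre line (percent).
#' @slot sd baseline between-batch SD (percent).
#' @slot k sigma multiplier (default 3).
#' @slot nBaseline number of baseline values used.
#' @seealso [establishChart()], [evaluatePoint()]
#' @export
setClass("ControlChart",
  slots = c(
    code = "character",
    material = "character",
    avg = "numeric",
    sd = "numeric",
    k = "numeric",
    nBaseline = "integer"
  )
)

setValidity("ControlChart", function(object) {
  msgs <- character()
  if (!(object@material %in% c("qc1", "qc2"))) {
    msgs <- c(msgs, "material must be 'qc1' or 'qc2'")
  }
  if (object@sd < 0) msgs <- c(msgs, "sd must be >= 0")
  if (object@k <= 0) msgs <- c(msgs, "k must be > 0")
  if (object@nBaseline < 2L) msgs <- c(msgs, "nBaseline must be >= 2")
  if (length(msgs)) msgs else TRUE
})

#' SimConfig: parameters of the synthetic peak-table generator
#'
#' @slot seed integer seed controlling every random draw.
#' @slot rtJitterSd SD of Gaussian retention-time jitter, minutes.
#' @slot areaNoiseCv coefficient of variation of multiplicative detector
#'   noise on peak areas (fraction, e.g. 0.02).
#' @slot totalArea total fatty acid signal of a nominal injection
#'   (signal units).
#' @slot driftPerBatch named numeric: per-analyte fractional multiplicative
#'   drift per batch; analytes not named drift by the unnamed default 0.
#' @slot blankTrace named numeric: percent-equivalent trace areas carried by
#'   the process blank (and by every vial, as contamination).
#' @slot compositionQc1,compositionQc2 `data.frame`s with columns `code`,
#'   `mean`, `sd` (percent) defining the QC materials.
#' @export
setClass("SimConfig",
  slots = c(
    seed = "integer",
    rtJitterSd = "numeric",
    areaNoiseCv = "numeric",
    totalArea = "numeric",
    driftPerBatch = "numeric",
    blankTrace = "numeric",
    compositionQc1 = "data.frame",
    compositionQc2 = "data.frame"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@rtJitterSd < 0) msgs <- c(msgs, "rtJitterSd must be >= 0")
  if (object@areaNoiseCv < 0) msgs <- c(msgs, "areaNoiseCv must be >= 0")
  if (object@totalArea <= 0) msgs <- c(msgs, "totalArea must be > 0")
  if (any(object@blankTrace < 0)) msgs <- c(msgs, "blankTrace must be >= 0")
  for (nm in c("compositionQc1", "compositionQc2")) {
    comp <- slot(object, nm)
    if (!all(c("code", "mean", "sd") %in% names(comp))) {
      msgs <- c(msgs, paste(nm, "needs columns code, mean, sd"))
      next
    }
    if (any(comp$mean < 0) || any(comp$sd < 0)) {
      msgs <- c(msgs, paste(nm, "means and sds must be >= 0"))
    }
    s <- sum(comp$mean)
    if (nrow(comp) && abs(s - 100) > 2) {
      msgs <- c(msgs, sprintf("%s means must sum to 100 +/- 2 (got %.2f)",
                              nm, s))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CalibrationDesign: the multi-level calibration series layout
#'
#' Describes a dilution series of the FAME standards: the relative volumes
#' transferred per level and the per-analyte stock amount (ng per unit
#' relative volume), so the nominal on-column amount at a level is
#' `volume * stock`.
#'
#' @slot levelVolumes strictly increasing positive relative volumes
#'   (default `c(0.01, 0.05, 0.1, 0.5, 1.0)`).
#' @slot stockAmount named numeric, ng per unit volume per analyte code.
#' @export
setClass("CalibrationDesign",
  slots = c(levelVolumes = "numeric", stockAmount = "numeric")
)

setValidity("CalibrationDesign", function(object) {
  msgs <- character()
  v <- object@levelVolumes
  if (length(v) < 2L || any(v <= 0) || is.unsorted(v, strictly = TRUE)) {
    msgs <- c(msgs, "levelVolumes must be >= 2 strictly increasing positive values")
  }
  if (is.null(names(object@stockAmount)) || any(object@stockAmount < 0)) {
    msgs <- c(msgs, "stockAmount must be a named nonnegative vector")
  }
  if (length(msgs)) msgs else TRUE
})

#' LoqContext: volumetric factors linking an on-column detection limit to a
#' plasma concentration
#'
#' Captures the sample-preparation volumetrics of the workflow: plasma
#' aliquot, the fraction of the chloroform layer transferred after the Folch
#' extraction, the fraction of the hexane layer transferred after
#' derivatization, reconstitution and injection volumes, and the fraction of
#' the injected amount reaching the column under split injection.
#'
#' @slot plasmaVolume microlitres of plasma prepared.
#' @slot injectionVolume microlitres injected.
#' @slot reconstitutionVolume microlitres of final hexane reconstitution
#'   (default 100).
#' @slot folchTransferFraction fraction of the lower chloroform layer
#'   recovered (default 0.8 = 1600/2000).
#' @slot hexaneTransferFraction fraction of the upper hexane layer
#'   recovered (default 0.6 = 600/1000).
#' @slot splitOnColumnFraction fraction of the injected amount reaching the
#'   column (default 1/21 for a 20:1 split).
#' @seealso [lodToPlasmaLoq()]
#' @export
setClass("LoqContext",
  slots = c(
    plasmaVolume = "numeric",
    injectionVolume = "numeric",
    reconstitutionVolume = "numeric",
    folchTransferFraction = "numeric",
    hexaneTransferFraction = "numeric",
    splitOnColumnFraction = "numeric"
  )
)

setValidity("LoqContext", function(object) {
  msgs <- character()
  vols <- c(object@plasmaVolume, object@injectionVolume,
            object@reconstitutionVolume)
  if (any(vols <= 0)) msgs <- c(msgs, "volumes must be > 0")
  fr <- c(object@folchTransferFraction, object@hexaneTransferFraction,
          object@splitOnColumnFraction)
  if (any(fr <= 0) || any(fr > 1)) {
    msgs <- c(msgs, "transfer fractions must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "FamePanel", function(object) {
  q <- quantifiableCodes(object)
  cat("FamePanel with", nrow(object@analytes), "analytes;",
      length(q), "quantifiable\n")
  cat("  reference:", object@referenceCode,
      " excluded:", paste(object@excludedCodes, collapse = ", "), "\n")
  if (length(object@coelutionGroups)) {
    for (nm in names(object@coelutionGroups)) {
      cat("  co-elution:", paste(object@coelutionGroups[[nm]],
                                 collapse = " + "), "->", nm, "\n")
    }
  }
  cat("  BLOQ threshold:", object@bloqThreshold, "%\n")
})

setMethod("show", "PeakTable", function(object) {
  cat(sprintf("PeakTable '%s' (role %s, batch %s): %d peaks\n",
              object@sampleId, object@role, object@batchId,
              nrow(object@peaks)))
})

setMethod("show", "FameBatch", function(object) {
  roles <- vapply(object@vials, function(v) v@role, character(1))
  cat(sprintf("FameBatch '%s': %d vials (%s)\n", object@batchId,
              length(object@vials),
              paste(sprintf("%s x%d", names(table(roles)), table(roles)),
                    collapse = ", ")))
})

setMethod("show", "FameProfile", function(object) {
  cat(sprintf("FameProfile '%s' (role %s, batch %s): %d analytes, %d BLOQ\n",
              object@sampleId, object@role, object@batchId,
              nrow(object@data), sum(object@data$bloq)))
})

setMethod("show", "ControlChart", function(object) {
  cat(sprintf(
    "ControlChart %s/%s: Avg %.4f, LCL %.4f, UCL %.4f (k = %g, n = %d)\n",
    object@material, object@code, object@avg, lcl(object), ucl(object),
    object@k, object@nBaseline))
})
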