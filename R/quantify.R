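#' Construct a peak table
#'
#' @param sample_id sample identifier.
#' @param role vial role, one of [vialRoles()].
#' @param peaks `data.frame` with columns `rt`, `area`, and optionally
#'   `height` (defaults to `area`); rows are sorted by `rt`.
#' @param batch_id batch identifier (`NA` for standalone tables).
#' @param injection_volume injection volume in microlitres; must be > 0.
#' @return A [PeakTable-class].
#' @examples
#' pt <- peakTable("s1", "sample", data.frame(rt = c(5, 9), area = c(2, 8)))
#' @export
peakTable <- function(sample_id, role = "sample",
                      peaks = data.frame(rt = numeric(0), area = numeric(0),
                                         height = numeric(0)),
                      batch_id = NA_character_, injection_volume = 1) {
  if (is.null(peaks$height)) peaks$height <- peaks$area
  peaks <- peaks[order(peaks$rt), c("rt", "area", "height"), drop = FALSE]
  rownames(peaks) <- NULL
  new("PeakTable", sampleId = as.character(sample_id), role = role,
      batchId = as.character(batch_id),
      injectionVolume = injection_volume, peaks = peaks)
}

#' Assign chromatographic peaks to panel analytes by retention time
#'
#' Matches the peaks of one injection to the panel's expected retention
#' ladder. Each analyte may receive at most one peak and each peak may
#' serve at most one analyte; only pairs within `rt_tolerance` are
#' eligible. Among all such matchings the one that (first) maximises the
#' number of assigned analytes and (then) minimises the total absolute
#' retention-time deviation is chosen; remaining ties are broken toward the
#' earlier-eluting peak. Because both the ladder and the peak list are
#' sorted, the optimal matching is order-preserving and is found by dynamic
#' programming. Unmatched analytes receive area 0.
#'
#' @param table a [PeakTable-class].
#' @param panel a [FamePanel-class] (excluded analytes are not assigned).
#' @param rt_tolerance maximum |observed - expected| retention-time
#'   difference in minutes (default 0.1).
#' @return list with `areas` (named numeric over assignable panel codes),
#'   `assignments` (`data.frame` code, expected_rt, peak_rt, area) and
#'   `unassigned` (`data.frame` of peaks not used).
#' @examples
#' panel <- defaultPanel()
#' rt <- analytes(panel)$expected_rt[analytes(panel)$code == "C16:0"]
#' pt <- peakTable("s", "sample", data.frame(rt = rt, area = 100))
#' assignPeaks(pt, panel)$areas[["C16:0"]]
#' @export
assignPeaks <- function(table, panel, rt_tolerance = 0.1) {
  stopifnot(rt_tolerance > 0)
  a <- analytes(panel)
  a <- a[!(a$code %in% panel@excludedCodes), , drop = FALSE]
  codes <- a$code
  expected <- a$expected_rt
  pk <- peaks(table)
  n <- length(codes)
  m <- nrow(pk)
  areas <- setNames(numeric(n), codes)
  if (m == 0L) {
    warning("empty peak table for sample '", sampleId(table),
            "': all-zero assignment")
    return(list(
      areas = areas,
      assignments = data.frame(code = codes, expected_rt = expected,
                               peak_rt = NA_real_, area = 0),
      unassigned = pk))
  }
  match_idx <- .matchLadder(expected, pk$rt, rt_tolerance)
  hit <- !is.na(match_idx)
  areas[hit] <- pk$area[match_idx[hit]]
  list(
    areas = areas,
    assignments = data.frame(
      code = codes, expected_rt = expected,
      peak_rt = ifelse(hit, pk$rt[match_idx], NA_real_),
      area = unname(areas), stringsAsFactors = FALSE),
    unassigned = pk[setdiff(seq_len(m), match_idx[hit]), , drop = FALSE]
  )
}

## Optimal order-preserving matching of sorted expected RTs to sorted peak
## RTs: lexicographically maximise matches then minimise total |dRT|, ties
## toward the earlier peak. Returns peak index per analyte (NA = unmatched).
.matchLadder <- function(expected, observed, tol) {
  n <- length(expected)
  m <- length(observed)
  ## cost[i+1, j+1] = best (-matches, total |dRT|) using first i analytes,
  ## first j peaks. Track matches and cost separately.
  M <- matrix(0L, n + 1L, m + 1L)       # matched count
  C <- matrix(0, n + 1L, m + 1L)        # total |dRT|
  ## choice: 0 = skip analyte (from i-1,j), 1 = skip peak (from i,j-1),
  ##         2 = match (from i-1,j-1)
  P <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      ## candidates as (matches, cost); prefer more matches, then lower
      ## cost, then the one that leaves the later peak unused (i.e. match
      ## or skip-analyte before skip-peak, so earlier peaks are consumed).
      bm <- M[i, j + 1L]; bc <- C[i, j + 1L]; bp <- 0L
      if (M[i + 1L, j] > bm ||
          (M[i + 1L, j] == bm && C[i + 1L, j] < bc)) {
        bm <- M[i + 1L, j]; bc <- C[i + 1L, j]; bp <- 1L
      }
      d <- abs(expected[i] - observed[j])
      if (d <= tol) {
        ## strict inequality: on equal cost the earlier-eluting peak
        ## (already consumed on the skip-peak path) wins the tie
        mm <- M[i, j] + 1L; mc <- C[i, j] + d
        if (mm > bm || (mm == bm && mc < bc)) {
          bm <- mm; bc <- mc; bp <- 2L
        }
      }
      M[i + 1L, j + 1L] <- bm
      C[i + 1L, j + 1L] <- bc
      P[i + 1L, j + 1L] <- bp
    }
  }
  out <- rep(NA_integer_, n)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    p <- P[i + 1L, j + 1L]
    if (p == 2L) {
      out[i] <- j; i <- i - 1L; j <- j - 1L
    } else if (p == 1L) {
      j <- j - 1L
    } else {
      i <- i - 1L
    }
  }
  out
}

#' Merge co-eluting analytes under their reported code
#'
#' Sums the areas of each configured co-elution group under the group's
#' reported code (for the default panel: C20:3n3 + C20:4n6 reported as
#' C20:4n6, C20:3n3 being negligible in human plasma). Total area is
#' conserved.
#'
#' @param assignment named numeric map code -> area over panel codes.
#' @param panel a [FamePanel-class].
#' @return named numeric over the panel's reported (quantifiable) codes.
#' @examples
#' p <- defaultPanel()
#' x <- setNames(numeric(39), analytes(p)$code[
#'   !analytes(p)$code %in% c("C4:0", "C6:0")])
#' x[c("C20:3n3", "C20:4n6")] <- c(10, 90)
#' mergeCoeluting(x, p)[["C20:4n6"]]
#' @export
mergeCoeluting <- function(assignment, panel) {
  out <- assignment
  for (rep_code in names(panel@coelutionGroups)) {
    members <- intersect(panel@coelutionGroups[[rep_code]], names(out))
    if (!length(members)) next
    total <- sum(out[members])
    out <- out[!(names(out) %in% setdiff(members, rep_code))]
    out[rep_code] <- total
  }
  q <- quantifiableCodes(panel)
  out[c(intersect(q, names(out)), setdiff(names(out), q))]
}

#' Subtract process-blank areas from a sample's assigned areas
#'
#' The process blank measures contamination introduced by reagents,
#' glassware and the preparation itself (typically trace C14:0, C16:0 and
#' C18:0); its areas are deducted per analyte before percentages are
#' computed. Corrected areas are clipped at zero.
#'
#' @param sample_areas named numeric code -> area.
#' @param blank_areas named numeric code -> area (codes absent here leave
#'   the sample unchanged).
#' @return named numeric of corrected areas, same codes as `sample_areas`.
#' @examples
#' subtractBlank(c("C16:0" = 1000), c("C16:0" = 50))
#' @export
subtractBlank <- function(sample_areas, blank_areas) {
  common <- intersect(names(sample_areas), names(blank_areas))
  out <- sample_areas
  out[common] <- pmax(out[common] - blank_areas[common], 0)
  out
}

#' Relative-percent quantification
#'
#' Converts corrected areas to each analyte's percentage of the total
#' fatty acid signal: `percent_i = 100 * area_i / sum(area)`. The result
#' closes to 100 within 1e-9.
#'
#' @param corrected_areas named numeric code -> area, at least one > 0.
#' @return named numeric of percents.
#' @examples
#' computePercent(c(A = 50, B = 30, C = 20))
#' @export
computePercent <- function(corrected_areas) {
  total <- sum(corrected_areas)
  if (!is.finite(total) || total <= 0) {
    stop("all-zero corrected areas: empty chromatogram")
  }
  100 * corrected_areas / total
}

#' Flag analytes below the limit of quantification
#'
#' An analyte is BLOQ when its final blank-corrected percent is strictly
#' below the threshold (default 0.15% of total signal); a value exactly at
#' the threshold is quantifiable. BLOQ analytes are flagged, not removed,
#' so percent closure is preserved.
#'
#' @param percents named numeric code -> percent.
#' @param threshold percent threshold (> 0).
#' @return named logical.
#' @examples
#' flagBloq(c(A = 0.149, B = 0.15, C = 30.12), 0.15)
#' @export
flagBloq <- function(percents, threshold = 0.15) {
  stopifnot(threshold > 0)
  percents < threshold
}

#' Quantify one peak table against a panel and a blank
#'
#' Composes peak assignment, co-elution merging, blank subtraction,
#' percent computation and BLOQ flagging into a [FameProfile-class].
#'
#' @param table a [PeakTable-class].
#' @param panel a [FamePanel-class].
#' @param blank_areas named numeric of blank areas on reported codes
#'   (zeros for none).
#' @param rt_tolerance retention-time matching tolerance, minutes.
#' @return A [FameProfile-class].
#' @export
quantifyPeakTable <- function(table, panel, blank_areas = numeric(0),
                              rt_tolerance = 0.1) {
  assigned <- assignPeaks(table, panel, rt_tolerance)$areas
  merged <- mergeCoeluting(assigned, panel)
  corrected <- subtractBlank(merged, blank_areas)
  pct <- computePercent(corrected)
  bloq <- flagBloq(pct, bloqThreshold(panel))
  codes <- quantifiableCodes(panel)
  new("FameProfile",
      sampleId = sampleId(table), batchId = batchId(table),
      role = vialRole(table), referenceCode = referenceCode(panel),
      data = data.frame(
        code = codes,
        assigned_area = unname(merged[codes]),
        corrected_area = unname(corrected[codes]),
        percent = unname(pct[codes]),
        bloq = unname(bloq[codes]),
        stringsAsFactors = FALSE))
}

#' Quantify every vial of a batch with its own process blank
#'
#' Locates the batch's single process blank, quantifies it, and uses its
#' reported-code areas to blank-correct every other vial. The blank itself
#' is consumed, not profiled: a full 32-vial batch yields 31 profiles. QC
#' vials keep their roles so the charting stage can pick them out.
#'
#' @param batch a [FameBatch-class].
#' @param panel a [FamePanel-class].
#' @param rt_tolerance retention-time matching tolerance, minutes.
#' @return list of [FameProfile-class], one per non-blank vial.
#' @examples
#' study <- simulateStudy(1, samples_per_batch = 2, sim = simConfig(seed = 1))
#' profs <- quantifyBatch(study[[1]], defaultPanel())
#' length(profs)  # 2 samples + QC1 + QC2
#' @export
quantifyBatch <- function(batch, panel, rt_tolerance = 0.1) {
  roles <- vapply(vials(batch), vialRole, character(1))
  nb <- sum(roles == "process_blank")
  if (nb == 0L) {
    stop("batch '", batchId(batch), "' has no process blank")
  }
  if (nb > 1L) {
    stop("batch '", batchId(batch), "' has ", nb, " process blanks")
  }
  blank_tab <- vials(batch)[[which(roles == "process_blank")]]
  blank_assigned <- assignPeaks(blank_tab, panel, rt_tolerance)$areas
  blank_areas <- mergeCoeluting(blank_assigned, panel)
  lapply(vials(batch)[roles != "process_blank"], function(v) {
    quantifyPeakTable(v, panel, blank_areas, rt_tolerance)
  })
}
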