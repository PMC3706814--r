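#' Assemble profiles into a SummarizedExperiment
#'
#' Collects a list of [FameProfile-class] into the field's standard
#' container: a [SummarizedExperiment::SummarizedExperiment] with one row
#' per panel analyte and one column per profiled vial, carrying `percent`,
#' `corrected_area` and `bloq` assays, analyte metadata (common name,
#' expected retention time) as `rowData`, and vial identity (sample id,
#' role, batch) as `colData`.
#'
#' @param profiles list of [FameProfile-class] sharing one panel.
#' @param panel the [FamePanel-class] the profiles were quantified
#'   against (supplies row metadata).
#' @return A `SummarizedExperiment`.
#' @examples
#' study <- simulateStudy(1, samples_per_batch = 2, sim = simConfig(seed = 1))
#' se <- profileAssay(quantifyBatch(study[[1]], defaultPanel()))
#' SummarizedExperiment::assayNames(se)
#' @export
profileAssay <- function(profiles, panel = defaultPanel()) {
  stopifnot(length(profiles) >= 1L)
  codes <- profileData(profiles[[1]])$code
  grab <- function(col) {
    vapply(profiles, function(p) {
      d <- profileData(p)
      stopifnot(identical(d$code, codes))
      d[[col]]
    }, numeric(length(codes)))
  }
  pct <- grab("percent")
  area <- grab("corrected_area")
  bloq <- vapply(profiles, function(p) profileData(p)$bloq,
                 logical(length(codes)))
  ids <- vapply(profiles, sampleId, character(1))
  dimnames(pct) <- dimnames(area) <- dimnames(bloq) <- list(codes, ids)
  a <- analytes(panel)
  a <- a[match(codes, a$code), , drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(percent = pct, corrected_area = area, bloq = bloq),
    rowData = S4Vectors::DataFrame(
      common_name = a$common_name, expected_rt = a$expected_rt,
      row.names = codes),
    colData = S4Vectors::DataFrame(
      sample_id = ids,
      role = vapply(profiles, vialRole, character(1)),
      batch_id = vapply(profiles, batchId, character(1)),
      row.names = ids))
}
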