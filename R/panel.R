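#' Build a FAME quantification panel
#'
#' Constructs a [FamePanel-class] from the codes of a commercial FAME mix
#' plus individually added standards, applying exclusions (analytes lost
#' under the solvent peak) and co-elution merges (analyte pairs not
#' resolved by the column, reported under one code). The number of
#' quantifiable analytes is
#' `|mix| + |added| - |excluded| - sum(group size - 1)`.
#'
#' @param mix_codes character codes of the mix components.
#' @param added_codes codes of individually added standards.
#' @param excluded_codes codes excluded from quantification.
#' @param coelution_groups named list: each element a character vector of
#'   co-eluting member codes, named by the code they are reported under
#'   (which must be a member).
#' @param reference_code the reference analyte (default `"C16:0"`); must
#'   not be excluded.
#' @param bloq_threshold percent of total signal below which a measurement
#'   is flagged BLOQ (default 0.15).
#' @param common_names optional named character vector code -> name.
#' @param expected_rt optional named numeric code -> retention time
#'   (minutes). If absent, fill with [defaultRtLadder()].
#' @param run_minutes chromatographic run time used by the default ladder.
#'
#' @return A validated [FamePanel-class].
#' @examples
#' p <- buildPanel(c("C14:0", "C16:0", "C18:0"), character(0))
#' quantifiableCodes(p)
#' @seealso [defaultPanel()] for the standard 37-analyte plasma panel.
#' @export
buildPanel <- function(mix_codes, added_codes = character(0),
                       excluded_codes = character(0),
                       coelution_groups = list(),
                       reference_code = "C16:0",
                       bloq_threshold = 0.15,
                       common_names = NULL,
                       expected_rt = NULL,
                       run_minutes = 30) {
  all_codes <- c(mix_codes, added_codes)
  if (anyDuplicated(all_codes)) {
    stop("duplicate analyte codes: ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "))
  }
  if (!all(excluded_codes %in% all_codes)) {
    stop("excluded codes not in the panel: ",
         paste(setdiff(excluded_codes, all_codes), collapse = ", "))
  }
  if (reference_code %in% excluded_codes) {
    stop("the reference analyte ", reference_code, " cannot be excluded")
  }
  if (!(reference_code %in% all_codes)) {
    stop("reference analyte ", reference_code, " is not in the panel")
  }
  remaining <- setdiff(all_codes, excluded_codes)
  for (rep_code in names(coelution_groups)) {
    members <- coelution_groups[[rep_code]]
    if (!all(members %in% remaining)) {
      stop("co-elution members not among quantifiable codes: ",
           paste(setdiff(members, remaining), collapse = ", "))
    }
  }
  nm <- if (is.null(common_names)) character(0) else common_names
  a <- data.frame(
    code = all_codes,
    common_name = ifelse(all_codes %in% names(nm), nm[all_codes], all_codes),
    expected_rt = NA_real_,
    source = rep(c("mix37", "added"),
                 c(length(mix_codes), length(added_codes))),
    notes = "",
    stringsAsFactors = FALSE
  )
  if (!is.null(expected_rt)) {
    a$expected_rt <- unname(expected_rt[a$code])
    a <- a[order(a$expected_rt), , drop = FALSE]
    rownames(a) <- NULL
  } else {
    a <- a[order(.elutionScore(a$code), a$code), , drop = FALSE]
    rownames(a) <- NULL
  }
  panel <- new("FamePanel", analytes = a, referenceCode = reference_code,
               excludedCodes = excluded_codes,
               coelutionGroups = coelution_groups,
               bloqThreshold = bloq_threshold)
  if (is.null(expected_rt)) panel <- defaultRtLadder(panel, run_minutes)
  validObject(panel)
  panel
}

## Elution ordering score for a lipid shorthand code Cx:y[(n-pos)][c/t] on a
## highly polar cyanopropyl column: carbon number dominates, then degree of
## unsaturation; trans before cis; within equal C:y, larger omega offsets
## (n3 after n6 after n9).
.elutionScore <- function(codes) {
  vapply(codes, function(code) {
    m <- regmatches(code, regexec("^C(\\d+):(\\d+)(n(\\d+))?([ct])?$", code))[[1]]
    if (length(m) == 0) {
      stop("cannot parse analyte code '", code,
           "'; supply expected_rt explicitly")
    }
    carbon <- as.numeric(m[2])
    db <- as.numeric(m[3])
    omega <- if (nzchar(m[5])) as.numeric(m[5]) else NA_real_
    geom <- m[6]
    score <- carbon + 0.25 * db
    if (!is.na(omega)) score <- score + 0.09 / omega  # n3 > n6 > n9
    if (identical(geom, "t")) score <- score + 0.005
    if (identical(geom, "c")) score <- score + 0.050
    score
  }, numeric(1))
}

#' Fill a panel's retention ladder deterministically
#'
#' Assigns expected retention times by spacing the panel's analytes evenly
#' over the usable window of the run, `(solvent_cutoff, run_minutes)`, in
#' carbon-number / unsaturation elution order. Only the relative ordering
#' and separability of the ladder matter to downstream peak assignment;
#' true per-analyte retention times depend on column chemistry and the oven
#' program, which this package does not model.
#'
#' @param panel a [FamePanel-class].
#' @param run_minutes total run time, minutes (default 30).
#' @param solvent_cutoff earliest usable retention time, minutes
#'   (default 2.5); earlier eluters are hidden by the solvent peak.
#' @return The panel with `expected_rt` filled; idempotent.
#' @export
defaultRtLadder <- function(panel, run_minutes = 30, solvent_cutoff = 2.5) {
  stopifnot(run_minutes > 0, solvent_cutoff >= 0,
            run_minutes > solvent_cutoff)
  a <- analytes(panel)
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 analytes to build a ladder")
  ord <- order(.elutionScore(a$code), a$code)
  a <- a[ord, , drop = FALSE]
  ## even spacing with half-gap margins at both ends
  gap <- (run_minutes - solvent_cutoff) / (n + 1)
  a$expected_rt <- solvent_cutoff + gap * seq_len(n)
  rownames(a) <- NULL
  panel@analytes <- a
  validObject(panel)
  panel
}

#' The default 37-analyte plasma phospholipid panel
#'
#' The standard panel of this workflow: a 37-component commercial FAME mix
#' plus three individually added long-chain polyunsaturates (C22:4,
#' C22:5n6, C22:5n3), with C4:0 and C6:0 excluded (they overlap the
#' solvent peak) and the unresolved C20:3n3/C20:4n6 pair reported as
#' C20:4n6 (C20:3n3 is negligible in human plasma). This yields exactly 37
#' quantifiable analytes; C16:0 (palmitic acid methyl ester) is the
#' reference.
#'
#' @param run_minutes run time for the default retention ladder.
#' @return A [FamePanel-class] with 37 quantifiable analytes.
#' @examples
#' length(quantifiableCodes(defaultPanel()))
#' @export
defaultPanel <- function(run_minutes = 30) {
  ref <- fameReferenceStats()
  final <- ref$code                       # the 37 quantifiable analytes
  added <- .ADDED_CODES
  mix <- c(setdiff(final, added), "C4:0", "C6:0", "C20:3n3")
  nms <- c(setNames(ref$common_name, ref$code),
           "C4:0" = "Butyric", "C6:0" = "Caproic",
           "C20:3n3" = "Eicosatrienoic")
  buildPanel(
    mix_codes = mix,
    added_codes = added,
    excluded_codes = c("C4:0", "C6:0"),
    coelution_groups = list("C20:4n6" = c("C20:3n3", "C20:4n6")),
    reference_code = "C16:0",
    bloq_threshold = 0.15,
    common_names = nms,
    run_minutes = run_minutes
  )
}

#' Read / write a panel configuration file
#'
#' Panels are serialized as YAML so that alternative panels (other sample
#' matrices, other standard mixes) can be configured without code changes.
#' The file carries the analyte list (code, name, expected retention time,
#' source) and the top-level `reference_code`, `excluded`, `coelutions`
#' (list of `members`/`reported`) and `bloq_threshold`.
#'
#' @param panel a [FamePanel-class].
#' @param path file path.
#' @return `writePanelConfig` returns `path` invisibly; `readPanelConfig`
#'   returns the [FamePanel-class].
#' @export
writePanelConfig <- function(panel, path) {
  a <- analytes(panel)
  cfg <- list(
    reference_code = referenceCode(panel),
    bloq_threshold = bloqThreshold(panel),
    excluded = as.list(panel@excludedCodes),
    coelutions = lapply(names(panel@coelutionGroups), function(nm) {
      list(reported = nm, members = as.list(panel@coelutionGroups[[nm]]))
    }),
    analytes = lapply(seq_len(nrow(a)), function(i) {
      list(code = a$code[i], common_name = a$common_name[i],
           expected_rt = a$expected_rt[i], source = a$source[i])
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writePanelConfig
#' @export
readPanelConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  an <- do.call(rbind, lapply(cfg$analytes, function(x) {
    data.frame(code = x$code, common_name = x$common_name,
               expected_rt = as.numeric(x$expected_rt), source = x$source,
               stringsAsFactors = FALSE)
  }))
  groups <- list()
  for (g in cfg$coelutions) {
    groups[[g$reported]] <- unlist(g$members)
  }
  rt <- setNames(an$expected_rt, an$code)
  buildPanel(
    mix_codes = an$code[an$source == "mix37"],
    added_codes = an$code[an$source == "added"],
    excluded_codes = unlist(cfg$excluded) %||% character(0),
    coelution_groups = groups,
    reference_code = cfg$reference_code,
    bloq_threshold = cfg$bloq_threshold,
    common_names = setNames(an$common_name, an$code),
    expected_rt = rt
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
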