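## CSV interchange schemas (column names are part of the public contract):
##   peak table: sample_id, role, batch_id, injection_volume_ul, rt_min,
##               area, height
##   manifest:   batch_id, vial_position, sample_id, role
##   profiles:   sample_id, batch_id, role, code, corrected_area, percent,
##               bloq

#' Write / read peak tables as CSV
#'
#' One row per peak; vials are reassembled on read by `(batch_id,
#' sample_id)`. Vials with no peaks are preserved via the companion
#' manifest, not the peak file.
#'
#' @param batches list of [FameBatch-class] (or a single batch).
#' @param path CSV path.
#' @return `writePeakTables` returns `path` invisibly; `readPeakTables`
#'   returns a list of [FameBatch-class] (requires the manifest to
#'   restore empty vials and vial order).
#' @export
writePeakTables <- function(batches, path) {
  if (is(batches, "FameBatch")) batches <- list(batches)
  rows <- lapply(batches, function(b) {
    do.call(rbind, lapply(vials(b), function(v) {
      p <- peaks(v)
      if (!nrow(p)) return(NULL)
      data.frame(sample_id = sampleId(v), role = vialRole(v),
                 batch_id = batchId(v),
                 injection_volume_ul = v@injectionVolume,
                 rt_min = p$rt, area = p$area, height = p$height,
                 stringsAsFactors = FALSE)
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePeakTables
#' @param manifest_path manifest CSV path (see [writeManifest()]).
#' @export
readPeakTables <- function(path, manifest_path) {
  pk <- read.csv(path, stringsAsFactors = FALSE)
  mf <- read.csv(manifest_path, stringsAsFactors = FALSE)
  if (any(mf$vial_position < 1 | mf$vial_position > 32)) {
    stop("vial_position must lie in 1..32")
  }
  if (any(pk$injection_volume_ul <= 0)) {
    stop("injection_volume_ul must be > 0")
  }
  lapply(split(mf, mf$batch_id), function(bm) {
    bm <- bm[order(bm$vial_position), , drop = FALSE]
    vial_list <- lapply(seq_len(nrow(bm)), function(i) {
      sel <- pk$batch_id == bm$batch_id[i] & pk$sample_id == bm$sample_id[i]
      iv <- if (any(sel)) pk$injection_volume_ul[sel][1] else 1
      peakTable(bm$sample_id[i], bm$role[i],
                data.frame(rt = pk$rt_min[sel], area = pk$area[sel],
                           height = pk$height[sel]),
                batch_id = bm$batch_id[i], injection_volume = iv)
    })
    new("FameBatch", batchId = as.character(bm$batch_id[1]),
        vials = vial_list)
  })
}

#' Write a batch manifest CSV
#'
#' @param batches list of [FameBatch-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(batches, path) {
  if (is(batches, "FameBatch")) batches <- list(batches)
  rows <- lapply(batches, function(b) {
    data.frame(batch_id = batchId(b),
               vial_position = seq_along(vials(b)),
               sample_id = vapply(vials(b), sampleId, character(1)),
               role = vapply(vials(b), vialRole, character(1)),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read quantified profiles as CSV
#'
#' @param profiles list of [FameProfile-class].
#' @param path CSV path.
#' @return `writeProfiles` returns `path` invisibly; `readProfiles`
#'   returns a list of [FameProfile-class].
#' @export
writeProfiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    d <- profileData(p)
    data.frame(sample_id = sampleId(p), batch_id = batchId(p),
               role = vialRole(p), code = d$code,
               corrected_area = d$corrected_area, percent = d$percent,
               bloq = d$bloq, stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeProfiles
#' @export
readProfiles <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  key <- paste(d$batch_id, d$sample_id, sep = "\r")
  lapply(unname(split(d, factor(key, levels = unique(key)))), function(s) {
    new("FameProfile", sampleId = as.character(s$sample_id[1]),
        batchId = as.character(s$batch_id[1]), role = s$role[1],
        referenceCode = "C16:0",
        data = data.frame(code = s$code, assigned_area = NA_real_,
                          corrected_area = s$corrected_area,
                          percent = s$percent,
                          bloq = as.logical(s$bloq),
                          stringsAsFactors = FALSE))
  })
}
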