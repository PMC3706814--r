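#' Accessors for pipeline objects
#'
#' Small accessor generics used across the package instead of direct slot
#' access: panel analytes and quantifiable codes, peak data, profile data,
#' and Shewhart chart limits.
#'
#' @param object a package S4 object ([FamePanel-class], [PeakTable-class],
#'   [FameProfile-class], [ControlChart-class], ...).
#' @return The accessed component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("analytes", function(object) standardGeneric("analytes"))

#' @rdname accessors
#' @export
setGeneric("quantifiableCodes",
           function(object) standardGeneric("quantifiableCodes"))

#' @rdname accessors
#' @export
setGeneric("referenceCode", function(object) standardGeneric("referenceCode"))

#' @rdname accessors
#' @export
setGeneric("bloqThreshold", function(object) standardGeneric("bloqThreshold"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("vialRole", function(object) standardGeneric("vialRole"))

#' @rdname accessors
#' @export
setGeneric("batchId", function(object) standardGeneric("batchId"))

#' @rdname accessors
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("vials", function(object) standardGeneric("vials"))

#' @rdname accessors
#' @export
setGeneric("profileData", function(object) standardGeneric("profileData"))

#' @rdname accessors
#' @export
setGeneric("percents", function(object) standardGeneric("percents"))

#' @rdname accessors
#' @export
setGeneric("lcl", function(object) standardGeneric("lcl"))

#' @rdname accessors
#' @export
setGeneric("ucl", function(object) standardGeneric("ucl"))

#' @rdname accessors
#' @export
setGeneric("avgLine", function(object) standardGeneric("avgLine"))

#' @rdname accessors
#' @export
setMethod("analytes", "FamePanel", function(object) object@analytes)

#' @rdname accessors
#' @export
setMethod("quantifiableCodes", "FamePanel", function(object) {
  codes <- setdiff(object@analytes$code, object@excludedCodes)
  for (rep_code in names(object@coelutionGroups)) {
    members <- object@coelutionGroups[[rep_code]]
    codes <- setdiff(codes, setdiff(members, rep_code))
  }
  ## keep elution (panel) order
  object@analytes$code[object@analytes$code %in% codes]
})

#' @rdname accessors
#' @export
setMethod("referenceCode", "FamePanel", function(object) object@referenceCode)

#' @rdname accessors
#' @export
setMethod("referenceCode", "FameProfile",
          function(object) object@referenceCode)

#' @rdname accessors
#' @export
setMethod("bloqThreshold", "FamePanel", function(object) object@bloqThreshold)

#' @rdname accessors
#' @export
setMethod("sampleId", "PeakTable", function(object) object@sampleId)

#' @rdname accessors
#' @export
setMethod("sampleId", "FameProfile", function(object) object@sampleId)

#' @rdname accessors
#' @export
setMethod("vialRole", "PeakTable", function(object) object@role)

#' @rdname accessors
#' @export
setMethod("vialRole", "FameProfile", function(object) object@role)

#' @rdname accessors
#' @export
setMethod("batchId", "PeakTable", function(object) object@batchId)

#' @rdname accessors
#' @export
setMethod("batchId", "FameBatch", function(object) object@batchId)

#' @rdname accessors
#' @export
setMethod("batchId", "FameProfile", function(object) object@batchId)

#' @rdname accessors
#' @export
setMethod("peaks", "PeakTable", function(object) object@peaks)

#' @rdname accessors
#' @export
setMethod("vials", "FameBatch", function(object) object@vials)

#' @rdname accessors
#' @export
setMethod("profileData", "FameProfile", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("percents", "FameProfile", function(object) {
  setNames(object@data$percent, object@data$code)
})

#' @rdname accessors
#' @export
setMethod("lcl", "ControlChart", function(object) {
  object@avg - object@k * object@sd
})

#' @rdname accessors
#' @export
setMethod("ucl", "ControlChart", function(object) {
  object@avg + object@k * object@sd
})

#' @rdname accessors
#' @export
setMethod("avgLine", "ControlChart", function(object) object@avg)
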