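## Generics and accessor methods.

#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<- isEmpty
NULL

#' Accessors for trnamap S4 objects
#'
#' Small accessor generics in the usual Bioconductor style; slot access via
#' \code{@} is discouraged in user code.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trnaId", function(x) standardGeneric("trnaId"))

#' @rdname accessors
#' @export
setGeneric("trnaSequence", function(x) standardGeneric("trnaSequence"))

#' @rdname accessors
#' @export
setGeneric("positionLabels", function(x) standardGeneric("positionLabels"))

#' @rdname accessors
#' @export
setGeneric("structuralElements",
           function(x) standardGeneric("structuralElements"))

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname accessors
#' @export
setGeneric("parentTRNA", function(x) standardGeneric("parentTRNA"))

#' @rdname accessors
#' @export
setGeneric("targetLabel", function(x) standardGeneric("targetLabel"))

#' @rdname accessors
#' @export
setGeneric("dnaTemplate", function(x) standardGeneric("dnaTemplate"))

#' @rdname accessors
#' @export
setGeneric("profileData", function(x) standardGeneric("profileData"))

#' @rdname accessors
#' @export
setGeneric("sampleRole", function(x) standardGeneric("sampleRole"))

#' @rdname accessors
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))

#' @rdname accessors
#' @export
setGeneric("mRate", function(x) standardGeneric("mRate"))

#' @rdname accessors
#' @export
setGeneric("subtractedRate", function(x) standardGeneric("subtractedRate"))

#' @rdname accessors
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname accessors
#' @export
setGeneric("isDefined", function(x) standardGeneric("isDefined"))

#' @rdname accessors
#' @export
setGeneric("km", function(x) standardGeneric("km"))

#' @rdname accessors
#' @export
setGeneric("vmax", function(x) standardGeneric("vmax"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' Subtract an untreated background from a treated measurement
#'
#' @param treated,untreated matching treated / untreated objects.
#' @param ... further arguments for methods.
#' @export
setGeneric("subtractBackground",
           function(treated, untreated, ...) standardGeneric("subtractBackground"))

#' @rdname accessors
#' @export
setMethod("trnaId", "AnnotatedTRNA", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("trnaSequence", "AnnotatedTRNA", function(x) x@sequence)

#' @rdname accessors
#' @export
setMethod("positionLabels", "AnnotatedTRNA", function(x) x@positionLabels)

#' @rdname accessors
#' @export
setMethod("structuralElements", "AnnotatedTRNA", function(x) x@elements)

#' @rdname accessors
#' @export
setMethod("variants", "VariantLibrary", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("parentTRNA", "VariantLibrary", function(x) x@parent)

#' @rdname accessors
#' @export
setMethod("targetLabel", "VariantLibrary", function(x) x@targetLabel)

#' @rdname accessors
#' @export
setMethod("dnaTemplate", "TranscriptionCassette", function(x) x@dnaTemplate)

#' @rdname accessors
#' @export
setMethod("profileData", "MutationProfile", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("sampleRole", "MutationProfile", function(x) x@sampleRole)

#' @rdname accessors
#' @export
setMethod("referenceId", "MutationProfile", function(x) x@referenceId)

#' @rdname accessors
#' @export
setMethod("sampleRole", "MRateResult", function(x) x@sampleRole)

#' @rdname accessors
#' @export
setMethod("mRate", "MRateResult", function(x) x@mRate)

#' @rdname accessors
#' @export
setMethod("subtractedRate", "MRateResult", function(x) x@subtractedRate)

#' @rdname accessors
#' @export
setMethod("readCounts", "MRateResult", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("isDefined", "MRateResult", function(x) x@defined)

#' @rdname accessors
#' @export
setMethod("km", "KineticFit", function(x) x@km)

#' @rdname accessors
#' @export
setMethod("vmax", "KineticFit", function(x) x@vmax)

#' @rdname accessors
#' @export
setMethod("converged", "KineticFit", function(x) x@converged)

setMethod("show", "AnnotatedTRNA", function(object) {
  cat("AnnotatedTRNA ", object@id, ": ", nchar(object@sequence), " nt, ",
      "labels ", object@positionLabels[1L], "..",
      object@positionLabels[length(object@positionLabels)], "\n", sep = "")
  cat("  ", object@sequence, "\n", sep = "")
  if (length(object@elements))
    cat("  elements: ", paste(unique(object@elements), collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "VariantLibrary", function(object) {
  cat("VariantLibrary of ", trnaId(object@parent), ": ",
      nrow(object@variants), " single-point variants over ",
      length(unique(object@variants$positionLabel)),
      " positions; target position ", object@targetLabel, "\n", sep = "")
})

setMethod("show", "TranscriptionCassette", function(object) {
  cat("TranscriptionCassette ", object@id, ": ", nchar(object@dnaTemplate),
      " bp template", if (object@extraGAdded) ", extra 5' G",
      if (object@ccaAdded) ", CCA appended", "\n", sep = "")
})

setMethod("show", "MutationProfile", function(object) {
  d <- object@data
  cat("MutationProfile ", object@referenceId, " (", object@sampleRole, "): ",
      nrow(d), " positions, ", sum(d$missing), " below depth floor\n",
      sep = "")
})

setMethod("show", "MRateResult", function(object) {
  cat("MRateResult ", object@variantName, " (", object@sampleRole, "): ",
      "Read_Total=", format(object@readTotal), ", M_rate=",
      if (object@defined) format(round(object@mRate, 4)) else "undefined",
      if (!is.na(object@subtractedRate))
        paste0(", subtracted=", format(round(object@subtractedRate, 4))),
      "\n", sep = "")
})

setMethod("show", "KineticFit", function(object) {
  cat("KineticFit: Km=", format(object@km), ", Vmax=", format(object@vmax),
      ", rss=", format(object@rss),
      if (!object@converged) paste0(" [flagged: ", object@message, "]"),
      "\n", sep = "")
})

setMethod("show", "ModificationSignature", function(object) {
  cat("ModificationSignature ", object@referenceId, " position ",
      object@positionLabel, ": misincorporation ",
      format(object@misincorporationRate), ", stop ",
      format(object@stopRate), "\n", sep = "")
})
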