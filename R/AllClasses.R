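## S4 class definitions and validity methods.

#' AnnotatedTRNA: a tRNA sequence with per-position labels
#'
#' Holds one tRNA reference: its RNA sequence, an ordered vector of
#' position labels (Sprinzl-style strings, insertion labels such as
#' \code{"20a"} or \code{"45b"} allowed) and an optional assignment of
#' labels to secondary-structure elements.
#'
#' @slot id single character identifier.
#' @slot sequence RNA sequence (uppercase, alphabet A/C/G/U).  DNA input is
#'   converted on construction.
#' @slot positionLabels character vector, one label per nucleotide, unique
#'   within the molecule.
#' @slot elements named character vector mapping position labels to one of
#'   \code{acceptor_stem}, \code{d_arm}, \code{anticodon_arm},
#'   \code{variable_region}, \code{t_arm}, \code{discriminator}, \code{cca}.
#'
#' @seealso [annotatedTRNA()], [loadReferences()]
#' @exportClass AnnotatedTRNA
setClass("AnnotatedTRNA",
  slots = c(id = "character", sequence = "character",
            positionLabels = "character", elements = "character"))

setValidity("AnnotatedTRNA", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (length(object@sequence) != 1L || nchar(object@sequence) == 0L)
    msg <- c(msg, "sequence must be a single non-empty string")
  if (grepl("[^ACGU]", object@sequence))
    msg <- c(msg, "sequence must be uppercase RNA (A/C/G/U)")
  if (length(object@positionLabels) != nchar(object@sequence))
    msg <- c(msg, sprintf(
      "'%s': %d position labels for a %d-nt sequence", object@id,
      length(object@positionLabels), nchar(object@sequence)))
  if (anyDuplicated(object@positionLabels))
    msg <- c(msg, sprintf("'%s': duplicated position labels", object@id))
  if (length(object@elements)) {
    if (is.null(names(object@elements)) ||
        !all(names(object@elements) %in% object@positionLabels))
      msg <- c(msg, sprintf(
        "'%s': element map refers to unknown position labels", object@id))
    if (!all(object@elements %in% STRUCTURAL_ELEMENTS))
      msg <- c(msg, sprintf(
        "'%s': unknown structural element names", object@id))
  }
  if (length(msg)) msg else TRUE
})

#' VariantLibrary: single-point substitution variants of one tRNA
#'
#' The result of [designPointVariantLibrary()]: for each mutable position,
#' the three possible base substitutions, each a full-length variant
#' sequence.  The monitored (target) position is never mutated so that the
#' RT signature there stays interpretable.
#'
#' @slot parent the parent [AnnotatedTRNA-class].
#' @slot targetLabel position label monitored for the modification signal.
#' @slot variants a \code{DataFrame} with columns \code{name} (e.g.
#'   \code{"U8A"}), \code{positionLabel}, \code{wtBase}, \code{newBase},
#'   \code{sequence}.
#'
#' @exportClass VariantLibrary
setClass("VariantLibrary",
  slots = c(parent = "AnnotatedTRNA", targetLabel = "character",
            variants = "DataFrame"))

setValidity("VariantLibrary", function(object) {
  msg <- character()
  v <- object@variants
  need <- c("name", "positionLabel", "wtBase", "newBase", "sequence")
  if (!all(need %in% colnames(v)))
    return("variants must have columns name, positionLabel, wtBase, newBase, sequence")
  if (!(object@targetLabel %in% positionLabels(object@parent)))
    msg <- c(msg, "targetLabel not found in parent position labels")
  if (anyDuplicated(v$name))
    msg <- c(msg, "variant names must be unique")
  if (any(v$wtBase == v$newBase))
    msg <- c(msg, "substituted base must differ from the wild-type base")
  if (any(v$positionLabel == object@targetLabel))
    msg <- c(msg, "variants must not mutate the target position")
  if (nrow(v)) {
    parentSeq <- trnaSequence(object@parent)
    ndiff <- mapply(function(s) {
      sum(seqChars(s) != seqChars(parentSeq))
    }, v$sequence)
    if (any(nchar(v$sequence) != nchar(parentSeq)) || any(ndiff != 1L))
      msg <- c(msg, "each variant must differ from the parent at exactly one position")
  }
  if (length(msg)) msg else TRUE
})

#' TranscriptionCassette: T7 run-off transcription template for one tRNA
#'
#' DNA template of the form promoter + (optional extra G) + tRNA + (CCA if
#' absent) + constant tail carrying the BsaI site; BsaI digestion leaves a
#' template whose run-off transcript is the tRNA ending in CCA.
#'
#' @slot id identifier of the encoded tRNA.
#' @slot dnaTemplate full cassette DNA string.
#' @slot promoterSpan,trnaSpan,tailSpan integer vectors \code{c(start, end)}
#'   (1-based, closed) delimiting the T7 promoter, the transcribed insert
#'   (including any added G and CCA) and the constant tail.
#' @slot extraGAdded TRUE when a 5' G was prepended for transcription
#'   efficiency.
#' @slot ccaAdded TRUE when the CCA terminus was appended because the input
#'   lacked it.
#'
#' @exportClass TranscriptionCassette
setClass("TranscriptionCassette",
  slots = c(id = "character", dnaTemplate = "character",
            promoterSpan = "integer", trnaSpan = "integer",
            tailSpan = "integer", extraGAdded = "logical",
            ccaAdded = "logical"))

setValidity("TranscriptionCassette", function(object) {
  msg <- character()
  if (!startsWith(object@dnaTemplate, T7_PROMOTER))
    msg <- c(msg, "cassette must start with the T7 promoter")
  ins <- substr(object@dnaTemplate, object@trnaSpan[1L], object@trnaSpan[2L])
  if (!startsWith(ins, "G") || !endsWith(ins, "CCA"))
    msg <- c(msg, "predicted transcript must start with G and end with CCA")
  if (length(msg)) msg else TRUE
})

#' MutationProfile: per-position depth and mutation rate for one reference
#'
#' @slot referenceId reference identifier.
#' @slot sampleRole one of \code{"treated"}, \code{"untreated"},
#'   \code{"subtracted"}.
#' @slot data \code{DataFrame} with columns \code{label}, \code{depth},
#'   \code{mutationCount}, \code{rate}, \code{missing}.  \code{missing} is
#'   TRUE where the depth fell below the profiling depth floor; \code{rate}
#'   is NA there.
#'
#' @exportClass MutationProfile
setClass("MutationProfile",
  slots = c(referenceId = "character", sampleRole = "character",
            data = "DataFrame"))

setValidity("MutationProfile", function(object) {
  msg <- character()
  if (!object@sampleRole %in% c("treated", "untreated", "subtracted"))
    msg <- c(msg, "sampleRole must be treated, untreated or subtracted")
  d <- object@data
  need <- c("label", "depth", "mutationCount", "rate", "missing")
  if (!all(need %in% colnames(d)))
    return("data must have columns label, depth, mutationCount, rate, missing")
  ok <- !d$missing & !is.na(d$rate)
  if (any(d$rate[ok] < 0 | d$rate[ok] > 1))
    msg <- c(msg, "rates must lie in [0, 1] where not missing")
  if (length(msg)) msg else TRUE
})

#' MRateResult: exact-match mutation rate at the target position
#'
#' Per-variant (or per-reference) read counts by target-position base and
#' the M_rate statistic: \code{M_rate = Read_Mutant / Read_Total}, where
#' \code{Read_Mutant} sums the reads carrying a non-wild-type base at the
#' target position and \code{Read_Total} sums all four base classes.
#'
#' @slot variantName variant (or reference) identifier.
#' @slot wtBase wild-type base at the target position (RNA alphabet).
#' @slot counts named numeric vector of read counts for A, C, G, U at the
#'   target position.
#' @slot readTotal,readMutant totals as above.
#' @slot mRate the raw rate; NA when undefined.
#' @slot defined FALSE when \code{readTotal} fell below the reporting floor.
#' @slot sampleRole \code{"treated"}, \code{"untreated"} or \code{"subtracted"}.
#' @slot subtractedRate background-subtracted rate (NA until
#'   [subtractMRate()] is applied).
#'
#' @exportClass MRateResult
setClass("MRateResult",
  slots = c(variantName = "character", wtBase = "character",
            counts = "numeric", readTotal = "numeric", readMutant = "numeric",
            mRate = "numeric", defined = "logical", sampleRole = "character",
            subtractedRate = "numeric"))

setValidity("MRateResult", function(object) {
  msg <- character()
  if (!identical(sort(names(object@counts)), sort(RNA_BASES)))
    msg <- c(msg, "counts must be named A, C, G, U")
  if (!object@wtBase %in% RNA_BASES)
    msg <- c(msg, "wtBase must be one of A, C, G, U")
  if (object@readMutant > object@readTotal + 1e-9)
    msg <- c(msg, "Read_Mutant cannot exceed Read_Total")
  if (object@defined && (is.na(object@mRate) ||
                         object@mRate < 0 || object@mRate > 1))
    msg <- c(msg, "a defined M_rate must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ModificationSignature: RT footprint of one modified position
#'
#' @slot referenceId reference carrying the modification.
#' @slot positionLabel modified position label.
#' @slot misincorporationRate probability that RT records a non-templated
#'   base at this position when the molecule is modified.
#' @slot substitutionSpectrum named numeric over A/C/G/U giving the
#'   distribution of the recorded base conditional on misincorporation;
#'   empty means uniform over the three non-wild-type bases.
#' @slot stopRate probability that RT terminates at this position.
#'
#' @exportClass ModificationSignature
setClass("ModificationSignature",
  slots = c(referenceId = "character", positionLabel = "character",
            misincorporationRate = "numeric", substitutionSpectrum = "numeric",
            stopRate = "numeric"))

setValidity("ModificationSignature", function(object) {
  msg <- character()
  r <- c(object@misincorporationRate, object@stopRate)
  if (any(r < 0 | r > 1))
    msg <- c(msg, "rates must lie in [0, 1]")
  sp <- object@substitutionSpectrum
  if (length(sp)) {
    if (!all(names(sp) %in% RNA_BASES) || any(sp < 0) ||
        abs(sum(sp) - 1) > 1e-6)
      msg <- c(msg, "substitutionSpectrum must be a distribution over A/C/G/U")
  }
  if (length(msg)) msg else TRUE
})

#' KineticFit: Michaelis-Menten fit result
#'
#' @slot km Michaelis constant (same units as the supplied substrate
#'   concentrations, typically micromolar).
#' @slot vmax limiting velocity (units of the supplied velocities).
#' @slot rss residual sum of squares.
#' @slot converged TRUE when the nonlinear fit converged and both
#'   parameters are identifiable.
#' @slot message diagnostic note for flagged fits.
#'
#' @exportClass KineticFit
setClass("KineticFit",
  slots = c(km = "numeric", vmax = "numeric", rss = "numeric",
            converged = "logical", message = "character"))

setValidity("KineticFit", function(object) {
  if (isTRUE(object@converged) &&
      (is.na(object@km) || is.na(object@vmax) ||
       object@km <= 0 || object@vmax <= 0))
    return("a converged fit must have Km > 0 and Vmax > 0")
  TRUE
})
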