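## Biological calls from rates: activity classification of variants,
## substrate calling across a tRNA pool, structural-element summaries.

#' Classify variant activity from subtracted M_rates
#'
#' A variant has lost methyl group acceptance activity when its
#' background-subtracted target-position rate is strictly below
#' \code{lossThreshold} (default 0.05); undefined rates give class
#' \code{"undefined"}.  The table is ordered by position index, then by
#' substituted base.
#'
#' @param mRates result of [countVariantLibrary()] (or any DataFrame with
#'   columns \code{variant}, \code{mRateSubtracted}, \code{defined}).
#' @param library the [VariantLibrary-class] the rates belong to (supplies
#'   position labels and structural elements).
#' @param lossThreshold activity-loss threshold on the subtracted rate.
#' @return \code{DataFrame} (the "variant activity table") with columns
#'   \code{variant}, \code{positionLabel}, \code{element},
#'   \code{subtractedRate}, \code{activityClass} in
#'   \code{lost/retained/undefined}.
#' @export
classifyVariants <- function(mRates, library, lossThreshold = 0.05) {
  stopifnot(is(library, "VariantLibrary"))
  v <- variants(library)
  parent <- parentTRNA(library)
  el <- structuralElements(parent)
  keep <- mRates$variant %in% c(v$name, "WT")
  m <- mRates[keep, , drop = FALSE]
  lab <- ifelse(m$variant == "WT", NA_character_,
                as.character(v$positionLabel)[match(m$variant, v$name)])
  rate <- as.numeric(m$mRateSubtracted)
  defined <- as.logical(m$defined) & !is.na(rate)
  cls <- ifelse(!defined, "undefined",
                ifelse(rate < lossThreshold, "lost", "retained"))
  out <- DataFrame(variant = as.character(m$variant), positionLabel = lab,
                   element = ifelse(is.na(lab), NA_character_,
                                    unname(el[lab])),
                   subtractedRate = rate, activityClass = cls)
  ## deterministic ordering: position index, then substituted base
  posIdx <- match(out$positionLabel, positionLabels(parent))
  newBase <- as.character(v$newBase)[match(out$variant, v$name)]
  out[order(is.na(posIdx), posIdx, newBase, method = "radix"), ,
      drop = FALSE]
}

#' Call substrate tRNAs from target-position rates
#'
#' A reference is a substrate when its background-subtracted rate at the
#' target position strictly exceeds \code{threshold} (default 0.01) and is
#' defined; references without a defined rate are reported as not
#' analyzable.
#'
#' @param rates a \code{SimpleList} of subtracted
#'   [MutationProfile-class] objects, or a named numeric vector of rates
#'   (NA = not analyzable).
#' @param targetLabel position label monitored (used with profiles).
#' @param threshold substrate-calling threshold.
#' @return \code{DataFrame} with columns \code{referenceId},
#'   \code{targetRate}, \code{isSubstrate}, \code{analyzable}.
#' @export
callSubstrates <- function(rates, targetLabel = "22", threshold = 0.01) {
  if (is(rates, "SimpleList") || (is.list(rates) && !is.numeric(rates))) {
    r <- vapply(rates, rateAt, numeric(1L), label = targetLabel)
    names(r) <- vapply(rates, referenceId, character(1L))
    rates <- r
  }
  analyzable <- !is.na(rates)
  DataFrame(referenceId = names(rates), targetRate = unname(rates),
            isSubstrate = analyzable & !is.na(rates) & rates > threshold,
            analyzable = analyzable)
}

#' Summarize a variant activity table by structural element
#'
#' Per structural element, counts the lost/retained/undefined variants and
#' lists the sensitive positions (at least one of the three substitutions
#' lost) and the critical positions (all three substitutions lost -- the
#' "critical nucleotide" criterion).  Row order of the input table does
#' not affect the result.
#'
#' @param table result of [classifyVariants()].
#' @param trna the parent [AnnotatedTRNA-class].
#' @return \code{DataFrame} with one row per element: \code{element},
#'   \code{nLost}, \code{nRetained}, \code{nUndefined},
#'   \code{sensitivePositions}, \code{criticalPositions} (comma-joined
#'   label lists, ordered by position).
#' @export
summarizeElements <- function(table, trna) {
  stopifnot(is(trna, "AnnotatedTRNA"))
  t <- table[!is.na(table$positionLabel), , drop = FALSE]
  if (nrow(t) && !all(t$positionLabel %in% positionLabels(trna)))
    stop("unknown position label(s): ",
         paste(setdiff(t$positionLabel, positionLabels(trna)),
               collapse = ", "), call. = FALSE)
  el <- structuralElements(trna)
  elems <- unique(unname(el))
  if (!length(elems))
    return(DataFrame(element = character(), nLost = integer(),
                     nRetained = integer(), nUndefined = integer(),
                     sensitivePositions = character(),
                     criticalPositions = character()))
  rows <- lapply(elems, function(e) {
    labs <- names(el)[el == e]
    te <- t[t$positionLabel %in% labs, , drop = FALSE]
    byPos <- split(as.character(te$activityClass),
                   as.character(te$positionLabel))
    sensitive <- names(byPos)[vapply(byPos, function(cl)
      any(cl == "lost"), logical(1L))]
    critical <- names(byPos)[vapply(byPos, function(cl)
      length(cl) == 3L && all(cl == "lost"), logical(1L))]
    ord <- function(x) x[order(match(x, positionLabels(trna)))]
    DataFrame(element = e,
              nLost = sum(te$activityClass == "lost"),
              nRetained = sum(te$activityClass == "retained"),
              nUndefined = sum(te$activityClass == "undefined"),
              sensitivePositions = paste(ord(sensitive), collapse = ","),
              criticalPositions = paste(ord(critical), collapse = ","))
  })
  do.call(rbind, rows)
}
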