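## Synthetic tRNA reference pools for simulation studies.

#' Generate a synthetic pool of tRNA-like references
#'
#' Produces \code{n} random tRNA-like sequences (default 70-90 nt, the
#' range of natural tRNAs) with a G start, a CCA end, an A at the monitored
#' target label and a coarse cloverleaf element partition.  Labels are
#' plain \code{"1"..."L"}; insertion labels are exercised by
#' [exampleLeuTRNA()] instead.  Intended for simulation studies, not as a
#' stand-in for genomic tRNA genes.
#'
#' @param n number of references.
#' @param seed RNG seed (integer).
#' @param lengthRange inclusive range of sequence lengths.
#' @param targetLabel label forced to \code{targetBase} in every member so
#'   that a single monitored position exists pool-wide.
#' @param targetBase base at the target label (default A, the m1A case).
#' @return named list of [AnnotatedTRNA-class] objects.
#' @examples
#' pool <- syntheticTRNAPool(3, seed = 1)
#' vapply(pool, baseAt, character(1), label = "22")
#' @export
syntheticTRNAPool <- function(n, seed, lengthRange = c(70L, 90L),
                              targetLabel = "22", targetBase = "A") {
  stopifnot(n >= 1L, lengthRange[1L] >= 68L)
  set.seed(seed)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    L <- sample(lengthRange[1L]:lengthRange[2L], 1L)
    b <- sample(RNA_BASES, L, replace = TRUE)
    b[1L] <- "G"
    b[(L - 2L):L] <- c("C", "C", "A")
    ti <- as.integer(targetLabel)
    b[ti] <- targetBase
    labels <- as.character(seq_len(L))
    el <- c(setNames(rep("acceptor_stem", 7), labels[1:7]),
            setNames(rep("d_arm", 18), labels[8:25]),
            setNames(rep("anticodon_arm", 18), labels[26:43]),
            if (L - 21L >= 44L)
              setNames(rep("variable_region", L - 64L), labels[44:(L - 21L)]),
            setNames(rep("t_arm", 17), labels[(L - 20L):(L - 4L)]),
            setNames("discriminator", labels[L - 3L]),
            setNames(rep("cca", 3), labels[(L - 2L):L]))
    id <- sprintf("synth-tRNA-%02d", k)
    out[[k]] <- annotatedTRNA(id, paste(b, collapse = ""), labels, el)
  }
  setNames(out, vapply(out, trnaId, character(1L)))
}
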