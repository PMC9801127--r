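## Self-contained simulation experiments used for validation: they tie the
## simulator, both quantification routes and the downstream statistics
## together, and are what the acceptance script and the deeper tests run.

#' Cross-validate the two mutation-rate callers on a simulated pool
#'
#' Simulates a pool of synthetic tRNA references with known target-position
#' misincorporation rates (paired treated/untreated samples), quantifies
#' the background-subtracted target-position rate per reference twice --
#' once with the alignment-based profiler ([assignReads()] +
#' [buildProfile()]) and once with exact-sequence-match counting
#' ([countExact()] + [computeMRate()]) -- and regresses one set of rates
#' on the other.
#'
#' @param seed integer seed driving every random draw.
#' @param nRefs number of pool references.
#' @param readsPerRef reads simulated per reference and sample.
#' @param errorRate per-base sequencing error.
#' @param rateRange range of the uniform draw for per-reference
#'   misincorporation rates at the target position.
#' @param targetLabel monitored position label.
#' @param minDepth depth floor for the profiler.
#' @return list with \code{rates} (data.frame: reference, true rate,
#'   profiler rate, exact-count rate), \code{fit} (the [linearFitR2()]
#'   result) and \code{rSquared}.
#' @export
methodAgreementExperiment <- function(seed, nRefs = 20L,
                                      readsPerRef = 50000L,
                                      errorRate = 0.001,
                                      rateRange = c(0, 0.8),
                                      targetLabel = "22",
                                      minDepth = 1000L) {
  pool <- syntheticTRNAPool(nRefs, seed = deriveSeed(seed, 1L))
  ids <- names(pool)
  set.seed(deriveSeed(seed, 2L))
  trueRates <- setNames(runif(nRefs, rateRange[1L], rateRange[2L]), ids)

  simulatePair <- function(treated, offset) {
    reads <- character(0)
    for (k in seq_along(ids)) {
      sig <- modificationSignature(ids[k], targetLabel, trueRates[[k]])
      sim <- simulateSample(
        poolSpec(setNames(1, ids[k])), pool[k], list(sig),
        simConfig(readsPerRef, errorRate = errorRate,
                  seed = deriveSeed(seed, offset + k)),
        treated = treated)
      names(sim$reads) <- paste0(ids[k], "_", names(sim$reads))
      reads <- c(reads, sim$reads)
    }
    reads
  }
  treatedReads <- simulatePair(TRUE, 100L)
  untreatedReads <- simulatePair(FALSE, 10000L)

  ## route A: alignment-based profiling
  profileRates <- local({
    rateOne <- function(reads, role) {
      tr <- trimAdapter(reads)
      asg <- assignReads(setNames(tr$sequence, rownames(tr)), pool)
      buildProfile(asg, pool, minDepth = minDepth, sampleRole = role)
    }
    sub <- subtractBackground(rateOne(treatedReads, "treated"),
                              rateOne(untreatedReads, "untreated"))
    vapply(ids, function(i) rateAt(sub[[i]], targetLabel), numeric(1L))
  })

  ## route B: exact-sequence-match counting (reads still carry adapters;
  ## substring mode)
  exactRates <- local({
    queries <- do.call(rbind, lapply(ids, function(i)
      targetQueries(i, trnaSequence(pool[[i]]),
                    labelIndex(pool[[i]], targetLabel))))
    ct <- countExact(treatedReads, queries)
    cu <- countExact(untreatedReads, queries)
    vapply(ids, function(i) {
      wt <- baseAt(pool[[i]], targetLabel)
      rt <- computeMRate(ct[ct$variant == i, , drop = FALSE], wt, i)
      ru <- computeMRate(cu[cu$variant == i, , drop = FALSE], wt, i)
      subtractMRate(rt, ru)@subtractedRate
    }, numeric(1L))
  })

  fit <- linearFitR2(exactRates, profileRates)
  list(rates = data.frame(reference = ids, trueRate = unname(trueRates),
                          profilerRate = unname(profileRates),
                          exactRate = unname(exactRates)),
       fit = fit, rSquared = fit$rSquared)
}

#' Parameter recovery on a simulated variant-library screen
#'
#' Designs a single-point variant library, assigns known per-variant
#' methyl group acceptance efficiencies (a designated lost set at 0, the
#' rest at 1, unless efficiencies are supplied), simulates paired
#' treated/untreated samples, quantifies by exact counting and classifies
#' activity.
#'
#' @param seed integer seed.
#' @param trna parent tRNA (default [exampleLeuTRNA()]).
#' @param mutableLabels positions to mutate (default: a compact screen over
#'   the D-arm and T-loop core).
#' @param lostPositions position labels whose three variants are set to
#'   efficiency 0 (ignored when \code{efficiencies} is given).
#' @param efficiencies optional named per-variant efficiencies.
#' @param signatureRate misincorporation rate at full activity (default
#'   0.79, the saturated m1A-type signal).
#' @param readsPerVariantSim reads per variant and sample.
#' @param errorRate per-base sequencing error.
#' @param lossThreshold activity-loss threshold.
#' @return list with \code{library}, \code{efficiencies}, \code{mRates}
#'   (the [countVariantLibrary()] table), \code{activity} (the
#'   [classifyVariants()] table) and \code{expectedRate} (per-variant
#'   efficiency times signature rate).
#' @export
variantRecoveryExperiment <- function(seed,
                                      trna = exampleLeuTRNA(),
                                      mutableLabels = c("8", "13", "14",
                                                        "18", "19", "54",
                                                        "55", "7", "34",
                                                        "35", "73"),
                                      lostPositions = c("8", "14", "18",
                                                        "55"),
                                      efficiencies = NULL,
                                      signatureRate = 0.79,
                                      readsPerVariantSim = 4000L,
                                      errorRate = 0,
                                      lossThreshold = 0.05) {
  lib <- designPointVariantLibrary(trna, targetLabel = "22",
                                   mutableLabels = mutableLabels)
  v <- variants(lib)
  if (is.null(efficiencies)) {
    efficiencies <- setNames(rep(1, nrow(v)), v$name)
    efficiencies[v$positionLabel %in% lostPositions] <- 0
  }
  sig <- modificationSignature("parent", "22", signatureRate)
  n <- (nrow(v) + 1L) * readsPerVariantSim
  simT <- simulateVariantLibrarySample(
    lib, sig, efficiencies,
    simConfig(n, errorRate = errorRate, seed = deriveSeed(seed, 31L)),
    treated = TRUE)
  simU <- simulateVariantLibrarySample(
    lib, sig, efficiencies,
    simConfig(n, errorRate = errorRate, seed = deriveSeed(seed, 32L)),
    treated = FALSE)
  mr <- countVariantLibrary(simT$reads, simU$reads, lib)
  act <- classifyVariants(mr, lib, lossThreshold = lossThreshold)
  eff <- simT$efficiency
  list(library = lib, efficiencies = eff, mRates = mr, activity = act,
       expectedRate = eff * signatureRate)
}

#' Recover Michaelis-Menten parameters from noisy synthetic data
#'
#' Generates initial-velocity data from known parameters with
#' multiplicative Gaussian noise and refits; the workhorse behind the
#' kinetics validation.
#'
#' @param km,vmax true parameters.
#' @param S substrate concentrations.
#' @param cv noise coefficient of variation (default 0.03).
#' @param nrep replicates (default 3).
#' @param seed RNG seed.
#' @return a [KineticFit-class].
#' @export
kineticRecoveryExperiment <- function(km, vmax, S, cv = 0.03, nrep = 3L,
                                      seed = 1L) {
  d <- simulateMichaelisMenten(S, km, vmax, cv = cv, nrep = nrep,
                               seed = seed)
  fitMichaelisMenten(d)
}
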