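test_that("adapter trimming matches a brute-force suffix/prefix oracle", {
  ad <- "CTGTAGGCACCATCAAT"
  expect_identical(trimAdapter(paste0("ACGT", ad, "GG"), ad)$sequence, "ACGT")

  ## 3'-terminal partial adapter
  r <- paste0("ACGTACGTAC", substr(ad, 1, 5))
  got <- trimAdapter(r, ad, minOverlap = 5)
  expect_identical(got$sequence, "ACGTACGTAC")
  expect_true(got$adapterFound)

  ## below the overlap floor: untouched and flagged absent
  r2 <- paste0("ACGTACGTAC", substr(ad, 1, 4))
  got2 <- trimAdapter(r2, ad, minOverlap = 5)
  expect_identical(got2$sequence, r2)
  expect_false(got2$adapterFound)

  ## randomized agreement with the brute-force oracle
  set.seed(21)
  for (i in 1:50) {
    body <- paste(sample(c("A", "C", "G", "T"), sample(10:40, 1), TRUE),
                  collapse = "")
    read <- switch(sample(3, 1),
                   paste0(body, ad, "AC"),
                   paste0(body, substr(ad, 1, sample(3:16, 1))),
                   body)
    expect_identical(trimAdapter(read, ad, 5)$sequence,
                     bruteTrim(read, ad, 5))
  }
})

test_that("read assignment is exact, tie-aware and matches pairwiseAlignment scores", {
  pool <- syntheticTRNAPool(6, seed = 22)
  ids <- names(pool)
  refDna <- vapply(pool, function(t) chartr("U", "T", trnaSequence(t)),
                   character(1))
  ## identical read: assigned with full score
  asg <- assignReads(setNames(refDna[3], "r1"), pool)
  expect_identical(asg$referenceId, ids[3])
  expect_equal(asg$score, unname(nchar(refDna[3])))

  ## read equidistant from two references -> unassigned
  twin <- c(a = "ACGTACGTACGTACGTACGT", b = "ACGTACGTACGTACGTACGA")
  read <- "ACGTACGTACGTACGTACGC"     # 1 mismatch to each
  asg2 <- assignReads(setNames(read, "tie"), twin)
  expect_true(is.na(asg2$referenceId))

  ## low-score junk read -> unassigned
  junk <- paste(rep("A", 60), collapse = "")
  asg3 <- assignReads(setNames(junk, "junk"), pool)
  expect_true(is.na(asg3$referenceId))

  ## scores agree with the Biostrings semi-global oracle on mutated reads
  set.seed(23)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    k <- sample(6, 1)
    r <- refDna[k]
    p <- sample(nchar(r), 2)
    for (q in p) substr(r, q, q) <- sample(c("A", "C", "G", "T"), 1)
    if (i %% 3 == 0) r <- substr(r, 5, nchar(r))   # truncated read
    asg <- assignReads(setNames(r, "m"), pool)
    oracle <- max(vapply(refDna, function(ref)
      Biostrings::pairwiseAlignment(r, ref, type = "global-local",
                                    substitutionMatrix = mat,
                                    gapOpening = 0, gapExtension = 2,
                                    scoreOnly = TRUE), numeric(1)))
    expect_equal(asg$score, oracle)
  }

  expect_error(assignReads("ACGT", character()), "empty reference")
})

test_that("error-free mixture assignment recovers the simulated composition", {
  pool <- syntheticTRNAPool(4, seed = 24)
  ids <- names(pool)
  ps <- poolSpec(setNames(c(4, 3, 2, 1), ids))
  sim <- simulateSample(ps, pool, list(), simConfig(1000, seed = 25), FALSE)
  tr <- trimAdapter(sim$reads)
  asg <- assignReads(setNames(tr$sequence, rownames(tr)), pool)
  got <- table(factor(asg$referenceId, levels = ids))
  truth <- table(factor(sim$readInfo$reference, levels = ids))
  expect_equal(as.integer(got), as.integer(truth))
  expect_equal(sum(!is.na(asg$referenceId)), 1000)
})

test_that("profiles tally depth and mutations with the depth floor per position", {
  pool <- syntheticTRNAPool(1, seed = 26)
  id <- names(pool)
  ps <- poolSpec(setNames(1, id), 1)
  sig <- modificationSignature(id, "22", 0.3)
  n <- 50000
  sim <- simulateSample(ps, pool, list(sig), simConfig(n, seed = 27), TRUE)
  tr <- trimAdapter(sim$reads)
  asg <- assignReads(setNames(tr$sequence, rownames(tr)), pool)
  prof <- buildProfile(asg, pool, minDepth = 1000)[[id]]
  d <- profileData(prof)
  expect_true(all(d$depth == n))
  expect_false(any(d$missing))
  r22 <- rateAt(prof, "22")
  expect_lt(abs(r22 - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  expect_true(all(d$rate[d$label != "22"] == 0))

  ## 500 reads: every position below the default depth floor
  sim2 <- simulateSample(ps, pool, list(), simConfig(500, seed = 28), FALSE)
  tr2 <- trimAdapter(sim2$reads)
  asg2 <- assignReads(setNames(tr2$sequence, rownames(tr2)), pool)
  prof2 <- buildProfile(asg2, pool, minDepth = 1000)
  expect_true(all(profileData(prof2[[id]])$missing))
  expect_identical(S4Vectors::metadata(prof2)$notAnalyzable, id)
})

test_that("background subtraction clamps at zero and propagates missingness", {
  mk <- function(rates, missing, role) {
    new("MutationProfile", referenceId = "r", sampleRole = role,
        data = S4Vectors::DataFrame(label = as.character(seq_along(rates)),
                                    depth = 5000L, mutationCount = 0L,
                                    rate = ifelse(missing, NA_real_, rates),
                                    missing = missing))
  }
  tr <- mk(c(0.80, 0.00, 0.50), c(FALSE, FALSE, FALSE), "treated")
  un <- mk(c(0.01, 0.02, 0.10), c(FALSE, FALSE, TRUE), "untreated")
  sub <- subtractBackground(tr, un)
  d <- profileData(sub)
  expect_equal(d$rate[1], 0.79)
  expect_equal(d$rate[2], 0)        # clamped
  expect_true(is.na(d$rate[3]) && d$missing[3])
  expect_identical(sampleRole(sub), "subtracted")

  un2 <- mk(c(0, 0), c(FALSE, FALSE), "untreated")
  expect_error(subtractBackground(tr, un2), "label mismatch")
})

test_that("modification-site calling uses a strict threshold", {
  mk <- function(rates) {
    new("MutationProfile", referenceId = "r", sampleRole = "subtracted",
        data = S4Vectors::DataFrame(label = as.character(seq_along(rates)),
                                    depth = 5000L, mutationCount = NA_integer_,
                                    rate = rates,
                                    missing = rep(FALSE, length(rates))))
  }
  called <- callModifiedPositions(mk(c(0.011, 0.01, 0.0, 0.5)), 0.01)
  expect_identical(as.character(called$label), c("1", "4"))
  expect_equal(nrow(callModifiedPositions(mk(rep(0, 5)), 0.01)), 0)
})

test_that("called positions on simulator output recover the signature set exactly at error 0", {
  pool <- syntheticTRNAPool(3, seed = 29)
  ids <- names(pool)
  ps <- poolSpec(setNames(rep(1, 3), ids), 1)
  sigs <- list(modificationSignature(ids[1], "22", 0.4),
               modificationSignature(ids[2], "9", 0.15))
  run <- function(treated, seed) {
    sim <- simulateSample(ps, pool, sigs, simConfig(9000, seed = seed),
                          treated)
    tr <- trimAdapter(sim$reads)
    asg <- assignReads(setNames(tr$sequence, rownames(tr)), pool)
    buildProfile(asg, pool, minDepth = 500,
                 sampleRole = if (treated) "treated" else "untreated")
  }
  sub <- subtractBackground(run(TRUE, 30), run(FALSE, 31))
  called <- callModifiedPositions(sub, 0.01)
  got <- paste(called$reference, called$label)
  expect_setequal(got, c(paste(ids[1], "22"), paste(ids[2], "9")))
})
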