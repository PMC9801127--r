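test_that("seeded simulation is reproducible byte-for-byte", {
  pool <- syntheticTRNAPool(2, seed = 3)
  ps <- poolSpec(setNames(c(2, 1), names(pool)), 1)
  sig <- modificationSignature(names(pool)[1], "22", 0.5, stopRate = 0.1)
  cfg <- simConfig(500, errorRate = 0.01, seed = 17)
  a <- simulateSample(ps, pool, list(sig), cfg, TRUE)
  b <- simulateSample(ps, pool, list(sig), cfg, TRUE)
  expect_identical(a$reads, b$reads)

  fa <- tempfile(fileext = ".fastq")
  fb <- tempfile(fileext = ".fastq")
  writeFastq(a, fa); writeFastq(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  ## FASTQ round-trip preserves sequences
  expect_identical(unname(readFastq(fa)), unname(a$reads))
})

test_that("error-free unmodified reads are exact reference + adapter", {
  pool <- syntheticTRNAPool(2, seed = 4)
  ps <- poolSpec(setNames(c(1, 1), names(pool)))
  sim <- simulateSample(ps, pool, list(), simConfig(300, seed = 5), FALSE)
  refDna <- vapply(pool, function(t)
    chartr("U", "T", trnaSequence(t)), character(1))
  expected <- paste0(refDna[sim$readInfo$reference], "CTGTAGGCACCATCAAT")
  expect_identical(unname(sim$reads), unname(expected))
})

test_that("misincorporation fractions follow the binomial sampling oracle", {
  pool <- syntheticTRNAPool(1, seed = 6)
  id <- names(pool)
  ps <- poolSpec(setNames(1, id), 1)
  sig <- modificationSignature(id, "22", 0.5)
  n <- 100000
  sim <- simulateSample(ps, pool, list(sig), simConfig(n, seed = 8), TRUE)
  wt <- chartr("U", "T", baseAt(pool[[1]], "22"))
  obs <- mean(substr(sim$reads, 22, 22) != wt)
  tol <- 3 * sqrt(0.5 * 0.5 / n)
  expect_lt(abs(obs - 0.5), tol)

  ## truth table records the expected rate
  expect_equal(sim$truth$expected_rate[sim$truth$label == "22"], 0.5)
})

test_that("empirical per-position rates converge to the truth table", {
  pool <- syntheticTRNAPool(2, seed = 9)
  ids <- names(pool)
  ps <- poolSpec(setNames(c(1, 1), ids), c(0.8, 1))
  sigs <- list(modificationSignature(ids[1], "9", 0.6),
               modificationSignature(ids[2], "22", 0.79))
  e <- 0.002
  n <- 60000
  sim <- simulateSample(ps, pool, sigs, simConfig(n, errorRate = e, seed = 10),
                        TRUE)
  for (k in 1:2) {
    sel <- sim$readInfo$reference == ids[k]
    lab <- c("9", "22")[k]
    i <- match(lab, positionLabels(pool[[k]]))
    wt <- chartr("U", "T", baseAt(pool[[k]], lab))
    obs <- mean(substr(sim$reads[sel], i, i) != wt)
    expected <- sim$truth$expected_rate[sim$truth$reference == ids[k] &
                                          sim$truth$label == lab]
    tol <- 4 * sqrt(expected * (1 - expected) / sum(sel))
    expect_lt(abs(obs - expected), tol)
  }
})

test_that("untreated samples show only sequencing error", {
  pool <- syntheticTRNAPool(1, seed = 11)
  id <- names(pool)
  sig <- modificationSignature(id, "22", 0.79, stopRate = 0.5)
  e <- 0.005
  n <- 50000
  sim <- simulateSample(poolSpec(setNames(1, id)), pool, list(sig),
                        simConfig(n, errorRate = e, seed = 12), FALSE)
  ## no truncation in untreated reads (stops act only on modified molecules)
  expect_true(all(sim$readInfo$start == 1))
  wt <- chartr("U", "T", baseAt(pool[[1]], "22"))
  obs <- mean(substr(sim$reads, 22, 22) != wt)
  expect_lt(abs(obs - e), 4 * sqrt(e * (1 - e) / n))
  expect_equal(unique(sim$truth$expected_rate), e)
})

test_that("RT stops truncate reads retaining the tRNA 3' side", {
  pool <- syntheticTRNAPool(1, seed = 13)
  id <- names(pool)
  sig <- modificationSignature(id, "22", 0, stopRate = 1)
  sim <- simulateSample(poolSpec(setNames(1, id), 1), pool, list(sig),
                        simConfig(500, seed = 14), TRUE)
  expect_true(all(sim$readInfo$start == 23))
  L <- nchar(trnaSequence(pool[[1]]))
  ref3 <- chartr("U", "T", substr(trnaSequence(pool[[1]]), 23, L))
  expect_true(all(sim$reads == paste0(ref3, "CTGTAGGCACCATCAAT")))
})

test_that("variant-library samples scale the target signature by efficiency", {
  t <- tiny76()
  lib <- designPointVariantLibrary(t, "22", c("8", "30"))
  sig <- modificationSignature("x", "22", 0.8)
  v <- variants(lib)$name
  eff <- setNames(c(1, 0.1, rep(1, 4)), v)
  n <- 60000
  sim <- simulateVariantLibrarySample(lib, sig, eff,
                                      simConfig(n, seed = 15), TRUE,
                                      includeWT = FALSE)
  for (k in 1:2) {
    sel <- sim$readInfo$reference == v[k]
    obs <- mean(substr(sim$reads[sel], 22, 22) != "A")
    expected <- c(0.8, 0.08)[k]
    tol <- 4 * sqrt(expected * (1 - expected) / sum(sel))
    expect_lt(abs(obs - expected), tol)
  }

  ## efficiency 0 everywhere: treated target column matches untreated
  eff0 <- setNames(rep(0, length(v)), v)
  simT <- simulateVariantLibrarySample(lib, sig, eff0,
                                       simConfig(5000, seed = 16), TRUE,
                                       includeWT = FALSE)
  expect_true(all(substr(simT$reads, 22, 22) == "A"))
})

test_that("simulator rejects invalid input", {
  pool <- syntheticTRNAPool(1, seed = 17)
  expect_error(simConfig(0), "positive")
  expect_error(simulateSample(poolSpec(setNames(1, names(pool))), pool,
                              list(modificationSignature("ghost", "22", 0.5)),
                              simConfig(10), TRUE),
               "ghost")
})
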