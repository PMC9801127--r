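test_that("activity classification applies a strict loss threshold", {
  t <- exampleLeuTRNA()
  lib <- designPointVariantLibrary(t, "22", c("8", "18"))
  v <- variants(lib)$name
  mr <- S4Vectors::DataFrame(
    variant = v,
    mRateSubtracted = c(0.04, 0.05, 0.79, 0.001, NA, 0.6),
    defined = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  act <- classifyVariants(mr, lib)
  cls <- setNames(act$activityClass, act$variant)
  expect_identical(cls[[v[1]]], "lost")        # 0.04 < 0.05
  expect_identical(cls[[v[2]]], "retained")    # exactly 0.05: strict
  expect_identical(cls[[v[3]]], "retained")
  expect_identical(cls[[v[5]]], "undefined")
  expect_identical(unique(act$element[act$positionLabel == "8"]), "d_arm")
  ## ordered by position then base
  expect_identical(as.character(act$variant), v)
})

test_that("substrate calling is strict and reports non-analyzable references", {
  rates <- c(r1 = 0.5, r2 = 0.011, r3 = 0.01, r4 = 0, r5 = NA)
  sc <- callSubstrates(rates, threshold = 0.01)
  expect_identical(sc$referenceId[sc$isSubstrate], c("r1", "r2"))
  expect_false(sc$analyzable[5])
  expect_false(sc$isSubstrate[5])
})

test_that("substrate calls on a simulated pool recover the designated set", {
  nRefs <- 8
  pool <- syntheticTRNAPool(nRefs, seed = 41)
  ids <- names(pool)
  substrates <- ids[c(1, 3, 6)]
  ps <- poolSpec(setNames(rep(1, nRefs), ids), 1)
  sigs <- lapply(substrates, function(i)
    modificationSignature(i, "22", 0.6))
  run <- function(treated, seed) {
    sim <- simulateSample(ps, pool, sigs, simConfig(24000, seed = seed),
                          treated)
    tr <- trimAdapter(sim$reads)
    asg <- assignReads(setNames(tr$sequence, rownames(tr)), pool)
    buildProfile(asg, pool, minDepth = 500,
                 sampleRole = if (treated) "treated" else "untreated")
  }
  sub <- subtractBackground(run(TRUE, 42), run(FALSE, 43))
  sc <- callSubstrates(sub, "22", 0.01)
  expect_setequal(sc$referenceId[sc$isSubstrate], substrates)

  ## all-zero efficiencies: nothing called
  run0 <- function(seed, role)
    subtractBackground(run(FALSE, seed), run(FALSE, seed + 1))
  sc0 <- callSubstrates(run0(44, "x"), "22", 0.01)
  expect_equal(sum(sc0$isSubstrate), 0)
})

test_that("element summaries report sensitive and critical nucleotides, invariant to row order", {
  t <- exampleLeuTRNA()
  lib <- designPointVariantLibrary(t, "22")
  v <- variants(lib)
  ## rule-based fixture: lost iff the position sits in the T-arm
  el <- structuralElements(t)
  lost <- unname(el[as.character(v$positionLabel)]) == "t_arm"
  mr <- S4Vectors::DataFrame(variant = v$name,
                             mRateSubtracted = ifelse(lost, 0.001, 0.7),
                             defined = TRUE)
  act <- classifyVariants(mr, lib)
  rep1 <- summarizeElements(act, t)
  tarm <- as.data.frame(rep1[rep1$element == "t_arm", ])
  expect_equal(tarm$nLost, sum(lost))
  expect_equal(tarm$nRetained, 0)
  tArmLabels <- names(el)[el == "t_arm"]
  expect_identical(tarm$criticalPositions, paste(tArmLabels, collapse = ","))
  others <- as.data.frame(rep1[rep1$element != "t_arm", ])
  expect_true(all(others$nLost == 0))
  expect_true(all(others$criticalPositions == ""))

  ## permuting rows changes nothing
  set.seed(45)
  act2 <- act[sample(nrow(act)), ]
  expect_identical(as.data.frame(summarizeElements(act2, t)),
                   as.data.frame(rep1))

  ## partial loss at a position is sensitive but not critical
  mr2 <- mr
  mr2$mRateSubtracted[mr2$variant == "U8A"] <- 0.001
  act3 <- classifyVariants(mr2, lib)
  rep3 <- summarizeElements(act3, t)
  darm <- as.data.frame(rep3[rep3$element == "d_arm", ])
  expect_identical(darm$sensitivePositions, "8")
  expect_identical(darm$criticalPositions, "")

  ## unknown labels are rejected
  bad <- act
  bad$positionLabel[1] <- "999"
  expect_error(summarizeElements(bad, t), "unknown")

  ## empty table: all-zero report
  rep0 <- summarizeElements(act[0, ], t)
  expect_true(all(rep0$nLost == 0 & rep0$nRetained == 0))
})

test_that("a simulated recognition screen recovers the designated critical set exactly", {
  res <- variantRecoveryExperiment(46, readsPerVariantSim = 1500)
  rep <- summarizeElements(res$activity, exampleLeuTRNA())
  critical <- unlist(strsplit(rep$criticalPositions[rep$criticalPositions != ""],
                              ","))
  expect_setequal(critical, c("8", "14", "18", "55"))
})
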