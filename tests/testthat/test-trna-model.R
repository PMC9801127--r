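test_that("references round-trip through FASTA + annotation and are normalized", {
  trnas <- list(tiny76("a"), tiny76("b"), exampleLeuTRNA())
  fx <- writeRefFixture(trnas)
  got <- loadReferences(fx$fasta, fx$annotation)
  expect_length(got, 3)
  expect_identical(trnaSequence(got[["a"]]), trnaSequence(trnas[[1]]))
  expect_identical(positionLabels(got[["tRNA-Leu-GAG-like"]]),
                   positionLabels(exampleLeuTRNA()))
  expect_mapequal(as.list(structuralElements(got[["tRNA-Leu-GAG-like"]])),
                  as.list(structuralElements(exampleLeuTRNA())))

  ## DNA input is normalized to RNA
  t <- annotatedTRNA("dna", "GGTACT")
  expect_identical(trnaSequence(t), "GGUACU")
})

test_that("annotation/sequence length mismatches are hard errors naming the record", {
  t <- tiny76("broken")
  fx <- writeRefFixture(list(t))
  writeLines(readLines(fx$annotation)[-2], fx$annotation)  # drop one row
  expect_error(loadReferences(fx$fasta, fx$annotation), "broken")

  expect_error(annotatedTRNA("x", "ACGU", c("1", "2", "3")), "position labels")
  expect_error(annotatedTRNA("x", "ACGU", c("1", "1", "2", "3")), "duplicated")
  expect_error(annotatedTRNA("x", "ACGU", elements = c(`99` = "d_arm")),
               "unknown position")
})

test_that("point-variant library matches brute-force enumeration and arithmetic", {
  ## tiny case: parent GAC, all three positions mutable, external target
  t <- annotatedTRNA("mini", "GACA", c("1", "2", "3", "t"))
  lib <- designPointVariantLibrary(t, targetLabel = "t",
                                   mutableLabels = c("1", "2", "3"))
  v <- variants(lib)
  oracle <- bruteForceVariants("GACA", 1:3)
  expect_equal(nrow(v), length(oracle))          # 9
  expect_identical(as.character(v$sequence),
                   vapply(oracle, `[[`, character(1), "seq"))
  expect_identical(as.character(v$newBase),
                   vapply(oracle, `[[`, character(1), "new"))

  ## one mutable U position gives the three non-U substitutions
  t2 <- annotatedTRNA("u", "GUCA", c("1", "2", "3", "t"))
  lib2 <- designPointVariantLibrary(t2, "t", "2")
  expect_identical(as.character(variants(lib2)$name),
                   c("U2A", "U2C", "U2G"))

  ## size law on random inputs
  set.seed(99)
  for (rep in 1:5) {
    L <- sample(20:40, 1)
    s <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
    t3 <- annotatedTRNA("r", s)
    mut <- sample(as.character(seq_len(L - 1)), sample(3:10, 1))
    lib3 <- designPointVariantLibrary(t3, as.character(L), mut)
    expect_equal(nrow(variants(lib3)), 3 * length(mut))
    ## reverting the single substitution reconstructs the parent
    v3 <- variants(lib3)
    k <- sample(nrow(v3), 1)
    i <- match(v3$positionLabel[k], positionLabels(t3))
    s2 <- v3$sequence[k]
    substr(s2, i, i) <- v3$wtBase[k]
    expect_identical(s2, s)
  }

  expect_error(designPointVariantLibrary(t, "t", c("1", "t")), "target")
  expect_error(designPointVariantLibrary(t, "t", c("1", "nope")), "unknown")
})

test_that("default mutable set excludes target and CCA, reproducing a 240-variant screen", {
  ## an 84-label tRNA with target + 3 CCA labels excluded leaves 80
  ## mutable positions and a 240-variant library
  set.seed(84)
  b <- sample(c("A", "C", "G", "U"), 84, TRUE)
  b[1] <- "G"; b[82:84] <- c("C", "C", "A"); b[22] <- "A"
  t <- annotatedTRNA("t84", paste(b, collapse = ""))
  lib <- designPointVariantLibrary(t, targetLabel = "22")
  expect_equal(nrow(variants(lib)), 240)
  expect_false("22" %in% variants(lib)$positionLabel)
})

test_that("T7 cassettes carry the fixed flanks and yield G...CCA transcripts", {
  t <- tiny76()
  cas <- buildT7Cassette(t)
  expect_false(cas@extraGAdded)
  expect_false(cas@ccaAdded)
  ## fixed flanks: 20 nt promoter + 76 nt insert + 38 nt tail
  expect_equal(nchar(dnaTemplate(cas)), 76 + 20 + 38)
  expect_identical(predictedTranscript(cas), trnaSequence(t))

  ## A-starting tRNA gets an extra G
  t2 <- annotatedTRNA("a-start", paste0("A", substr(trnaSequence(t), 2, 76)))
  cas2 <- buildT7Cassette(t2)
  expect_true(cas2@extraGAdded)
  expect_identical(substr(predictedTranscript(cas2), 1, 1), "G")
  expect_identical(predictedTranscript(cas2),
                   paste0("G", trnaSequence(t2)))

  ## property: transcripts always start with G and end with CCA
  set.seed(7)
  for (rep in 1:10) {
    L <- sample(70:90, 1)
    s <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
    tr <- predictedTranscript(buildT7Cassette(annotatedTRNA("r", s)))
    expect_identical(substr(tr, 1, 1), "G")
    expect_identical(substr(tr, nchar(tr) - 2, nchar(tr)), "CCA")
  }
})

test_that("library capacity arithmetic matches the screen design", {
  expect_equal(doubleVariantCount(240), 240 * 239)
  expect_equal(readsPerVariant(10e6, 240), 41666)
  t <- tiny76()
  lib <- designPointVariantLibrary(t, "22", c("1", "2"))
  expect_equal(doubleVariantCount(lib), 6 * 5)
})
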