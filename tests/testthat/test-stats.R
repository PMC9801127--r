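test_that("noiseless Michaelis-Menten data are refit to at least 4 significant digits", {
  S <- c(0.5, 1, 2, 5, 10, 20)
  d <- simulateMichaelisMenten(S, km = 4.6, vmax = 0.003, cv = 0, nrep = 3)
  fit <- fitMichaelisMenten(d)
  expect_true(converged(fit))
  expect_lt(abs(km(fit) - 4.6) / 4.6, 1e-4)
  expect_lt(abs(vmax(fit) - 0.003) / 0.003, 1e-4)

  S2 <- c(5, 10, 20, 40, 80, 160)
  fit2 <- fitMichaelisMenten(simulateMichaelisMenten(S2, 30, 0.0025))
  expect_lt(abs(km(fit2) - 30) / 30, 1e-4)
})

test_that("optimizer minimum agrees with a brute-force grid-search oracle", {
  S <- c(1, 2, 4, 8, 16, 32)
  set.seed(51)
  v <- 0.01 * S / (5 + S) * (1 + rnorm(6, 0, 0.05))
  fit <- fitMichaelisMenten(data.frame(S = S, v = v))
  rssOf <- function(Km, Vmax) sum((v - Vmax * S / (Km + S))^2)
  grid <- expand.grid(Km = seq(1, 15, by = 0.02),
                      Vmax = seq(0.005, 0.02, by = 5e-5))
  grid$rss <- mapply(rssOf, grid$Km, grid$Vmax)
  bestGrid <- grid[which.min(grid$rss), ]
  expect_lt(abs(km(fit) - bestGrid$Km), 0.05)
  expect_lt(abs(vmax(fit) - bestGrid$Vmax), 2e-4)
  expect_lte(fit@rss, bestGrid$rss + 1e-12)
})

test_that("Michaelis-Menten fitting is scale-equivariant and flags degenerate designs", {
  S <- c(0.5, 1, 2, 5, 10, 20)
  d <- simulateMichaelisMenten(S, 4.6, 0.003, cv = 0.03, nrep = 3, seed = 52)
  f1 <- fitMichaelisMenten(d)
  d2 <- d; d2$v <- d2$v * 1000
  f2 <- fitMichaelisMenten(d2)
  expect_equal(km(f2), km(f1), tolerance = 1e-6)
  expect_equal(vmax(f2), 1000 * vmax(f1), tolerance = 1e-6)

  ## saturated-only design: Km unidentifiable, flagged not raised
  flat <- data.frame(S = c(100, 200, 400), v = c(0.003, 0.003, 0.003))
  ff <- fitMichaelisMenten(flat)
  expect_false(converged(ff))

  expect_error(fitMichaelisMenten(data.frame(S = c(1, 1, 1), v = 1:3)),
               "distinct")
  expect_warning(fitMichaelisMenten(
    data.frame(S = c(1, 2, 4, 8), v = c(-0.001, 0.01, 0.02, 0.025))),
    "clipped")
})

test_that("noisy kinetic recovery keeps Km within 15 percent over seeds", {
  kms <- vapply(1:20, function(s)
    km(kineticRecoveryExperiment(4.6, 0.003, c(0.5, 1, 2, 5, 10, 20),
                                 cv = 0.03, nrep = 3, seed = s)),
    numeric(1))
  expect_lt(abs(median(kms) - 4.6) / 4.6, 0.15)
  expect_gt(mean(abs(kms - 4.6) / 4.6 < 0.15), 0.8)
})

test_that("linear fits reproduce hand-computed normal equations and edge cases", {
  f <- linearFitR2(1:4, 2 * (1:4) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$rSquared, 1)

  ## zero covariance: slope 0, r2 0
  f0 <- linearFitR2(c(-1, 0, 1), c(1, 0, 1))
  expect_equal(f0$slope, 0)
  expect_equal(f0$rSquared, 0)

  ## 4-point dataset against hand-solved normal equations:
  ## x = (0,1,2,3), y = (1,3,2,5): slope = Sxy/Sxx = 5.5/5 = 1.1,
  ## intercept = ybar - slope*xbar = 2.75 - 1.65 = 1.1
  f4 <- linearFitR2(0:3, c(1, 3, 2, 5))
  expect_equal(f4$slope, 1.1)
  expect_equal(f4$intercept, 1.1)
  ssRes <- sum((c(1, 3, 2, 5) - (1.1 + 1.1 * (0:3)))^2)
  ssTot <- sum((c(1, 3, 2, 5) - 2.75)^2)
  expect_equal(f4$rSquared, 1 - ssRes / ssTot)

  expect_error(linearFitR2(c(1, 1, 1), 1:3), "constant")
  expect_error(linearFitR2(1:3, 1:2), "equal length")
})

test_that("group comparison is a two-sided Welch test with sane degenerate behavior", {
  expect_equal(compareGroups(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5)), 1)
  expect_equal(compareGroups(c(0.5, 0.5), c(0.7, 0.7)), 0)

  p <- compareGroups(c(0.79, 0.79, 0.79) + c(-1e-4, 0, 1e-4),
                     c(0.10, 0.11, 0.09))
  expect_lt(p, 1e-4)
  expect_equal(p, t.test(c(0.7899, 0.79, 0.7901),
                         c(0.10, 0.11, 0.09))$p.value)

  ## agreement with a permutation oracle within Monte-Carlo error
  set.seed(53)
  a <- c(0.30, 0.35, 0.28, 0.40, 0.33)
  b <- c(0.45, 0.50, 0.42, 0.48, 0.52)
  pW <- compareGroups(a, b)
  stat <- function(x, y) abs(mean(x) - mean(y))
  obs <- stat(a, b)
  pooled <- c(a, b)
  perm <- replicate(4000, {
    idx <- sample(10, 5)
    stat(pooled[idx], pooled[-idx]) >= obs - 1e-12
  })
  pPerm <- mean(perm)
  expect_lt(abs(pW - pPerm), 0.02 + 3 * sqrt(pPerm * (1 - pPerm) / 4000))

  expect_error(compareGroups(1, c(1, 2)), "at least 2")
})

test_that("the methyl-transfer distance is the difference of the two measured distances", {
  expect_equal(methylTransferDistance(9.4, 1.8), 7.6)
  expect_error(methylTransferDistance(1, 2))
})
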