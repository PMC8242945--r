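test_that("TPM columns sum to one million and follow the formula", {
  m1 <- matrix(5, 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(computeTPM(m1, 123)[1, ]), c(1e6, 1e6))

  m2 <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- computeTPM(m2, c(a = 100, b = 200))
  expect_equal(unname(tpm[, 1]), c(666666.67, 333333.33),
               tolerance = 1e-6)

  set.seed(1)
  m3 <- matrix(rpois(60, 40), 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  len <- runif(10, 200, 3000)
  tpm3 <- computeTPM(m3, len)
  expect_equal(unname(colSums(tpm3)), rep(1e6, 6), tolerance = 1e-6)

  # scale invariance within a column
  m4 <- m3; m4[, 2] <- m3[, 2] * 2
  expect_equal(computeTPM(m4, len)[, 2], tpm3[, 2])
})

test_that("TPM errors are informative", {
  m <- matrix(c(1, 0, 2, 0), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  m[, 2] <- 0
  expect_error(computeTPM(m, c(a = 100, b = 100)), "s2")
  expect_error(computeTPM(m, c(a = -1, b = 100)), "positive")
})

test_that("TMM factors are unity for identical and scaled libraries", {
  set.seed(2)
  a <- rpois(200, 50) + 1
  two <- cbind(s1 = a, s2 = a)
  expect_equal(unname(computeTMMFactors(two)), c(1, 1))
  # composition identical, library size 3x: absorbed by the M definition
  three <- cbind(s1 = a, s2 = 3 * a)
  expect_equal(unname(computeTMMFactors(three)), c(1, 1))
})

test_that("TMM matches the straight-line oracle on small instances", {
  set.seed(3)
  # <= 20 x 4 instances (the untrimmed fallback regime)
  for (i in 1:20) {
    nG <- sample(12:20, 1); nS <- sample(2:4, 1)
    m <- matrix(rpois(nG * nS, lambda = runif(nG, 5, 500)) + 1, nG, nS,
                dimnames = list(paste0("g", seq_len(nG)),
                                paste0("s", seq_len(nS))))
    m[1, 1] <- m[1, 1] * sample(5:20, 1)   # one inflated gene
    f <- suppressWarnings(computeTMMFactors(m))
    o <- oracleTMM(m)
    expect_equal(f, o, tolerance = 1e-12)
  }
  # larger instances where the double trim is active
  for (i in 1:10) {
    m <- matrix(rnbinom(200 * 4, mu = runif(200, 20, 2000), size = 3) + 1,
                200, 4, dimnames = list(paste0("g", 1:200),
                                        paste0("s", 1:4)))
    expect_equal(computeTMMFactors(m), oracleTMM(m), tolerance = 1e-12)
  }
})

test_that("TMM agrees with an established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(4)
  m <- matrix(rnbinom(500 * 6, mu = 80, size = 5) + 1, 500, 6,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:6)))
  m[1:20, 1] <- m[1:20, 1] * 8
  f <- computeTMMFactors(m)
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(f), unname(ref), tolerance = 1e-8)
})

test_that("TMM invariance under global scaling of one library", {
  set.seed(5)
  m <- matrix(rpois(300 * 4, 60) + 1, 300, 4,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:4)))
  m2 <- m; m2[, 3] <- m[, 3] * 7
  # M and A values are library-size fractions, so the unweighted factor
  # is exactly invariant; precision weights depend on library size, so
  # the weighted factor is invariant only to first order
  expect_equal(computeTMMFactors(m, weighted = FALSE),
               computeTMMFactors(m2, weighted = FALSE),
               tolerance = 1e-12)
  expect_equal(computeTMMFactors(m), computeTMMFactors(m2),
               tolerance = 0.01)
})

test_that("TMM fallbacks and errors trigger as specified", {
  # fewer than 10 genes surviving trimming -> warning, untrimmed fallback
  set.seed(6)
  small <- matrix(rpois(8 * 2, 30) + 1, 8, 2,
                  dimnames = list(paste0("g", 1:8), c("s1", "s2")))
  small[, 2] <- small[, 2] + rpois(8, 5)
  expect_warning(computeTMMFactors(small), "fewer than 10")

  # no shared positive genes -> error
  disjoint <- matrix(c(1, 0, 2, 0, 0, 3, 0, 4), 4, 2,
                     dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  expect_error(computeTMMFactors(disjoint), "no positive genes")
  expect_error(computeTMMFactors(matrix(1, 3, 1)), "2 samples")
})

test_that("applying TMM factors is exactly invertible", {
  set.seed(7)
  tpm <- matrix(runif(50, 0, 1000), 10, 5,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  f <- setNames(c(1, 1, 1, 1, 1), colnames(tpm))
  expect_equal(applyTMM(tpm, f), tpm)
  f2 <- setNames(c(2, 1, 1, 1, 1), colnames(tpm))
  expect_equal(applyTMM(tpm, f2)[, 1], tpm[, 1] / 2)
  expect_equal(applyTMM(applyTMM(tpm, f2), 1 / f2), tpm,
               tolerance = 1e-12)
  expect_error(applyTMM(tpm, -f2), "positive")
})

test_that("tmm-normalized TPM factors have geometric mean one", {
  set.seed(8)
  m <- matrix(rnbinom(200 * 5, mu = 60, size = 5) + 1, 200, 5,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:5)))
  res <- tmmNormalizedTPM(m, runif(200, 200, 2000))
  expect_equal(exp(mean(log(res$factors))), 1, tolerance = 1e-9)
  expect_equal(unname(colSums(res$tpm)), rep(1e6, 5), tolerance = 1e-6)
})
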