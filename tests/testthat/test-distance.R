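test_that("identical sequences give exactly zero distance", {
  mod <- jttModel(1)
  expect_identical(as.numeric(mlPairwiseDistance("ARNDCQE", "ARNDCQE", mod)), 0)
  ## gaps and unknowns are removed before the identity check
  expect_identical(as.numeric(mlPairwiseDistance("ARND-QE", "ARNDCXE", mod)), 0)
})

test_that("input validation: length mismatch, bad symbols, all-gap pairs", {
  mod <- jttModel(NA)
  expect_error(mlPairwiseDistance("ARND", "ARNDC", mod), "equal aligned length")
  expect_error(mlPairwiseDistance("ARNB", "ARND", mod), "invalid residue")
  expect_error(mlPairwiseDistance("--XX", "ARND", mod), "no sites survive")
})

test_that("simulate-then-recover: estimates track the true distance", {
  mod <- jttModel(NA)
  set.seed(101)
  for (d in c(0.05, 0.15, 0.5)) {
    p <- simulateAllelePair(d, 5000, mod)
    est <- as.numeric(mlPairwiseDistance(p$a, p$b, mod))
    expect_lt(abs(est - d), 0.03)
  }
})

test_that("estimator is symmetric and matches an independent ML oracle", {
  mod <- jttModel(NA)
  set.seed(5)
  p <- simulateAllelePair(0.2, 2000, mod)
  d1 <- as.numeric(mlPairwiseDistance(p$a, p$b, mod))
  d2 <- as.numeric(mlPairwiseDistance(p$b, p$a, mod))
  expect_lt(abs(d1 - d2), 1e-7)
  ## phangorn's ML distance under the same model is an independent route
  pd <- phangorn::phyDat(rbind(x = strsplit(p$a, "")[[1]],
                               y = strsplit(p$b, "")[[1]]), type = "AA")
  oracle <- as.numeric(phangorn::dist.ml(pd, model = "JTT", k = 1))
  expect_equal(d1, oracle, tolerance = 1e-4)
})

test_that("huge gamma shape converges to the rate-homogeneous estimate", {
  set.seed(42)
  p <- simulateAllelePair(0.18, 3000, jttModel(NA))
  dHom <- as.numeric(mlPairwiseDistance(p$a, p$b, jttModel(NA)))
  dBig <- as.numeric(mlPairwiseDistance(p$a, p$b, jttModel(1e6)))
  expect_lt(abs(dHom - dBig), 1e-4)
})

test_that("mean absolute error shrinks with sequence length", {
  mod <- jttModel(NA)
  set.seed(77)
  mae <- vapply(c(500, 5000, 50000), function(L) {
    errs <- replicate(8, {
      p <- simulateAllelePair(0.15, L, mod)
      abs(as.numeric(mlPairwiseDistance(p$a, p$b, mod)) - 0.15)
    })
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
})

test_that("profiled log-likelihood is unimodal for non-saturated pairs", {
  mod <- jttModel(1)
  set.seed(13)
  for (d in c(0.1, 0.4)) {
    p <- simulateAllelePair(d, 1000, mod)
    ea <- strsplit(p$a, "")[[1]]; eb <- strsplit(p$b, "")[[1]]
    N <- table(factor(ea, levels = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]),
               factor(eb, levels = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]))
    nll <- vapply(seq(0.005, 3, by = 0.005), function(dd) {
      P <- transitionProbabilities(mod, dd)
      -sum(N[N > 0] * log(P[N > 0]))
    }, numeric(1))
    s <- sign(diff(nll))
    expect_equal(sum(s[-length(s)] < 0 & s[-1] > 0), 1)  # one interior minimum
  }
})

test_that("distance matrices have the contracted shape and invariants", {
  mod <- jttModel(NA)
  m <- buildDistanceMatrix(c(a1 = "ARNDCQE", a2 = "ARNDCQE"), mod, locus = "L")
  expect_identical(unname(distValues(m)), matrix(0, 2, 2))
  seqs <- c(a1 = "ARNDCQEGHI", a2 = "ARNDCQEGHV", a3 = "GRNDCQEGHI")
  m3 <- buildDistanceMatrix(seqs, mod, locus = "L")
  v <- distValues(m3)
  expect_identical(v, t(v))
  expect_identical(diag(v), c(a1 = 0, a2 = 0, a3 = 0))
  expect_true(all(v[upper.tri(v)] > 0))
  expect_error(buildDistanceMatrix(c(a1 = "AR", a1 = "AR"), mod), "duplicate")
  expect_error(buildDistanceMatrix(c(a1 = "AR"), mod), "at least 2")
})

test_that("a synthetic low-divergence matrix is recovered within 0.01 per cell", {
  set.seed(2024)
  ## DQB1-like fixture: 6 alleles, true pair distances well under 0.1,
  ## 6000 sites so per-cell sampling noise sits below the 0.01 tolerance
  cfg <- simulationConfig(sequenceLength = 6000)
  gen <- generateAlleles(cfg, slaRegistry(), jttModel(1))
  est <- buildDistanceMatrix(gen$sequences[["DQB1"]], jttModel(1),
                             locus = "DQB1")
  true <- distValues(gen$matrices[["DQB1"]])
  expect_lt(max(abs(distValues(est) - true)), 0.01)
})

test_that("matrix summaries use the unordered pair set", {
  expect_equal(summarizeMatrix(toyMatrix(c("x", "y"), 0.1)),
               data.frame(locus = "toy", n_alleles = 2L, min = 0.1,
                          max = 0.1, overall_mean = 0.1))
  s <- summarizeMatrix(toyMatrix(c("x", "y", "z"), c(0.1, 0.2, 0.3)))
  expect_equal(s$overall_mean, 0.2)
  expect_equal(c(s$min, s$max), c(0.1, 0.3))
})
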