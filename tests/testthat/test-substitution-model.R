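test_that("model construction normalises the rate matrix and validates input", {
  mod <- jttModel(NA)
  p <- equilibriumFrequencies(mod)
  expect_equal(sum(p), 1, tolerance = 1e-10)
  expect_true(all(p > 0))
  ## normalisation: mean rate is 1, so d is in substitutions per site
  S <- mod@exchangeabilities
  Q <- sweep(S, 2, p, "*")
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(p * diag(Q)))
  expect_equal(-sum(p * diag(Q)), 1, tolerance = 1e-12)
  expect_true(all(mod@eigenValues <= 0))
  expect_error(substitutionModel(S, p, gammaShape = Inf), "gammaShape")
  expect_error(jttModel(-1), "positive")
})

test_that("zero-distance kernel is the identity and rows are stochastic", {
  for (mod in list(jttModel(NA), jttModel(1))) {
    expect_equal(transitionProbabilities(mod, 0), diag(20),
                 ignore_attr = TRUE, tolerance = 1e-12)
    for (d in c(0.01, 0.1, 1, 5)) {
      P <- transitionProbabilities(mod, d)
      expect_true(max(abs(rowSums(P) - 1)) < 1e-10)
      expect_true(min(P) >= 0)
    }
  }
  expect_error(transitionProbabilities(jttModel(1), -0.1), "nonnegative")
})

test_that("detailed balance holds at arbitrary distances", {
  mod <- jttModel(0.7)
  p <- equilibriumFrequencies(mod)
  for (d in c(0.05, 0.3, 2)) {
    P <- transitionProbabilities(mod, d)
    expect_true(max(abs(p * P - t(p * P))) < 1e-10)  # pi_i P_ij = pi_j P_ji
  }
})

test_that("gamma kernel equals quadrature over Gamma(alpha, alpha) rates", {
  ## eigenvalue shortcut vs independent Gauss-Laguerre integration
  set.seed(11)
  for (i in 1:50) {
    alpha <- exp(runif(1, log(0.2), log(20)))
    d <- runif(1, 0.01, 2)
    mod <- jttModel(alpha)
    P <- transitionProbabilities(mod, d)
    Pq <- quadratureGammaKernel(mod, d, alpha)
    expect_true(max(abs(P - Pq)) < 1e-7)
  }
})
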