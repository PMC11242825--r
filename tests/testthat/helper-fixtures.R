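## Shared fixtures and independent oracles for the test suite.

## Toy distance matrix with explicit values.
toyMatrix <- function(ids = c("x", "y", "z"),
                      d = c(0.1, 0.2, 0.3), locus = "toy") {
  n <- length(ids)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  v[upper.tri(v)] <- d
  v <- v + t(v)
  alleleDistanceMatrix(v, locus)
}

## Quadrature oracle for the continuous-gamma transition kernel:
## integrates the rate-homogeneous kernel over Gamma(alpha, alpha) rates by
## composite Gauss-Legendre panels, independently of the closed-form
## eigenvalue transform.  The r^(alpha-1) density endpoint is handled by a
## u = r^alpha substitution (alpha < 1) or geometric panels (alpha >= 1).
quadratureGammaKernel <- function(model, d, alpha) {
  hom <- substitutionModel(model@exchangeabilities,
                           equilibriumFrequencies(model),
                           gammaShape = NA, name = "hom")
  P <- matrix(0, 20, 20)
  addGL <- function(a, b, n, P) {
    gl <- pracma::gaussLegendre(n, a, b)
    for (k in seq_along(gl$x))
      P <- P + gl$w[k] * stats::dgamma(gl$x[k], alpha, alpha) *
        transitionProbabilities(hom, d * gl$x[k])
    P
  }
  if (alpha < 1) {
    glA <- pracma::gaussLegendre(48, 0, 1)
    cA <- alpha^(alpha - 1) / gamma(alpha)
    for (k in seq_along(glA$x)) {
      r <- glA$x[k]^(1 / alpha)
      P <- P + glA$w[k] * cA * exp(-alpha * r) *
        transitionProbabilities(hom, d * r)
    }
  } else {
    brk <- 10^seq(-10, 0, by = 1)
    for (s in seq_len(length(brk) - 1)) P <- addGL(brk[s], brk[s + 1], 16, P)
  }
  rmax <- max(3, stats::qgamma(1e-15, alpha, alpha, lower.tail = FALSE))
  h <- min(0.5, 3 / sqrt(alpha))
  brk <- seq(1, rmax, length.out = max(2, ceiling((rmax - 1) / h) + 1))
  for (s in seq_len(length(brk) - 1)) P <- addGL(brk[s], brk[s + 1], 24, P)
  P
}

## Brute-force four-term score, written independently of pairScore.
bruteForceScore <- function(sire, dam, v) {
  s <- 0
  for (a in sire) for (b in dam) s <- s + v[a, b]
  s
}

## A minimal valid mating table.
makeMatings <- function(litter, live, weaned = NULL, sow = "s1", boar = "b1") {
  n <- length(litter)
  if (is.null(weaned)) weaned <- rep(NA_integer_, n)
  data.frame(mating_id = paste0("m", seq_len(n)),
             sow_id = rep_len(sow, n), boar_id = rep_len(boar, n),
             litter_size = litter, n_live = live,
             n_stillborn = litter - live,
             n_weaned = weaned, n_preweaning_dead = live - weaned,
             stringsAsFactors = FALSE)
}

## Run the complete synthetic pipeline for one seed.  With
## `estimateDistances = TRUE` the analysis uses ML-estimated matrices from
## the simulated sequences (so estimator noise is part of the exercise);
## otherwise the generator's true matrices are used.
fullPipeline <- function(seed, config = simulationConfig(),
                         estimateDistances = TRUE, model = jttModel()) {
  sim <- simulateStudy(seed, config = config, model = model)
  mats <- if (estimateDistances) {
    out <- lapply(names(sim$sequences), function(lc)
      buildDistanceMatrix(sim$sequences[[lc]], model, locus = lc))
    names(out) <- names(sim$sequences)
    out
  } else sim$trueMatrices
  runAnalysis(sim$matings, sim$animals, sim$registry, mats)
}
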