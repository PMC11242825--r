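## Synthetic herd, allele-sequence and outcome generator.
##
## Emulates the statistical structure the analysis assumes: a small closed
## herd typed at 11 SLA haplotypes, 650 matings of 106 sows x 42 boars,
## per-locus allele sets evolved under JTT at locus-specific scales, and
## count outcomes whose means are linked to the true dissimilarity scores.

#' Generator configuration
#'
#' Collects the knobs of the synthetic-data generator with defaults
#' matching the emulated herd: 106 sows, 42 boars, 650 matings, haplotype
#' frequencies as accumulated over the published mating series, sequence
#' length 180, per-locus true-distance scales equal to the published
#' per-locus overall mean distances, outcome baselines anchored to the
#' published cohort means (litter 5.47, stillborn 0.93, pre-weaning death
#' rate ~0.15), a litter-vs-DQB1 effect `beta1` and a death-vs-SLA-2 effect
#' `gamma1`, and a 33/650 missing-weaning fraction.
#'
#' @param nSows,nBoars,nMatings herd and series sizes.
#' @param haplotypeFreqs named haplotype sampling probabilities; default:
#'   the packaged registry's pooled dam+sire counts, normalised.
#' @param inbreedingF probability that an animal's second haplotype copies
#'   its first (excess homozygosity), in `[0, 1)`.
#' @param sequenceLength residues per simulated allele sequence.
#' @param distanceScales named per-locus target scale of true pairwise
#'   distances (substitutions per site).
#' @param beta0 log of the mean extra litter size (litter = 1 + Poisson).
#' @param beta1 litter effect per SD of the true DQB1 score.
#' @param pStill per-piglet stillbirth probability.
#' @param gamma0 baseline logit of the pre-weaning death probability.
#' @param gamma1 death-logit effect per SD of the true SLA-2 score.
#' @param missingWeaningFraction fraction of matings with weaning fields
#'   blanked.
#' @return A named list of validated generator settings.
#' @export
simulationConfig <- function(nSows = 106, nBoars = 42, nMatings = 650,
                             haplotypeFreqs = NULL, inbreedingF = 0,
                             sequenceLength = 180,
                             distanceScales = c("SLA-1" = 0.1972,
                                                "SLA-3" = 0.1178,
                                                "SLA-2" = 0.2330,
                                                "DRB1" = 0.1695,
                                                "DQB1" = 0.0651),
                             beta0 = log(4.47), beta1 = 0.1,
                             pStill = 0.17, gamma0 = stats::qlogis(0.15),
                             gamma1 = -0.4,
                             missingWeaningFraction = 33 / 650) {
  if (is.null(haplotypeFreqs)) {
    h <- haplotypeTable(slaRegistry())
    haplotypeFreqs <- stats::setNames(
      (h$dam_count + h$sire_count) / sum(h$dam_count + h$sire_count),
      h$haplotype_id)
  }
  stopifnot(nSows > 0, nBoars > 0, nMatings > 0,
            inbreedingF >= 0, inbreedingF < 1,
            sequenceLength >= 1,
            all(distanceScales >= 0),
            pStill >= 0, pStill <= 1,
            missingWeaningFraction >= 0, missingWeaningFraction < 1,
            abs(sum(haplotypeFreqs) - 1) < 1e-8)
  list(nSows = nSows, nBoars = nBoars, nMatings = nMatings,
       haplotypeFreqs = haplotypeFreqs, inbreedingF = inbreedingF,
       sequenceLength = sequenceLength, distanceScales = distanceScales,
       beta0 = beta0, beta1 = beta1, pStill = pStill, gamma0 = gamma0,
       gamma1 = gamma1, missingWeaningFraction = missingWeaningFraction)
}

#' Generate synthetic allele sequences with known distances
#'
#' For each locus, evolves the registry's allele set from a common random
#' ancestor under the given model along a star tree.  Branch lengths are
#' drawn as `scale/2 * U(0.85, 1.15)`, so every true pairwise distance
#' (the sum of the two branch lengths) lies within 15% of the locus target
#' scale.  Continuous-gamma site rates, when present in the model, are
#' drawn once per locus and shared across branches.
#'
#' @param config a [simulationConfig()].
#' @param registry a [HaplotypeRegistry-class] naming the alleles per
#'   locus.
#' @param model evolution model (also the default estimation model).
#' @return list with `sequences` (named list of `AAStringSet` per locus)
#'   and `matrices` (true [AlleleDistanceMatrix-class] per locus).
#' @export
generateAlleles <- function(config = simulationConfig(),
                            registry = slaRegistry(),
                            model = jttModel()) {
  h <- haplotypeTable(registry)
  p <- model@frequencies
  a <- model@gammaShape
  hom <- if (is.na(a)) model else
    substitutionModel(model@exchangeabilities, p, NA_real_, model@name)
  L <- config$sequenceLength
  out <- list(sequences = list(), matrices = list())
  for (lc in SLA_LOCI) {
    alleles <- sort(unique(unlist(lapply(h$haplotype_id, function(id)
      haplotypeAlleles(registry, id, lc)))))
    nA <- length(alleles)
    t <- config$distanceScales[[lc]] / 2 * stats::runif(nA, 0.85, 1.15)
    anc <- sample.int(20L, L, replace = TRUE, prob = p)
    rates <- if (is.na(a)) rep(1, L) else stats::rgamma(L, shape = a, rate = a)
    lam <- hom@eigenValues
    U <- hom@eigenVectors
    sp <- sqrt(p)
    UT <- upper.tri(diag(20), diag = TRUE) * 1
    seqs <- vapply(seq_len(nA), function(i) {
      if (t[i] == 0) {
        des <- anc
      } else {
        ## per-site transition rows, conditional on the site rates, in one
        ## matrix reconstruction: row s of M is P(t_i * r_s)[anc_s, ]
        G <- exp(outer(t[i] * rates, lam))
        M <- (U[anc, , drop = FALSE] * G) %*% t(U)
        M <- sweep(M, 2, sp, "*") / sp[anc]
        M[M < 0] <- 0
        C <- M %*% UT
        u <- stats::runif(L) * C[, 20]
        des <- max.col(C >= u, ties.method = "first")
      }
      paste(AA_ORDER[des], collapse = "")
    }, character(1))
    names(seqs) <- alleles
    true <- outer(t, t, `+`)
    diag(true) <- 0
    dimnames(true) <- list(alleles, alleles)
    out$sequences[[lc]] <- Biostrings::AAStringSet(seqs)
    out$matrices[[lc]] <- alleleDistanceMatrix(true, lc,
                                               gammaShape = model@gammaShape,
                                               gapMode = "complete")
  }
  out
}

#' Generate a synthetic herd and random mating series
#'
#' Diplotypes are sampled from the haplotype frequencies; with probability
#' `inbreedingF` an animal's second haplotype copies its first, so expected
#' homozygosity is `sum p_i^2 + F (1 - sum p_i^2)`.  Matings pair a uniform
#' random sow with a uniform random boar, with replacement (the emulated
#' herd mated at random).
#'
#' @inheritParams generateAlleles
#' @return list with `animals` and `matings` data.frames (matings carry
#'   only ids; outcomes come from [generateOutcomes()]).
#' @export
generateHerdAndMatings <- function(config = simulationConfig(),
                                   registry = slaRegistry()) {
  hf <- config$haplotypeFreqs
  ids <- names(hf)
  stopifnot(all(ids %in% haplotypeIds(registry)))
  nA <- config$nSows + config$nBoars
  hap1 <- sample(ids, nA, replace = TRUE, prob = hf)
  copy <- stats::runif(nA) < config$inbreedingF
  hap2 <- ifelse(copy, hap1, sample(ids, nA, replace = TRUE, prob = hf))
  animals <- data.frame(
    animal_id = c(sprintf("sow%03d", seq_len(config$nSows)),
                  sprintf("boar%03d", seq_len(config$nBoars))),
    sex = rep(c("sow", "boar"), c(config$nSows, config$nBoars)),
    hap1 = hap1, hap2 = hap2, stringsAsFactors = FALSE)
  matings <- data.frame(
    mating_id = sprintf("m%04d", seq_len(config$nMatings)),
    sow_id = sample(animals$animal_id[animals$sex == "sow"],
                    config$nMatings, replace = TRUE),
    boar_id = sample(animals$animal_id[animals$sex == "boar"],
                     config$nMatings, replace = TRUE),
    stringsAsFactors = FALSE)
  list(animals = animals, matings = matings)
}

#' Generate reproductive outcomes linked to true scores
#'
#' Outcome model: `litter = 1 + Poisson(exp(beta0 + beta1 z_DQB1))` (the
#' `1 +` excludes zero litters, which are non-farrowings and outside this
#' analysis); `stillborn ~ Binomial(litter, pStill)`; pre-weaning deaths
#' `~ Binomial(live, logistic(gamma0 + gamma1 z_SLA2))`;
#' `weaned = live - deaths`.  `z` scores are the true per-mating
#' dissimilarity scores standardised over the series (zero when the scores
#' are constant).  Weaning fields are blanked in a random
#' `missingWeaningFraction` subset.  Every record satisfies the mating
#' invariants by construction.
#'
#' @param matings data.frame with `mating_id`, `sow_id`, `boar_id`.
#' @param scores per-mating score matrix from [matingScores()] computed on
#'   the \emph{true} matrices (columns include `DQB1` and `SLA-2`).
#' @param config a [simulationConfig()].
#' @return The matings data.frame completed with outcome columns.
#' @export
generateOutcomes <- function(matings, scores, config = simulationConfig()) {
  n <- nrow(matings)
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else rep(0, n)
  zD <- z(scores[, "DQB1"])
  zS <- z(scores[, "SLA-2"])
  litter <- 1L + stats::rpois(n, exp(config$beta0 + config$beta1 * zD))
  still <- stats::rbinom(n, litter, config$pStill)
  live <- litter - still
  pDie <- stats::plogis(config$gamma0 + config$gamma1 * zS)
  dead <- stats::rbinom(n, live, pDie)
  weaned <- live - dead
  ## a fixed-size random subset, so the emulated birth/weaning split is
  ## exact (650 vs 617 under the defaults)
  nBlank <- round(n * config$missingWeaningFraction)
  blank <- seq_len(n) %in% sample.int(n, nBlank)
  weaned[blank] <- NA_integer_
  dead[blank] <- NA_integer_
  out <- matings
  out$litter_size <- litter
  out$n_live <- live
  out$n_stillborn <- still
  out$n_weaned <- weaned
  out$n_preweaning_dead <- dead
  validateMatings(out)
  out
}

#' Simulate a complete synthetic study
#'
#' One call produces everything the pipeline consumes: allele sequences
#' with known true distance matrices, a herd, a mating series and outcome
#' records linked to the true scores.  All randomness flows from `seed`.
#'
#' @param seed integer seed.
#' @param config a [simulationConfig()].
#' @param registry a [HaplotypeRegistry-class].
#' @param model evolution model.
#' @param alleles optional precomputed result of [generateAlleles()];
#'   supplying it reuses the allele set across replicate herds.
#' @return list with `registry`, `model`, `sequences`, `trueMatrices`,
#'   `animals`, `matings` (with outcomes), and `truth` (true per-mating
#'   scores, config echo, seed).
#' @export
simulateStudy <- function(seed, config = simulationConfig(),
                          registry = slaRegistry(), model = jttModel(),
                          alleles = NULL) {
  set.seed(seed)
  if (is.null(alleles)) alleles <- generateAlleles(config, registry, model)
  herd <- generateHerdAndMatings(config, registry)
  trueScores <- matingScores(herd$matings, herd$animals, registry,
                             alleles$matrices)
  matings <- generateOutcomes(herd$matings, trueScores, config)
  list(registry = registry, model = model,
       sequences = alleles$sequences, trueMatrices = alleles$matrices,
       animals = herd$animals, matings = matings,
       truth = list(scores = trueScores, config = config, seed = seed))
}
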