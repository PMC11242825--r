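test_that("generated allele sets honour locus scales and counts", {
  set.seed(51)
  gen <- generateAlleles(simulationConfig(), slaRegistry(), jttModel(1))
  nA <- vapply(gen$matrices, function(m) length(alleleIds(m)), integer(1))
  expect_equal(unname(nA[c("SLA-1", "SLA-3", "SLA-2", "DRB1", "DQB1")]),
               c(9L, 8L, 8L, 8L, 6L))
  ## DQB1 scale 0.0651: every true pair distance stays well below 0.15
  dq <- distValues(gen$matrices[["DQB1"]])
  expect_true(all(dq[upper.tri(dq)] < 0.15))
  ## true distances sit within 15% of each locus target
  for (lc in names(gen$matrices)) {
    v <- distValues(gen$matrices[[lc]])
    target <- simulationConfig()$distanceScales[[lc]]
    expect_true(all(abs(v[upper.tri(v)] - target) <= 0.2 * target))
  }
  ## sequence lengths follow the config
  expect_true(all(Biostrings::width(gen$sequences[["SLA-2"]]) == 180L))
})

test_that("zero branch scales give identical alleles and a zero matrix", {
  set.seed(52)
  cfg <- simulationConfig(distanceScales = c("SLA-1" = 0, "SLA-3" = 0,
                                             "SLA-2" = 0, "DRB1" = 0,
                                             "DQB1" = 0))
  gen <- generateAlleles(cfg, slaRegistry(), jttModel(1))
  expect_true(all(distValues(gen$matrices[["SLA-1"]]) == 0))
  seqs <- as.character(gen$sequences[["SLA-1"]])
  expect_equal(length(unique(seqs)), 1L)
})

test_that("herd generation respects sizes, frequencies and inbreeding", {
  set.seed(53)
  cfg <- simulationConfig()
  herd <- generateHerdAndMatings(cfg, slaRegistry())
  expect_equal(nrow(herd$animals), 106L + 42L)
  expect_equal(nrow(herd$matings), 650L)
  expect_true(all(herd$matings$sow_id %in%
                    herd$animals$animal_id[herd$animals$sex == "sow"]))
  ## F = 1: every animal homozygous
  cfgF <- simulationConfig(inbreedingF = 1 - 1e-12)
  herdF <- generateHerdAndMatings(cfgF, slaRegistry())
  expect_true(all(herdF$animals$hap1 == herdF$animals$hap2))
  ## F = 0 at large n: homozygosity within the binomial envelope of sum p^2
  cfg0 <- simulationConfig(nSows = 5000, nBoars = 5000, inbreedingF = 0)
  herd0 <- generateHerdAndMatings(cfg0, slaRegistry())
  p2 <- sum(cfg0$haplotypeFreqs^2)
  obs <- mean(herd0$animals$hap1 == herd0$animals$hap2)
  expect_lt(abs(obs - p2), 4 * sqrt(p2 * (1 - p2) / 10000))
})

test_that("outcomes satisfy every record invariant by construction", {
  set.seed(54)
  sim <- simulateStudy(54)
  m <- sim$matings
  expect_silent(validateMatings(m))
  expect_true(all(m$litter_size >= 1))             # 1 + Poisson: no zero litters
  expect_equal(sum(!is.na(m$n_weaned)), 617L)      # exact missing split
  ## null effects: litter mean within the Poisson envelope of 1 + exp(beta0)
  cfg0 <- simulationConfig(beta1 = 0, gamma1 = 0)
  sim0 <- simulateStudy(55, config = cfg0)
  mu <- 1 + exp(cfg0$beta0)
  expect_lt(abs(mean(sim0$matings$litter_size) - mu),
            4 * sqrt(exp(cfg0$beta0) / 650))
  ## no stillbirth channel
  cfgS <- simulationConfig(pStill = 0)
  simS <- simulateStudy(56, config = cfgS)
  expect_true(all(simS$matings$n_stillborn == 0))
})

test_that("a strongly negative death effect orders deaths across score quartiles", {
  cfg <- simulationConfig(gamma1 = -1)
  sim <- simulateStudy(57, config = cfg)
  z <- sim$truth$scores[, "SLA-2"]
  q <- cut(z, quantile(z, 0:4 / 4), include.lowest = TRUE, labels = FALSE)
  rate <- tapply(sim$matings$n_preweaning_dead / pmax(sim$matings$n_live, 1),
                 q, mean, na.rm = TRUE)
  expect_true(all(diff(rate) < 0))
})

test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulateStudy(99)
  s2 <- simulateStudy(99)
  expect_identical(as.character(s1$sequences[["DRB1"]]),
                   as.character(s2$sequences[["DRB1"]]))
  expect_identical(s1$matings, s2$matings)
  expect_identical(s1$truth$scores, s2$truth$scores)
})
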