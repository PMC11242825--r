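test_that("trait derivation follows the rate definitions", {
  m <- makeMatings(litter = 5, live = 4, weaned = 3)
  tv <- deriveTraits(m)
  expect_equal(tv$survival_rate, 0.8)      # live / litter
  expect_equal(tv$weaning_rate, 0.75)      # weaned / live
  expect_equal(tv$n_preweaning_dead, 1)
})

test_that("missing weaning data propagates, zero denominators give NA", {
  m <- makeMatings(litter = c(5, 3, 2), live = c(4, 0, 2),
                   weaned = c(NA, NA, 2))
  tv <- deriveTraits(m)
  expect_true(is.na(tv$weaning_rate[1]))   # no weaning record
  expect_true(is.na(tv$weaning_rate[2]))   # live = 0 denominator
  expect_equal(tv$weaning_rate[3], 1)
  m0 <- makeMatings(litter = 0, live = 0)
  expect_true(is.na(deriveTraits(m0)$survival_rate))
})

test_that("invariant violations name the failing identity and location", {
  bad <- makeMatings(litter = 5, live = 4)
  bad$n_stillborn <- 2
  expect_error(validateMatings(bad), "n_live \\+ n_stillborn != litter_size")
  bad2 <- makeMatings(litter = 5, live = 4, weaned = 4)
  bad2$n_preweaning_dead <- 1
  expect_error(validateMatings(bad2),
               "n_weaned \\+ n_preweaning_dead != n_live")
  half <- makeMatings(litter = 5, live = 4, weaned = 3)
  half$n_preweaning_dead <- NA_integer_
  expect_error(validateMatings(half), "missing together")
})

test_that("cohort summaries split birth and weaning denominators", {
  m <- makeMatings(litter = c(4, 6), live = c(4, 5), weaned = c(3, NA))
  cs <- cohortSummary(m)
  expect_equal(cs$mean[cs$trait == "litter_size"], 5.0)
  expect_equal(cs$se[cs$trait == "litter_size"], 1.0)
  expect_equal(cs$n[cs$trait == "litter_size"], 2L)
  expect_equal(cs$n[cs$trait == "n_weaned"], 1L)
  ## all-identical records: SE exactly 0
  mi <- makeMatings(litter = rep(5, 4), live = rep(4, 4))
  csi <- cohortSummary(mi)
  expect_equal(csi$se[csi$trait == "litter_size"], 0)
})

test_that("pooled and per-mating cohort rates differ as documented", {
  m <- makeMatings(litter = c(5, 4), live = c(4, 2))
  pooled <- cohortSummary(m, rateMode = "pooled")
  per <- cohortSummary(m, rateMode = "per-mating")
  expect_equal(pooled$mean[pooled$trait == "survival_rate"], 100 * 6 / 9)
  expect_equal(per$mean[per$trait == "survival_rate"],
               100 * mean(c(4 / 5, 2 / 4)))
})

test_that("additivity identities transfer to cohort means exactly", {
  set.seed(9)
  sim <- simulateStudy(9)
  cs <- cohortSummary(sim$matings)
  expect_equal(cs$mean[cs$trait == "n_live"] +
                 cs$mean[cs$trait == "n_stillborn"],
               cs$mean[cs$trait == "litter_size"], tolerance = 1e-12)
})
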