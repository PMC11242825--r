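test_that("the packaged registry matches the published haplotype layout", {
  reg <- slaRegistry()
  expect_equal(length(reg), 11L)
  h <- haplotypeTable(reg)
  expect_equal(sum(h$recombinant), 3L)
  ## the duplicated-SLA-1 family carries both alleles
  expect_setequal(haplotypeAlleles(reg, "35.23", "SLA-1"),
                  c("SLA-1*12:01", "SLA-1*13:01"))
  expect_setequal(haplotypeAlleles(reg, "35.17", "SLA-1"),
                  c("SLA-1*12:01", "SLA-1*13:01"))
  expect_equal(haplotypeAlleles(reg, "17.17", "DRB1"), "DRB1*08:01")
  expect_equal(haplotypeAlleles(reg, "17.17", "DQB1"), "DQB1*05:01")
  ## variant selection applies only to duplicated carriers
  expect_equal(haplotypeAlleles(reg, "35.23", "SLA-1", "SLA-1*13:01"),
               "SLA-1*13:01")
  expect_equal(haplotypeAlleles(reg, "43.37", "SLA-1", "SLA-1*13:01"),
               "SLA-1*11:04")
  ## allele counts per locus: 9, 8, 8, 8, 6
  nAlleles <- vapply(c("SLA-1", "SLA-3", "SLA-2", "DRB1", "DQB1"),
                     function(lc) {
    length(unique(unlist(lapply(h$haplotype_id, haplotypeAlleles,
                                registry = reg, locus = lc))))
  }, integer(1))
  expect_equal(unname(nAlleles), c(9L, 8L, 8L, 8L, 6L))
})

test_that("registry CSVs validate their structure", {
  reg <- slaRegistry()
  tmp <- withr::local_tempfile(fileext = ".csv")
  h <- haplotypeTable(reg)
  write.csv(h[, setdiff(names(h), "dqb1_allele")], tmp, row.names = FALSE)
  expect_error(readRegistry(tmp), "dqb1_allele")
  write.csv(rbind(h, h[1, ]), tmp, row.names = FALSE)
  expect_error(readRegistry(tmp), "unique")
})

test_that("two-digit calls resolve through the class II context", {
  reg <- slaRegistry()
  expect_equal(resolveTwoDigit("DQB1*04:XX", "0.11", reg), "DQB1*04:02")
  expect_equal(resolveTwoDigit("DQB1*04:XX", "0.18", reg), "DQB1*04:01:02")
  expect_equal(resolveTwoDigit("DQB1*05:XX", "0.17", reg), "DQB1*05:01")
  expect_equal(resolveTwoDigit("DQB1*05:XX", "0.37", reg), "DQB1*05:02")
  ## a full haplotype id works as context too
  expect_equal(resolveTwoDigit("DQB1*04:XX", "10.11", reg), "DQB1*04:02")
  ## four-digit input is an identity
  expect_identical(resolveTwoDigit("DQB1*06:01", "0.7", reg), "DQB1*06:01")
  expect_error(resolveTwoDigit("DQB1*04:XX", "9.99", reg), "unknown class II")
  expect_error(resolveTwoDigit("DQB1*07:XX", "0.11", reg), "no four-digit")
  ## ambiguity: a constructed context carrying two alleles of one group
  amb <- haplotypeTable(reg)
  amb$dqb1_allele[amb$haplotype_id == "10.23"] <- "DQB1*05:09"
  amb$class2_id[amb$haplotype_id == "10.23"] <- "0.17"
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(amb, tmp, row.names = FALSE)
  expect_error(resolveTwoDigit("DQB1*05:XX", "0.17", readRegistry(tmp)),
               "ambiguous")
})

test_that("mating haplotype counts enumerate 2 dam + 2 sire per mating", {
  reg <- slaRegistry()
  animals <- data.frame(animal_id = c("s1", "b1"), sex = c("sow", "boar"),
                        hap1 = c("35.23", "35.23"),
                        hap2 = c("43.37", "35.23"))
  matings <- data.frame(mating_id = "m1", sow_id = "s1", boar_id = "b1")
  fc <- matingHaplotypeCounts(matings, animals, reg)
  expect_equal(attr(fc, "denominator"), 4L)
  expect_equal(fc$count[fc$haplotype_id == "35.23"], 3L)
  expect_equal(fc$count[fc$haplotype_id == "43.37"], 1L)
  expect_equal(sum(fc$count), 4L)
  ## empty mating list
  f0 <- matingHaplotypeCounts(matings[0, ], animals, reg)
  expect_equal(attr(f0, "denominator"), 0L)
  expect_equal(sum(f0$count), 0L)
  expect_error(
    matingHaplotypeCounts(data.frame(mating_id = "m", sow_id = "nope",
                                     boar_id = "b1"), animals, reg),
    "unknown animal")
})

test_that("packaged per-sex counts each sum to twice the mating number", {
  h <- haplotypeTable(slaRegistry())
  expect_equal(sum(h$dam_count), 2L * 650L)
  expect_equal(sum(h$sire_count), 2L * 650L)
})

test_that("allele counts conserve the haplotype denominator at each locus", {
  af <- alleleFrequencies()
  denom <- attr(af, "denominator")
  expect_equal(denom, 2600)
  perLocus <- tapply(af$count, af$locus, sum)
  expect_true(all(perLocus == denom))
})

test_that("homozygosity counts identical-haplotype diplotypes per sex", {
  a <- data.frame(animal_id = paste0("a", 1:6),
                  sex = c(rep("sow", 4), rep("boar", 2)),
                  hap1 = c("35.23", "17.17", "10.11", "43.37", "35.23", "17.17"),
                  hap2 = c("35.23", "20.18", "16.16", "31.13", "43.37", "20.18"))
  hr <- homozygosityRate(a)
  expect_equal(hr$percent[hr$sex == "sow"], 25.0)
  expect_equal(hr$percent[hr$sex == "boar"], 0.0)
})

test_that("homozygosity under inbreeding matches the closed form", {
  set.seed(31)
  cfg <- simulationConfig(nSows = 5000, nBoars = 5000, inbreedingF = 0.3)
  herd <- generateHerdAndMatings(cfg, slaRegistry())
  p <- cfg$haplotypeFreqs
  expected <- sum(p^2) + 0.3 * (1 - sum(p^2))
  obs <- mean(herd$animals$hap1 == herd$animals$hap2)
  expect_lt(abs(obs - expected),
            4 * sqrt(expected * (1 - expected) / nrow(herd$animals)))
})
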