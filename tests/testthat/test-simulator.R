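test_that("identical seeds reproduce identical broods bit-for-bit", {
  cfg <- simulationConfig(mode = "TERMINAL_FUSION_AUTOMIXIS", nLoci = 5,
                          broodSize = 6, hRetain = 0.3, missingRate = 0.05,
                          seed = 77L)
  a <- simulateOffspring(simulateMother(cfg), cfg)
  b <- simulateOffspring(simulateMother(cfg), cfg)
  expect_identical(a@allele1, b@allele1)
  expect_identical(a@allele2, b@allele2)

  # substreams: growing the brood never reshuffles earlier offspring
  cfg2 <- simulationConfig(mode = "TERMINAL_FUSION_AUTOMIXIS", nLoci = 5,
                           broodSize = 9, hRetain = 0.3, missingRate = 0.05,
                           seed = 77L)
  c6 <- simulateOffspring(simulateMother(cfg2), cfg2)
  expect_identical(a@allele1[1:7, ], c6@allele1[1:7, ])
})

test_that("mechanism signatures are forced by construction", {
  for (mode in c("GAMETE_DUPLICATION", "HAPLOID_DEVELOPMENT")) {
    cfg <- simulationConfig(mode = mode, nLoci = 4, broodSize = 8, seed = 5L)
    tab <- simulateOffspring(simulateMother(cfg), cfg)
    z <- zygosityMatrix(tab)[offspringOf(tab), ]
    expect_true(all(z == "HOM_OR_HEMI"))
    if (mode == "HAPLOID_DEVELOPMENT") {
      # exactly one stored allele per call
      expect_true(all(!is.na(tab@allele1[offspringOf(tab), ])))
      expect_true(all(is.na(tab@allele2[offspringOf(tab), ])))
    } else {
      expect_true(all(!is.na(tab@allele2[offspringOf(tab), ])))
    }
  }

  # retention extremes
  cfgT <- simulationConfig(mode = "TERMINAL_FUSION_AUTOMIXIS", nLoci = 4,
                           broodSize = 8, hRetain = 1, seed = 5L)
  zT <- zygosityMatrix(simulateOffspring(simulateMother(cfgT), cfgT))
  expect_true(all(zT[-1, ] == "HET"))
  cfgC <- simulationConfig(mode = "CENTRAL_FUSION_AUTOMIXIS", nLoci = 4,
                           broodSize = 8, hRetain = 0, seed = 5L)
  zC <- zygosityMatrix(simulateOffspring(simulateMother(cfgC), cfgC))
  expect_true(all(zC[-1, ] == "HET"))

  expect_error(
    simulateMother(simulationConfig(
      alleleFreqs = list(c("100" = 1)), nLoci = 1)),
    "single allele")
})

test_that("every simulated parthenogenetic offspring is maternally compatible", {
  modes <- c("TERMINAL_FUSION_AUTOMIXIS", "CENTRAL_FUSION_AUTOMIXIS",
             "GAMETE_DUPLICATION", "HAPLOID_DEVELOPMENT")
  for (seed in c(1L, 2L, 3L)) {
    for (mode in modes) {
      cfg <- simulationConfig(
        mode = mode, nLoci = 3, broodSize = 5, seed = seed, hRetain = 0.4,
        alleleFreqs = rep(list(c("100" = 0.3, "104" = 0.3, "108" = 0.4)), 3))
      tab <- simulateOffspring(simulateMother(cfg), cfg)
      expect_true(all(maternalCompatibility(tab, "M")$compatible))
    }
  }
})

test_that("missing-call masking hits at about the configured rate", {
  cfg <- simulationConfig(mode = "GAMETE_DUPLICATION", nLoci = 10,
                          broodSize = 100, missingRate = 0.2, seed = 9L)
  tab <- simulateOffspring(simulateMother(cfg), cfg)
  z <- zygosityMatrix(tab)[offspringOf(tab), ]
  frac <- mean(z == "MISSING")
  se <- sqrt(0.2 * 0.8 / length(z))
  expect_lt(abs(frac - 0.2), 4 * se)
})

test_that("sexual-mode homozygote fraction matches the binomial closed form", {
  cfg <- simulationConfig(mode = "SEXUAL", nLoci = 1, broodSize = 10000,
                          seed = 13L)
  tab <- simulateOffspring(simulateMother(cfg), cfg)
  z <- zygosityMatrix(tab)[offspringOf(tab), , drop = FALSE]
  frac <- mean(z == "HOM_OR_HEMI")
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac - 0.5), 3 * se)

  # randomized pools: empirical rate tracks (f_A + f_a) / 2
  set.seed(61)
  for (i in 1:3) {
    pool <- randomPool(c("100", "104", "108", "112"))
    cfgP <- simulationConfig(mode = "SEXUAL", nLoci = 1, broodSize = 4000,
                             alleleFreqs = list(pool), seed = 17L + i)
    mom <- list(L1 = c(100L, 104L))
    tabP <- simulateOffspring(mom, cfgP)
    zP <- zygosityMatrix(tabP)[offspringOf(tabP), , drop = FALSE]
    p <- perLocusSexualHomProb(mom$L1, pool)
    seP <- sqrt(p * (1 - p) / 4000)
    expect_lt(abs(mean(zP == "HOM_OR_HEMI") - p), 3 * seP)
  }
})

test_that("false-positive rate estimation matches the analytic product", {
  cfg <- simulationConfig(mode = "SEXUAL", nLoci = 7, broodSize = 1,
                          seed = 23L)
  fpr <- estimateFalsePositiveRate(cfg, 50000)
  expect_lt(abs(fpr$rate - 0.5^7), 3 * sqrt(0.5^7 * (1 - 0.5^7) / 50000))

  # paternal pool disjoint from maternal alleles: nothing can pass
  mom <- list(L1 = c(100L, 104L))
  cfgD <- simulationConfig(mode = "SEXUAL", nLoci = 1,
                           alleleFreqs = list(c("300" = 0.5, "304" = 0.5)),
                           broodSize = 1, seed = 3L)
  expect_identical(estimateFalsePositiveRate(cfgD, 2000, mother = mom)$rate, 0)

  cfgBad <- simulationConfig(mode = "GAMETE_DUPLICATION", nLoci = 2)
  expect_error(estimateFalsePositiveRate(cfgBad, 10), "sexual-mode")
})

test_that("detection power follows the bound for deterministic modes", {
  pc <- powerCurve(mode = "GAMETE_DUPLICATION", nLociGrid = 6:7,
                   broodGrid = 1L, alpha = 0.01)
  expect_identical(pc$detection[pc$nLoci == 7], 1)  # 0.5^7 < 0.01
  expect_identical(pc$detection[pc$nLoci == 6], 0)  # 0.5^6 > 0.01

  # terminal fusion with no retained heterozygosity behaves like duplication
  pcT <- powerCurve(mode = "TERMINAL_FUSION_AUTOMIXIS", hRetain = 0,
                    nLociGrid = 6:7, broodGrid = 1L, alpha = 0.01)
  expect_identical(pcT$detection, pc$detection)

  # full retention never produces the all-homozygous signature
  pcH <- powerCurve(mode = "TERMINAL_FUSION_AUTOMIXIS", hRetain = 1,
                    nLociGrid = 7, broodGrid = 1L, alpha = 0.01,
                    replicates = 30L)
  expect_identical(pcH$detection, 0)
})
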