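test_that("homozygous-observation counting follows the maternal-het rule", {
  t4 <- waterDragonGenotypes()
  cnt <- countHomozygousObservations(t4, "WD-10")
  expect_identical(cnt$n, 62L)
  expect_identical(cnt$nMissing, 1L)
  expect_identical(cnt$nHet, 0L)
  expect_length(cnt$informativeLoci, 7L)

  expect_identical(countHomozygousObservations(t4, "WD-10", character(0))$n, 0L)

  # one fully typed all-homozygous offspring at 7 maternal-het loci
  mom <- genotypeRow(t4, "WD-10")
  tab <- makeTable(mom, list(O1 = lapply(unname(mom), `[`, 1L)))
  cnt <- countHomozygousObservations(tab, "M")
  expect_identical(cnt$n, 7L)
  expect_identical(cnt$nMissing, 0L)

  expect_error(countHomozygousObservations(t4, "nobody"), "unknown individual")

  # maternally homozygous loci are excluded with a warning
  tab <- makeTable(list(L1 = c(100L, 104L), L2 = c(90L, 90L)),
                   list(O1 = list(100L, 90L)))
  expect_warning(cnt <- countHomozygousObservations(tab, "M"), "uninformative")
  expect_identical(cnt$informativeLoci, "L1")
  expect_identical(cnt$n, 1L)
})

test_that("per-locus sexual homozygosity probability matches enumeration", {
  mom <- c(100L, 104L)
  expect_equal(perLocusSexualHomProb(mom, c("100" = 0.5, "104" = 0.5)), 0.5)
  expect_equal(
    perLocusSexualHomProb(mom, c("100" = 0.3, "104" = 0.2, "108" = 0.5)),
    0.25
  )
  expect_equal(perLocusSexualHomProb(mom, c("200" = 0.6, "204" = 0.4)), 0)
  expect_error(perLocusSexualHomProb(c(100L, 100L), c("100" = 1)),
               "heterozygous")

  # agreement with exhaustive gamete enumeration on random pools
  set.seed(21)
  for (i in 1:25) {
    pool <- randomPool(as.character(sample(c(100L, 104L, 96L, 112L),
                                           sample(2:4, 1))))
    expect_equal(
      perLocusSexualHomProb(mom, pool),
      oracleSexualAllHomProb(list(mom), list(pool))
    )
  }
})

test_that("no paternal pool can push the per-locus probability above 0.5", {
  mom <- c(100L, 104L)
  set.seed(31)
  probs <- replicate(2000, {
    alleles <- as.character(sample(c(96L, 100L, 104L, 108L, 112L),
                                   sample(1:5, 1)))
    perLocusSexualHomProb(mom, randomPool(alleles))
  })
  expect_true(all(probs <= 0.5 + 1e-12))
  # equality iff paternal alleles are confined to the maternal pair
  expect_equal(perLocusSexualHomProb(mom, c("100" = 0.9, "104" = 0.1)), 0.5)
})

test_that("probability bounds reproduce the case-study values and decrease", {
  expect_equal(signif(unlinkedBound(62), 3), 2.17e-19)
  expect_equal(unlinkedBound(0), 1)
  expect_equal(signif(unlinkedBound(9), 3), 1.95e-3)
  expect_equal(signif(linkedBound(9), 3), 1.95e-3)
  expect_equal(linkedBound(1), 0.5)
  expect_equal(linkedBound(0), 1)
  expect_error(unlinkedBound(-1), "non-negative")
  expect_error(linkedBound(-2), "non-negative")

  expect_true(all(diff(vapply(0:80, unlinkedBound, numeric(1))) < 0))
  # perfect linkage is the conservative (larger) bound whenever n >= k >= 1
  for (k in 1:9) {
    for (n in c(k, 2 * k, 7 * k)) {
      expect_lte(unlinkedBound(n), linkedBound(k))
    }
  }
})

test_that("the full screen supports parthenogenesis on the case study", {
  t4 <- waterDragonGenotypes()
  res <- runParthenogenesisTest(t4, "WD-10", alpha = 0.01)
  expect_true(res@verdict)
  expect_identical(res@nHomozygousObs, 62L)
  expect_equal(signif(res@unlinkedBound, 3), 2.17e-19)
  expect_equal(signif(res@linkedBound, 3), 1.95e-3)
  expect_lt(res@unlinkedBound, 0.01)
  expect_lt(res@linkedBound, 0.01)
  expect_identical(reportedP(res), res@unlinkedBound)
  # accounting identity: hom + missing + het = offspring x informative loci
  expect_identical(
    res@nHomozygousObs + res@nMissing + res@nHet,
    length(res@offspringIds) * length(res@informativeLoci)
  )
  resL <- runParthenogenesisTest(t4, "WD-10", assumeLinked = TRUE)
  expect_identical(reportedP(resL), resL@linkedBound)
})

test_that("sexual broods and foreign alleles defeat the verdict", {
  # a simulated sexual brood of 9 x 7 with the worst-case pool essentially
  # always shows heterozygous calls
  cfg <- simulationConfig(mode = "SEXUAL", nLoci = 7, broodSize = 9,
                          seed = 101L)
  tab <- simulateOffspring(simulateMother(cfg), cfg)
  res <- runParthenogenesisTest(tab, "M")
  expect_gt(res@nHet, 0L)
  expect_false(res@verdict)

  # one non-maternal allele vetoes the verdict regardless of the bounds
  t4 <- waterDragonGenotypes()
  mom <- genotypeRow(t4, "WD-10")
  kids <- lapply(1:9, function(i) lapply(unname(mom), `[`, 1L))
  names(kids) <- sprintf("O%d", 1:9)
  kids$O1[[2]] <- 999L
  tab <- makeTable(mom, kids)
  res <- runParthenogenesisTest(tab, "M")
  expect_false(res@verdict)
  expect_lt(reportedP(res), res@alpha)  # the bound alone is not the verdict

  expect_error(
    runParthenogenesisTest(
      makeTable(list(L1 = c(100L, 100L)), list(O1 = list(100L))), "M"),
    "no informative loci")
})

test_that("pooled per-locus probabilities multiply like the enumeration oracle", {
  set.seed(41)
  momCalls <- list(c(100L, 104L), c(90L, 96L), c(200L, 208L))
  for (i in 1:10) {
    nl <- sample(1:3, 1)
    pools <- lapply(seq_len(nl), function(j) {
      universe <- as.character(c(momCalls[[j]], momCalls[[j]] + 2L))
      randomPool(sample(universe, sample(2:4, 1)))
    })
    product <- prod(vapply(seq_len(nl), function(j) {
      perLocusSexualHomProb(momCalls[[j]], pools[[j]])
    }, numeric(1)))
    expect_equal(product,
                 oracleSexualAllHomProb(momCalls[seq_len(nl)], pools))
  }
})
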