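#' Build a simulation configuration
#'
#' Defines the study conditions for brood simulation: locus allele pools,
#' reproductive mode, brood size, dropout rate and seed. With no pool
#' supplied, each locus defaults to the worst-case biallelic pool with equal
#' frequencies — the configuration that maximises the probability of an
#' all-homozygous brood under sexual reproduction, matching the conditions
#' under which the probability bounds are tight (7 loci, brood of 9, as in
#' the water dragon case study).
#'
#' @param mode reproductive mode: `"SEXUAL"`, `"SPERM_STORAGE"` (simulated
#'   identically to sexual — stored sperm is genetically indistinguishable
#'   from fresh mating), `"TERMINAL_FUSION_AUTOMIXIS"`,
#'   `"CENTRAL_FUSION_AUTOMIXIS"`, `"GAMETE_DUPLICATION"`, or
#'   `"HAPLOID_DEVELOPMENT"`.
#' @param nLoci number of loci when `alleleFreqs` is not given.
#' @param alleleFreqs optional list of named numeric frequency vectors, one
#'   per locus (names are allele sizes).
#' @param hRetain heterozygosity-retention probability per locus (recycled);
#'   terminal fusion retains heterozygosity with probability `hRetain`,
#'   central fusion with probability `1 - hRetain`. Default 0 reproduces the
#'   fully homozygous automictic signature.
#' @param broodSize offspring per brood; default 9.
#' @param missingRate per-call dropout probability in `[0, 1)`; default 0.
#' @param seed integer seed.
#' @param loci locus names; default `L1..Ln`.
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(mode = "SEXUAL", nLoci = 7L, alleleFreqs = NULL,
                             hRetain = 0, broodSize = 9L, missingRate = 0,
                             seed = 1L,
                             loci = sprintf("L%d", seq_len(nLoci))) {
  if (is.null(alleleFreqs)) {
    # worst-case biallelic pool, alleles 100/104 at every locus
    alleleFreqs <- rep(list(c("100" = 0.5, "104" = 0.5)), length(loci))
  }
  new("SimulationConfig",
      mode = mode,
      loci = as.character(loci),
      alleleFreqs = alleleFreqs,
      hRetain = rep_len(as.numeric(hRetain), length(loci)),
      broodSize = as.integer(broodSize),
      missingRate = as.numeric(missingRate),
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: mode %s, %d loci, brood %d, missing rate %.3g, seed %d\n",
    object@mode, length(object@loci), object@broodSize, object@missingRate,
    object@seed))
})

# hierarchical substreams: a fixed-offset child seed per unit, so changing the
# brood size never reshuffles earlier offspring
.childSeed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1000003 * k) %% 2147483629
}

.drawAllele <- function(freqs, n = 1L) {
  as.integer(sample(names(freqs), n, replace = TRUE, prob = freqs))
}

#' Simulate a mother genotype
#'
#' Draws two alleles per locus from the population pool; with
#' `requireHet = TRUE` (the default) the draw is conditioned on
#' heterozygosity at every locus, matching the informative-marker selection
#' of a real screen (only maternally heterozygous loci are usable).
#'
#' @param config a [SimulationConfig-class].
#' @param requireHet condition each locus on heterozygosity.
#' @return Named list (by locus) of sorted two-allele integer vectors.
#' @export
simulateMother <- function(config, requireHet = TRUE) {
  validObject(config)
  set.seed(.childSeed(config@seed, 0L))
  out <- vector("list", length(config@loci))
  names(out) <- config@loci
  for (j in seq_along(config@loci)) {
    f <- config@alleleFreqs[[j]]
    if (requireHet && sum(f > 0) < 2L) {
      stop(sprintf(
        "locus %s has a single allele; cannot condition on heterozygosity",
        config@loci[j]))
    }
    repeat {
      pair <- .drawAllele(f, 2L)
      if (!requireHet || pair[1L] != pair[2L]) break
    }
    out[[j]] <- sort(pair)
  }
  out
}

.simulateBroodMatrices <- function(mother, config) {
  nl <- length(config@loci)
  b <- config@broodSize
  a1 <- matrix(NA_integer_, b, nl)
  a2 <- matrix(NA_integer_, b, nl)
  mode <- config@mode
  for (k in seq_len(b)) {
    set.seed(.childSeed(config@seed, k))
    for (j in seq_len(nl)) {
      mom <- mother[[j]]
      mAllele <- mom[sample.int(length(mom), 1L)]
      call <- switch(mode,
        SEXUAL = ,
        SPERM_STORAGE = {
          pat <- .drawAllele(config@alleleFreqs[[j]])
          sort(c(mAllele, pat))
        },
        GAMETE_DUPLICATION = c(mAllele, mAllele),
        HAPLOID_DEVELOPMENT = mAllele,
        TERMINAL_FUSION_AUTOMIXIS = {
          if (stats::runif(1) < config@hRetain[j]) sort(mom)
          else c(mAllele, mAllele)
        },
        CENTRAL_FUSION_AUTOMIXIS = {
          if (stats::runif(1) < 1 - config@hRetain[j]) sort(mom)
          else c(mAllele, mAllele)
        },
        stop(sprintf("unknown mode '%s'", mode))
      )
      if (config@missingRate > 0 && stats::runif(1) < config@missingRate) {
        call <- integer(0)
      }
      if (length(call) >= 1L) a1[k, j] <- call[1L]
      if (length(call) == 2L) a2[k, j] <- call[2L]
    }
  }
  list(allele1 = a1, allele2 = a2)
}

#' Simulate a brood
#'
#' Generates a brood under the configured reproductive mode and returns a
#' [GenotypeTable-class] containing the mother (id `"M"`) and her offspring
#' (`"O1"`, `"O2"`, ...). Per offspring and locus:
#' \itemize{
#'   \item sexual / sperm storage: one maternal allele drawn uniformly plus
#'     one paternal allele drawn from the locus pool;
#'   \item gamete duplication: one maternal allele, duplicated into a
#'     two-equal-allele call;
#'   \item haploid development: one maternal allele, stored as a
#'     single-allele call (preserving the hemizygous ambiguity downstream);
#'   \item terminal fusion automixis: heterozygous with both maternal alleles
#'     with probability `hRetain`, else homozygous for a uniformly chosen
#'     maternal allele; central fusion mirrors this with `1 - hRetain`.
#' }
#' Each call is finally masked to missing with probability `missingRate`.
#'
#' @param mother named list of per-locus maternal calls, as from
#'   [simulateMother()].
#' @param config a [SimulationConfig-class].
#' @return A GenotypeTable with one mother row and `broodSize` offspring.
#' @export
simulateOffspring <- function(mother, config) {
  validObject(config)
  stopifnot(identical(names(mother), config@loci))
  mats <- .simulateBroodMatrices(mother, config)
  ids <- c("M", sprintf("O%d", seq_len(config@broodSize)))
  momCalls <- list(mother)
  kidCalls <- lapply(seq_len(config@broodSize), function(k) {
    lapply(seq_along(config@loci), function(j) {
      al <- c(mats$allele1[k, j], mats$allele2[k, j])
      al[!is.na(al)]
    })
  })
  GenotypeTable(ids, c("mother", rep("offspring", config@broodSize)),
                config@loci, c(momCalls, kidCalls))
}

# vectorized: does each of `reps` simulated sexual broods pass the
# parthenogenetic criteria (every call single-allele and maternal)?
.sexualBroodPasses <- function(mother, config, reps) {
  nl <- length(config@loci)
  b <- config@broodSize
  pass <- rep(TRUE, reps)
  for (j in seq_len(nl)) {
    mom <- mother[[j]]
    f <- config@alleleFreqs[[j]]
    for (k in seq_len(b)) {
      mAl <- mom[sample.int(2L, reps, replace = TRUE)]
      pat <- .drawAllele(f, reps)
      pass <- pass & (pat == mAl)
    }
  }
  pass
}

#' Empirical false-positive rate of the parthenogenesis criteria
#'
#' Simulates sexually produced broods and reports the fraction in which every
#' offspring call would pass the parthenogenetic screen (all alleles
#' maternal, single allele at every maternally heterozygous locus), together
#' with the binomial Monte-Carlo standard error. This is the empirical twin
#' of the analytic product bound: under the worst-case biallelic pool the
#' rate approaches `0.5^(loci x brood)`.
#'
#' @param config a [SimulationConfig-class] with `mode = "SEXUAL"` (or
#'   `"SPERM_STORAGE"`).
#' @param replicates number of simulated broods.
#' @param mother optional maternal genotype; defaults to a heterozygous draw
#'   from the pool via [simulateMother()].
#' @return List with `rate`, `se`, and `replicates`.
#' @export
estimateFalsePositiveRate <- function(config, replicates, mother = NULL) {
  validObject(config)
  if (!config@mode %in% c("SEXUAL", "SPERM_STORAGE")) {
    stop("false-positive rate is defined for sexual-mode configurations")
  }
  if (replicates < 1L) stop("replicates must be >= 1")
  if (is.null(mother)) mother <- simulateMother(config)
  set.seed(.childSeed(config@seed, 1L))
  pass <- .sexualBroodPasses(mother, config, as.integer(replicates))
  rate <- mean(pass)
  list(rate = rate,
       se = sqrt(rate * (1 - rate) / replicates),
       replicates = as.integer(replicates))
}

#' Detection power of the screen across design sizes
#'
#' For each combination of informative-locus count and brood size, the
#' probability that a parthenogenetic brood yields a supported verdict at
#' `alpha`. With `hRetain = 0` (duplication, haploid development, terminal
#' fusion without retained heterozygosity) every call is homozygous, so
#' detection is the deterministic indicator `0.5^(loci x brood) < alpha`;
#' with `hRetain > 0` retained-heterozygosity calls shrink the homozygous
#' count and detection is estimated by simulation.
#'
#' @param mode parthenogenetic mode.
#' @param nLociGrid vector of informative-locus counts.
#' @param broodGrid vector of brood sizes.
#' @param alpha significance level.
#' @param hRetain heterozygosity-retention probability.
#' @param replicates Monte-Carlo replicates for stochastic modes.
#' @param seed integer seed.
#' @return data.frame with columns `nLoci`, `broodSize`, `detection`.
#' @export
powerCurve <- function(mode = "GAMETE_DUPLICATION", nLociGrid = 1:10,
                       broodGrid = 1L, alpha = 0.01, hRetain = 0,
                       replicates = 1000L, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  grid <- expand.grid(nLoci = nLociGrid, broodSize = broodGrid)
  deterministic <- mode %in% c("GAMETE_DUPLICATION", "HAPLOID_DEVELOPMENT") ||
    (hRetain == 0 && mode == "TERMINAL_FUSION_AUTOMIXIS") ||
    (hRetain == 1 && mode == "CENTRAL_FUSION_AUTOMIXIS")
  grid$detection <- mapply(function(nl, b) {
    if (deterministic) {
      return(as.numeric(unlinkedBound(nl * b) < alpha))
    }
    cfg <- simulationConfig(mode = mode, nLoci = nl, hRetain = hRetain,
                            broodSize = b, seed = seed)
    mother <- simulateMother(cfg)
    hits <- vapply(seq_len(replicates), function(r) {
      cfg@seed <- as.integer(.childSeed(seed, r) %% 2147483629)
      tab <- simulateOffspring(mother, cfg)
      res <- runParthenogenesisTest(tab, "M", alpha = alpha)
      res@verdict
    }, logical(1))
    mean(hits)
  }, grid$nLoci, grid$broodSize)
  grid
}
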