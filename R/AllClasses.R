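#' @import methods
NULL

#' GenotypeTable: individuals x loci codominant genotype calls
#'
#' Stores up to two allele fragment sizes (integer base pairs) per individual
#' and locus. Internally two integer matrices hold the smaller and larger
#' allele of each call; a call with a single scored allele has `NA` in the
#' second matrix, and a missing call has `NA` in both. Single-allele calls are
#' deliberately ambiguous between homozygous and hemizygous — fragment-length
#' genotyping cannot tell them apart — and that interpretation is deferred to
#' the zygosity classifier.
#'
#' @slot allele1 integer matrix (individuals x loci), smaller allele or NA.
#' @slot allele2 integer matrix, larger allele; NA for single-allele or
#'   missing calls.
#' @slot role character vector, one of "mother", "offspring", "reference"
#'   per individual, parallel to `rownames(allele1)`.
#'
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  representation(
    allele1 = "matrix",
    allele2 = "matrix",
    role = "character"
  )
)

.validRoles <- c("mother", "offspring", "reference")

setValidity("GenotypeTable", function(object) {
  a1 <- object@allele1
  a2 <- object@allele2
  msg <- character(0)
  if (!is.integer(a1) || !is.integer(a2)) {
    msg <- c(msg, "allele matrices must be integer")
  }
  if (!identical(dim(a1), dim(a2))) {
    msg <- c(msg, "allele matrices must share dimensions")
  }
  if (ncol(a1) < 1L) msg <- c(msg, "at least one locus is required")
  if (is.null(rownames(a1)) || is.null(colnames(a1))) {
    msg <- c(msg, "allele matrices must carry individual and locus names")
  } else {
    if (anyDuplicated(rownames(a1))) {
      msg <- c(msg, "individual ids must be unique")
    }
    if (anyDuplicated(colnames(a1))) msg <- c(msg, "locus names must be unique")
  }
  if (length(object@role) != nrow(a1)) {
    msg <- c(msg, "one role per individual is required")
  } else if (!all(object@role %in% .validRoles)) {
    msg <- c(msg, sprintf(
      "roles must be one of: %s", paste(.validRoles, collapse = ", ")
    ))
  }
  # allele2 implies allele1; sizes positive; pairs sorted
  if (any(!is.na(a2) & is.na(a1))) {
    msg <- c(msg, "second allele present without first")
  }
  if (any(a1 <= 0L, na.rm = TRUE) || any(a2 <= 0L, na.rm = TRUE)) {
    msg <- c(msg, "allele sizes must be strictly positive")
  }
  both <- !is.na(a1) & !is.na(a2)
  if (any(a1[both] > a2[both])) {
    msg <- c(msg, "allele pairs must be stored sorted (allele1 <= allele2)")
  }
  if (length(msg)) msg else TRUE
})

#' ParthenogenesisResult: outcome of the brood-level screen
#'
#' @slot motherId id of the putative mother.
#' @slot offspringIds ids of the screened brood.
#' @slot informativeLoci loci at which the mother is heterozygous (the only
#'   loci that enter the homozygosity count).
#' @slot compatibility data.frame with columns id, compatible,
#'   incompatibleLoci (comma-separated locus names, "" when compatible).
#' @slot nHomozygousObs number of non-missing single-allele offspring calls at
#'   informative loci.
#' @slot nMissing missing offspring calls at informative loci.
#' @slot nHet heterozygous offspring calls at informative loci (each one is
#'   evidence against an all-homozygous parthenogenetic signature).
#' @slot perLocusProb per informative locus, probability that one sexual
#'   mating yields a single-maternal-allele call under the paternal pool used.
#' @slot unlinkedBound probability of the observed all-homozygous calls if
#'   every offspring-by-locus observation is independent.
#' @slot linkedBound probability treating each offspring as one observation
#'   (perfect linkage across loci).
#' @slot alpha significance level.
#' @slot assumeLinked whether the linked bound is the reported p.
#' @slot verdict TRUE when the brood is consistent with parthenogenesis and
#'   the applicable bound falls below alpha.
#'
#' @exportClass ParthenogenesisResult
setClass("ParthenogenesisResult",
  representation(
    motherId = "character",
    offspringIds = "character",
    informativeLoci = "character",
    compatibility = "data.frame",
    nHomozygousObs = "integer",
    nMissing = "integer",
    nHet = "integer",
    perLocusProb = "numeric",
    unlinkedBound = "numeric",
    linkedBound = "numeric",
    alpha = "numeric",
    assumeLinked = "logical",
    verdict = "logical"
  )
)

setValidity("ParthenogenesisResult", function(object) {
  msg <- character(0)
  if (object@alpha <= 0 || object@alpha >= 1) {
    msg <- c(msg, "alpha must lie in (0, 1)")
  }
  for (b in c(object@unlinkedBound, object@linkedBound)) {
    if (b < 0 || b > 1) msg <- c(msg, "bounds must be probabilities")
  }
  if (object@nHomozygousObs < 0L || object@nMissing < 0L || object@nHet < 0L) {
    msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: reproductive-mode brood simulation settings
#'
#' @slot mode one of "SEXUAL", "SPERM_STORAGE", "TERMINAL_FUSION_AUTOMIXIS",
#'   "CENTRAL_FUSION_AUTOMIXIS", "GAMETE_DUPLICATION", "HAPLOID_DEVELOPMENT".
#' @slot loci locus names.
#' @slot alleleFreqs list (one per locus) of named numeric frequency vectors;
#'   names are allele sizes. Used for the paternal pool (sexual modes) and for
#'   drawing maternal genotypes.
#' @slot hRetain per-locus heterozygosity-retention probability used by the
#'   automictic modes.
#' @slot broodSize number of offspring per simulated brood.
#' @slot missingRate per-call probability of masking to a missing genotype.
#' @slot seed integer seed of the hierarchical random stream.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    mode = "character",
    loci = "character",
    alleleFreqs = "list",
    hRetain = "numeric",
    broodSize = "integer",
    missingRate = "numeric",
    seed = "integer"
  )
)

.simModes <- c(
  "SEXUAL", "SPERM_STORAGE", "TERMINAL_FUSION_AUTOMIXIS",
  "CENTRAL_FUSION_AUTOMIXIS", "GAMETE_DUPLICATION", "HAPLOID_DEVELOPMENT"
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (length(object@mode) != 1L || !object@mode %in% .simModes) {
    msg <- c(msg, sprintf("mode must be one of: %s",
                          paste(.simModes, collapse = ", ")))
  }
  nl <- length(object@loci)
  if (nl < 1L) msg <- c(msg, "at least one locus is required")
  if (length(object@alleleFreqs) != nl) {
    msg <- c(msg, "one allele-frequency vector per locus is required")
  } else {
    for (f in object@alleleFreqs) {
      if (is.null(names(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-9) {
        msg <- c(msg, "allele frequencies must be named, non-negative and sum to 1")
        break
      }
    }
  }
  if (length(object@hRetain) != nl ||
      any(object@hRetain < 0 | object@hRetain > 1)) {
    msg <- c(msg, "hRetain must be one probability per locus")
  }
  if (object@broodSize < 1L) msg <- c(msg, "brood size must be >= 1")
  if (object@missingRate < 0 || object@missingRate >= 1) {
    msg <- c(msg, "missing-call rate must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})
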