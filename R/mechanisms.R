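.homMechanisms <- c("TERMINAL_FUSION_AUTOMIXIS", "GAMETE_DUPLICATION",
                    "HAPLOID_DEVELOPMENT")

#' Parthenogenesis mechanisms consistent with a screened brood
#'
#' Reasoning over zygosity signatures at maternally heterozygous loci:
#' \itemize{
#'   \item any non-maternal allele: only sexual reproduction (or sperm
#'     storage, genetically indistinguishable) explains the brood;
#'   \item all offspring calls single-allele: terminal fusion automixis,
#'     gamete duplication, and spontaneous haploid development all produce
#'     complete homozygosity and none can be excluded;
#'   \item some heterozygous calls with maternal-only alleles: gamete
#'     duplication and haploid development are excluded (both force a
#'     single-allele genotype), leaving the automictic fusions, with central
#'     fusion the canonical heterozygosity-retaining mechanism.
#' }
#'
#' @param result a [ParthenogenesisResult-class] computed on `x`.
#' @param x the GenotypeTable the result was computed on.
#' @return Character vector of mechanism names.
#' @export
consistentMechanisms <- function(result, x) {
  if (length(result@offspringIds) == 0L) stop("empty brood")
  if (!all(result@compatibility$compatible)) return("SEXUAL")
  if (result@nHet == 0L) return(.homMechanisms)
  c("TERMINAL_FUSION_AUTOMIXIS", "CENTRAL_FUSION_AUTOMIXIS")
}

#' Multilocus phase patterns of a brood
#'
#' At each maternally heterozygous locus the mother's two alleles are sorted
#' ascending and indexed FIRST/SECOND. A single-allele offspring call maps to
#' the index of the maternal allele it shows; heterozygous or missing calls
#' map to `NA` (unknown). Variation among the resulting multilocus patterns
#' reveals that maternal gametes were not clonal — recombination and/or
#' independent assortment occurred during their formation.
#'
#' @param x a GenotypeTable.
#' @param motherId id of the mother.
#' @param offspringIds brood ids.
#' @return Character matrix (offspring x informative loci) with entries
#'   `"FIRST"`, `"SECOND"` or `NA`.
#' @export
phasePatterns <- function(x, motherId, offspringIds = offspringOf(x)) {
  z <- zygosityMatrix(x)
  info <- loci(x)[z[motherId, ] == "HET"]
  if (length(info) == 0L) stop("mother heterozygous at no locus")
  out <- matrix(NA_character_, length(offspringIds), length(info),
                dimnames = list(offspringIds, info))
  for (id in offspringIds) {
    for (l in info) {
      kid <- genotypeCall(x, id, l)
      if (length(kid) != 1L) next  # HET or missing -> unknown
      mom <- sort(genotypeCall(x, motherId, l))
      idx <- match(kid, mom)
      if (is.na(idx)) {
        stop(sprintf(
          "offspring '%s' carries non-maternal allele %d at %s; run the compatibility screen first",
          id, kid, l))
      }
      out[id, l] <- c("FIRST", "SECOND")[idx]
    }
  }
  out
}

.patternFits <- function(pattern, v) {
  def <- !is.na(pattern)
  all(pattern[def] == v[def]) || all(pattern[def] != v[def])
}

#' Detect multilocus phase variation among offspring
#'
#' Tests whether the brood's phase patterns could all derive from a single
#' complementary pair of multilocus phases (one maternal haplotype
#' configuration and its mirror). Unknown cells act as wildcards and are
#' resolved by exhaustive assignment over candidate phase vectors. A `TRUE`
#' flag means the patterns exceed one complementary pair, i.e. the maternal
#' gametes differ by recombination and/or independent assortment.
#'
#' @param patterns matrix from [phasePatterns()].
#' @return List with `variation` (logical flag) and `nDistinct` (number of
#'   distinct fully-defined patterns).
#' @export
detectPhaseVariation <- function(patterns) {
  defined <- rowSums(!is.na(patterns))
  if (nrow(patterns) < 2L || ncol(patterns) < 2L) {
    stop("need at least two offspring and two informative loci")
  }
  L <- ncol(patterns)
  if (L > 25L) stop("phase search supports at most 25 informative loci")
  # fix the first coordinate of v: complementation symmetry halves the space
  fits <- FALSE
  for (code in 0:(2^(L - 1) - 1)) {
    v <- c("FIRST", ifelse(bitwAnd(code, 2^(0:(L - 2))) > 0, "SECOND", "FIRST"))
    if (L == 1L) v <- "FIRST"
    if (all(apply(patterns, 1L, .patternFits, v = v))) {
      fits <- TRUE
      break
    }
  }
  full <- patterns[defined == ncol(patterns), , drop = FALSE]
  nDistinct <- if (nrow(full)) nrow(unique(full)) else 0L
  list(variation = !fits, nDistinct = nDistinct)
}
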