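#' Count homozygous observations across a brood
#'
#' Only loci at which the mother is heterozygous are informative: at a
#' maternally homozygous locus an all-maternal homozygous offspring is
#' expected under sexual reproduction too, so such loci are excluded (with a
#' warning). The count `n` is the number of offspring-by-locus cells with a
#' non-missing single-allele (`HOM_OR_HEMI`) call at informative loci;
#' missing cells reduce the count and never weigh for or against.
#'
#' @param x a GenotypeTable.
#' @param motherId id of the mother.
#' @param offspringIds brood ids; defaults to all offspring-role individuals.
#' @return List with `n` (homozygous observations), `nMissing`, `nHet`
#'   (heterozygous offspring calls at informative loci) and
#'   `informativeLoci`.
#' @export
countHomozygousObservations <- function(x, motherId,
                                        offspringIds = offspringOf(x)) {
  ids <- c(motherId, offspringIds)
  missingIds <- setdiff(ids, individualIds(x))
  if (length(missingIds)) {
    stop(sprintf("unknown individual(s): %s", paste(missingIds, collapse = ", ")))
  }
  z <- zygosityMatrix(x)
  info <- loci(x)[z[motherId, ] == "HET"]
  dropped <- setdiff(loci(x), info)
  if (length(dropped)) {
    warning(sprintf("mother not heterozygous at %s; excluded as uninformative",
                    paste(dropped, collapse = ", ")))
  }
  if (length(offspringIds) == 0L) {
    return(list(n = 0L, nMissing = 0L, nHet = 0L, informativeLoci = info))
  }
  zo <- z[offspringIds, info, drop = FALSE]
  list(
    n = sum(zo == "HOM_OR_HEMI"),
    nMissing = sum(zo == "MISSING"),
    nHet = sum(zo == "HET"),
    informativeLoci = info
  )
}

#' Probability that one sexual mating yields a single-allele call
#'
#' For a mother heterozygous with alleles A and a at a locus, a sexually
#' produced offspring shows a single allele exactly when the paternal gamete
#' carries the same maternal allele as the (independently drawn) maternal
#' gamete: P = f_A/2 + f_a/2, where f are paternal allele frequencies. The
#' maximum over all paternal pools is 0.5, attained iff the paternal pool is
#' confined to the two maternal alleles — no "equal frequencies" assumption
#' is needed for the bound.
#'
#' @param motherAlleles integer vector of the mother's two distinct alleles.
#' @param pool named numeric vector of paternal allele frequencies (names are
#'   allele sizes); non-negative, summing to at most 1.
#' @return Probability in `[0, 0.5]`.
#' @export
perLocusSexualHomProb <- function(motherAlleles, pool) {
  motherAlleles <- as.integer(motherAlleles)
  if (length(motherAlleles) != 2L || motherAlleles[1L] == motherAlleles[2L]) {
    stop("mother must be heterozygous (two distinct alleles) at the locus")
  }
  if (any(pool < 0) || sum(pool) > 1 + 1e-12) {
    stop("pool frequencies must be non-negative and sum to at most 1")
  }
  f <- pool[as.character(motherAlleles)]
  f[is.na(f)] <- 0
  unname(0.5 * sum(f))
}

#' Worst-case probability of n independent homozygous observations
#'
#' Each offspring-by-locus observation at a maternally heterozygous locus has
#' sexual single-allele probability at most 0.5; assuming observations
#' unlinked (independent across offspring and loci), the probability of n of
#' them is at most `0.5^n`.
#'
#' @param n number of homozygous observations (>= 0).
#' @return `0.5^n`.
#' @export
unlinkedBound <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 0) stop("n must be a non-negative count")
  0.5^n
}

#' Worst-case probability under perfect linkage
#'
#' If all loci were perfectly linked, one offspring contributes a single
#' observation regardless of how many loci were scored; the bound is
#' `0.5^k` for k offspring. This is the conservative alternative to
#' [unlinkedBound()].
#'
#' @param k number of offspring (>= 0).
#' @return `0.5^k`.
#' @export
linkedBound <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 0) stop("k must be a non-negative count")
  0.5^k
}

#' Run the parthenogenesis screen on a brood
#'
#' Composes maternal-compatibility screening, homozygous-observation counting
#' and both worst-case sexual-reproduction probability bounds. The verdict
#' supports parthenogenesis when (i) every offspring carries only maternal
#' alleles, (ii) no offspring is heterozygous at a maternally heterozygous
#' locus, and (iii) the applicable bound falls below `alpha`.
#'
#' When a paternal pool is supplied the per-locus probabilities use the pool
#' frequencies; otherwise the worst-case value 0.5 is used per observation.
#'
#' @param x a GenotypeTable.
#' @param motherId id of the mother.
#' @param offspringIds brood ids; defaults to all offspring-role individuals.
#' @param alpha significance level in (0, 1); default 0.01.
#' @param assumeLinked report the perfect-linkage bound as the primary p.
#' @param pool optional named list (per informative locus) or single named
#'   numeric vector of paternal allele frequencies.
#' @return A [ParthenogenesisResult-class].
#' @export
runParthenogenesisTest <- function(x, motherId,
                                   offspringIds = offspringOf(x),
                                   alpha = 0.01, assumeLinked = FALSE,
                                   pool = NULL) {
  if (length(offspringIds) < 1L) stop("at least one offspring is required")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  suppressWarnings(
    counts <- countHomozygousObservations(x, motherId, offspringIds)
  )
  info <- counts$informativeLoci
  if (length(info) == 0L) {
    stop("test undefined: no informative loci (mother heterozygous nowhere)")
  }
  compat <- maternalCompatibility(x, motherId, offspringIds)

  perLocus <- vapply(info, function(l) {
    mom <- genotypeCall(x, motherId, l)
    if (is.null(pool)) return(0.5)
    p <- if (is.list(pool)) pool[[l]] else pool
    if (is.null(p)) 0.5 else perLocusSexualHomProb(mom, p)
  }, numeric(1))

  z <- zygosityMatrix(x)[offspringIds, info, drop = FALSE]
  # product over the observed single-allele cells, locus by locus
  perCellHom <- sweep(z == "HOM_OR_HEMI", 2, perLocus, `*`)
  unlinked <- prod(ifelse(z == "HOM_OR_HEMI", perCellHom, 1))
  linked <- linkedBound(length(offspringIds))

  allHom <- counts$nHet == 0L
  allCompat <- all(compat$compatible)
  p <- if (assumeLinked) linked else unlinked
  verdict <- allCompat && allHom && p < alpha

  new("ParthenogenesisResult",
      motherId = motherId,
      offspringIds = as.character(offspringIds),
      informativeLoci = info,
      compatibility = compat,
      nHomozygousObs = as.integer(counts$n),
      nMissing = as.integer(counts$nMissing),
      nHet = as.integer(counts$nHet),
      perLocusProb = perLocus,
      unlinkedBound = unlinked,
      linkedBound = linked,
      alpha = alpha,
      assumeLinked = assumeLinked,
      verdict = verdict)
}

#' @describeIn runParthenogenesisTest The bound reported as primary p.
#' @param result a ParthenogenesisResult.
#' @export
reportedP <- function(result) {
  if (result@assumeLinked) result@linkedBound else result@unlinkedBound
}

setMethod("show", "ParthenogenesisResult", function(object) {
  cat("Parthenogenesis screen\n")
  cat(sprintf("  mother: %s; brood: %d offspring; informative loci: %d\n",
              object@motherId, length(object@offspringIds),
              length(object@informativeLoci)))
  cat(sprintf("  maternally compatible: %d / %d offspring\n",
              sum(object@compatibility$compatible),
              nrow(object@compatibility)))
  cat(sprintf(
    "  homozygous observations: n = %d (missing %d, heterozygous %d)\n",
    object@nHomozygousObs, object@nMissing, object@nHet))
  cat(sprintf("  unlinked bound: %s; linked bound: %s\n",
              signif(object@unlinkedBound, 3), signif(object@linkedBound, 3)))
  cat(sprintf("  verdict at alpha = %s: parthenogenesis %s\n",
              format(object@alpha),
              if (object@verdict) "SUPPORTED" else "NOT supported"))
})
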