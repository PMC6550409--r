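#' Classify the zygosity of a genotype call
#'
#' Fragment-length genotyping cannot distinguish a true homozygote (two equal
#' allele copies) from a hemizygote (a single allele copy, as in a haploid
#' individual), so single-allele calls are classified `HOM_OR_HEMI` rather
#' than `HOM`.
#'
#' @param alleles integer vector of 0, 1 or 2 allele sizes (a call as
#'   returned by [genotypeCall()]).
#' @return `"HET"` (two distinct alleles), `"HOM_OR_HEMI"` (one allele, or
#'   two equal), or `"MISSING"` (no alleles).
#' @export
classifyZygosity <- function(alleles) {
  alleles <- as.integer(alleles)
  if (length(alleles) > 2L) stop("a call holds at most two alleles")
  if (length(alleles) == 0L) return("MISSING")
  if (length(alleles) == 2L && alleles[1L] != alleles[2L]) return("HET")
  "HOM_OR_HEMI"
}

#' Zygosity classification of every call in a table
#'
#' @param x a GenotypeTable.
#' @return Character matrix (individuals x loci) of zygosity classes.
#' @export
zygosityMatrix <- function(x) {
  a1 <- x@allele1
  a2 <- x@allele2
  out <- matrix("HOM_OR_HEMI", nrow(a1), ncol(a1), dimnames = dimnames(a1))
  out[is.na(a1)] <- "MISSING"
  out[!is.na(a2) & a1 != a2] <- "HET"
  out
}

#' Screen offspring alleles against the maternal genotype
#'
#' A locus is incompatible when the offspring call is non-missing and carries
#' any allele absent from the mother's call at that locus. Missing offspring
#' calls are skipped, never counted against compatibility. Maternal
#' compatibility is a necessary (not sufficient) condition for
#' parthenogenetic origin.
#'
#' @param x a GenotypeTable.
#' @param motherId id of the mother.
#' @param offspringIds ids to screen; defaults to every individual with role
#'   `"offspring"`.
#' @return data.frame with columns `id`, `compatible` (logical) and
#'   `incompatibleLoci` (comma-separated locus names, `""` when compatible).
#' @export
maternalCompatibility <- function(x, motherId,
                                  offspringIds = offspringOf(x)) {
  mom <- genotypeRow(x, motherId)
  if (any(vapply(mom, length, integer(1)) == 0L)) {
    warning("mother has missing calls; those loci are skipped")
  }
  res <- lapply(offspringIds, function(id) {
    kid <- genotypeRow(x, id)
    bad <- vapply(loci(x), function(l) {
      length(kid[[l]]) > 0L && length(mom[[l]]) > 0L &&
        !all(kid[[l]] %in% mom[[l]])
    }, logical(1))
    data.frame(
      id = id,
      compatible = !any(bad),
      incompatibleLoci = paste(loci(x)[bad], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Individuals with a given role
#'
#' @param x a GenotypeTable.
#' @param role role to select.
#' @return Character vector of ids.
#' @export
offspringOf <- function(x, role = "offspring") {
  rownames(x@allele1)[x@role == role]
}

#' Observed heterozygosity
#'
#' Per individual, H_obs is the fraction of non-missing calls that show two
#' distinct alleles. The pooled mean (total heterozygous calls over total
#' non-missing calls across the subset) is the headline value; the unweighted
#' average of per-individual fractions is reported alongside. The two agree
#' whenever all individuals carry the same number of non-missing calls.
#'
#' @param x a GenotypeTable.
#' @param ids individual subset; defaults to the reference individuals.
#' @return List with `perIndividual` (data.frame: id, nHet, nTyped, hObs),
#'   `meanPooled`, `meanUnweighted`, and both means rounded to 3 decimals
#'   (`meanPooled3`, `meanUnweighted3`).
#' @export
observedHeterozygosity <- function(x, ids = offspringOf(x, "reference")) {
  if (length(ids) == 0L) stop("individual subset must be non-empty")
  z <- zygosityMatrix(x)[ids, , drop = FALSE]
  nHet <- rowSums(z == "HET")
  nTyped <- rowSums(z != "MISSING")
  if (sum(nTyped) == 0L) stop("no non-missing calls in the subset")
  allMissing <- nTyped == 0L
  if (any(allMissing)) {
    warning(sprintf("excluding individual(s) with no typed calls: %s",
                    paste(ids[allMissing], collapse = ", ")))
  }
  keep <- !allMissing
  per <- data.frame(
    id = ids[keep],
    nHet = as.integer(nHet[keep]),
    nTyped = as.integer(nTyped[keep]),
    hObs = nHet[keep] / nTyped[keep],
    stringsAsFactors = FALSE
  )
  pooled <- sum(per$nHet) / sum(per$nTyped)
  unweighted <- mean(per$hObs)
  list(
    perIndividual = per,
    meanPooled = pooled,
    meanUnweighted = unweighted,
    meanPooled3 = round(pooled, 3),
    meanUnweighted3 = round(unweighted, 3)
  )
}

#' Per-locus allele frequencies
#'
#' Frequencies are estimated from allele counts over an individual subset.
#' A single-allele call contributes two copies of its allele (scored as a
#' homozygote; possible null alleles are ignored), a missing call contributes
#' nothing.
#'
#' @param x a GenotypeTable.
#' @param ids individual subset.
#' @return Named list, one element per locus: named numeric vector of
#'   frequencies (names are allele sizes), summing to 1 wherever any call
#'   exists; `numeric(0)` for a locus with no typed calls in the subset.
#' @export
alleleFrequencies <- function(x, ids = offspringOf(x, "reference")) {
  if (length(ids) == 0L) stop("individual subset must be non-empty")
  lapply(stats::setNames(loci(x), loci(x)), function(l) {
    copies <- unlist(lapply(ids, function(id) {
      al <- genotypeCall(x, id, l)
      if (length(al) == 1L) rep(al, 2L) else al
    }))
    if (length(copies) == 0L) return(numeric(0))
    tab <- table(copies)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
}
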