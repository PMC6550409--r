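#' Egg-clutch reproduction summary
#'
#' Fertility and hatch rates as percentages of all eggs recovered. For the
#' water dragon case study: 64 eggs, at least 30 fertile, 2 hatched, giving a
#' fertility rate near 46.875% and a hatch rate of 3.125%.
#'
#' @param eggs total eggs recovered.
#' @param fertile number of fertile eggs (`hatched <= fertile <= eggs`).
#' @param hatched number of eggs that hatched into viable offspring.
#' @return List with the counts, `fertilityRate` and `hatchRate` (exact
#'   percentages) and 3-decimal roundings (`fertilityRate3`, `hatchRate3`).
#' @export
reproductionSummary <- function(eggs, fertile, hatched) {
  if (eggs < 0 || fertile < 0 || hatched < 0) stop("counts must be non-negative")
  if (!(hatched <= fertile && fertile <= eggs)) {
    stop("counts must satisfy hatched <= fertile <= eggs")
  }
  fr <- 100 * fertile / eggs
  hr <- 100 * hatched / eggs
  list(
    eggs = as.integer(eggs), fertile = as.integer(fertile),
    hatched = as.integer(hatched),
    fertilityRate = fr, hatchRate = hr,
    fertilityRate3 = round(fr, 3), hatchRate3 = round(hr, 3)
  )
}

#' Full brood report
#'
#' Bundles every stage of the screen into one JSON-serialisable document:
#' maternal compatibility, the zygosity matrix, observed heterozygosity of
#' the reference individuals (when present), homozygous-observation counts,
#' both probability bounds, the verdict, the consistent parthenogenesis
#' mechanisms and the phase-variation summary. Stages that cannot run (e.g.
#' no offspring) are flagged explicitly rather than dropped.
#'
#' @param x a GenotypeTable.
#' @param motherId id of the mother.
#' @param offspringIds brood ids; defaults to all offspring-role individuals.
#' @param alpha significance level.
#' @param assumeLinked report the perfect-linkage bound as primary.
#' @return Nested list; serialise with [writeReport()].
#' @export
runFullReport <- function(x, motherId, offspringIds = offspringOf(x),
                          alpha = 0.01, assumeLinked = FALSE) {
  doc <- list(
    package = list(
      name = "parthenoscreen",
      version = as.character(utils::packageVersion("parthenoscreen"))
    ),
    input = list(
      individuals = length(individualIds(x)),
      loci = loci(x),
      motherId = motherId,
      offspringIds = as.character(offspringIds)
    ),
    zygosity = as.data.frame(zygosityMatrix(x)),
    notes = character(0)
  )
  refs <- offspringOf(x, "reference")
  if (length(refs)) {
    h <- observedHeterozygosity(x, refs)
    doc$referenceHeterozygosity <- list(
      ids = refs,
      perIndividual = h$perIndividual,
      meanPooled = h$meanPooled,
      meanPooled3 = h$meanPooled3,
      meanUnweighted = h$meanUnweighted
    )
  } else {
    doc$notes <- c(doc$notes, "no reference individuals: H_obs section skipped")
  }
  if (length(offspringIds) == 0L) {
    doc$notes <- c(doc$notes, "no offspring: test skipped")
    return(doc)
  }
  res <- runParthenogenesisTest(x, motherId, offspringIds, alpha = alpha,
                                assumeLinked = assumeLinked)
  patterns <- phasePatterns(x, motherId, offspringIds)
  phase <- if (nrow(patterns) >= 2L && ncol(patterns) >= 2L) {
    detectPhaseVariation(patterns)
  } else {
    doc$notes <- c(doc$notes, "too few offspring/loci for phase analysis")
    NULL
  }
  doc$test <- list(
    informativeLoci = res@informativeLoci,
    compatibility = res@compatibility,
    nHomozygousObs = res@nHomozygousObs,
    nMissing = res@nMissing,
    nHet = res@nHet,
    unlinkedBound = res@unlinkedBound,
    unlinkedBound3sf = signif(res@unlinkedBound, 3),
    linkedBound = res@linkedBound,
    linkedBound3sf = signif(res@linkedBound, 3),
    alpha = res@alpha,
    assumeLinked = res@assumeLinked,
    reportedP = reportedP(res),
    verdict = res@verdict
  )
  doc$mechanisms = list(
    consistent = consistentMechanisms(res, x),
    note = paste(
      "phase variation, when present, indicates recombination and/or",
      "independent assortment in maternal gametes; the two cannot be",
      "distinguished without chromosome assignments"
    )
  )
  if (!is.null(phase)) {
    doc$phaseVariation <- list(
      variation = phase$variation,
      nDistinctFullPatterns = phase$nDistinct
    )
  }
  doc
}

#' Serialise a report to JSON
#'
#' @param doc report list from [runFullReport()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(doc, path) {
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Render a report as text
#'
#' @param doc report list from [runFullReport()].
#' @return Character vector of report lines.
#' @export
formatReport <- function(doc) {
  lines <- c(
    sprintf("parthenoscreen %s report", doc$package$version),
    sprintf("mother %s; %d offspring; loci: %s",
            doc$input$motherId, length(doc$input$offspringIds),
            paste(doc$input$loci, collapse = ", "))
  )
  if (!is.null(doc$referenceHeterozygosity)) {
    lines <- c(lines, sprintf(
      "reference H_obs (pooled mean): %s",
      signif(doc$referenceHeterozygosity$meanPooled, 3)))
  }
  if (!is.null(doc$test)) {
    lines <- c(lines,
      sprintf("maternally compatible offspring: %d / %d",
              sum(doc$test$compatibility$compatible),
              nrow(doc$test$compatibility)),
      sprintf("homozygous observations: %d (missing %d, het %d)",
              doc$test$nHomozygousObs, doc$test$nMissing, doc$test$nHet),
      sprintf("unlinked bound: %s; linked bound: %s; alpha: %s",
              signif(doc$test$unlinkedBound, 3),
              signif(doc$test$linkedBound, 3), doc$test$alpha),
      sprintf("verdict: parthenogenesis %s",
              if (doc$test$verdict) "SUPPORTED" else "NOT supported"),
      sprintf("consistent mechanisms: %s",
              paste(doc$mechanisms$consistent, collapse = ", ")))
  }
  if (!is.null(doc$phaseVariation)) {
    lines <- c(lines, sprintf(
      "phase variation among offspring: %s (%d distinct full patterns)",
      doc$phaseVariation$variation, doc$phaseVariation$nDistinctFullPatterns))
  }
  for (nt in doc$notes) lines <- c(lines, sprintf("note: %s", nt))
  lines
}
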