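# Independent oracles used by unit and acceptance tests. These deliberately
# re-derive results with different machinery than the package (chunk+rle
# scanning, exhaustive gamete enumeration) so agreement is informative.

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracleCanonical <- function(m) {
  n <- nchar(m)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L && strrep(substr(m, 1L, p), n / p) == m) {
      return(NA_character_)
    }
  }
  rots <- function(s) {
    vapply(0:(nchar(s) - 1L), function(i) {
      paste0(substr(s, i + 1L, nchar(s)), substr(s, 1L, i))
    }, character(1))
  }
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", m), "")[[1L]]),
              collapse = "")
  min(c(rots(m), rots(rc)))
}

# brute-force tandem-repeat scan: chunk the sequence at every phase offset of
# every motif length and take rle runs of identical chunks
oracleRepeats <- function(seq, minRepeats, seqId = "seq") {
  n <- nchar(seq)
  rec <- list()
  for (k in c(3L, 4L)) {
    for (off in 0:(k - 1L)) {
      starts <- seq.int(1L + off, n, by = k)
      starts <- starts[starts + k - 1L <= n]
      if (length(starts) < minRepeats) next
      chunks <- substring(seq, starts, starts + k - 1L)
      r <- rle(chunks)
      ends <- cumsum(r$lengths)
      for (ri in which(r$lengths >= minRepeats)) {
        motif <- r$values[ri]
        canon <- oracleCanonical(motif)
        if (is.na(canon)) next
        i0 <- starts[ends[ri] - r$lengths[ri] + 1L]
        rec[[length(rec) + 1L]] <- data.frame(
          seqId = seqId, motif = motif, canonicalMotif = canon,
          start = i0 - 1L, end = i0 - 1L + r$lengths[ri] * k,
          repeats = r$lengths[ri], length = r$lengths[ri] * k,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  df <- if (length(rec)) do.call(rbind, rec) else data.frame(
    seqId = character(0), motif = character(0),
    canonicalMotif = character(0), start = integer(0), end = integer(0),
    repeats = integer(0), length = integer(0), stringsAsFactors = FALSE
  )
  # collapse overlapping reports of one array (rotated phases): per canonical
  # motif keep the record with most repeats, earliest start on ties
  df <- df[order(df$canonicalMotif, df$start), , drop = FALSE]
  out <- df[0, , drop = FALSE]
  i <- 1L
  while (i <= nrow(df)) {
    cur <- df[i, , drop = FALSE]
    j <- i + 1L
    while (j <= nrow(df) && df$canonicalMotif[j] == cur$canonicalMotif &&
           df$start[j] < cur$end) {
      if (df$repeats[j] > cur$repeats) cur <- df[j, , drop = FALSE]
      j <- j + 1L
    }
    out <- rbind(out, cur)
    i <- j
  }
  out <- out[order(out$start, out$canonicalMotif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive enumeration of P(brood member shows a single allele at every
# locus) under sexual reproduction: sum over the full cross product of
# (maternal gamete x paternal allele) outcomes at every locus
oracleSexualAllHomProb <- function(motherCalls, pools) {
  stopifnot(length(motherCalls) == length(pools))
  perLocusOutcomes <- lapply(seq_along(pools), function(j) {
    mom <- motherCalls[[j]]
    f <- pools[[j]]
    grid <- expand.grid(g = seq_along(mom), p = seq_along(f))
    data.frame(
      prob = 0.5 * f[grid$p],
      hom = as.integer(names(f)[grid$p]) == mom[grid$g]
    )
  })
  idx <- do.call(expand.grid, lapply(perLocusOutcomes, function(o) seq_len(nrow(o))))
  total <- 0
  for (r in seq_len(nrow(idx))) {
    pr <- 1
    ok <- TRUE
    for (j in seq_along(perLocusOutcomes)) {
      o <- perLocusOutcomes[[j]][idx[r, j], ]
      pr <- pr * o$prob
      ok <- ok && o$hom
    }
    if (ok) total <- total + pr
  }
  total
}

sortArrays <- function(d) {
  d <- d[order(d$start, d$canonicalMotif), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# random proper frequency vector on a given allele set
randomPool <- function(alleles) {
  w <- stats::rexp(length(alleles))
  stats::setNames(w / sum(w), alleles)
}

# tiny hand-built table: mother + offspring described by per-locus calls
makeTable <- function(motherCalls, offspringCalls, loci = names(motherCalls)) {
  ids <- c("M", names(offspringCalls))
  GenotypeTable(ids, c("mother", rep("offspring", length(offspringCalls))),
                loci, c(list(motherCalls), unname(offspringCalls)))
}
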