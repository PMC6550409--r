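.rotations <- function(motif) {
  n <- nchar(motif)
  vapply(seq_len(n) - 1L, function(s) {
    paste0(substring(motif, s + 1L, n), substring(motif, 1L, s))
  }, character(1))
}

.revComp <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}

.hasInternalPeriod <- function(motif) {
  n <- nchar(motif)
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L) {
      unit <- substring(motif, 1L, p)
      if (paste(rep(unit, n / p), collapse = "") == motif) return(TRUE)
    }
  }
  FALSE
}

#' Canonical form of a microsatellite motif
#'
#' The canonical motif is the lexicographically smallest string among all
#' rotations of the motif and all rotations of its reverse complement, so the
#' same tandem array is named identically whichever phase or strand it was
#' read from. Motifs that are a tandem repetition of a shorter unit (e.g.
#' `ACAC` = (AC)2, homopolymer triplets) are degenerate — they describe a
#' mono- or dinucleotide repeat, not a tri-/tetranucleotide one — and are
#' rejected.
#'
#' @param motif 3 or 4 nt string over ACGT.
#' @return Canonical motif string, or `NA_character_` for a degenerate motif.
#' @export
canonicalMotif <- function(motif) {
  motif <- toupper(motif)
  if (!nchar(motif) %in% c(3L, 4L) || !grepl("^[ACGT]+$", motif)) {
    stop("motif must be 3 or 4 nt over ACGT")
  }
  if (.hasInternalPeriod(motif)) return(NA_character_)
  min(c(.rotations(motif), .rotations(.revComp(motif))))
}

.collapseArrays <- function(df) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(df$canonicalMotif, df$start), , drop = FALSE]
  i <- 1L
  out <- df[0, , drop = FALSE]
  while (i <= nrow(df)) {
    cur <- df[i, , drop = FALSE]
    j <- i + 1L
    while (j <= nrow(df) &&
           df$canonicalMotif[j] == cur$canonicalMotif &&
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

#' Find perfect tri-/tetranucleotide tandem arrays in one sequence
#'
#' Reports every maximal perfect tandem array of a non-degenerate tri- or
#' tetranucleotide motif with at least `minRepeats` copies. Maximality means
#' the array cannot be extended by one full motif copy on either side.
#' Overlapping reports of one array under rotated motifs are collapsed to a
#' single record via [canonicalMotif()]. Coordinates are 0-based, half-open,
#' on the given strand.
#'
#' Detection scans the self-comparison vector `s[i] == s[i+k]` for maximal
#' periodic runs, so runtime is linear in sequence length per motif size.
#'
#' @param sequence nucleotide string.
#' @param minRepeats minimum repeat count (>= 2).
#' @param seqId sequence identifier recorded in the output.
#' @return data.frame with columns `seqId`, `motif` (leading unit as
#'   observed), `canonicalMotif`, `start`, `end`, `repeats`, `length`.
#' @export
findRepeats <- function(sequence, minRepeats = 20L, seqId = "seq") {
  if (minRepeats < 2L) stop("minRepeats must be >= 2")
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  empty <- data.frame(
    seqId = character(0), motif = character(0),
    canonicalMotif = character(0), start = integer(0), end = integer(0),
    repeats = integer(0), length = integer(0), stringsAsFactors = FALSE
  )
  out <- empty
  for (k in c(3L, 4L)) {
    if (n < k * minRepeats) next
    eq <- chars[seq_len(n - k)] == chars[(k + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values)) {
      L <- r$lengths[ri] + k        # length of the periodic stretch
      m <- L %/% k                  # full motif copies, anchored at the start
      if (m < minRepeats) next
      s0 <- starts[ri]              # 1-based start of the stretch
      motif <- paste(chars[s0:(s0 + k - 1L)], collapse = "")
      canon <- canonicalMotif(motif)
      if (is.na(canon)) next        # degenerate (shorter true period)
      out <- rbind(out, data.frame(
        seqId = seqId, motif = motif, canonicalMotif = canon,
        start = s0 - 1L, end = s0 - 1L + m * k,
        repeats = m, length = m * k, stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  .collapseArrays(out)
}

#' Filter candidate arrays for marker development
#'
#' Retains arrays whose repeat count strictly exceeds `minRepeats` (the
#' ">20 repeats" selection rule) and, when an estimated PCR product size is
#' available in a `productSize` column, at most `maxProduct`.
#'
#' @param arrays data.frame as from [findRepeats()].
#' @param minRepeats strict lower bound on repeat count; default 20.
#' @param maxProduct optional upper bound on estimated product size.
#' @return Filtered data.frame.
#' @export
filterCandidates <- function(arrays, minRepeats = 20L, maxProduct = NULL) {
  keep <- arrays$repeats > minRepeats
  if (!is.null(maxProduct) && "productSize" %in% names(arrays)) {
    keep <- keep & (is.na(arrays$productSize) |
                      arrays$productSize <= maxProduct)
  }
  out <- arrays[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine a FASTA file for microsatellite arrays
#'
#' Streams every sequence through [findRepeats()] and summarises the scan:
#' sequences scanned, sequences carrying at least one passing array, and
#' their fraction.
#'
#' @param path FASTA path.
#' @param minRepeats minimum repeat count.
#' @return List with `arrays` (combined data.frame) and `summary` (list:
#'   `nSequences`, `nWithArray`, `fraction`).
#' @export
mineFasta <- function(path, minRepeats = 20L) {
  seqs <- readFastaSequences(path)
  hits <- lapply(seq_along(seqs), function(i) {
    findRepeats(seqs[[i]], minRepeats = minRepeats, seqId = names(seqs)[i])
  })
  arrays <- do.call(rbind, hits)
  rownames(arrays) <- NULL
  withArray <- length(unique(arrays$seqId))
  list(
    arrays = arrays,
    summary = list(
      nSequences = length(seqs),
      nWithArray = withArray,
      fraction = withArray / length(seqs)
    )
  )
}

#' Write mined arrays as TSV
#'
#' @param arrays data.frame from [findRepeats()] or [mineFasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRepeatTsv <- function(arrays, path) {
  utils::write.table(arrays, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write mined arrays as BED
#'
#' BED uses the same 0-based half-open convention as the array coordinates;
#' the name field is `motif x count`.
#'
#' @inheritParams writeRepeatTsv
#' @return `path`, invisibly.
#' @export
writeRepeatBed <- function(arrays, path) {
  bed <- data.frame(
    chrom = arrays$seqId,
    chromStart = arrays$start,
    chromEnd = arrays$end,
    name = sprintf("%sx%d", arrays$canonicalMotif, arrays$repeats),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
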