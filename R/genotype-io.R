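#' Construct a GenotypeTable
#'
#' @param ids character vector of unique individual identifiers.
#' @param roles character vector parallel to `ids`; each one of
#'   `"mother"`, `"offspring"`, `"reference"`.
#' @param loci character vector of locus names.
#' @param calls list of length `length(ids)`; each element a list of
#'   `length(loci)` integer vectors holding 0, 1 or 2 allele fragment sizes
#'   (base pairs). An empty vector encodes a missing call. Two-allele calls
#'   are stored sorted ascending.
#'
#' @return A validated [GenotypeTable-class] object.
#' @export
GenotypeTable <- function(ids, roles, loci, calls) {
  ids <- as.character(ids)
  loci <- as.character(loci)
  n <- length(ids)
  p <- length(loci)
  if (length(roles) != n) stop("one role per individual is required")
  if (length(calls) != n) stop("one call row per individual is required")
  a1 <- matrix(NA_integer_, n, p, dimnames = list(ids, loci))
  a2 <- a1
  for (i in seq_len(n)) {
    row <- calls[[i]]
    if (length(row) != p) {
      stop(sprintf("individual '%s': expected %d calls, got %d",
                   ids[i], p, length(row)))
    }
    for (j in seq_len(p)) {
      al <- sort(as.integer(row[[j]]))
      if (length(al) > 2L) {
        stop(sprintf("individual '%s', locus '%s': more than two alleles",
                     ids[i], loci[j]))
      }
      if (length(al) >= 1L) a1[i, j] <- al[1L]
      if (length(al) == 2L) a2[i, j] <- al[2L]
    }
  }
  new("GenotypeTable", allele1 = a1, allele2 = a2,
      role = as.character(roles))
}

#' @describeIn GenotypeTable Locus names, in table order.
#' @param x a GenotypeTable.
#' @export
loci <- function(x) colnames(x@allele1)

#' @describeIn GenotypeTable Individual identifiers, in table order.
#' @export
individualIds <- function(x) rownames(x@allele1)

#' @describeIn GenotypeTable Role of each individual, named by id.
#' @export
roles <- function(x) stats::setNames(x@role, rownames(x@allele1))

#' Retrieve one genotype call
#'
#' @param x a GenotypeTable.
#' @param id individual identifier.
#' @param locus locus name.
#' @return Integer vector of 0, 1 or 2 allele sizes; `integer(0)` for a
#'   missing call.
#' @export
genotypeCall <- function(x, id, locus) {
  if (!id %in% rownames(x@allele1)) stop(sprintf("unknown individual '%s'", id))
  if (!locus %in% colnames(x@allele1)) stop(sprintf("unknown locus '%s'", locus))
  al <- c(x@allele1[id, locus], x@allele2[id, locus])
  al[!is.na(al)]
}

#' Retrieve all calls of one individual
#'
#' @inheritParams genotypeCall
#' @return Named list (by locus) of integer allele vectors.
#' @export
genotypeRow <- function(x, id) {
  if (!id %in% rownames(x@allele1)) stop(sprintf("unknown individual '%s'", id))
  lapply(stats::setNames(loci(x), loci(x)), function(l) genotypeCall(x, id, l))
}

setMethod("show", "GenotypeTable", function(object) {
  rl <- table(factor(object@role, levels = .validRoles))
  cat(sprintf(
    "GenotypeTable: %d individuals x %d loci (%d mother, %d offspring, %d reference)\n",
    nrow(object@allele1), ncol(object@allele1),
    rl[["mother"]], rl[["offspring"]], rl[["reference"]]
  ))
  miss <- sum(is.na(object@allele1))
  cat(sprintf("  loci: %s\n", paste(loci(object), collapse = ", ")))
  cat(sprintf("  missing calls: %d\n", miss))
})

.parseCell <- function(cell, id, locus, line) {
  cell <- trimws(cell)
  if (cell == "" || toupper(cell) == "NA" ||
      tolower(cell) == "missing") {
    return(integer(0))
  }
  parts <- trimws(strsplit(cell, "/", fixed = TRUE)[[1L]])
  if (!length(parts) || !all(grepl("^[0-9]+$", parts))) {
    stop(sprintf(
      "line %d: non-integer allele '%s' (individual '%s', locus '%s')",
      line, cell, id, locus
    ))
  }
  as.integer(parts)
}

#' Read a genotype table from CSV
#'
#' Expected dialect: header `id,role,<locus1>,<locus2>,...`; one row per
#' individual; within a cell, two alleles are separated by `/`; a missing call
#' is an empty cell or `NA`.
#'
#' @param path path to the CSV file.
#' @return A [GenotypeTable-class].
#' @export
readGenotypeTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("genotype CSV needs a header and at least one row")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  header <- trimws(header)
  if (length(header) < 3L || tolower(header[1L]) != "id" ||
      tolower(header[2L]) != "role") {
    stop("header must be: id,role,<locus names>")
  }
  lociNames <- header[-(1:2)]
  ncols <- length(header)
  ids <- character(0); rls <- character(0); calls <- list()
  for (k in 2:length(lines)) {
    # sentinel keeps strsplit from dropping a trailing empty field
    fields <- strsplit(paste0(lines[k], "\x01"), ",", fixed = TRUE)[[1L]]
    fields[length(fields)] <- sub("\x01$", "", fields[length(fields)])
    if (length(fields) != ncols) {
      stop(sprintf("line %d: expected %d columns, found %d",
                   k, ncols, length(fields)))
    }
    id <- trimws(fields[1L])
    if (id %in% ids) stop(sprintf("line %d: duplicate individual id '%s'", k, id))
    role <- tolower(trimws(fields[2L]))
    if (role %in% c("wild", "ref")) role <- "reference"
    ids <- c(ids, id)
    rls <- c(rls, role)
    calls[[length(calls) + 1L]] <- lapply(seq_along(lociNames), function(j) {
      .parseCell(fields[j + 2L], id, lociNames[j], k)
    })
  }
  GenotypeTable(ids, rls, lociNames, calls)
}

#' Write a genotype table to CSV
#'
#' Inverse of [readGenotypeTable()]: `readGenotypeTable(writeGenotypeTable(x,
#' p))` reproduces `x`.
#'
#' @param x a GenotypeTable.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(x, path) {
  cells <- vapply(seq_len(nrow(x@allele1)), function(i) {
    row <- vapply(seq_len(ncol(x@allele1)), function(j) {
      al <- c(x@allele1[i, j], x@allele2[i, j])
      paste(al[!is.na(al)], collapse = "/")
    }, character(1))
    paste(c(rownames(x@allele1)[i], x@role[i], row), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("id", "role", loci(x)), collapse = ","), cells), path)
  invisible(path)
}

#' Water dragon case-study genotypes
#'
#' The packaged genotype table for the captive Asian water dragon
#' (*Physignathus cocincinus*) case study: mother WD-10 (heterozygous at all
#' seven microsatellite loci), nine of her offspring, and four wild reference
#' individuals from Vietnam. One offspring call (WD-5 at Pcoc7) is missing.
#'
#' @return A [GenotypeTable-class] with 14 individuals and 7 loci.
#' @export
waterDragonGenotypes <- function() {
  readGenotypeTable(system.file("extdata", "waterdragon_genotypes.csv",
                                package = "parthenoscreen", mustWork = TRUE))
}

#' Read FASTA sequences
#'
#' Thin wrapper over Biostrings that uppercases sequences, preserves record
#' order, and warns (but keeps the characters) when a sequence contains
#' non-IUPAC letters.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of uppercase sequences, names are record
#'   ids (first whitespace-delimited token of the header).
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path))
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  iupac <- "^[ACGTRYSWKMBDHVN-]*$"
  bad <- !grepl(iupac, seqs)
  if (any(bad)) {
    warning(sprintf("non-IUPAC characters in %d record(s): %s",
                    sum(bad), paste(utils::head(names(seqs)[bad], 5),
                                    collapse = ", ")))
  }
  seqs
}
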