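## Readers/writers for the formats the pipeline touches, plus haplotype
## collapsing. FASTA goes through Biostrings; the GenePop and tidy-CSV
## genotype dialects are parsed here (no GenePop reader ships with the
## installed stack).

#' Construct a HaplotypeAlignment from character sequences
#'
#' @param sequences named character vector of equal-length sequences over
#'   \{A,C,G,T,N,-\} (case-insensitive; stored upper-case).
#' @return a \code{\linkS4class{HaplotypeAlignment}}
#' @export
haplotypeAlignment <- function(sequences) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  if (length(unique(nchar(sequences))) > 1L)
    stop("alignment error: sequences have unequal lengths")
  new("HaplotypeAlignment",
      sequences = Biostrings::DNAStringSet(toupper(sequences)))
}

#' Read a FASTA alignment
#'
#' Records are kept in file order and upper-cased; the alignment length is
#' taken from the first record and all others must match.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @return a \code{\linkS4class{HaplotypeAlignment}}
#' @export
readFastaAlignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e) stop("format error: ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("format error: empty FASTA file")
  ids <- sub("\\s.*$", "", names(seqs))   # id = first whitespace-delimited token
  if (anyDuplicated(ids)) stop("format error: duplicate record ids")
  names(seqs) <- ids
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    stop("alignment error: records of unequal length (", paste(unique(w), collapse = ", "), ")")
  haplotypeAlignment(stats::setNames(as.character(seqs), ids))
}

#' Write a FASTA alignment
#' @param alignment a \code{HaplotypeAlignment}
#' @param path output file
#' @export
writeFastaAlignment <- function(alignment, path) {
  stopifnot(is(alignment, "HaplotypeAlignment"))
  Biostrings::writeXStringSet(alignment@sequences, path, width = 80L)
  invisible(path)
}

#' Construct a GenotypeMatrix
#'
#' @param alleleA,alleleB integer matrices (individuals x loci); \code{NA}
#'   marks missing calls (both slots NA together).
#' @param population character/factor of population codes per individual.
#' @param ids individual ids (defaults to rownames of \code{alleleA}).
#' @param loci locus names (defaults to colnames of \code{alleleA}).
#' @return a \code{\linkS4class{GenotypeMatrix}}
#' @export
genotypeMatrix <- function(alleleA, alleleB, population, ids = NULL, loci = NULL) {
  alleleA <- as.matrix(alleleA); alleleB <- as.matrix(alleleB)
  storage.mode(alleleA) <- "integer"; storage.mode(alleleB) <- "integer"
  if (is.null(ids)) ids <- rownames(alleleA)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(alleleA)))
  if (is.null(loci)) loci <- colnames(alleleA)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(alleleA)))
  dimnames(alleleA) <- dimnames(alleleB) <- list(ids, loci)
  # enforce joint missingness of the two slots of a call
  miss <- is.na(alleleA) | is.na(alleleB)
  alleleA[miss] <- NA_integer_; alleleB[miss] <- NA_integer_
  new("GenotypeMatrix", alleleA = alleleA, alleleB = alleleB,
      population = factor(population, levels = unique(as.character(population))))
}

#' Read diploid microsatellite genotypes
#'
#' Two dialects are supported. \code{csv}: one row per individual with
#' columns \code{population}, \code{id}, then two columns per locus
#' (named \code{<locus>.1}/\code{<locus>.2} or any paired names); empty
#' cells, \code{NA} or \code{0} mark missing. \code{genepop}: the
#' standard POP-block format with 3-digit (or 2-digit) allele codes,
#' where an all-zero code marks missing.
#'
#' Missing data are encoded uniformly as \code{NA}; populations are kept
#' in file order.
#'
#' @param path input file
#' @param dialect "csv" or "genepop"
#' @return a \code{\linkS4class{GenotypeMatrix}}
#' @export
readGenotypes <- function(path, dialect = c("csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") readGenotypesCsv(path) else readGenotypesGenepop(path)
}

readGenotypesCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("population", "id") %in% names(df)))
    stop("format error: csv dialect needs 'population' and 'id' columns")
  allele_cols <- setdiff(names(df), c("population", "id"))
  if (length(allele_cols) %% 2L != 0L)
    stop("format error: odd allele-column count (two columns per locus required)")
  loci <- unique(sub("\\.[12]$", "", allele_cols))
  if (length(loci) != length(allele_cols) / 2L)
    loci <- allele_cols[seq(1L, length(allele_cols), by = 2L)]
  parse_col <- function(x) {
    x[x %in% c("", "NA", "0")] <- NA
    bad <- !is.na(x) & !grepl("^[0-9]+$", x)
    if (any(bad)) stop("format error: non-integer allele value '", x[bad][1], "'")
    as.integer(x)
  }
  a <- sapply(seq_along(loci), function(j) parse_col(df[[allele_cols[2 * j - 1L]]]))
  b <- sapply(seq_along(loci), function(j) parse_col(df[[allele_cols[2 * j]]]))
  a <- matrix(a, nrow = nrow(df)); b <- matrix(b, nrow = nrow(df))
  genotypeMatrix(a, b, population = df$population, ids = df$id, loci = loci)
}

readGenotypesGenepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 3L) stop("format error: truncated GenePop file")
  body <- lines[-1L]                           # first line is a title comment
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0L) stop("format error: no POP block")
  header <- body[seq_len(pop_idx[1] - 1L)]
  loci <- trimws(unlist(strsplit(paste(header, collapse = ","), ",")))
  loci <- loci[loci != ""]
  n_loci <- length(loci)
  pops <- character(0); ids <- character(0)
  a <- NULL; b <- NULL
  block_starts <- pop_idx; block_ends <- c(pop_idx[-1] - 1L, length(body))
  for (k in seq_along(block_starts)) {
    rows <- body[seq(block_starts[k] + 1L, block_ends[k])]
    rows <- rows[!grepl("^\\s*pop\\s*$", rows, ignore.case = TRUE)]
    for (row in rows) {
      parts <- strsplit(row, ",")[[1]]
      if (length(parts) != 2L) stop("format error: GenePop row lacks 'id , genotypes'")
      id <- trimws(parts[1])
      calls <- strsplit(trimws(parts[2]), "\\s+")[[1]]
      if (length(calls) != n_loci)
        stop("format error: expected ", n_loci, " loci, got ", length(calls))
      digits <- nchar(calls[1]) / 2L
      if (any(nchar(calls) != 2L * digits) || digits < 2L)
        stop("format error: GenePop allele codes must be 2x2 or 2x3 digits")
      if (any(!grepl("^[0-9]+$", calls)))
        stop("format error: non-integer allele in GenePop row")
      a1 <- as.integer(substr(calls, 1L, digits))
      a2 <- as.integer(substr(calls, digits + 1L, 2L * digits))
      a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
      a <- rbind(a, a1); b <- rbind(b, a2)
      ids <- c(ids, id); pops <- c(pops, paste0("pop", k))
    }
  }
  genotypeMatrix(a, b, population = pops, ids = make.unique(ids), loci = loci)
}

#' Write genotypes in the tidy CSV or GenePop dialect
#'
#' @param genotypes a \code{GenotypeMatrix}
#' @param path output file
#' @param dialect "csv" or "genepop"
#' @param digits GenePop allele-code width (3 by default)
#' @export
writeGenotypes <- function(genotypes, path, dialect = c("csv", "genepop"),
                           digits = 3L) {
  dialect <- match.arg(dialect)
  stopifnot(is(genotypes, "GenotypeMatrix"))
  a <- genotypes@alleleA; b <- genotypes@alleleB
  if (dialect == "csv") {
    out <- data.frame(population = as.character(genotypes@population),
                      id = rownames(a), check.names = FALSE,
                      stringsAsFactors = FALSE)
    for (j in seq_len(ncol(a))) {
      out[[paste0(colnames(a)[j], ".1")]] <- a[, j]
      out[[paste0(colnames(a)[j], ".2")]] <- b[, j]
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    fmt <- function(x) {
      x[is.na(x)] <- 0L
      sprintf(paste0("%0", digits, "d"), x)
    }
    con <- file(path, "w"); on.exit(close(con))
    writeLines("kelpconn genotype export", con)
    writeLines(colnames(a), con)
    for (p in levels(genotypes@population)) {
      writeLines("POP", con)
      sel <- which(genotypes@population == p)
      for (i in sel)
        writeLines(paste0(rownames(a)[i], " ,  ",
                          paste0(fmt(a[i, ]), fmt(b[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read sampling-location metadata
#'
#' CSV with columns \code{code,name,lat,lon,source}; codes must be unique,
#' latitudes within [-90, 90], longitudes within [-180, 180], source one
#' of "wild"/"culture".
#' @param path CSV file
#' @return data.frame
#' @export
readPopulationMetadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "name", "lat", "lon", "source")
  if (!all(need %in% names(df)))
    stop("format error: metadata needs columns ", paste(need, collapse = ","))
  if (anyDuplicated(df$code)) stop("format error: duplicate population codes")
  if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
    stop("format error: coordinates out of range")
  if (!all(df$source %in% c("wild", "culture")))
    stop("format error: source must be wild or culture")
  df
}

#' Collapse aligned sequences into a haplotype frequency table
#'
#' Identical sequences share a haplotype label; labels (a, b, c, ...) are
#' assigned in order of first appearance. Sequences that differ only at
#' sites where at least one of them is unresolved (N or -) are merged
#' into the earlier haplotype: two sequences are distinct haplotypes only
#' if they differ at a mutually resolved site.
#'
#' @param alignment a \code{HaplotypeAlignment}
#' @param populationOf named character vector mapping record id to
#'   population code; every id must be mapped.
#' @return a \code{\linkS4class{HaplotypeFreqTable}}
#' @export
collapseHaplotypes <- function(alignment, populationOf) {
  stopifnot(is(alignment, "HaplotypeAlignment"))
  ids <- seqIds(alignment)
  unmapped <- setdiff(ids, names(populationOf))
  if (length(unmapped))
    stop("key error: unmapped sequence id(s): ", paste(utils::head(unmapped, 3), collapse = ", "))
  seqs <- as.character(alignment@sequences)
  reps <- character(0)            # representative sequence per haplotype
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (identical(seqs[i], reps[k]) ||
          resolvedDifferences(seqs[i], reps[k]) == 0L) { hit <- k; break }
    }
    if (hit == 0L) { reps <- c(reps, seqs[i]); hit <- length(reps) }
    assign[i] <- hit
  }
  labels <- hapLabels(length(reps))
  pops <- unique(as.character(populationOf[ids]))
  cts <- matrix(0L, nrow = length(pops), ncol = length(reps),
                dimnames = list(pops, labels))
  for (i in seq_along(seqs))
    cts[populationOf[ids[i]], assign[i]] <- cts[populationOf[ids[i]], assign[i]] + 1L
  new("HaplotypeFreqTable", counts = cts,
      haplotypeSeqs = stats::setNames(reps, labels))
}

#' Construct a frequency table from a count matrix
#' @param counts integer matrix populations x haplotypes (dimnames required,
#'   default labels supplied when absent)
#' @param haplotypeSeqs optional named character of haplotype sequences
#' @return a \code{\linkS4class{HaplotypeFreqTable}}
#' @export
haplotypeFreqTable <- function(counts, haplotypeSeqs = character(0)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts))) colnames(counts) <- hapLabels(ncol(counts))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("P", seq_len(nrow(counts)))
  new("HaplotypeFreqTable", counts = counts, haplotypeSeqs = haplotypeSeqs)
}

#' Expand a frequency table back to per-individual haplotype labels
#'
#' Inverse of \code{\link{collapseHaplotypes}} up to sequence ids: returns
#' one haplotype label per individual, named by population.
#' @param freqTable a \code{HaplotypeFreqTable}
#' @return data.frame with columns population, haplotype
#' @export
expandHaplotypes <- function(freqTable) {
  cts <- hapCounts(freqTable)
  idx <- which(cts > 0, arr.ind = TRUE)
  data.frame(
    population = rep(rownames(cts)[idx[, 1]], cts[idx]),
    haplotype = rep(colnames(cts)[idx[, 2]], cts[idx]),
    stringsAsFactors = FALSE)
}

## haplotype labels a, b, ..., z, aa, ab, ...
hapLabels <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  c(letters, as.vector(t(outer(letters, letters, paste0))))[seq_len(n)]
}

## number of sites at which both sequences are resolved (ACGT) and differ
resolvedDifferences <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(a[ok] != b[ok])
}
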