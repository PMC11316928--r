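## Readers/writers for the tabular formats the toolkit consumes, plus basic
## FASTA statistics. Coordinates follow BED conventions: 0-based half-open
## internally; anything rendered for display is converted to 1-based at the
## display boundary only.

#' Read a BED file of gene positions
#'
#' Accepts 4- to 6-column BED (seqid, start, end, name, score, strand).
#' Missing score defaults to 0 and missing strand to "+". Coordinates are kept
#' 0-based half-open. Input order is preserved.
#'
#' @param path path to a tab-separated BED file.
#' @return data.frame with columns `seqid`, `start`, `end`, `accn`, `score`,
#'   `strand`.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) dataError("readBed: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines))
    return(data.frame(seqid = character(0), start = integer(0), end = integer(0),
                      accn = character(0), score = numeric(0), strand = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 4L))
    dataError("readBed: line %d has %d columns, need >= 4",
              which(n < 4L)[1], n[which(n < 4L)[1]])
  get <- function(i, default = NA_character_)
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) dataError("readBed: non-numeric coordinates at line %d", bad[1])
  if (any(start < 0)) dataError("readBed: negative start at line %d", which(start < 0)[1])
  if (any(start >= end))
    dataError("readBed: start >= end at line %d", which(start >= end)[1])
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[is.na(score)] <- 0
  strand <- get(6, "+")
  strand[is.na(strand) | !(strand %in% c("+", "-"))] <- "+"
  bed <- data.frame(seqid = get(1), start = start, end = end, accn = get(4),
                    score = score, strand = strand, stringsAsFactors = FALSE)
  if (anyDuplicated(bed$accn))
    dataError("readBed: duplicate gene identifiers: %s",
              paste(unique(bed$accn[duplicated(bed$accn)]), collapse = ", "))
  bed
}

#' Write gene records as 6-column BED
#'
#' @param bed data.frame as returned by [readBed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(bed, path) {
  score <- if (is.null(bed$score)) rep(0, nrow(bed)) else bed$score
  strand <- if (is.null(bed$strand)) rep("+", nrow(bed)) else bed$strand
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", bed$seqid, as.integer(bed$start),
                   as.integer(bed$end), bed$accn,
                   formatC(score, format = "fg"), strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read BLAST/LAST tabular hits (12-column outfmt 6)
#'
#' Columns: query, subject, pct_identity, aln_len, mismatches, gap_opens,
#' qstart, qend, sstart, send, evalue, bitscore. Row order is preserved.
#'
#' @param path path to the tab-separated file.
#' @return data.frame with typed columns named as above.
#' @export
readHits <- function(path) {
  if (!file.exists(path)) dataError("readHits: no such file: %s", path)
  cols <- c("query", "subject", "pct_identity", "aln_len", "mismatches",
            "gap_opens", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- data.frame(query = character(0), subject = character(0))
    for (cc in cols[3:12]) out[[cc]] <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n != 12L))
    dataError("readHits: line %d has %d columns, need 12",
              which(n != 12L)[1], n[which(n != 12L)[1]])
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = 1)
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1, any))[1]
    dataError("readHits: non-numeric field at line %d", bad)
  }
  out <- data.frame(query = m[, 1], subject = m[, 2], stringsAsFactors = FALSE)
  for (i in 3:12) out[[cols[i]]] <- num[, i - 2]
  if (any(out$bitscore < 0)) dataError("readHits: negative bitscore")
  out
}

#' Read a map CSV (scaffold, pos, lg, cm)
#'
#' Comma-separated with a mandatory header. Markers may belong to several
#' maps by reading several files into [mapSet()]; within one file the
#' (scaffold, pos, lg) triple must be unique.
#'
#' @param path path to the CSV file.
#' @return data.frame `scaffold`, `pos`, `lg`, `cm`.
#' @export
readMapCSV <- function(path) {
  if (!file.exists(path)) dataError("readMapCSV: no such file: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scaffold", "pos", "lg", "cm")
  if (!all(need %in% names(m)))
    dataError("readMapCSV: header must contain: %s", paste(need, collapse = ", "))
  m <- m[, need]
  m$scaffold <- as.character(m$scaffold)
  m$lg <- as.character(m$lg)
  if (any(is.na(m$pos)) || any(is.na(m$cm)))
    dataError("readMapCSV: non-numeric pos or cm")
  if (any(m$pos < 0)) dataError("readMapCSV: negative marker position")
  dup <- duplicated(m[, c("scaffold", "pos", "lg")])
  if (any(dup))
    dataError("readMapCSV: duplicate (scaffold,pos,lg) at row %d", which(dup)[1])
  m
}

#' Write a marker table as map CSV
#'
#' @param markers data.frame `scaffold`, `pos`, `lg`, `cm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMapCSV <- function(markers, path) {
  utils::write.csv(markers[, c("scaffold", "pos", "lg", "cm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a PED pedigree file
#'
#' Whitespace-separated rows of `name parent_a parent_b`; "0" or "-" denotes
#' an unknown parent. Rows with exactly one known parent are rejected (the
#' gene-dropping model assumes two progenitors or none). Parents referenced
#' but never declared become implicit founders with a warning.
#'
#' @param path path to the PED file.
#' @return a [Pedigree-class] object.
#' @export
readPed <- function(path) {
  if (!file.exists(path)) dataError("readPed: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[ \t]+")
  n <- lengths(fields)
  if (any(n != 3L))
    dataError("readPed: line %d has %d fields, need 3 (name parent_a parent_b)",
              which(n != 3L)[1], n[which(n != 3L)[1]])
  m <- do.call(rbind, fields)
  unk <- function(x) ifelse(x %in% c("0", "-"), NA_character_, x)
  pedigree(data.frame(name = m[, 1], parent_a = unk(m[, 2]),
                      parent_b = unk(m[, 3]), stringsAsFactors = FALSE))
}

#' Write a Pedigree as a PED file
#'
#' @param ped a [Pedigree-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePed <- function(ped, path) {
  e <- pedigreeTable(ped)
  fmt <- function(x) ifelse(is.na(x), "0", x)
  writeLines(sprintf("%s\t%s\t%s", e$name, fmt(e$parent_a), fmt(e$parent_b)), path)
  invisible(path)
}

#' Read a two-column k-mer count histogram
#'
#' jellyfish/KMC `histo` compatible: each row is `multiplicity count`.
#' Duplicate multiplicities are summed; sparse multiplicities are allowed.
#'
#' @param path path to the histogram file.
#' @param k k-mer length if known (informational).
#' @return a [KmerSpectrum-class] object.
#' @export
readHistogram <- function(path, k = 0L) {
  if (!file.exists(path)) dataError("readHistogram: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[ \t]+")
  n <- lengths(fields)
  if (any(n != 2L)) dataError("readHistogram: line %d needs 2 columns", which(n != 2L)[1])
  m <- do.call(rbind, fields)
  j <- suppressWarnings(as.numeric(m[, 1]))
  cnt <- suppressWarnings(as.numeric(m[, 2]))
  if (anyNA(j) || any(j != floor(j)))
    dataError("readHistogram: non-integer multiplicity at line %d",
              which(is.na(j) | j != floor(j))[1])
  if (anyNA(cnt)) dataError("readHistogram: non-numeric count at line %d", which(is.na(cnt))[1])
  if (any(j < 1)) dataError("readHistogram: multiplicity must be >= 1")
  kmerSpectrum(as.integer(j), cnt, k = k)
}

#' Write a KmerSpectrum as a two-column histogram
#'
#' @param spec a [KmerSpectrum-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHistogram <- function(spec, path) {
  tab <- spectrumTable(spec)
  writeLines(sprintf("%d %s", tab$multiplicity, formatC(tab$count, format = "fg")), path)
  invisible(path)
}

#' Read a two-column sequence sizes table
#'
#' @param path tab- or whitespace-separated rows `name length`.
#' @return named numeric vector of lengths.
#' @export
readSizes <- function(path) {
  if (!file.exists(path)) dataError("readSizes: no such file: %s", path)
  m <- utils::read.table(path, stringsAsFactors = FALSE,
                         col.names = c("name", "length"))
  if (any(m$length <= 0)) dataError("readSizes: non-positive length")
  stats::setNames(as.numeric(m$length), m$name)
}

#' Write a sizes table
#'
#' @param sizes named numeric vector of sequence lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

#' Basic statistics of a FASTA file
#'
#' Reports sequence count, total length, N50, GC fraction over non-N bases,
#' and assembly gaps (runs of consecutive N of at least `min_gap` bases,
#' case-insensitive).
#'
#' @param path path to a FASTA file.
#' @param min_gap minimum N-run length counted as a gap (default 1).
#' @return list with `n_seqs`, `total_length`, `n50`, `gc`, `gap_count`,
#'   `gap_length`.
#' @export
fastaStats <- function(path, min_gap = 1L) {
  if (!file.exists(path)) dataError("fastaStats: no such file: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) dataError("fastaStats: no sequences in %s", path)
  lens <- Biostrings::width(seqs)
  total <- sum(lens)
  ## N50: smallest length such that sequences >= it cover half the assembly
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE, collapse = TRUE)
  acgt <- sum(freq[c("A", "C", "G", "T")])
  gc <- if (acgt > 0) sum(freq[c("G", "C")]) / acgt else NA_real_
  ## gaps: N-runs of >= min_gap
  nruns <- Biostrings::vmatchPattern("N", seqs, fixed = TRUE)
  gap_count <- 0L; gap_length <- 0L
  for (i in seq_along(seqs)) {
    ir <- IRanges::reduce(nruns[[i]])
    w <- IRanges::width(ir)
    keep <- w >= min_gap
    gap_count <- gap_count + sum(keep)
    gap_length <- gap_length + sum(w[keep])
  }
  list(n_seqs = length(seqs), total_length = as.integer(total),
       n50 = as.integer(n50), gc = gc, gap_count = as.integer(gap_count),
       gap_length = as.integer(gap_length))
}

#' Read and write the ".anchors" text format
#'
#' Blocks are separated by lines starting with "###"; each pair line is
#' tab-separated `gene_a gene_b score`. Reading then writing reproduces the
#' file byte-exactly.
#'
#' @param path path to the anchors file.
#' @return for `readAnchors`, a data.frame `gene_a`, `gene_b`, `score`,
#'   `block_id`; for `writeAnchors`, `path` invisibly.
#' @export
readAnchors <- function(path) {
  if (!file.exists(path)) dataError("readAnchors: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  block <- cumsum(startsWith(lines, "###"))
  keep <- !startsWith(lines, "###") & nzchar(lines)
  if (!any(keep))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), block_id = integer(0)))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n != 3L)) dataError("readAnchors: pair line needs 3 columns")
  m <- do.call(rbind, fields)
  data.frame(gene_a = m[, 1], gene_b = m[, 2],
             score = as.numeric(m[, 3]),
             block_id = block[keep], stringsAsFactors = FALSE)
}

#' @rdname readAnchors
#' @param anchors data.frame `gene_a`, `gene_b`, `score`, `block_id`.
#' @export
writeAnchors <- function(anchors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in unique(anchors$block_id)) {
    writeLines("###", con)
    sub <- anchors[anchors$block_id == b, ]
    writeLines(sprintf("%s\t%s\t%s", sub$gene_a, sub$gene_b,
                       formatC(sub$score, format = "fg")), con)
  }
  invisible(path)
}

#' Read 4-column Hi-C contact pairs
#'
#' @param path tab-separated rows `chrom1 pos1 chrom2 pos2`.
#' @return data.frame with those columns.
#' @export
readContacts <- function(path) {
  if (!file.exists(path)) dataError("readContacts: no such file: %s", path)
  m <- utils::read.table(path, stringsAsFactors = FALSE,
                         col.names = c("chrom1", "pos1", "chrom2", "pos2"))
  m$chrom1 <- as.character(m$chrom1); m$chrom2 <- as.character(m$chrom2)
  m
}

#' Read a 4-column per-bin depth table (bedgraph-compatible)
#'
#' @param path tab-separated rows `chrom start end depth`.
#' @return data.frame with those columns.
#' @export
readDepth <- function(path) {
  if (!file.exists(path)) dataError("readDepth: no such file: %s", path)
  m <- utils::read.table(path, stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "depth"))
  m$chrom <- as.character(m$chrom)
  m
}

#' Read a tabular haplotype/genotype matrix
#'
#' First two header lines give the marker map: a line `#chrom <tab> c1 c2 ...`
#' and a line `#pos <tab> p1 p2 ...`; each following row is
#' `individual <tab> calls...` with NA or "." for missing.
#'
#' @param path path to the matrix file.
#' @param phased whether calls are phased haplotypes (0/1) or genotype
#'   dosages (0/1/2).
#' @return a [GenotypeMatrix-class] object.
#' @export
readGenotypes <- function(path, phased = TRUE) {
  if (!file.exists(path)) dataError("readGenotypes: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) dataError("readGenotypes: need 2 header lines plus data")
  h1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  h2 <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (h1[1] != "#chrom" || h2[1] != "#pos")
    dataError("readGenotypes: headers must be '#chrom' and '#pos'")
  markers <- data.frame(chrom = h1[-1], pos = as.numeric(h2[-1]),
                        stringsAsFactors = FALSE)
  rows <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  ids <- vapply(rows, `[`, character(1), 1)
  calls <- t(vapply(rows, function(r) {
    v <- r[-1]
    v[v %in% c("NA", ".", "")] <- NA
    as.integer(v)
  }, integer(nrow(markers))))
  rownames(calls) <- ids
  new("GenotypeMatrix", markers = markers, calls = calls, phased = phased)
}

#' Write a GenotypeMatrix in the tabular haplotype format
#'
#' @param g a [GenotypeMatrix-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#chrom", g@markers$chrom), collapse = "\t"), con)
  writeLines(paste(c("#pos", g@markers$pos), collapse = "\t"), con)
  for (i in seq_len(nrow(g@calls))) {
    v <- g@calls[i, ]
    v <- ifelse(is.na(v), "NA", as.character(v))
    writeLines(paste(c(rownames(g@calls)[i], v), collapse = "\t"), con)
  }
  invisible(path)
}
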