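#' @import methods
NULL

#' GeneIndex: the gene-order coordinate system
#'
#' Holds one genome's genes with their chromosome, interval, strand, and
#' per-chromosome rank. Rank is the 0-based ordinal of a gene along its
#' chromosome sorted by start coordinate; all synteny arithmetic (proximal
#' duplicate windows, chaining distances, block spans) runs in rank space so
#' that results are invariant to intergenic distances.
#'
#' @slot genes data.frame with columns `accn`, `seqid`, `start`, `end`,
#'   `strand`, `rank`.
#' @seealso [geneIndex()]
#' @export
setClass("GeneIndex", representation(genes = "data.frame"))

setValidity("GeneIndex", function(object) {
  g <- object@genes
  need <- c("accn", "seqid", "start", "end", "strand", "rank")
  if (!all(need %in% names(g)))
    return(paste("missing columns:", paste(setdiff(need, names(g)), collapse = ", ")))
  if (anyDuplicated(g$accn)) return("duplicate gene identifiers")
  ## ranks must be consecutive 0..n-1 within each seqid
  bad <- vapply(split(g$rank, g$seqid), function(r)
    !identical(sort(as.integer(r)), seq(0L, length(r) - 1L)), logical(1))
  if (any(bad))
    return(paste("non-consecutive ranks on:", paste(names(bad)[bad], collapse = ", ")))
  TRUE
})

#' SyntenyBlocks: chained anchor pairs
#'
#' The result of chaining filtered anchor pairs into synteny blocks. Each
#' block is a single-linkage cluster of gene pairs in rank space with a
#' consistent chromosome pair, an orientation given by the sign of the
#' Spearman correlation of its ranks, and rank-interval spans on both genomes.
#'
#' @slot blocks data.frame, one row per block: `block_id`, `seqid_a`,
#'   `seqid_b`, `orientation`, `span_a_lo`, `span_a_hi`, `span_b_lo`,
#'   `span_b_hi`, `n_pairs`, `score`.
#' @slot pairs data.frame, one row per anchor pair: `block_id`, `gene_a`,
#'   `gene_b`, `rank_a`, `rank_b`, `score`, `cscore`.
#' @seealso [chainBlocks()]
#' @export
setClass("SyntenyBlocks", representation(blocks = "data.frame", pairs = "data.frame"))

setValidity("SyntenyBlocks", function(object) {
  b <- object@blocks; p <- object@pairs
  if (nrow(b) && !all(p$block_id %in% b$block_id)) return("orphan pairs")
  if (nrow(b) && !all(b$orientation %in% c("+", "-"))) return("bad orientation")
  TRUE
})

#' MapSet: a weighted collection of maps
#'
#' Markers tie scaffold positions to linkage-group map positions (cM for
#' genetic maps, or a comparative-map coordinate). Several maps can be
#' combined, each with a positive weight expressing confidence; the
#' scaffold-ordering objective is a weighted sum over maps.
#'
#' @slot markers data.frame with columns `map`, `scaffold`, `pos`, `lg`, `cm`.
#' @slot weights named numeric, one positive weight per map name.
#' @seealso [mapSet()], [orderScaffolds()]
#' @export
setClass("MapSet", representation(markers = "data.frame", weights = "numeric"))

setValidity("MapSet", function(object) {
  m <- object@markers
  need <- c("map", "scaffold", "pos", "lg", "cm")
  if (!all(need %in% names(m)))
    return(paste("missing columns:", paste(setdiff(need, names(m)), collapse = ", ")))
  if (any(m$pos < 0)) return("negative marker position")
  if (!all(unique(m$map) %in% names(object@weights))) return("map without weight")
  if (any(object@weights <= 0)) return("weights must be positive")
  if (anyDuplicated(m[, c("map", "scaffold", "pos", "lg")]))
    return("duplicate (map, scaffold, pos, lg) marker")
  TRUE
})

#' ScaffoldSolution: an ordering and orientation of scaffolds
#'
#' @slot placements data.frame: `chrom`, `position` (1-based slot in the
#'   chromosome), `scaffold`, `orientation` ("+"/"-").
#' @slot fitness numeric scalar, the weighted-rho objective of the solution.
#' @slot rho data.frame of per-map, per-linkage-group Spearman correlations:
#'   `map`, `lg`, `rho`, `n_markers`.
#' @slot unplaced character, scaffolds carrying no markers.
#' @seealso [orderScaffolds()], [solutionFitness()]
#' @export
setClass("ScaffoldSolution", representation(
  placements = "data.frame", fitness = "numeric",
  rho = "data.frame", unplaced = "character"))

setValidity("ScaffoldSolution", function(object) {
  if (anyDuplicated(object@placements$scaffold))
    return("scaffold placed more than once")
  if (nrow(object@placements) &&
      !all(object@placements$orientation %in% c("+", "-")))
    return("bad orientation code")
  TRUE
})

#' KmerSpectrum: an observed k-mer multiplicity histogram
#'
#' @slot k integer k-mer length (0 when unknown).
#' @slot multiplicity integer vector of multiplicities j (>= 1), sorted.
#' @slot count numeric vector, number of distinct k-mers at each multiplicity.
#' @seealso [readHistogram()], [fitSpectrum()]
#' @export
setClass("KmerSpectrum", representation(
  k = "integer", multiplicity = "integer", count = "numeric"))

setValidity("KmerSpectrum", function(object) {
  if (length(object@multiplicity) != length(object@count)) return("length mismatch")
  if (any(object@multiplicity < 1L)) return("multiplicities must be >= 1")
  if (any(object@count < 0)) return("negative counts")
  if (is.unsorted(object@multiplicity, strictly = TRUE)) return("multiplicities must be strictly increasing")
  TRUE
})

#' SpectrumModel: fitted negative binomial mixture for a k-mer spectrum
#'
#' The spectrum is decomposed into subspectra from genome regions of copy
#' number c = 1..c_max; the component for copy number c is a negative binomial
#' with size c*n and success probability p, so its mean coverage scales
#' linearly with copy number. G[c] is the mixing mass: the number of distinct
#' k-mers with genome copy number c.
#'
#' @slot G numeric vector of mixing masses, names "1".."c_max".
#' @slot n numeric, shape parameter of the copy-number-1 component.
#' @slot p numeric in (0,1), negative binomial success probability.
#' @slot c_max integer, highest modeled copy number.
#' @slot l2 numeric, final L2 distance between observed and model spectrum.
#' @slot converged logical.
#' @slot trace numeric vector of L2 values across optimizer rounds.
#' @slot estimate list: genome_size, coverage, repeat_fraction, het_proxy,
#'   ploidy_call (see [genomeEstimate()]).
#' @seealso [fitSpectrum()]
#' @export
setClass("SpectrumModel", representation(
  G = "numeric", n = "numeric", p = "numeric", c_max = "integer",
  l2 = "numeric", converged = "logical", trace = "numeric", estimate = "list"))

setValidity("SpectrumModel", function(object) {
  if (any(object@G < 0)) return("negative mixing mass")
  if (object@n <= 0) return("n must be positive")
  if (object@p <= 0 || object@p >= 1) return("p must lie in (0,1)")
  TRUE
})

#' Pedigree: a directed acyclic graph of individuals
#'
#' Each individual has zero or two named parents. Founders (both parents
#' unknown) are assumed non-inbred and unrelated, carrying unique alleles in
#' gene-dropping simulations.
#'
#' @slot entries data.frame `name`, `parent_a`, `parent_b` (NA = unknown),
#'   stored in a topological order (parents precede children).
#' @slot founders character vector of founder names.
#' @seealso [readPed()], [geneDrop()]
#' @export
setClass("Pedigree", representation(entries = "data.frame", founders = "character"))

setValidity("Pedigree", function(object) {
  e <- object@entries
  if (anyDuplicated(e$name)) return("duplicate individual")
  seen <- character(0)
  for (i in seq_len(nrow(e))) {
    pa <- e$parent_a[i]; pb <- e$parent_b[i]
    if (xor(is.na(pa), is.na(pb))) return("individual with exactly one known parent")
    if (!is.na(pa) && !(pa %in% seen && pb %in% seen))
      return("entries not topologically ordered")
    seen <- c(seen, e$name[i])
  }
  TRUE
})

#' ContactBins: a binned symmetric Hi-C contact matrix
#'
#' @slot matrix symmetric numeric matrix of contact counts over genome bins.
#' @slot bin integer bin size in bp.
#' @slot offsets named integer vector: first bin index (1-based) of each
#'   chromosome in matrix order.
#' @slot nbins named integer vector: bins per chromosome.
#' @slot dropped integer, contacts discarded for falling outside the sizes.
#' @seealso [binContacts()]
#' @export
setClass("ContactBins", representation(
  matrix = "matrix", bin = "integer", offsets = "integer",
  nbins = "integer", dropped = "integer"))

setValidity("ContactBins", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix not square")
  if (any(m < 0)) return("negative counts")
  if (!isTRUE(all.equal(m, t(m)))) return("matrix not symmetric")
  TRUE
})

#' GenotypeMatrix: biallelic haplotype calls over ordered markers
#'
#' @slot markers data.frame `chrom`, `pos`, sorted by (chrom, pos) with
#'   chromosomes in natural order.
#' @slot calls integer matrix, individuals x markers, values 0/1 (allele) with
#'   NA for missing; for unphased genotype input, 0/1/2 dosage codes.
#' @slot phased logical, whether `calls` are haplotypes (TRUE) or genotype
#'   dosages (FALSE).
#' @seealso [readGenotypes()], [ldMatrix()]
#' @export
setClass("GenotypeMatrix", representation(
  markers = "data.frame", calls = "matrix", phased = "logical"))

setValidity("GenotypeMatrix", function(object) {
  if (ncol(object@calls) != nrow(object@markers)) return("marker count mismatch")
  TRUE
})

## ---- show methods ----

setMethod("show", "GeneIndex", function(object) {
  g <- object@genes
  cat(sprintf("GeneIndex: %d genes on %d sequences\n",
              nrow(g), length(unique(g$seqid))))
})

setMethod("show", "SyntenyBlocks", function(object) {
  cat(sprintf("SyntenyBlocks: %d blocks, %d anchor pairs\n",
              nrow(object@blocks), nrow(object@pairs)))
})

setMethod("show", "MapSet", function(object) {
  m <- object@markers
  cat(sprintf("MapSet: %d markers, %d maps (%s), %d linkage groups\n",
              nrow(m), length(object@weights),
              paste(names(object@weights), collapse = ", "),
              length(unique(m$lg))))
})

setMethod("show", "ScaffoldSolution", function(object) {
  cat(sprintf("ScaffoldSolution: %d scaffolds on %d chromosomes, fitness %.4f (%d unplaced)\n",
              nrow(object@placements), length(unique(object@placements$chrom)),
              object@fitness, length(object@unplaced)))
})

setMethod("show", "KmerSpectrum", function(object) {
  cat(sprintf("KmerSpectrum: k=%s, %d multiplicity bins, %.3g distinct k-mers\n",
              if (object@k > 0) object@k else "?", length(object@multiplicity),
              sum(object@count)))
})

setMethod("show", "SpectrumModel", function(object) {
  est <- object@estimate
  cat(sprintf("SpectrumModel: c_max=%d, n=%.3f, p=%.4f, L2=%.4g (%s)\n",
              object@c_max, object@n, object@p, object@l2,
              if (object@converged) "converged" else "not converged"))
  if (length(est))
    cat(sprintf("  genome size %.4g, coverage %.1fx, repeats %.1f%%, ploidy call %d\n",
                est$genome_size, est$coverage, 100 * est$repeat_fraction,
                est$ploidy_call))
})

setMethod("show", "Pedigree", function(object) {
  cat(sprintf("Pedigree: %d individuals, %d founders\n",
              nrow(object@entries), length(object@founders)))
})

setMethod("show", "ContactBins", function(object) {
  cat(sprintf("ContactBins: %d bins at %d bp over %d chromosomes (%d contacts dropped)\n",
              nrow(object@matrix), object@bin, length(object@offsets),
              object@dropped))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d markers (%s)\n",
              nrow(object@calls), ncol(object@calls),
              if (object@phased) "phased haplotypes" else "unphased dosages"))
})

## ---- accessors ----

#' Accessors for cgkit S4 objects
#'
#' Small accessor family: prefer these over direct slot access.
#'
#' @param x a cgkit S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
geneTable <- function(x) {
  stopifnot(is(x, "GeneIndex"))
  x@genes
}

#' @rdname accessors
#' @export
blockTable <- function(x) {
  stopifnot(is(x, "SyntenyBlocks"))
  x@blocks
}

#' @rdname accessors
#' @export
pairTable <- function(x) {
  stopifnot(is(x, "SyntenyBlocks"))
  x@pairs
}

#' @rdname accessors
#' @export
markerTable <- function(x) {
  stopifnot(is(x, "MapSet"))
  x@markers
}

#' @rdname accessors
#' @export
mapWeights <- function(x) {
  stopifnot(is(x, "MapSet"))
  x@weights
}

#' @rdname accessors
#' @export
placements <- function(x) {
  stopifnot(is(x, "ScaffoldSolution"))
  x@placements
}

#' @rdname accessors
#' @export
fitness <- function(x) {
  stopifnot(is(x, "ScaffoldSolution"))
  x@fitness
}

#' @rdname accessors
#' @export
rhoTable <- function(x) {
  stopifnot(is(x, "ScaffoldSolution"))
  x@rho
}

#' @rdname accessors
#' @export
founders <- function(x) {
  stopifnot(is(x, "Pedigree"))
  x@founders
}

#' @rdname accessors
#' @export
pedigreeTable <- function(x) {
  stopifnot(is(x, "Pedigree"))
  x@entries
}

#' @rdname accessors
#' @export
spectrumTable <- function(x) {
  stopifnot(is(x, "KmerSpectrum"))
  data.frame(multiplicity = x@multiplicity, count = x@count)
}

#' @rdname accessors
#' @export
mixingMasses <- function(x) {
  stopifnot(is(x, "SpectrumModel"))
  x@G
}

#' @rdname accessors
#' @export
genomeEstimate <- function(x) {
  stopifnot(is(x, "SpectrumModel"))
  x@estimate
}

#' @rdname accessors
#' @export
contactMatrix <- function(x) {
  stopifnot(is(x, "ContactBins"))
  x@matrix
}

## ---- constructors ----

#' Build a GeneIndex from gene records
#'
#' Assigns each gene its 0-based rank along its chromosome (sorted by start,
#' ties by end then accession, so ranking is permutation-stable).
#'
#' @param genes data.frame with columns `seqid`, `start`, `end`, `accn` and
#'   optionally `strand` (defaulting to "+"), e.g. from [readBed()].
#' @return a [GeneIndex-class] object.
#' @examples
#' bed <- data.frame(seqid = "chr1", start = c(0, 200), end = c(100, 300),
#'                   accn = c("g1", "g2"))
#' geneIndex(bed)
#' @export
geneIndex <- function(genes) {
  need <- c("seqid", "start", "end", "accn")
  if (!all(need %in% names(genes)))
    dataError("geneIndex: missing columns: %s",
              paste(setdiff(need, names(genes)), collapse = ", "))
  if (anyDuplicated(genes$accn))
    dataError("geneIndex: duplicate gene identifiers: %s",
              paste(unique(genes$accn[duplicated(genes$accn)]), collapse = ", "))
  if (is.null(genes$strand)) genes$strand <- "+"
  g <- genes[order(genes$seqid, genes$start, genes$end, genes$accn, method = "radix"), ]
  g$rank <- as.integer(stats::ave(seq_len(nrow(g)), g$seqid, FUN = seq_along)) - 1L
  rownames(g) <- NULL
  new("GeneIndex", genes = g[, c("accn", "seqid", "start", "end", "strand", "rank")])
}

#' Build a MapSet from marker tables
#'
#' @param markers either one data.frame with columns `scaffold`, `pos`, `lg`,
#'   `cm` (single map) or a named list of such data.frames (one per map).
#' @param weights named numeric of positive per-map weights; defaults to 1
#'   for every map.
#' @return a [MapSet-class] object.
#' @examples
#' m <- data.frame(scaffold = "s1", pos = c(100, 900), lg = "LG1", cm = c(0, 1))
#' mapSet(m)
#' @export
mapSet <- function(markers, weights = NULL) {
  if (is.data.frame(markers)) markers <- list(map1 = markers)
  if (is.null(names(markers)) || any(names(markers) == ""))
    dataError("mapSet: maps must be named")
  tab <- do.call(rbind, lapply(names(markers), function(nm) {
    m <- markers[[nm]]
    data.frame(map = rep(nm, nrow(m)), scaffold = as.character(m$scaffold),
               pos = as.numeric(m$pos), lg = as.character(m$lg),
               cm = as.numeric(m$cm), stringsAsFactors = FALSE)
  }))
  if (is.null(weights)) {
    weights <- rep(1, length(markers))
    names(weights) <- names(markers)
  }
  new("MapSet", markers = tab, weights = weights)
}

#' Build a KmerSpectrum from multiplicities and counts
#'
#' Duplicate multiplicities are summed.
#'
#' @param multiplicity integer vector of multiplicities (>= 1).
#' @param count numeric vector of distinct-k-mer counts.
#' @param k k-mer length if known (informational).
#' @return a [KmerSpectrum-class] object.
#' @export
kmerSpectrum <- function(multiplicity, count, k = 0L) {
  if (length(multiplicity) != length(count))
    dataError("kmerSpectrum: multiplicity/count length mismatch")
  agg <- tapply(count, multiplicity, sum)
  j <- as.integer(names(agg))
  o <- order(j)
  new("KmerSpectrum", k = as.integer(k), multiplicity = j[o],
      count = as.numeric(agg)[o])
}

#' Build a Pedigree from an entries table
#'
#' Parents must either both be named or both be unknown (NA); individuals are
#' reordered topologically. Parents referenced but never declared are added as
#' implicit founders with a warning (pedigree files in the wild commonly
#' truncate ancestry).
#'
#' @param entries data.frame with columns `name`, `parent_a`, `parent_b`
#'   (NA for unknown).
#' @return a [Pedigree-class] object.
#' @export
pedigree <- function(entries) {
  e <- data.frame(name = as.character(entries$name),
                  parent_a = as.character(entries$parent_a),
                  parent_b = as.character(entries$parent_b),
                  stringsAsFactors = FALSE)
  one <- xor(is.na(e$parent_a), is.na(e$parent_b))
  if (any(one))
    dataError("pedigree: individuals with exactly one known parent: %s",
              paste(e$name[one], collapse = ", "))
  if (anyDuplicated(e$name))
    dataError("pedigree: duplicate individuals: %s",
              paste(unique(e$name[duplicated(e$name)]), collapse = ", "))
  refs <- setdiff(stats::na.omit(c(e$parent_a, e$parent_b)), e$name)
  if (length(refs)) {
    warning(sprintf("pedigree: undeclared parents added as implicit founders: %s",
                    paste(refs, collapse = ", ")), call. = FALSE)
    e <- rbind(data.frame(name = refs, parent_a = NA_character_,
                          parent_b = NA_character_, stringsAsFactors = FALSE), e)
  }
  ## Kahn topological sort; detects cycles
  placed <- character(0)
  remaining <- e
  out <- e[0, ]
  while (nrow(remaining)) {
    ready <- is.na(remaining$parent_a) |
      (remaining$parent_a %in% placed & remaining$parent_b %in% placed)
    if (!any(ready))
      dataError("pedigree: cycle detected involving: %s",
                paste(remaining$name, collapse = ", "))
    out <- rbind(out, remaining[ready, ])
    placed <- c(placed, remaining$name[ready])
    remaining <- remaining[!ready, ]
  }
  rownames(out) <- NULL
  new("Pedigree", entries = out, founders = out$name[is.na(out$parent_a)])
}
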