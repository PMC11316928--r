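## Synteny inference from gene-anchored alignment hits: C-score computation,
## anchor filtering (score cutoff + proximal-duplicate removal), rank-space
## chaining into blocks, and synteny-depth summaries.

#' Compute C-scores for alignment hits
#'
#' The C-score of a hit (A, B) is its alignment score divided by the maximum
#' score achieved by either gene in any hit:
#' `C = score(A,B) / max(best score of A, best score of B)`.
#' It normalizes scores to (0, 1]: a value of 1 marks a hit whose score equals
#' the best score either of its genes ever achieves, which makes the cutoff
#' independent of database size (unlike E-values) and robust to repeats.
#'
#' @param hits data.frame of hits as returned by [readHits()] (columns
#'   `query`, `subject`, `bitscore` are used).
#' @return `hits` with an added `cscore` column.
#' @examples
#' h <- data.frame(query = c("A", "A", "C"), subject = c("B", "C", "B"),
#'                 bitscore = c(100, 200, 200))
#' computeCScores(h)$cscore  # A-B: 100/200 = 0.5
#' @export
computeCScores <- function(hits) {
  if (nrow(hits) == 0L) dataError("computeCScores: no hits")
  if (any(!nzchar(hits$query)) || any(!nzchar(hits$subject)))
    dataError("computeCScores: empty gene identifier")
  if (all(hits$bitscore == 0)) dataError("computeCScores: all scores zero, C-score undefined")
  ## best score per gene across both roles
  gene <- c(hits$query, hits$subject)
  sc <- c(hits$bitscore, hits$bitscore)
  best <- tapply(sc, gene, max)
  denom <- pmax(best[hits$query], best[hits$subject])
  hits$cscore <- as.numeric(hits$bitscore / denom)
  hits
}

#' Filter anchor pairs by C-score and proximal duplicates
#'
#' Keeps pairs whose C-score is at least `cscore_cutoff` (inclusive), then
#' removes repetitive matches between proximal duplicates: for each gene, its
#' partners lying on the same chromosome are clustered by single linkage at
#' rank distance at most `proximal_dist`; within each cluster only the
#' best-scoring pair survives (ties broken by the smaller partner rank, so the
#' output is deterministic).
#'
#' @param pairs data.frame with `query`, `subject`, `bitscore`, `cscore`
#'   (from [computeCScores()]).
#' @param index_a,index_b [GeneIndex-class] for the query and subject genome
#'   (pass the same object for self-comparison).
#' @param cscore_cutoff minimum C-score retained (default 0.7).
#' @param proximal_dist rank-distance window defining proximal duplicates
#'   (default 10 genes).
#' @return the surviving subset of `pairs`, with added `seqid_a`, `rank_a`,
#'   `seqid_b`, `rank_b` columns.
#' @export
filterAnchors <- function(pairs, index_a, index_b = index_a,
                          cscore_cutoff = 0.7, proximal_dist = 10L) {
  ga <- geneTable(index_a); gb <- geneTable(index_b)
  ia <- match(pairs$query, ga$accn); ib <- match(pairs$subject, gb$accn)
  missing <- unique(c(pairs$query[is.na(ia)], pairs$subject[is.na(ib)]))
  if (length(missing))
    dataError("filterAnchors: genes absent from index: %s",
              paste(utils::head(missing, 10), collapse = ", "))
  pairs$seqid_a <- ga$seqid[ia]; pairs$rank_a <- ga$rank[ia]
  pairs$seqid_b <- gb$seqid[ib]; pairs$rank_b <- gb$rank[ib]
  pairs <- pairs[pairs$cscore >= cscore_cutoff, , drop = FALSE]
  if (nrow(pairs) == 0L) return(pairs)

  ## proximal-duplicate removal, applied from each side
  drop <- rep(FALSE, nrow(pairs))
  markLosers <- function(gene_of, partner_seqid, partner_rank) {
    for (rows in split(seq_len(nrow(pairs)), pairs[[gene_of]])) {
      if (length(rows) < 2L) next
      for (sub in split(rows, pairs[[partner_seqid]][rows])) {
        if (length(sub) < 2L) next
        r <- pairs[[partner_rank]][sub]
        o <- order(r)
        sub <- sub[o]; r <- r[o]
        grp <- cumsum(c(1L, diff(r) > proximal_dist))  # single linkage on sorted ranks
        for (g in split(sub, grp)) {
          if (length(g) < 2L) next
          sc <- pairs$bitscore[g]
          win <- g[order(-sc, pairs[[partner_rank]][g])][1]
          drop[setdiff(g, win)] <<- TRUE
        }
      }
    }
  }
  markLosers("query", "seqid_b", "rank_b")
  markLosers("subject", "seqid_a", "rank_a")
  out <- pairs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain anchor pairs into synteny blocks
#'
#' Single-linkage clustering of anchor pairs in rank space: two pairs are
#' linked iff they share the same chromosome pair and their rank gaps are at
#' most `dist` on both genomes. Clusters with fewer than `min_size` pairs are
#' discarded. Within a block, pairs are sorted by `rank_a`; block orientation
#' is the sign of the Spearman correlation of (rank_a, rank_b), "+" on ties.
#' With `strict = TRUE`, pairs violating the block's monotone trend are
#' dropped afterwards (longest monotone subsequence in the block orientation)
#' and the block re-tested against `min_size`.
#'
#' @param pairs filtered anchor pairs from [filterAnchors()].
#' @param dist maximum rank gap linking two pairs (default 20 genes).
#' @param min_size minimum pairs per block (default 4).
#' @param self remove the trivial self-diagonal (gene paired with itself)
#'   before chaining; use for self-comparisons.
#' @param strict apply the strict-collinearity post-filter.
#' @return a [SyntenyBlocks-class] object.
#' @export
chainBlocks <- function(pairs, dist = 20L, min_size = 4L, self = FALSE,
                        strict = FALSE) {
  need <- c("query", "subject", "seqid_a", "rank_a", "seqid_b", "rank_b")
  if (!all(need %in% names(pairs)))
    dataError("chainBlocks: pairs must come from filterAnchors()")
  if (self) pairs <- pairs[pairs$query != pairs$subject, , drop = FALSE]
  emptyBlocks <- function() new("SyntenyBlocks",
    blocks = data.frame(block_id = integer(0), seqid_a = character(0),
                        seqid_b = character(0), orientation = character(0),
                        span_a_lo = integer(0), span_a_hi = integer(0),
                        span_b_lo = integer(0), span_b_hi = integer(0),
                        n_pairs = integer(0), score = numeric(0)),
    pairs = data.frame(block_id = integer(0), gene_a = character(0),
                       gene_b = character(0), rank_a = integer(0),
                       rank_b = integer(0), score = numeric(0),
                       cscore = numeric(0)))
  if (nrow(pairs) == 0L) return(emptyBlocks())

  key <- paste(pairs$seqid_a, pairs$seqid_b, sep = "\r")
  comp <- integer(nrow(pairs))
  next_id <- 0L
  for (rows in split(seq_len(nrow(pairs)), key)) {
    o <- order(pairs$rank_a[rows], pairs$rank_b[rows])
    rows <- rows[o]
    ra <- pairs$rank_a[rows]; rb <- pairs$rank_b[rows]
    n <- length(rows)
    ei <- integer(0); ej <- integer(0)
    for (i in seq_len(n)) {           # only forward neighbours within dist on A
      j <- i + 1L
      while (j <= n && ra[j] - ra[i] <= dist) {
        if (abs(rb[j] - rb[i]) <= dist) { ei <- c(ei, i); ej <- c(ej, j) }
        j <- j + 1L
      }
    }
    lab <- unionFindComponents(n, ei, ej)
    comp[rows] <- lab + next_id
    next_id <- next_id + max(lab)
  }

  blk_rows <- split(seq_len(nrow(pairs)), comp)
  blk_rows <- blk_rows[lengths(blk_rows) >= min_size]
  if (!length(blk_rows)) return(emptyBlocks())

  out_pairs <- list(); out_blocks <- list()
  bid <- 0L
  for (rows in blk_rows) {
    rows <- rows[order(pairs$rank_a[rows], pairs$rank_b[rows])]
    ra <- pairs$rank_a[rows]; rb <- pairs$rank_b[rows]
    rho <- spearmanRho(ra, rb)
    ori <- if (rho < 0) "-" else "+"
    if (strict) {
      keep <- longestMonotoneRun(rb, decreasing = (ori == "-"))
      rows <- rows[keep]
      if (length(rows) < min_size) next
      ra <- pairs$rank_a[rows]; rb <- pairs$rank_b[rows]
    }
    bid <- bid + 1L
    out_pairs[[bid]] <- data.frame(
      block_id = bid, gene_a = pairs$query[rows], gene_b = pairs$subject[rows],
      rank_a = ra, rank_b = rb, score = pairs$bitscore[rows],
      cscore = if (is.null(pairs$cscore)) NA_real_ else pairs$cscore[rows],
      stringsAsFactors = FALSE)
    out_blocks[[bid]] <- data.frame(
      block_id = bid, seqid_a = pairs$seqid_a[rows[1]],
      seqid_b = pairs$seqid_b[rows[1]], orientation = ori,
      span_a_lo = min(ra), span_a_hi = max(ra),
      span_b_lo = min(rb), span_b_hi = max(rb),
      n_pairs = length(rows), score = sum(pairs$bitscore[rows]),
      stringsAsFactors = FALSE)
  }
  if (bid == 0L) return(emptyBlocks())
  new("SyntenyBlocks", blocks = do.call(rbind, out_blocks),
      pairs = do.call(rbind, out_pairs))
}

## indices of a longest monotone (strictly increasing or decreasing)
## subsequence; classic O(n log n) patience algorithm
longestMonotoneRun <- function(x, decreasing = FALSE) {
  if (decreasing) x <- -x
  n <- length(x)
  if (n <= 1L) return(seq_len(n))
  tails <- integer(0)      # indices of smallest tail of each length
  prev <- integer(n)
  for (i in seq_len(n)) {
    vals <- x[tails]
    pos <- which(vals >= x[i])[1]   # strict increase: replace first tail >= x[i]
    if (is.na(pos)) pos <- length(tails) + 1L
    prev[i] <- if (pos > 1L) tails[pos - 1L] else 0L
    tails[pos] <- i
  }
  out <- integer(length(tails))
  k <- tails[length(tails)]
  for (j in rev(seq_along(tails))) { out[j] <- k; k <- prev[k] }
  out
}

#' Synteny depth per gene and modal depth ratio
#'
#' For each gene of one genome, its synteny depth is the number of blocks
#' whose rank span on that genome's axis covers the gene. A 1:1 orthologous
#' comparison gives modal depth 1 on both axes; a genome triplication shared
#' before divergence gives depth 3 against the other descendant (the classic
#' 3:3 pattern of the core-eudicot paleohexaploidy).
#'
#' @param blocks a [SyntenyBlocks-class] object.
#' @param index [GeneIndex-class] of the genome on the chosen axis.
#' @param axis "a" or "b": which side of the blocks to summarize.
#' @return list with `depth` (integer per-gene depth, named by accession),
#'   `histogram` (table depth -> gene count), `modal` (modal depth over genes
#'   with depth > 0; 0 if none).
#' @export
syntenyDepth <- function(blocks, index, axis = c("a", "b")) {
  axis <- match.arg(axis)
  g <- geneTable(index)
  depth <- stats::setNames(integer(nrow(g)), g$accn)
  b <- blockTable(blocks)
  if (nrow(b)) {
    seq_col <- paste0("seqid_", axis)
    lo_col <- paste0("span_", axis, "_lo"); hi_col <- paste0("span_", axis, "_hi")
    for (i in seq_len(nrow(b))) {
      sel <- g$seqid == b[[seq_col]][i] & g$rank >= b[[lo_col]][i] & g$rank <= b[[hi_col]][i]
      depth[sel] <- depth[sel] + 1L
    }
  }
  hist <- table(depth)
  covered <- depth[depth > 0L]
  list(depth = depth, histogram = hist,
       modal = if (length(covered)) modalValue(covered) else 0L)
}

#' Modal synteny depth ratio between two genomes
#'
#' @param blocks a [SyntenyBlocks-class] object.
#' @param index_a,index_b [GeneIndex-class] objects for the two genomes.
#' @return string "p:q" with p the modal depth over genes of genome A and q
#'   over genome B.
#' @export
depthRatio <- function(blocks, index_a, index_b) {
  da <- syntenyDepth(blocks, index_a, "a")
  db <- syntenyDepth(blocks, index_b, "b")
  sprintf("%d:%d", da$modal, db$modal)
}
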