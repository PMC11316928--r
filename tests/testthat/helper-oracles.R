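## Independent oracles used by the tests. These deliberately re-derive
## quantities by definition (brute force / recursion), independent of the
## package implementations they check.

## N50 by definition: scan sorted lengths until the cumulative sum reaches
## half the total.
oracleN50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  run <- 0
  for (x in s) {
    run <- run + x
    if (run >= half) return(x)
  }
}

## C-score by definition: per-hit loop over the full table.
oracleCScores <- function(hits) {
  vapply(seq_len(nrow(hits)), function(i) {
    q <- hits$query[i]; s <- hits$subject[i]
    best_q <- max(hits$bitscore[hits$query == q | hits$subject == q])
    best_s <- max(hits$bitscore[hits$query == s | hits$subject == s])
    hits$bitscore[i] / max(best_q, best_s)
  }, numeric(1))
}

## Exhaustive transitive closure for chaining: pairs i, j are linked iff same
## chromosome pair and rank gaps <= dist on both genomes; clusters via BFS on
## the full adjacency matrix. Returns list of clusters (index vectors) with
## >= min_size members.
oracleChainClusters <- function(pairs, dist = 20L, min_size = 4L) {
  n <- nrow(pairs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- pairs$seqid_a[i] == pairs$seqid_a[j] &&
      pairs$seqid_b[i] == pairs$seqid_b[j] &&
      abs(pairs$rank_a[i] - pairs$rank_a[j]) <= dist &&
      abs(pairs$rank_b[i] - pairs$rank_b[j]) <= dist
  }
  seen <- rep(FALSE, n)
  clusters <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i; queue <- i; seen[i] <- TRUE
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      nb <- which(adj[k, ] & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb); queue <- c(queue, nb)
    }
    if (length(comp) >= min_size) clusters[[length(clusters) + 1L]] <- sort(comp)
  }
  clusters
}

## Brute-force proximal-duplicate filter: for each gene on each side, cluster
## its partners (same seqid) by BFS over |rank diff| <= d, keep best bitscore
## (tie -> smaller partner rank).
oracleProximalFilter <- function(pairs, d = 10L) {
  n <- nrow(pairs)
  drop <- rep(FALSE, n)
  mark <- function(gene_col, pseq_col, prank_col) {
    for (g in unique(pairs[[gene_col]])) {
      rows <- which(pairs[[gene_col]] == g)
      for (sq in unique(pairs[[pseq_col]][rows])) {
        sub <- rows[pairs[[pseq_col]][rows] == sq]
        if (length(sub) < 2) next
        adj <- abs(outer(pairs[[prank_col]][sub], pairs[[prank_col]][sub], "-")) <= d
        seen <- rep(FALSE, length(sub))
        for (s in seq_along(sub)) {
          if (seen[s]) next
          comp <- s; queue <- s; seen[s] <- TRUE
          while (length(queue)) {
            k <- queue[1]; queue <- queue[-1]
            nb <- which(adj[k, ] & !seen)
            seen[nb] <- TRUE; comp <- c(comp, nb); queue <- c(queue, nb)
          }
          cl <- sub[comp]
          if (length(cl) < 2) next
          win <- cl[order(-pairs$bitscore[cl], pairs[[prank_col]][cl])][1]
          drop[setdiff(cl, win)] <<- TRUE
        }
      }
    }
  }
  mark("query", "seqid_b", "rank_b")
  mark("subject", "seqid_a", "rank_a")
  pairs[!drop, , drop = FALSE]
}

## Exact inbreeding coefficient by the classic kinship recursion:
## F(x) = phi(father, mother); phi(a,a) = (1 + F(a)) / 2; founders unrelated.
oracleInbreeding <- function(ped, target) {
  e <- pedigreeTable(ped)
  pa <- stats::setNames(e$parent_a, e$name)
  pb <- stats::setNames(e$parent_b, e$name)
  order_ix <- stats::setNames(seq_len(nrow(e)), e$name)
  memo <- new.env()
  phi <- function(x, y) {
    if (order_ix[[x]] > order_ix[[y]]) { t <- x; x <- y; y <- t }
    key <- paste(x, y)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (x == y) {
      if (is.na(pa[[x]])) 0.5 else 0.5 * (1 + phi(pa[[x]], pb[[x]]))
    } else if (is.na(pa[[y]])) {
      0   # y is a founder and x precedes it: unrelated
    } else {
      0.5 * (phi(x, pa[[y]]) + phi(x, pb[[y]]))
    }
    memo[[key]] <- val
    val
  }
  if (is.na(pa[[target]])) return(0)
  phi(pa[[target]], pb[[target]])
}

## All permutations of a small vector (for exhaustive scaffold OO search).
allPermutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in allPermutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

## Exhaustive optimum over all permutations x orientations of one chromosome.
oracleBestArrangement <- function(maps, sizes, chrom = "LG1", gap_size = 100) {
  scs <- naturalSort(unique(markerTable(maps)$scaffold))
  n <- length(scs)
  best <- -Inf; best_sol <- NULL
  for (pm in allPermutations(seq_len(n))) {
    for (mask in 0:(2^n - 1)) {
      ori <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, "-", "+")
      sol <- new("ScaffoldSolution",
                 placements = data.frame(chrom = chrom, position = seq_len(n),
                                         scaffold = scs[pm], orientation = ori[pm],
                                         stringsAsFactors = FALSE),
                 fitness = 0, rho = data.frame(), unplaced = character(0))
      f <- solutionFitness(sol, maps, sizes, gap_size)
      if (f > best) { best <- f; best_sol <- sol }
    }
  }
  list(fitness = best, sol = best_sol)
}

## A placement table is the truth or its full reversal (orientations flipped).
matchesUpToReversal <- function(pl, truth) {
  fwd <- identical(pl$scaffold, truth$scaffold) &&
    identical(pl$orientation, truth$orientation)
  flip <- c("+" = "-", "-" = "+")
  rev_ok <- identical(pl$scaffold, rev(truth$scaffold)) &&
    identical(pl$orientation, unname(flip[rev(truth$orientation)]))
  fwd || rev_ok
}

## random anchor-pair table on a 2x2 chromosome grid for property tests
randomPairTable <- function(n_hits, n_ranks = 30L) {
  data.frame(
    query = sprintf("a%d", seq_len(n_hits)),
    subject = sprintf("b%d", seq_len(n_hits)),
    bitscore = stats::runif(n_hits, 50, 500),
    cscore = 1,
    seqid_a = sample(c("A1", "A2"), n_hits, TRUE),
    rank_a = sample.int(n_ranks, n_hits, TRUE) - 1L,
    seqid_b = sample(c("B1", "B2"), n_hits, TRUE),
    rank_b = sample.int(n_ranks, n_hits, TRUE) - 1L,
    stringsAsFactors = FALSE)
}
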