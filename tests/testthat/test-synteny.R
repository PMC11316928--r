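## small deterministic gene index: one genome with 2 chromosomes x n genes
makeIndex <- function(prefix = "a", n = 20L, chroms = c("c1", "c2")) {
  geneIndex(do.call(rbind, lapply(chroms, function(ch) data.frame(
    seqid = paste0(prefix, ch), start = (seq_len(n) - 1L) * 1000L,
    end = (seq_len(n) - 1L) * 1000L + 500L,
    accn = sprintf("%s_%s_g%d", prefix, ch, seq_len(n)),
    stringsAsFactors = FALSE))))
}

test_that("C-score matches its definition", {
  h <- data.frame(query = c("A", "A", "C"), subject = c("B", "C", "B"),
                  bitscore = c(100, 200, 200), stringsAsFactors = FALSE)
  cs <- computeCScores(h)$cscore
  expect_equal(cs[1], 0.5)          # 100 / max(200, 200)
  expect_equal(cs[2], 1)
  expect_equal(cs[3], 1)

  single <- data.frame(query = "A", subject = "B", bitscore = 42)
  expect_equal(computeCScores(single)$cscore, 1)  # its own maximum

  allzero <- data.frame(query = "A", subject = "B", bitscore = 0)
  expect_error(computeCScores(allzero), "undefined")
})

test_that("C-scores lie in (0,1] and the genome-wide best hit scores exactly 1", {
  set.seed(21)
  for (rep in 1:10) {
    h <- data.frame(query = sample(sprintf("q%d", 1:8), 25, TRUE),
                    subject = sample(sprintf("s%d", 1:8), 25, TRUE),
                    bitscore = runif(25, 1, 500))
    cs <- computeCScores(h)$cscore
    expect_true(all(cs > 0 & cs <= 1))
    expect_equal(max(cs), 1)     # the top-scoring hit is its own genes' best
  }
})

test_that("anchor filter boundary is inclusive and removes proximal duplicates", {
  ia <- makeIndex("a"); ib <- makeIndex("b")
  ga <- geneTable(ia); gb <- geneTable(ib)
  pick_a <- function(r) ga$accn[ga$seqid == "ac1" & ga$rank == r]
  pick_b <- function(r) gb$accn[gb$seqid == "bc1" & gb$rank == r]

  pairs <- data.frame(query = c(pick_a(0), pick_a(1), pick_a(2)),
                      subject = c(pick_b(0), pick_b(1), pick_b(2)),
                      bitscore = 100, cscore = c(0.69, 0.70, 0.71))
  kept <- filterAnchors(pairs, ia, ib)
  expect_equal(nrow(kept), 2L)              # 0.70 is kept: inclusive cutoff
  expect_setequal(kept$cscore, c(0.70, 0.71))

  ## gene A hits tandem copies at ranks 5 (score 90) and 8 (score 100)
  tandem <- data.frame(query = pick_a(0), subject = c(pick_b(5), pick_b(8)),
                       bitscore = c(90, 100), cscore = 1)
  kept <- filterAnchors(tandem, ia, ib)
  expect_equal(kept$subject, pick_b(8))

  ## partners at rank distance 11: outside the window, both kept
  far <- data.frame(query = pick_a(0), subject = c(pick_b(5), pick_b(16)),
                    bitscore = c(90, 100), cscore = 1)
  expect_equal(nrow(filterAnchors(far, ia, ib)), 2L)

  bad <- data.frame(query = "nosuch", subject = pick_b(0), bitscore = 1, cscore = 1)
  expect_error(filterAnchors(bad, ia, ib), "nosuch")
})

test_that("filter and chain defaults follow the documented configuration", {
  expect_equal(eval(formals(filterAnchors)$cscore_cutoff), 0.7)
  expect_equal(eval(formals(filterAnchors)$proximal_dist), 10L)
  expect_equal(eval(formals(chainBlocks)$dist), 20L)
  expect_equal(eval(formals(chainBlocks)$min_size), 4L)
})

test_that("chaining links pairs within the distance cutoff on both genomes", {
  ia <- makeIndex("a", n = 60L, chroms = "c1")
  ib <- makeIndex("b", n = 60L, chroms = "c1")
  mk <- function(ra, rb) data.frame(
    query = sprintf("a_c1_g%d", ra + 1L), subject = sprintf("b_c1_g%d", rb + 1L),
    bitscore = 100, cscore = 1, seqid_a = "ac1", rank_a = ra,
    seqid_b = "bc1", rank_b = rb, stringsAsFactors = FALSE)

  five <- do.call(rbind, lapply(0:4, function(i) mk(i, i)))
  bl <- chainBlocks(five)
  expect_equal(nrow(blockTable(bl)), 1L)
  expect_equal(blockTable(bl)$orientation, "+")
  expect_equal(blockTable(bl)$n_pairs, 5L)

  three <- do.call(rbind, lapply(0:2, function(i) mk(i, i)))
  expect_equal(nrow(blockTable(chainBlocks(three))), 0L)  # below min 4 pairs

  ## two 4-pair runs separated by a 21-gene gap on genome A: two blocks
  run1 <- do.call(rbind, lapply(0:3, function(i) mk(i, i)))
  run2 <- do.call(rbind, lapply(24:27, function(i) mk(i, i)))
  expect_equal(nrow(blockTable(chainBlocks(rbind(run1, run2)))), 2L)
  ## at gap exactly 20 they merge
  run2b <- do.call(rbind, lapply(23:26, function(i) mk(i, i)))
  expect_equal(nrow(blockTable(chainBlocks(rbind(run1, run2b)))), 1L)

  ## reversed run: orientation "-"
  neg <- do.call(rbind, lapply(0:4, function(i) mk(i, 10 - i)))
  expect_equal(blockTable(chainBlocks(neg))$orientation, "-")
})

test_that("chaining equals the exhaustive transitive-closure oracle", {
  set.seed(33)
  for (rep in 1:8) {
    pairs <- randomPairTable(sample(40:120, 1))
    bl <- chainBlocks(pairs, dist = 5L, min_size = 3L)
    got <- unname(lapply(split(seq_len(nrow(pairTable(bl))),
                               pairTable(bl)$block_id), function(ix) {
      p <- pairTable(bl)[ix, ]
      sort(paste(p$gene_a, p$gene_b))
    }))
    want <- lapply(oracleChainClusters(pairs, dist = 5L, min_size = 3L),
                   function(ix) sort(paste(pairs$query[ix], pairs$subject[ix])))
    expect_setequal(got, want)
  }
})

test_that("proximal-duplicate filter equals the brute-force oracle", {
  set.seed(44)
  ia <- makeIndex("a", n = 40L); ib <- makeIndex("b", n = 40L)
  ga <- geneTable(ia); gb <- geneTable(ib)
  for (rep in 1:8) {
    n <- sample(30:80, 1)
    pairs <- data.frame(query = sample(ga$accn, n, TRUE),
                        subject = sample(gb$accn, n, TRUE),
                        bitscore = round(runif(n, 50, 500)), cscore = 1,
                        stringsAsFactors = FALSE)
    pairs <- pairs[!duplicated(pairs[, c("query", "subject")]), ]
    got <- filterAnchors(pairs, ia, ib, cscore_cutoff = 0)
    ## oracle needs the rank columns; borrow them from an unfiltered pass
    full <- filterAnchors(pairs, ia, ib, cscore_cutoff = 0, proximal_dist = -1L)
    want <- oracleProximalFilter(full, d = 10L)
    expect_setequal(paste(got$query, got$subject), paste(want$query, want$subject))
  }
})

test_that("raising the C-score cutoff never increases survivors; raising dist never drops chained pairs", {
  set.seed(55)
  ia <- makeIndex("a", n = 40L); ib <- makeIndex("b", n = 40L)
  ga <- geneTable(ia); gb <- geneTable(ib)
  n <- 60
  pairs <- data.frame(query = sample(ga$accn, n, TRUE),
                      subject = sample(gb$accn, n, TRUE),
                      bitscore = runif(n, 50, 500),
                      cscore = runif(n), stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pairs[, c("query", "subject")]), ]
  kept <- vapply(c(0.2, 0.5, 0.7, 0.9),
                 function(ct) nrow(filterAnchors(pairs, ia, ib, cscore_cutoff = ct)),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))

  chained <- vapply(c(2L, 5L, 10L, 30L), function(d) {
    bl <- chainBlocks(filterAnchors(pairs, ia, ib, cscore_cutoff = 0),
                      dist = d, min_size = 3L)
    nrow(pairTable(bl))
  }, numeric(1))
  expect_true(all(diff(chained) >= 0))
})

test_that("swapping the two genomes mirrors blocks and preserves orientation", {
  set.seed(66)
  pairs <- randomPairTable(60)
  swapped <- data.frame(query = pairs$subject, subject = pairs$query,
                        bitscore = pairs$bitscore, cscore = pairs$cscore,
                        seqid_a = pairs$seqid_b, rank_a = pairs$rank_b,
                        seqid_b = pairs$seqid_a, rank_b = pairs$rank_a,
                        stringsAsFactors = FALSE)
  b1 <- blockTable(chainBlocks(pairs, dist = 6L, min_size = 3L))
  b2 <- blockTable(chainBlocks(swapped, dist = 6L, min_size = 3L))
  key1 <- sort(sprintf("%s|%s|%d-%d|%d-%d|%s", b1$seqid_a, b1$seqid_b,
                       b1$span_a_lo, b1$span_a_hi, b1$span_b_lo, b1$span_b_hi,
                       b1$orientation))
  key2 <- sort(sprintf("%s|%s|%d-%d|%d-%d|%s", b2$seqid_b, b2$seqid_a,
                       b2$span_b_lo, b2$span_b_hi, b2$span_a_lo, b2$span_a_hi,
                       b2$orientation))
  expect_identical(key1, key2)
})

test_that("synteny depth counts block coverage per gene", {
  ## genome A duplicated (two copies of the same 12 genes), B single copy:
  ## every A gene sits in 1 block, every B gene in 2 -> modal ratio 1:2
  n <- 12L
  bed_a <- do.call(rbind, lapply(1:2, function(cp) data.frame(
    seqid = sprintf("a%d", cp), start = (seq_len(n) - 1L) * 100L,
    end = (seq_len(n) - 1L) * 100L + 50L,
    accn = sprintf("a%d_g%d", cp, seq_len(n)), stringsAsFactors = FALSE)))
  bed_b <- data.frame(seqid = "b1", start = (seq_len(n) - 1L) * 100L,
                      end = (seq_len(n) - 1L) * 100L + 50L,
                      accn = sprintf("b_g%d", seq_len(n)), stringsAsFactors = FALSE)
  ia <- geneIndex(bed_a); ib <- geneIndex(bed_b)
  pairs <- do.call(rbind, lapply(1:2, function(cp) data.frame(
    query = sprintf("a%d_g%d", cp, seq_len(n)),
    subject = sprintf("b_g%d", seq_len(n)),
    bitscore = 100, cscore = 1, seqid_a = sprintf("a%d", cp),
    rank_a = seq_len(n) - 1L, seqid_b = "b1", rank_b = seq_len(n) - 1L,
    stringsAsFactors = FALSE)))
  bl <- chainBlocks(pairs)
  expect_equal(depthRatio(bl, ia, ib), "1:2")

  empty <- chainBlocks(pairs[0, ])
  d0 <- syntenyDepth(empty, ia, "a")
  expect_true(all(d0$depth == 0L))
  expect_equal(d0$modal, 0L)
})

test_that("self-comparison drops the diagonal and reports 1:1 between copies", {
  n <- 10L
  bed <- do.call(rbind, lapply(1:2, function(cp) data.frame(
    seqid = sprintf("c%d", cp), start = (seq_len(n) - 1L) * 100L,
    end = (seq_len(n) - 1L) * 100L + 50L,
    accn = sprintf("c%d_g%d", cp, seq_len(n)), stringsAsFactors = FALSE)))
  gi <- geneIndex(bed)
  self_pairs <- data.frame(query = bed$accn, subject = bed$accn,
                           bitscore = 500, cscore = 1, seqid_a = bed$seqid,
                           rank_a = rep(seq_len(n) - 1L, 2), seqid_b = bed$seqid,
                           rank_b = rep(seq_len(n) - 1L, 2), stringsAsFactors = FALSE)
  cross <- data.frame(query = sprintf("c1_g%d", seq_len(n)),
                      subject = sprintf("c2_g%d", seq_len(n)),
                      bitscore = 450, cscore = 0.9, seqid_a = "c1",
                      rank_a = seq_len(n) - 1L, seqid_b = "c2",
                      rank_b = seq_len(n) - 1L, stringsAsFactors = FALSE)
  bl <- chainBlocks(rbind(self_pairs, cross), self = TRUE)
  expect_false(any(pairTable(bl)$gene_a == pairTable(bl)$gene_b))
  expect_equal(depthRatio(bl, gi, gi), "1:1")
})

test_that("strict collinearity post-filter drops trend violators", {
  mk <- function(ra, rb) data.frame(
    query = sprintf("qa%d", ra), subject = sprintf("sb%d", rb),
    bitscore = 100, cscore = 1, seqid_a = "A", rank_a = ra,
    seqid_b = "B", rank_b = rb, stringsAsFactors = FALSE)
  ## increasing run with one violator at rank_b far off-trend but in range
  pairs <- rbind(mk(0, 0), mk(1, 1), mk(2, 9), mk(3, 3), mk(4, 4), mk(5, 5))
  loose <- chainBlocks(pairs, min_size = 4L)
  strict <- chainBlocks(pairs, min_size = 4L, strict = TRUE)
  expect_equal(blockTable(loose)$n_pairs, 6L)
  expect_equal(blockTable(strict)$n_pairs, 5L)
  expect_false("sb9" %in% pairTable(strict)$gene_b)
})
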