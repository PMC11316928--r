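test_that("ldR2 reproduces the analytic cases", {
  expect_equal(ldR2(0.5, 0.5, 0.5), 1)        # complete LD
  expect_equal(ldR2(0.3, 0.6, 0.18), 0)       # p_ab = p_a p_b: equilibrium
  expect_equal(ldR2(0.5, 0.5, 0.35), 0.16)    # (0.35-0.25)^2 / 0.0625
  expect_true(is.nan(ldR2(1, 0.5, 0.5)))      # monomorphic
})

test_that("ldR2 is symmetric and invariant under allele-label swaps", {
  set.seed(3)
  for (rep in 1:20) {
    pa <- runif(1, 0.1, 0.9); pb <- runif(1, 0.1, 0.9)
    lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
    pab <- runif(1, lo, hi)
    expect_equal(ldR2(pa, pb, pab), ldR2(pb, pa, pab))
    ## swapping labels at marker a: p_a -> 1 - p_a, p_ab -> p_b - p_ab
    expect_equal(ldR2(pa, pb, pab), ldR2(1 - pa, pb, pb - pab))
  }
})

test_that("ldMatrix matches squared Pearson correlation on complete haplotypes", {
  set.seed(7)
  calls <- vapply(runif(12, 0.2, 0.8),
                  function(q) rbinom(300, 1L, q), integer(300))
  g <- new("GenotypeMatrix",
           markers = data.frame(chrom = rep(c("chr1", "chr2"), each = 6),
                                pos = rep(1:6, 2) * 1e5),
           calls = calls, phased = TRUE)
  ld <- ldMatrix(g)
  want <- stats::cor(calls)^2
  diag(want) <- 1
  expect_equal(ld$r2, want, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("duplicated markers show r2 = 1; monomorphic markers are NaN", {
  set.seed(8)
  x <- rbinom(100, 1L, 0.5)
  calls <- cbind(x, x, rbinom(100, 1L, 0.4), 1L)
  g <- new("GenotypeMatrix",
           markers = data.frame(chrom = "chr1", pos = (1:4) * 1e5),
           calls = calls, phased = TRUE)
  ld <- ldMatrix(g)
  expect_equal(ld$r2[1, 2], 1)
  expect_true(all(is.nan(ld$r2[4, -4])))
  expect_error(ldMatrix(new("GenotypeMatrix",
                            markers = data.frame(chrom = "c", pos = 1),
                            calls = matrix(0L, 5, 1), phased = TRUE)),
               ">= 2 markers")
})

test_that("independent markers give mean off-diagonal r2 near 1/n", {
  set.seed(12)
  n <- 500L
  sc <- genPedigreeAndGenotypes(n_markers = 50L, n_individuals = n, seed = 12)
  ld <- ldMatrix(sc$genotypes)
  off <- ld$r2[upper.tri(ld$r2)]
  se <- stats::sd(off) / sqrt(length(off))
  expect_lt(abs(mean(off) - 1 / n), 3 * se)
})

test_that("a planted translocation produces its inter-chromosome hot block", {
  sc <- genPedigreeAndGenotypes(n_markers = 60L, n_individuals = 400L,
                                translocation = TRUE, seed = 5)
  ld <- ldMatrix(sc$genotypes)
  bm <- ld$block_means
  hot <- bm[which.max(bm$mean_r2), ]
  expect_setequal(unlist(hot[, c("chrom1", "chrom2")]), sc$truth$translocation)
})

test_that("contact binning is symmetric and scores diagonality", {
  sizes <- c(chr1 = 1e6, chr2 = 5e5)
  onediag <- data.frame(chrom1 = c("chr1", "chr2"), pos1 = c(1e5, 2e5),
                        chrom2 = c("chr1", "chr2"), pos2 = c(1.1e5, 2.2e5))
  cb <- binContacts(onediag, sizes, bin = 1e5)
  expect_true(isSymmetric(contactMatrix(cb)))
  expect_true(all(diagonalityScore(cb) == 1))

  outside <- rbind(onediag, data.frame(chrom1 = "chr9", pos1 = 1,
                                       chrom2 = "chr1", pos2 = 1))
  expect_warning(cb2 <- binContacts(outside, sizes, bin = 1e5), "dropped 1")
  expect_equal(cb2@dropped, 1L)
})

test_that("uniform random contacts split between chromosomes as bin counts predict", {
  set.seed(20)
  sizes <- c(chr1 = 1e6, chr2 = 1e6)
  n <- 4000L
  ch1 <- sample(names(sizes), n, TRUE); ch2 <- sample(names(sizes), n, TRUE)
  contacts <- data.frame(chrom1 = ch1, pos1 = runif(n, 0, 1e6),
                         chrom2 = ch2, pos2 = runif(n, 0, 1e6))
  cb <- binContacts(contacts, sizes, bin = 1e5)
  m <- contactMatrix(cb)
  inter <- sum(m[1:10, 11:20])
  ## each endpoint picks either chromosome uniformly: half the pairs inter
  expect_lt(abs(inter / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("an inverted segment lowers diagonality against its unscrambled twin", {
  set.seed(21)
  sizes <- c(chr1 = 2e6)
  n <- 3000L
  pos1 <- runif(n, 0, 2e6)
  pos2 <- pmin(pmax(pos1 + rnorm(n, 0, 5e4), 0), 2e6 - 1)
  clean <- data.frame(chrom1 = "chr1", pos1 = pos1, chrom2 = "chr1", pos2 = pos2)
  ## invert coordinates in [1.0, 1.6] Mb for one end only: misjoin signature
  inv <- clean
  sel <- inv$pos2 >= 1e6 & inv$pos2 < 1.6e6
  inv$pos2[sel] <- 2.6e6 - inv$pos2[sel]
  d_clean <- diagonalityScore(binContacts(clean, sizes, bin = 1e5))
  d_inv <- diagonalityScore(binContacts(inv, sizes, bin = 1e5))
  expect_lt(d_inv[["chr1"]], d_clean[["chr1"]])
})

test_that("gene dropping: founders, selfing, and outbred parents behave as expected", {
  sc <- genPedigreeAndGenotypes(scheme = "selfing", seed = 1)
  ped <- sc$ped
  gd_f <- geneDrop(ped, "F0a", N = 100L, seed = 1)
  expect_equal(gd_f$F, 0)
  expect_equal(gd_f$parentage[["F0a"]], 1)

  gd <- geneDrop(ped, "S1", N = 10000L, seed = 2)
  expect_lt(abs(gd$F - 0.5), 0.02)

  gd_p <- geneDrop(ped, "P", N = 10000L, seed = 3)
  expect_equal(gd_p$F, 0)                      # child of unrelated founders
  expect_lt(abs(gd_p$parentage[["F0a"]] - 0.5), 0.02)
  expect_lt(abs(gd_p$parentage[["F0b"]] - 0.5), 0.02)
})

test_that("gene dropping is seed-reproducible and parentage sums to 1", {
  sc <- genPedigreeAndGenotypes(scheme = "cousins", seed = 1)
  a <- geneDrop(sc$ped, sc$target, N = 2000L, seed = 7)
  b <- geneDrop(sc$ped, sc$target, N = 2000L, seed = 7)
  expect_identical(a, b)
  expect_equal(sum(a$parentage), 1)
  expect_true(a$F >= 0 && a$F <= 1)
  expect_error(geneDrop(sc$ped, sc$target, ploidy = 3L), "odd ploidy")
  expect_error(geneDrop(sc$ped, "nobody"), "unknown target")
})

test_that("gene dropping at ploidy 4 still matches the recursive oracle", {
  ## for selfing at any even ploidy with with-replacement transmission,
  ## compare against a tiny direct simulation written independently
  sc <- genPedigreeAndGenotypes(scheme = "selfing", seed = 1)
  gd <- geneDrop(sc$ped, "S1", ploidy = 4L, N = 20000L, seed = 5)
  set.seed(99)
  direct <- replicate(20000, {
    p <- c(sample(1:4, 2, TRUE), sample(5:8, 2, TRUE))  # P draws from founders
    child <- c(sample(p, 2, TRUE), sample(p, 2, TRUE))  # S1 draws from P twice
    tab <- table(child)
    sum(tab[tab >= 2]) / 4
  })
  expect_lt(abs(gd$F - mean(direct)), 3 * stats::sd(direct) / sqrt(20000) + 0.01)
})

test_that("Monte-Carlo error shrinks like 1/sqrt(N)", {
  sc <- genPedigreeAndGenotypes(scheme = "selfing", seed = 1)
  sds <- vapply(c(250L, 1000L, 4000L), function(N) {
    est <- vapply(1:40, function(s) geneDrop(sc$ped, "S1", N = N, seed = s)$F,
                  numeric(1))
    stats::sd(est)
  }, numeric(1))
  ## quadrupling N should halve the sd (allow generous stochastic slack)
  expect_lt(sds[2] / sds[1], 0.75)
  expect_lt(sds[3] / sds[2], 0.75)
})

test_that("depth landscape flags planted CNVs and nothing else", {
  ## chrB is a minority of the genome so the per-variety median stays at the
  ## baseline even when the whole chromosome is deleted
  sizes <- c(chrA = 2e6, chrB = 1e6)
  segs <- data.frame(variety = "v2", chrom = "chrB", start = 0, end = 1e6,
                     multiplier = 0.5)
  sc <- genDepthTracks(sizes, bin = 1e5, cnv_segments = segs,
                       varieties = c("v1", "v2"), noise = FALSE, seed = 1)
  ls <- depthLandscape(sc$tracks)
  v2 <- ls$layout[ls$layout$variety == "v2", ]
  expect_true(all(v2$flag[v2$chrom == "chrB"] == "loss"))
  expect_true(all(v2$flag[v2$chrom == "chrA"] == "none"))

  same <- genDepthTracks(sizes, bin = 1e5, varieties = c("v1", "v2"),
                         noise = FALSE, seed = 2)
  expect_equal(nrow(depthLandscape(same$tracks)$flagged), 0L)

  ## 1.5x duplicated arm: contiguous run of gain flags covering the arm
  arm <- data.frame(variety = "v2", chrom = "chrB", start = 5e5, end = 1e6,
                    multiplier = 1.5)
  sc3 <- genDepthTracks(sizes, bin = 1e5, cnv_segments = arm,
                        varieties = c("v1", "v2"), noise = FALSE, seed = 3)
  ls3 <- depthLandscape(sc3$tracks)
  v2b <- ls3$layout[ls3$layout$variety == "v2" & ls3$layout$chrom == "chrB", ]
  expect_equal(v2b$flag, c(rep("none", 5), rep("gain", 5)))

  bad <- sc3$tracks
  bad$v2 <- bad$v2[-1, ]
  expect_error(depthLandscape(bad), "different binning")
})

test_that("qc renderers draw files (smoke)", {
  sc <- genPedigreeAndGenotypes(n_markers = 30L, n_individuals = 100L,
                                translocation = TRUE, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".png")
  plotLDHeatmap(ldMatrix(sc$genotypes), f1)
  sizes <- c(chr1 = 5e5)
  cb <- binContacts(data.frame(chrom1 = "chr1", pos1 = c(1e5, 2e5),
                               chrom2 = "chr1", pos2 = c(1.2e5, 2.2e5)),
                    sizes, bin = 1e5)
  f2 <- withr::local_tempfile(fileext = ".png")
  plotContactMap(cb, f2)
  f3 <- withr::local_tempfile(fileext = ".pdf")
  plotPedigree(sc$ped, f3, N = 200L, seed = 1)
  segs <- genDepthTracks(sizes, bin = 1e5, varieties = "v1", seed = 1)
  f4 <- withr::local_tempfile(fileext = ".png")
  plotDepthLandscape(depthLandscape(segs$tracks), f4)
  expect_true(all(file.size(c(f1, f2, f3, f4)) > 0))
})
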