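test_that("spearmanRho reproduces rank correlation by definition", {
  expect_equal(spearmanRho(1:7, (1:7) * 3 + 2), 1)      # any strictly increasing
  expect_equal(spearmanRho(1:7, rev(1:7)), -1)
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(spearmanRho(1:5, rep(2, 5)), 0)           # constant defined as 0
  expect_error(spearmanRho(1, 1), "length")
})

test_that("solutionFitness is the weighted rho x marker-count sum", {
  sizes <- c(s1 = 1000, s2 = 1000)
  ## one map, one lg, 10 markers in perfectly concordant order
  mk <- data.frame(scaffold = rep(c("s1", "s2"), each = 5),
                   pos = rep(c(100, 300, 500, 700, 900), 2),
                   lg = "LG1", cm = 1:10)
  ms <- mapSet(mk)
  sol <- new("ScaffoldSolution",
             placements = data.frame(chrom = "LG1", position = 1:2,
                                     scaffold = c("s1", "s2"),
                                     orientation = c("+", "+")),
             fitness = 0, rho = data.frame(), unplaced = character(0))
  expect_equal(solutionFitness(sol, ms, sizes), 10)   # rho 1 x 10 markers

  flipped <- sol
  flipped@placements$orientation <- c("-", "+")
  expect_lt(solutionFitness(flipped, ms, sizes), 10)

  ms2 <- mapSet(list(mapA = mk, mapB = mk), weights = c(mapA = 2, mapB = 1))
  expect_equal(solutionFitness(sol, ms2, sizes), 30)  # linear in weights
})

test_that("reversing a chromosome and flipping orientations negates fitness only", {
  sc <- genMapScenario(n_scaffolds = 6L, markers_per_scaffold = 4L, seed = 9)
  ms <- mapSet(sc$maps)
  tr <- sc$truth$LG1
  mkSol <- function(scaffold, orientation) new("ScaffoldSolution",
    placements = data.frame(chrom = "LG1", position = seq_along(scaffold),
                            scaffold = scaffold, orientation = orientation,
                            stringsAsFactors = FALSE),
    fitness = 0, rho = data.frame(), unplaced = character(0))
  fwd <- mkSol(tr$scaffold, tr$orientation)
  flip <- c("+" = "-", "-" = "+")
  rev_sol <- mkSol(rev(tr$scaffold), unname(flip[rev(tr$orientation)]))
  f1 <- solutionFitness(fwd, ms, sc$sizes)
  f2 <- solutionFitness(rev_sol, ms, sc$sizes)
  expect_equal(abs(f1), abs(f2))
  expect_equal(f1, -f2)
})

test_that("GA recovers the planted order on an error-free map", {
  sc <- genMapScenario(n_scaffolds = 8L, markers_per_scaffold = 5L,
                       error_rate = 0, seed = 0)
  sol <- orderScaffolds(mapSet(sc$maps), sc$sizes, seed = 0)
  expect_true(matchesUpToReversal(placements(sol), sc$truth$LG1))
  expect_true(all(rhoTable(sol)$rho == 1))
  ## deterministic: same seed, same solution
  sol2 <- orderScaffolds(mapSet(sc$maps), sc$sizes, seed = 0)
  expect_identical(placements(sol), placements(sol2))
  expect_identical(fitness(sol), fitness(sol2))
  ## fitness slot is reproducible from the solution itself
  expect_equal(fitness(sol), solutionFitness(sol, mapSet(sc$maps), sc$sizes))
})

test_that("GA tolerates 10% shuffled markers with rho >= 0.9", {
  sc <- genMapScenario(n_scaffolds = 8L, markers_per_scaffold = 5L,
                       error_rate = 0.1, seed = 4)
  sol <- orderScaffolds(mapSet(sc$maps), sc$sizes, seed = 0)
  expect_true(all(rhoTable(sol)$rho >= 0.9))
})

test_that("single scaffold is placed trivially with trend-based orientation", {
  sizes <- c(s1 = 10000)
  ## cm decreases along the scaffold: the scaffold should be flipped
  mk <- data.frame(scaffold = "s1", pos = c(1000, 5000, 9000),
                   lg = "LG1", cm = c(3, 2, 1))
  sol <- orderScaffolds(mapSet(mk), sizes, seed = 0)
  expect_equal(placements(sol)$orientation, "-")
  expect_equal(rhoTable(sol)$rho, 1)
})

test_that("with two conflicting maps the GA does at least as well as either pure order", {
  sc <- genMapScenario(n_scaffolds = 5L, markers_per_scaffold = 4L,
                       n_maps = 2L, seed = 12)
  ## make map2 prefer the reversed chromosome
  maps <- sc$maps
  maps$map2$cm <- max(maps$map2$cm) - maps$map2$cm
  ms <- mapSet(maps)
  tr <- sc$truth$LG1
  mkSol <- function(scaffold, orientation) new("ScaffoldSolution",
    placements = data.frame(chrom = "LG1", position = seq_along(scaffold),
                            scaffold = scaffold, orientation = orientation,
                            stringsAsFactors = FALSE),
    fitness = 0, rho = data.frame(), unplaced = character(0))
  flip <- c("+" = "-", "-" = "+")
  pureA <- solutionFitness(mkSol(tr$scaffold, tr$orientation), ms, sc$sizes)
  pureB <- solutionFitness(mkSol(rev(tr$scaffold), unname(flip[rev(tr$orientation)])),
                           ms, sc$sizes)
  sol <- orderScaffolds(ms, sc$sizes, seed = 0)
  expect_gte(fitness(sol), max(pureA, pureB) - 1e-9)
})

test_that("scaffolds without markers stay unplaced and empty maps error", {
  sc <- genMapScenario(n_scaffolds = 4L, markers_per_scaffold = 3L, seed = 2)
  sizes <- c(sc$sizes, orphan = 5000)
  sol <- orderScaffolds(mapSet(sc$maps), sizes, seed = 0)
  expect_equal(sol@unplaced, "orphan")
  empty <- mapSet(data.frame(scaffold = character(0), pos = numeric(0),
                             lg = character(0), cm = numeric(0)))
  expect_error(orderScaffolds(empty, sizes), "empty")
})

test_that("AGP conserves lengths, alternates W/U rows, and reverse-complements", {
  sizes <- c(s1 = 1000, s2 = 1000)
  sol <- new("ScaffoldSolution",
             placements = data.frame(chrom = "chr1", position = 1:2,
                                     scaffold = c("s1", "s2"),
                                     orientation = c("+", "-")),
             fitness = 0, rho = data.frame(), unplaced = character(0))
  seqs <- Biostrings::DNAStringSet(c(
    s1 = paste(rep("ACGT", 250), collapse = ""),
    s2 = paste(rep("AACC", 250), collapse = "")))
  out <- buildAgp(sol, sizes, gap_size = 100L, seqs = seqs)
  expect_equal(max(out$agp$object_end), 2100L)       # 1000 + 100 + 1000
  expect_equal(out$agp$component_type, c("W", "U", "W"))
  chr <- as.character(out$fasta[["chr1"]])
  expect_equal(nchar(chr), 2100L)
  expect_equal(substr(chr, 1001, 1100), strrep("N", 100))
  rc <- as.character(Biostrings::reverseComplement(seqs[["s2"]]))
  expect_equal(substr(chr, 1101, 2100), rc)

  f <- withr::local_tempfile()
  writeAgp(out$agp, f)
  expect_true(all(lengths(strsplit(readLines(f), "\t")) == 9L))

  sol@placements$scaffold[2] <- "missing"
  expect_error(buildAgp(sol, sizes), "missing")
})

test_that("concordance report summarizes anchoring and conserves totals", {
  sc <- genMapScenario(n_scaffolds = 6L, markers_per_scaffold = 4L,
                       n_chroms = 2L, seed = 7)
  sizes <- c(sc$sizes, orphan = 4000)
  ms <- mapSet(sc$maps)
  sol <- orderScaffolds(ms, sizes, seed = 0)
  rep <- concordanceReport(sol, ms, sizes)
  expect_true(all(rep$rho$rho == 1))
  expect_equal(rep$totals$n_scaffolds, sum(rep$summary$n_scaffolds))
  expect_equal(rep$totals$anchored_length, sum(rep$summary$anchored_length))
  expect_equal(rep$totals$n_unplaced, 1L)
  expect_equal(rep$totals$anchored_length, sum(sc$sizes))

  png <- withr::local_tempfile(fileext = ".png")
  plotConcordance(rep, rep$summary$chrom[1], png)
  expect_true(file.size(png) > 0)
})
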