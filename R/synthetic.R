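## Seeded generators for every input the toolkit consumes, each returning the
## generated objects together with the planted ground truth needed to score
## recovery. All generators are pure functions of (parameters, seed).

#' Synthetic synteny scenario: an ancestor evolved into two genomes
#'
#' An ancestral gene order is distributed over `n_chroms` chromosomes, then
#' inherited by two descendant genomes A and B. A shared polyploidy of
#' `copies` (2 = whole-genome duplication before divergence, 3 = shared
#' triplication as in the core-eudicot paleohexaploidy) places each ancestral
#' chromosome in `copies` homologous copies in both genomes, so every gene of
#' one genome is homologous to `copies` regions of the other (the m:m depth
#' pattern). Inversions reverse random gene segments of B; translocations
#' exchange segments between B chromosomes; `gene_loss` removes a fraction of
#' B's gene copies. Hits carry bitscores such that same-copy orthologs score
#' highest (around 500), cross-copy homeologs around 0.85 of that (surviving
#' the default C-score cutoff), and random decoy hits below 0.7 of the best
#' (removed by it).
#'
#' @param n_genes ancestral gene count (>= 50).
#' @param n_chroms ancestral chromosome count.
#' @param copies shared polyploidy level (1 = none).
#' @param inversions,translocations number of rearrangement events in B.
#' @param gene_loss fraction of B gene copies lost.
#' @param n_decoys number of random decoy hits.
#' @param seed RNG seed.
#' @return list with `bed_a`, `bed_b` (gene tables), `hits`, and `truth`
#'   (expected depth ratio, per-copy region map, parameters).
#' @export
genSyntenyScenario <- function(n_genes = 200L, n_chroms = 2L, copies = 1L,
                               inversions = 0L, translocations = 0L,
                               gene_loss = 0, n_decoys = 0L, seed = 0L) {
  if (n_genes < 50L) dataError("genSyntenyScenario: need n_genes >= 50")
  if (copies < 1L) dataError("genSyntenyScenario: copies must be >= 1")
  if (gene_loss < 0 || gene_loss >= 1)
    dataError("genSyntenyScenario: gene_loss must lie in [0,1)")
  set.seed(as.integer(seed))
  anc_chrom <- sort(rep_len(seq_len(n_chroms), n_genes))

  makeGenome <- function(prefix) {
    rows <- list()
    for (cp in seq_len(copies)) {
      for (ch in seq_len(n_chroms)) {
        ix <- which(anc_chrom == ch)
        seqid <- sprintf("%s%d_%d", prefix, ch, cp)
        rows[[length(rows) + 1L]] <- data.frame(
          seqid = seqid,
          start = (seq_along(ix) - 1L) * 1000L,
          end = (seq_along(ix) - 1L) * 1000L + 500L,
          accn = sprintf("%s_g%d_c%d", prefix, ix, cp),
          score = 0, strand = "+",
          anc = ix, copy = cp, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  bed_a <- makeGenome("A")
  bed_b <- makeGenome("B")

  ## rearrangements in B: operate on row order within chromosomes
  applyInversion <- function(bed) {
    ch <- sample(unique(bed$seqid), 1)
    ix <- which(bed$seqid == ch)
    if (length(ix) < 4L) return(bed)
    span <- sort(sample(length(ix), 2))
    seg <- ix[span[1]:span[2]]
    bed[seg, c("accn", "anc", "copy")] <- bed[rev(seg), c("accn", "anc", "copy")]
    bed$strand[seg] <- ifelse(bed$strand[seg] == "+", "-", "+")
    bed
  }
  applyTranslocation <- function(bed) {
    chs <- unique(bed$seqid)
    if (length(chs) < 2L) return(bed)
    pick <- sample(chs, 2)
    i1 <- which(bed$seqid == pick[1]); i2 <- which(bed$seqid == pick[2])
    k <- min(length(i1), length(i2)) %/% 4L
    if (k < 1L) return(bed)
    tail1 <- utils::tail(i1, k); tail2 <- utils::tail(i2, k)
    tmp <- bed[tail1, c("accn", "anc", "copy", "strand")]
    bed[tail1, c("accn", "anc", "copy", "strand")] <-
      bed[tail2, c("accn", "anc", "copy", "strand")]
    bed[tail2, c("accn", "anc", "copy", "strand")] <- tmp
    bed
  }
  for (i in seq_len(inversions)) bed_b <- applyInversion(bed_b)
  for (i in seq_len(translocations)) bed_b <- applyTranslocation(bed_b)
  if (gene_loss > 0) {
    keep <- stats::runif(nrow(bed_b)) >= gene_loss
    bed_b <- bed_b[keep, , drop = FALSE]
    ## recompute positions so gene order stays dense
    for (ch in unique(bed_b$seqid)) {
      ix <- which(bed_b$seqid == ch)
      bed_b$start[ix] <- (seq_along(ix) - 1L) * 1000L
      bed_b$end[ix] <- bed_b$start[ix] + 500L
    }
  }

  ## hits: all copy-pair homologies per ancestral gene
  ortho_score <- 500
  homeo_score <- 425   # 0.85 of best: survives the 0.7 C-score cutoff
  ha <- bed_a[, c("accn", "anc", "copy")]
  hb <- bed_b[, c("accn", "anc", "copy")]
  mrg <- merge(ha, hb, by = "anc", suffixes = c("_a", "_b"))
  score <- ifelse(mrg$copy_a == mrg$copy_b, ortho_score, homeo_score)
  hits <- data.frame(
    query = mrg$accn_a, subject = mrg$accn_b, pct_identity = 90,
    aln_len = 500, mismatches = 10, gap_opens = 1, qstart = 1, qend = 500,
    sstart = 1, send = 500, evalue = 1e-50, bitscore = score,
    stringsAsFactors = FALSE)
  if (n_decoys > 0L) {
    decoys <- data.frame(
      query = sample(bed_a$accn, n_decoys, replace = TRUE),
      subject = sample(bed_b$accn, n_decoys, replace = TRUE),
      pct_identity = 60, aln_len = 100, mismatches = 40, gap_opens = 5,
      qstart = 1, qend = 100, sstart = 1, send = 100, evalue = 1e-5,
      bitscore = stats::runif(n_decoys, 50, 0.65 * ortho_score),
      stringsAsFactors = FALSE)
    hits <- rbind(hits, decoys)
  }
  hits <- hits[sample.int(nrow(hits)), ]
  rownames(hits) <- NULL

  bedCols <- function(b) b[, c("seqid", "start", "end", "accn", "score", "strand")]
  list(bed_a = bedCols(bed_a), bed_b = bedCols(bed_b), hits = hits,
       truth = list(expected_ratio = sprintf("%d:%d", copies, copies),
                    copies = copies, n_genes = n_genes, n_chroms = n_chroms,
                    n_true_pairs = nrow(mrg), seed = seed))
}

#' Synthetic map scenario: a chromosome cut into shuffled scaffolds
#'
#' One or more chromosomes are cut into scaffolds of random length; the
#' scaffolds are shuffled and randomly flipped (that is the assembly the
#' solver sees). Each of `n_maps` maps carries markers whose map position (cM)
#' is monotone in the true chromosome coordinate; a fraction `error_rate` of
#' markers get their cM values swapped with a nearby marker, emulating
#' genotyping noise.
#'
#' @param n_scaffolds scaffolds per chromosome.
#' @param markers_per_scaffold markers on each scaffold per map.
#' @param error_rate fraction of markers displaced.
#' @param n_maps number of maps.
#' @param n_chroms number of chromosomes.
#' @param seed RNG seed.
#' @return list with `sizes` (named vector), `maps` (named list of marker
#'   data.frames suitable for [mapSet()]), and `truth` (per chromosome, the
#'   true scaffold order and orientations).
#' @export
genMapScenario <- function(n_scaffolds = 8L, markers_per_scaffold = 5L,
                           error_rate = 0, n_maps = 1L, n_chroms = 1L,
                           seed = 0L) {
  set.seed(as.integer(seed))
  sizes <- numeric(0)
  truth <- list()
  maps <- stats::setNames(
    replicate(n_maps, NULL, simplify = FALSE), paste0("map", seq_len(n_maps)))
  for (ch in seq_len(n_chroms)) {
    lg <- sprintf("LG%d", ch)
    scs <- sprintf("scf%d_%d", ch, seq_len(n_scaffolds))
    len <- round(stats::runif(n_scaffolds, 50000, 150000))
    names(len) <- scs
    sizes <- c(sizes, len)
    flip <- sample(c(FALSE, TRUE), n_scaffolds, replace = TRUE)
    offs <- cumsum(c(0, len[-n_scaffolds]))
    truth[[lg]] <- data.frame(scaffold = scs, position = seq_len(n_scaffolds),
                              orientation = ifelse(flip, "-", "+"),
                              length = as.numeric(len), stringsAsFactors = FALSE)
    for (mi in seq_len(n_maps)) {
      rows <- list()
      for (si in seq_len(n_scaffolds)) {
        ## marker positions along the true chromosome within this scaffold
        within <- sort(round(stats::runif(markers_per_scaffold, 1, len[si] - 1)))
        chrom_pos <- offs[si] + within
        scaffold_pos <- if (flip[si]) len[si] - within else within
        rows[[si]] <- data.frame(scaffold = scs[si], pos = scaffold_pos,
                                 lg = lg, chrom_pos = chrom_pos,
                                 stringsAsFactors = FALSE)
      }
      mm <- do.call(rbind, rows)
      mm <- mm[order(mm$chrom_pos), ]
      mm$cm <- mm$chrom_pos / 1e6 * 4          # ~4 cM / Mb
      if (error_rate > 0) {
        n_err <- round(error_rate * nrow(mm))
        if (n_err > 0) {
          for (k in sample(seq_len(nrow(mm) - 1L), min(n_err, nrow(mm) - 1L))) {
            tmp <- mm$cm[k]; mm$cm[k] <- mm$cm[k + 1L]; mm$cm[k + 1L] <- tmp
          }
        }
      }
      mm$chrom_pos <- NULL
      maps[[mi]] <- rbind(maps[[mi]], mm)
    }
  }
  for (mi in seq_len(n_maps)) rownames(maps[[mi]]) <- NULL
  list(sizes = sizes, maps = maps, truth = truth)
}

#' Synthetic k-mer spectrum from a planted mixture
#'
#' Builds the model spectrum `K_j = sum_c G_c NB(j; c*n, p)` from planted
#' parameters and optionally adds Poisson sampling noise per multiplicity bin
#' and a decaying error tail at low multiplicities. The planted masses are
#' scaled so that `sum(c * G_c)` equals `genome_size` exactly; `coverage`
#' sets the copy-number-1 component mean via p (default 0.5), and
#' `repeat_fraction` is the share of genome bases in copy numbers >= 2
#' (spread geometrically over c = 2..5). `het` adds a half-coverage component
#' emulating heterozygous k-mers in a diploid.
#'
#' @param genome_size total bp-equivalent k-mer count, sum of c * G_c.
#' @param coverage mean multiplicity of single-copy k-mers.
#' @param repeat_fraction fraction of genome_size in copy numbers >= 2.
#' @param het fraction of genome_size in the half-coverage heterozygous
#'   component.
#' @param p negative binomial success probability (default 0.5).
#' @param noise add Poisson sampling noise per bin.
#' @param error_rate scale of the low-multiplicity error tail relative to the
#'   main peak height (0 disables it).
#' @param seed RNG seed.
#' @return list with `spectrum` (a [KmerSpectrum-class]) and `truth`
#'   (G, n, p, genome_size, coverage).
#' @export
genSpectrum <- function(genome_size = 1e6, coverage = 30, repeat_fraction = 0,
                        het = 0, p = 0.5, noise = TRUE, error_rate = 0,
                        seed = 0L) {
  set.seed(as.integer(seed))
  n <- coverage * p / (1 - p)
  c_max <- 5L
  G <- numeric(c_max)
  rep_mass <- repeat_fraction * genome_size
  het_mass <- het * genome_size
  G[1] <- genome_size - rep_mass - het_mass   # bp in single copy
  if (rep_mass > 0) {
    w <- 0.5^(0:3); w <- w / sum(w)
    for (c in 2:5) G[c] <- rep_mass * w[c - 1] / c  # mass in distinct k-mers
  }
  if (G[1] < 0) dataError("genSpectrum: repeat_fraction + het exceed 1")
  j <- seq_len(as.integer(ceiling(coverage * (c_max + 2))))
  K <- modelSpectrum(j, G, n, p)
  if (het_mass > 0)   # heterozygous k-mers peak at half coverage
    K <- K + het_mass * stats::dnbinom(j, size = n / 2, prob = p)
  if (error_rate > 0) {
    peak_height <- max(K)
    K <- K + error_rate * peak_height * exp(-(j - 1) / 1.5)
  }
  if (noise) K <- stats::rpois(length(j), K)
  keep <- K > 0
  spec <- kmerSpectrum(j[keep], K[keep], k = 21L)
  list(spectrum = spec,
       truth = list(G = G, n = n, p = p,
                    genome_size = sum(seq_len(c_max) * G) + het_mass,
                    coverage = coverage, het_mass = het_mass))
}

#' Synthetic pedigree and genotype matrix
#'
#' Standard breeding schemes with known inbreeding coefficients for the final
#' individual: selfing (F = 1/2), full-sib mating (F = 1/4), half-sib mating
#' (F = 1/8), backcross parent x offspring (F = 1/4), and first-cousin mating
#' (F = 1/16). The genotype matrix holds independent biallelic haplotype
#' markers for unrelated individuals; `translocation = TRUE` plants a
#' misassembly signal by making the trailing markers labelled chr4 copies of
#' chr6 markers, creating an inter-chromosome LD block.
#'
#' @param scheme one of "selfing", "fullsib", "halfsib", "backcross",
#'   "cousins".
#' @param n_markers markers in the genotype matrix.
#' @param n_individuals haplotypes in the genotype matrix.
#' @param n_chroms chromosomes the markers are spread over.
#' @param translocation plant the chr4/chr6 misassembly signal.
#' @param seed RNG seed.
#' @return list with `ped` (a [Pedigree-class]), `genotypes`
#'   (a [GenotypeMatrix-class]), and `truth` (exact F of the last individual,
#'   planted chromosome pair if any).
#' @export
genPedigreeAndGenotypes <- function(scheme = c("selfing", "fullsib", "halfsib",
                                               "backcross", "cousins"),
                                    n_markers = 60L, n_individuals = 200L,
                                    n_chroms = 6L, translocation = FALSE,
                                    seed = 0L) {
  scheme <- match.arg(scheme)
  set.seed(as.integer(seed))
  ped_df <- switch(scheme,
    selfing = data.frame(
      name = c("F0a", "F0b", "P", "S1"),
      parent_a = c(NA, NA, "F0a", "P"),
      parent_b = c(NA, NA, "F0b", "P")),
    fullsib = data.frame(
      name = c("P1", "P2", "C1", "C2", "X"),
      parent_a = c(NA, NA, "P1", "P1", "C1"),
      parent_b = c(NA, NA, "P2", "P2", "C2")),
    halfsib = data.frame(
      name = c("P1", "P2", "P3", "C1", "C2", "X"),
      parent_a = c(NA, NA, NA, "P1", "P1", "C1"),
      parent_b = c(NA, NA, NA, "P2", "P3", "C2")),
    backcross = data.frame(
      name = c("P1", "P2", "C", "X"),
      parent_a = c(NA, NA, "P1", "P1"),
      parent_b = c(NA, NA, "P2", "C")),
    cousins = data.frame(
      name = c("G1", "G2", "M1", "M2", "S1", "S2", "C1", "C2", "X"),
      parent_a = c(NA, NA, NA, NA, "G1", "G1", "S1", "S2", "C1"),
      parent_b = c(NA, NA, NA, NA, "G2", "G2", "M1", "M2", "C2")))
  truth_F <- c(selfing = 0.5, fullsib = 0.25, halfsib = 0.125,
               backcross = 0.25, cousins = 0.0625)[[scheme]]
  ped <- pedigree(ped_df)
  target <- ped_df$name[nrow(ped_df)]

  per_chrom <- ceiling(n_markers / n_chroms)
  chrom <- rep(sprintf("chr%d", seq_len(n_chroms)), each = per_chrom)[seq_len(n_markers)]
  pos <- as.numeric(stats::ave(seq_len(n_markers), chrom, FUN = seq_along)) * 1e5
  maf <- stats::runif(n_markers, 0.2, 0.5)
  calls <- vapply(maf, function(q) stats::rbinom(n_individuals, 1L, q),
                  integer(n_individuals))
  planted <- NULL
  if (translocation) {
    src <- which(chrom == "chr6")
    dst <- which(chrom == "chr4")
    k <- min(length(src), length(dst), 5L)
    dst_tail <- utils::tail(dst, k)
    calls[, dst_tail] <- calls[, utils::head(src, k)]  # chr4 tail is really chr6
    planted <- c("chr4", "chr6")
  }
  rownames(calls) <- sprintf("ind%d", seq_len(n_individuals))
  g <- new("GenotypeMatrix",
           markers = data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE),
           calls = calls, phased = TRUE)
  list(ped = ped, genotypes = g, target = target,
       truth = list(F = truth_F, translocation = planted))
}

#' Synthetic per-variety depth tracks with planted CNV segments
#'
#' @param sizes named numeric of chromosome lengths.
#' @param bin bin size in bp.
#' @param cnv_segments data.frame `variety`, `chrom`, `start`, `end`,
#'   `multiplier` (e.g. 0.5 for a loss, 1.5 for a duplicated arm); may be
#'   empty.
#' @param varieties character vector of variety names.
#' @param base_depth expected depth of unaffected bins.
#' @param noise Poisson-sample the depths (FALSE gives exact multiples).
#' @param seed RNG seed.
#' @return list with `tracks` (named list of depth data.frames) and `truth`
#'   (the planted segments).
#' @export
genDepthTracks <- function(sizes, bin = 100000L,
                           cnv_segments = NULL,
                           varieties = c("var1", "var2"),
                           base_depth = 30, noise = TRUE, seed = 0L) {
  set.seed(as.integer(seed))
  grid <- do.call(rbind, lapply(names(sizes), function(ch) {
    starts <- seq(0L, sizes[[ch]] - 1L, by = bin)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin, sizes[[ch]]), stringsAsFactors = FALSE)
  }))
  tracks <- list()
  for (v in varieties) {
    mult <- rep(1, nrow(grid))
    if (!is.null(cnv_segments) && nrow(cnv_segments)) {
      segs <- cnv_segments[cnv_segments$variety == v, , drop = FALSE]
      for (i in seq_len(nrow(segs)))
        mult[grid$chrom == segs$chrom[i] & grid$start >= segs$start[i] &
               grid$end <= segs$end[i]] <- segs$multiplier[i]
    }
    depth <- base_depth * mult
    if (noise) depth <- stats::rpois(length(depth), depth)
    tracks[[v]] <- data.frame(grid, depth = depth, stringsAsFactors = FALSE)
  }
  list(tracks = tracks, truth = list(segments = cnv_segments))
}
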