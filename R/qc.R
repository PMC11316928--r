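## Genome-build concordance QC (linkage-disequilibrium and Hi-C contact
## heatmaps) and diversity analysis (pedigree gene-dropping, binned CNV
## landscapes).

#' Linkage disequilibrium r-squared from allele frequencies
#'
#' `r2 = (p_ab - p_a p_b)^2 / (p_a (1 - p_a) p_b (1 - p_b))`, the squared
#' correlation of allelic states at two markers, clipped to [0, 1] for
#' numerical safety. Monomorphic markers (frequency 0 or 1) give NaN and are
#' excluded from heatmaps.
#'
#' @param freq_a,freq_b allele frequencies at the two markers.
#' @param freq_ab frequency of the haplotype carrying both alleles.
#' @return r-squared in [0, 1], or NaN for a monomorphic marker.
#' @examples
#' ldR2(0.5, 0.5, 0.5)   # complete LD: 1
#' ldR2(0.5, 0.5, 0.25)  # equilibrium: 0
#' ldR2(0.5, 0.5, 0.35)  # 0.16
#' @export
ldR2 <- function(freq_a, freq_b, freq_ab) {
  denom <- freq_a * (1 - freq_a) * freq_b * (1 - freq_b)
  out <- (freq_ab - freq_a * freq_b)^2 / denom
  out[denom <= 0] <- NaN
  pmin(pmax(out, 0), 1)
}

#' Pairwise LD r-squared matrix with heatmap layout
#'
#' Computes r-squared between all marker pairs. For phased haplotype input,
#' haplotype frequencies come directly from counts (missing calls dropped
#' pairwise). For unphased dosage input, a composite estimator is used: the
#' squared Pearson correlation of dosages, which applies the same formula to
#' the composite haplotype frequency. Monomorphic markers yield NaN rows and
#' the diagonal is 1.
#'
#' @param g a [GenotypeMatrix-class] object.
#' @param thin maximum number of markers retained for the heatmap layout by
#'   uniform subsampling (the full matrix is always returned; default 1000).
#' @return list with `r2` (symmetric matrix), `markers`, `boundaries` (first
#'   marker index per chromosome), and `block_means` (mean r-squared of every
#'   chromosome-pair block, for misassembly screening).
#' @export
ldMatrix <- function(g, thin = 1000L) {
  calls <- g@calls
  if (ncol(calls) < 2L) dataError("ldMatrix: need >= 2 markers")
  m <- ncol(calls)
  if (g@phased) {
    X <- calls                     # 0/1 haplotypes
    obs <- !is.na(X)
    X0 <- X; X0[!obs] <- 0
    n_pair <- crossprod(obs)                 # pairwise complete sizes
    s_pair <- crossprod(X0, obs)             # sum of x over pairwise-complete
    pa <- s_pair / n_pair                    # pa[i,j] = freq of allele i over obs(i,j)
    pab <- crossprod(X0) / n_pair
    r2 <- (pab - pa * t(pa))^2 / (pa * (1 - pa) * t(pa) * (1 - t(pa)))
    r2[pa * (1 - pa) * t(pa) * (1 - t(pa)) <= 0] <- NaN
    r2 <- pmin(pmax(r2, 0), 1)
  } else {
    r2 <- suppressWarnings(stats::cor(calls, use = "pairwise.complete.obs"))^2
  }
  diag(r2) <- 1
  mono <- apply(calls, 2, function(x) {
    v <- x[!is.na(x)]
    length(unique(v)) < 2L
  })
  r2[mono, ] <- NaN; r2[, mono] <- NaN
  chroms <- naturalSort(unique(g@markers$chrom))
  boundaries <- vapply(chroms, function(cc) which(g@markers$chrom == cc)[1], integer(1))
  ## mean r2 per chromosome-pair block (off-diagonal screening)
  blocks <- expand.grid(chrom1 = chroms, chrom2 = chroms, stringsAsFactors = FALSE)
  blocks <- blocks[match(blocks$chrom1, chroms) < match(blocks$chrom2, chroms), ]
  blocks$mean_r2 <- vapply(seq_len(nrow(blocks)), function(i) {
    ix <- which(g@markers$chrom == blocks$chrom1[i])
    jx <- which(g@markers$chrom == blocks$chrom2[i])
    mean(r2[ix, jx, drop = FALSE], na.rm = TRUE)
  }, numeric(1))
  idx <- if (m > thin) unique(round(seq(1, m, length.out = thin))) else seq_len(m)
  list(r2 = r2, markers = g@markers, boundaries = boundaries,
       block_means = blocks, thinned_index = idx)
}

#' Bin Hi-C contacts into a symmetric matrix
#'
#' Contacts are accumulated into fixed-size genome bins; both (i, j) and
#' (j, i) cells are incremented so the matrix is symmetric. Contacts falling
#' outside the sizes table are dropped with a warning. A per-chromosome
#' diagonality score — the fraction of intra-chromosome contacts within one
#' bin of the diagonal — summarizes how assembly-concordant the map is.
#'
#' @param contacts data.frame `chrom1`, `pos1`, `chrom2`, `pos2` (see
#'   [readContacts()]).
#' @param sizes named numeric of chromosome lengths.
#' @param bin bin size in bp (default 500000).
#' @return a [ContactBins-class] object; see also [diagonalityScore()].
#' @export
binContacts <- function(contacts, sizes, bin = 500000L) {
  chroms <- naturalSort(names(sizes))
  nb <- stats::setNames(as.integer(ceiling(sizes[chroms] / bin)), chroms)
  offs <- stats::setNames(cumsum(c(0L, nb[-length(nb)])) + 1L, chroms)
  total <- sum(nb)
  ok <- contacts$chrom1 %in% chroms & contacts$chrom2 %in% chroms &
    contacts$pos1 >= 0 & contacts$pos2 >= 0 &
    contacts$pos1 < sizes[contacts$chrom1] & contacts$pos2 < sizes[contacts$chrom2]
  ok[is.na(ok)] <- FALSE
  dropped <- sum(!ok)
  if (dropped > 0L)
    warning(sprintf("binContacts: dropped %d contacts outside sizes", dropped),
            call. = FALSE)
  cc <- contacts[ok, , drop = FALSE]
  b1 <- offs[cc$chrom1] + as.integer(cc$pos1 %/% bin)
  b2 <- offs[cc$chrom2] + as.integer(cc$pos2 %/% bin)
  mat <- matrix(0, total, total)
  for (k in seq_along(b1)) {
    mat[b1[k], b2[k]] <- mat[b1[k], b2[k]] + 1
    if (b1[k] != b2[k]) mat[b2[k], b1[k]] <- mat[b2[k], b1[k]] + 1
  }
  new("ContactBins", matrix = mat, bin = as.integer(bin), offsets = offs,
      nbins = nb, dropped = as.integer(dropped))
}

#' Per-chromosome diagonality of a binned contact map
#'
#' @param cb a [ContactBins-class] object.
#' @param window how far from the diagonal (in bins) still counts as
#'   "on-diagonal" (default 1).
#' @return named numeric: fraction of intra-chromosome contact weight within
#'   `window` bins of the diagonal, per chromosome.
#' @export
diagonalityScore <- function(cb, window = 1L) {
  out <- numeric(0)
  for (chrom in names(cb@offsets)) {
    lo <- cb@offsets[[chrom]]
    hi <- lo + cb@nbins[[chrom]] - 1L
    sub <- cb@matrix[lo:hi, lo:hi, drop = FALSE]
    tot <- sum(sub)
    if (tot == 0) { out[chrom] <- NA_real_; next }
    near <- abs(row(sub) - col(sub)) <= window
    out[chrom] <- sum(sub[near]) / tot
  }
  out
}

#' Gene-dropping simulation: parentage and inbreeding coefficient
#'
#' Monte-Carlo transmission of founder alleles down the pedigree. Founders
#' carry `ploidy` unique allele labels each; every child draws `ploidy/2`
#' alleles uniformly with replacement from each parent's `ploidy` alleles
#' (Mendelian transmission at ploidy 2). Over `N` replicates, the inbreeding
#' coefficient F of the target is the mean fraction of its alleles appearing
#' more than once in the same replicate (identical by descent), and the
#' parentage of founder X is the mean fraction of target alleles originating
#' from X.
#'
#' @param ped a [Pedigree-class] object.
#' @param target individual to score.
#' @param ploidy even integer >= 2 (default 2).
#' @param N number of simulated replicates (default 10000).
#' @param seed RNG seed.
#' @return list with `F`, `parentage` (named proportions over founders,
#'   summing to 1), `N`, `ploidy`.
#' @export
geneDrop <- function(ped, target, ploidy = 2L, N = 10000L, seed = 0L) {
  e <- pedigreeTable(ped)
  if (!(target %in% e$name)) dataError("geneDrop: unknown target: %s", target)
  ploidy <- as.integer(ploidy)
  if (ploidy < 1L) dataError("geneDrop: ploidy must be >= 1")
  if (ploidy %% 2L != 0L)
    dataError("geneDrop: odd ploidy not supported (each parent transmits ploidy/2 alleles)")
  set.seed(as.integer(seed))
  half <- ploidy %/% 2L
  fnd <- founders(ped)
  if (target %in% fnd) {
    ## founders are non-inbred by assumption
    parentage <- stats::setNames(rep(0, length(fnd)), fnd)
    parentage[target] <- 1
    return(list(F = 0, parentage = parentage, N = as.integer(N), ploidy = ploidy))
  }
  ## allele matrices: N replicates x ploidy alleles of integer labels; label
  ## encodes founder of origin via label %/% ploidy
  alleles <- list()
  founder_id <- stats::setNames(seq_along(fnd) - 1L, fnd)
  for (i in seq_len(nrow(e))) {
    nm <- e$name[i]
    if (is.na(e$parent_a[i])) {
      alleles[[nm]] <- matrix(rep(founder_id[nm] * ploidy + seq_len(ploidy), each = N),
                              nrow = N)
    } else {
      pa <- alleles[[e$parent_a[i]]]
      pb <- alleles[[e$parent_b[i]]]
      draw <- function(par) {
        cols <- matrix(sample.int(ploidy, N * half, replace = TRUE), nrow = N)
        matrix(par[cbind(rep(seq_len(N), half), as.vector(cols))], nrow = N)
      }
      alleles[[nm]] <- cbind(draw(pa), draw(pb))
    }
    if (nm == target) break
  }
  tg <- alleles[[target]]
  if (ploidy == 2L) {
    Fhat <- mean(tg[, 1] == tg[, 2])
  } else {
    dupfrac <- apply(tg, 1, function(r) {
      tab <- table(r)
      sum(tab[tab >= 2L]) / ploidy
    })
    Fhat <- mean(dupfrac)
  }
  origin <- fnd[(tg - 1L) %/% ploidy + 1L]
  parentage <- table(factor(origin, levels = fnd)) / length(tg)
  list(F = Fhat, parentage = stats::setNames(as.numeric(parentage), fnd),
       N = as.integer(N), ploidy = ploidy)
}

#' Normalized depth landscape and CNV flagging
#'
#' Each variety's binned depth track is normalized by its genome-wide median
#' (robust to large CNVs); bins with normalized depth below `loss` are flagged
#' as losses and above `gain` as gains. All varieties must share the same
#' binning.
#'
#' @param tracks named list of depth data.frames (`chrom`, `start`, `end`,
#'   `depth`), one per variety; see [readDepth()].
#' @param loss,gain flagging thresholds on normalized depth (defaults 0.6
#'   and 1.4).
#' @return list with `layout` (long data.frame: variety, chrom, start, end,
#'   depth, norm_depth, flag) and `flagged` (only the flagged bins).
#' @export
depthLandscape <- function(tracks, loss = 0.6, gain = 1.4) {
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    dataError("depthLandscape: tracks must be a named list")
  ref <- tracks[[1]][, c("chrom", "start", "end")]
  for (nm in names(tracks)) {
    t <- tracks[[nm]][, c("chrom", "start", "end")]
    if (!identical(dim(t), dim(ref)) || !all(t == ref))
      dataError("depthLandscape: '%s' uses a different binning", nm)
  }
  out <- lapply(names(tracks), function(nm) {
    t <- tracks[[nm]]
    med <- stats::median(t$depth)
    if (med <= 0) dataError("depthLandscape: non-positive median depth for '%s'", nm)
    nd <- t$depth / med
    data.frame(variety = nm, chrom = t$chrom, start = t$start, end = t$end,
               depth = t$depth, norm_depth = nd,
               flag = ifelse(nd < loss, "loss", ifelse(nd > gain, "gain", "none")),
               stringsAsFactors = FALSE)
  })
  layout <- do.call(rbind, out)
  list(layout = layout, flagged = layout[layout$flag != "none", ])
}
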