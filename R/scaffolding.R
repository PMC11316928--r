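## Map-guided scaffold ordering & orientation (OO). The OO problem is cast as
## a traveling-salesman-style search over (permutation, orientation) pairs and
## solved per chromosome with a genetic algorithm; the objective is the
## weighted sum over maps and linkage groups of Spearman's rho between marker
## physical positions and map locations, scaled by marker count.

#' Spearman rank correlation
#'
#' Standard rank correlation with average ranks for ties. A constant vector
#' has no defined rank order; the correlation is defined as 0 in that case so
#' degenerate linkage groups contribute nothing to the ordering objective.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1].
#' @examples
#' spearmanRho(1:4, c(1, 3, 2, 4))  # 0.8
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    dataError("spearmanRho: need two vectors of equal length >= 2")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(0)
  rho <- stats::cor(x, y, method = "spearman")
  ## snap floating-point residue at the exact endpoints
  if (abs(abs(rho) - 1) < 1e-10) rho <- sign(rho)
  rho
}

#' Assign scaffolds to chromosomes (linkage groups)
#'
#' Each scaffold goes to the linkage group where it carries the greatest
#' weight-summed marker count; ties break to the natural-sort-first group.
#'
#' @param maps a [MapSet-class] object.
#' @return named character vector: scaffold -> linkage group.
#' @export
assignChromosomes <- function(maps) {
  m <- markerTable(maps)
  w <- mapWeights(maps)[m$map]
  agg <- stats::aggregate(w, list(scaffold = m$scaffold, lg = m$lg), sum)
  out <- character(0)
  for (sub in split(agg, agg$scaffold)) {
    best <- sub$x == max(sub$x)
    out[sub$scaffold[1]] <- naturalSort(sub$lg[best])[1]
  }
  out
}

## Per-chromosome evaluation context: everything needed to score an
## arrangement quickly. Scaffolds indexed 1..n in `scaffolds` order.
chromContext <- function(chrom, scaffolds, maps, sizes, gap_size = 100) {
  m <- markerTable(maps)
  m <- m[m$lg == chrom & m$scaffold %in% scaffolds, , drop = FALSE]
  w <- mapWeights(maps)
  list(chrom = chrom, scaffolds = scaffolds,
       len = as.numeric(sizes[scaffolds]), gap = gap_size,
       sc_idx = match(m$scaffold, scaffolds), pos = m$pos, cm = m$cm,
       group = paste(m$map, m$lg, sep = "\r"),
       weight = stats::setNames(w[m$map], NULL),
       groups = split(seq_len(nrow(m)), paste(m$map, m$lg, sep = "\r")))
}

## physical marker positions for an arrangement (perm = scaffold indices in
## chromosome order; flips indexed by scaffold index, not position)
markerPositions <- function(ctx, perm, flips) {
  offs <- cumsum(c(0, ctx$len[perm][-length(perm)] + ctx$gap))
  off_by_scaffold <- numeric(length(perm))
  off_by_scaffold[perm] <- offs
  ifelse(flips[ctx$sc_idx],
         off_by_scaffold[ctx$sc_idx] + ctx$len[ctx$sc_idx] - ctx$pos,
         off_by_scaffold[ctx$sc_idx] + ctx$pos)
}

evalArrangement <- function(ctx, perm, flips) {
  phys <- markerPositions(ctx, perm, flips)
  total <- 0
  for (g in ctx$groups) {
    if (length(g) < 2L) { total <- total + ctx$weight[g[1]] * length(g); next }
    rho <- spearmanRho(phys[g], ctx$cm[g])
    total <- total + ctx$weight[g[1]] * rho * length(g)
  }
  total
}

#' Fitness of a scaffold solution under a map set
#'
#' The objective the genetic algorithm maximizes: for every map m and linkage
#' group g, `weight(m) * rho(physical order, map position) * n_markers(m, g)`,
#' summed. Markers on unplaced scaffolds do not contribute. A single-marker
#' group contributes `weight * 1 * 1` (its order is trivially concordant).
#'
#' @param sol a [ScaffoldSolution-class] object.
#' @param maps a [MapSet-class] object.
#' @param sizes named numeric of scaffold lengths.
#' @param gap_size gap inserted between consecutive scaffolds (bp).
#' @return numeric fitness.
#' @export
solutionFitness <- function(sol, maps, sizes, gap_size = 100) {
  pl <- placements(sol)
  total <- 0
  for (chrom in unique(pl$chrom)) {
    sub <- pl[pl$chrom == chrom, ]
    sub <- sub[order(sub$position), ]
    ctx <- chromContext(chrom, sub$scaffold, maps, sizes, gap_size)
    if (!length(ctx$pos)) next
    total <- total + evalArrangement(ctx, seq_along(sub$scaffold),
                                     sub$orientation == "-")
  }
  total
}

## order crossover (OX) for permutations
orderCrossover <- function(p1, p2) {
  n <- length(p1)
  cut <- sort(sample.int(n, 2))
  seg <- p1[cut[1]:cut[2]]
  rest <- p2[!(p2 %in% seg)]
  child <- integer(n)
  child[cut[1]:cut[2]] <- seg
  child[-(cut[1]:cut[2])] <- rest
  child
}

## GA over (permutation, orientation bits) for one chromosome
gaOrderChromosome <- function(ctx, pop_size = 100L, generations = 500L,
                              stagnation = 50L, p_cross = 0.7, p_mut = 0.2,
                              elitism = 1L) {
  n <- length(ctx$scaffolds)
  if (n == 1L) {
    flip <- FALSE
    if (length(ctx$pos) >= 2L) {
      trend <- sum(vapply(ctx$groups, function(g)
        if (length(g) >= 2L) ctx$weight[g[1]] * spearmanRho(ctx$pos[g], ctx$cm[g]) * length(g)
        else 0, numeric(1)))
      flip <- trend < 0
    }
    return(list(perm = 1L, flips = flip,
                fitness = evalArrangement(ctx, 1L, flip)))
  }
  newInd <- function() list(perm = sample.int(n), flips = sample(c(TRUE, FALSE), n, TRUE))
  pop <- replicate(pop_size, newInd(), simplify = FALSE)
  fit <- vapply(pop, function(ind) evalArrangement(ctx, ind$perm, ind$flips), numeric(1))
  best_i <- which.max(fit)
  best <- pop[[best_i]]; best_fit <- fit[best_i]
  stagnant <- 0L
  tournament <- function() {
    cand <- sample.int(pop_size, 3L)
    cand[which.max(fit[cand])]
  }
  for (gen in seq_len(generations)) {
    nxt <- vector("list", pop_size)
    nxt[[1]] <- best                      # elitism
    nxt_fit <- numeric(pop_size)
    nxt_fit[1] <- best_fit
    for (k in (elitism + 1L):pop_size) {
      a <- pop[[tournament()]]
      if (stats::runif(1) < p_cross) {
        b <- pop[[tournament()]]
        perm <- orderCrossover(a$perm, b$perm)
        pick <- stats::runif(n) < 0.5     # uniform crossover on per-scaffold bits
        flips <- ifelse(pick, a$flips, b$flips)
      } else {
        perm <- a$perm; flips <- a$flips
      }
      if (stats::runif(1) < p_mut) {      # swap two slots
        ij <- sample.int(n, 2)
        perm[ij] <- perm[rev(ij)]
      }
      if (stats::runif(1) < p_mut) {      # flip one scaffold
        j <- sample.int(n, 1)
        flips[j] <- !flips[j]
      }
      nxt[[k]] <- list(perm = perm, flips = flips)
      nxt_fit[k] <- evalArrangement(ctx, perm, flips)
    }
    pop <- nxt; fit <- nxt_fit
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_fit + 1e-12) {
      best_fit <- fit[gen_best]; best <- pop[[gen_best]]; stagnant <- 0L
    } else stagnant <- stagnant + 1L
    if (stagnant >= stagnation) break
  }
  list(perm = best$perm, flips = best$flips, fitness = best_fit)
}

#' Order and orient scaffolds against weighted maps
#'
#' Scaffolds are first assigned to chromosomes by weighted marker majority
#' ([assignChromosomes()]); within each chromosome a genetic algorithm
#' searches (permutation, orientation) space with tournament selection, order
#' crossover, swap and flip mutations, and elitism, maximizing
#' [solutionFitness()]. Scaffolds without markers are left unplaced. Results
#' are reproducible for a fixed `seed`.
#'
#' @param maps a [MapSet-class] object.
#' @param sizes named numeric of scaffold lengths (bp).
#' @param seed RNG seed (default 0).
#' @param pop_size,generations,stagnation,p_cross,p_mut,elitism GA controls.
#' @param gap_size gap between scaffolds used for physical positions (bp).
#' @return a [ScaffoldSolution-class] object.
#' @export
orderScaffolds <- function(maps, sizes, seed = 0L, pop_size = 100L,
                           generations = 500L, stagnation = 50L,
                           p_cross = 0.7, p_mut = 0.2, elitism = 1L,
                           gap_size = 100) {
  m <- markerTable(maps)
  if (nrow(m) == 0L) dataError("orderScaffolds: empty map")
  missing <- setdiff(unique(m$scaffold), names(sizes))
  if (length(missing))
    dataError("orderScaffolds: scaffolds missing from sizes: %s",
              paste(missing, collapse = ", "))
  set.seed(as.integer(seed))
  assign <- assignChromosomes(maps)
  chroms <- naturalSort(unique(assign))
  pl <- list(); total_fit <- 0
  for (chrom in chroms) {
    scs <- naturalSort(names(assign)[assign == chrom])
    ctx <- chromContext(chrom, scs, maps, sizes, gap_size)
    res <- gaOrderChromosome(ctx, pop_size, generations, stagnation,
                             p_cross, p_mut, elitism)
    total_fit <- total_fit + res$fitness
    pl[[chrom]] <- data.frame(
      chrom = chrom, position = seq_along(res$perm),
      scaffold = scs[res$perm],
      orientation = ifelse(res$flips[res$perm], "-", "+"),
      stringsAsFactors = FALSE)
  }
  placements <- do.call(rbind, pl)
  rownames(placements) <- NULL
  sol <- new("ScaffoldSolution", placements = placements,
             fitness = total_fit, rho = data.frame(),
             unplaced = setdiff(names(sizes), placements$scaffold))
  sol@rho <- solutionRho(sol, maps, sizes, gap_size)
  sol
}

## per-map per-lg Spearman rho of a solution
solutionRho <- function(sol, maps, sizes, gap_size = 100) {
  pl <- placements(sol)
  out <- list()
  for (chrom in unique(pl$chrom)) {
    sub <- pl[pl$chrom == chrom, ]
    sub <- sub[order(sub$position), ]
    ctx <- chromContext(chrom, sub$scaffold, maps, sizes, gap_size)
    if (!length(ctx$pos)) next
    phys <- markerPositions(ctx, seq_along(sub$scaffold), sub$orientation == "-")
    for (gname in names(ctx$groups)) {
      g <- ctx$groups[[gname]]
      parts <- strsplit(gname, "\r", fixed = TRUE)[[1]]
      rho <- if (length(g) >= 2L) spearmanRho(phys[g], ctx$cm[g]) else 1
      out[[length(out) + 1L]] <- data.frame(
        map = parts[1], lg = parts[2], rho = rho, n_markers = length(g),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(map = character(0), lg = character(0),
                      rho = numeric(0), n_markers = integer(0)))
  do.call(rbind, out)
}

#' Build an AGP v2 document (and optional pseudo-chromosome FASTA)
#'
#' Rows alternate W (scaffold component) and U (100 bp spacer gap of type
#' "map") per chromosome; total object length per chromosome equals the sum
#' of its scaffold lengths plus gaps. If `seqs` is given, pseudo-chromosome
#' sequences are assembled with N gaps and reverse-complemented segments for
#' "-" orientations.
#'
#' @param sol a [ScaffoldSolution-class] object.
#' @param sizes named numeric of scaffold lengths.
#' @param gap_size spacer gap length (bp, default 100).
#' @param seqs optional [Biostrings::DNAStringSet] of scaffold sequences.
#' @return list with `agp` (data.frame of 9 AGP columns) and `fasta`
#'   (DNAStringSet or NULL).
#' @export
buildAgp <- function(sol, sizes, gap_size = 100L, seqs = NULL) {
  pl <- placements(sol)
  missing <- setdiff(pl$scaffold, names(sizes))
  if (length(missing))
    dataError("buildAgp: scaffolds missing from sizes: %s",
              paste(missing, collapse = ", "))
  rows <- list(); chrs <- list()
  for (chrom in unique(pl$chrom)) {
    sub <- pl[pl$chrom == chrom, ]
    sub <- sub[order(sub$position), ]
    if (nrow(sub) == 0L) next
    at <- 0L; part <- 0L
    pieces <- if (!is.null(seqs)) list() else NULL
    for (i in seq_len(nrow(sub))) {
      if (i > 1L) {
        part <- part + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          object = chrom, object_beg = at + 1L, object_end = at + gap_size,
          part_number = part, component_type = "U", col6 = as.character(gap_size),
          col7 = "map", col8 = "yes", col9 = "map", stringsAsFactors = FALSE)
        at <- at + gap_size
        if (!is.null(pieces))
          pieces[[length(pieces) + 1L]] <- paste(rep("N", gap_size), collapse = "")
      }
      len <- as.integer(sizes[sub$scaffold[i]])
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = chrom, object_beg = at + 1L, object_end = at + len,
        part_number = part, component_type = "W", col6 = sub$scaffold[i],
        col7 = "1", col8 = as.character(len), col9 = sub$orientation[i],
        stringsAsFactors = FALSE)
      at <- at + len
      if (!is.null(pieces)) {
        s <- seqs[[sub$scaffold[i]]]
        if (sub$orientation[i] == "-") s <- Biostrings::reverseComplement(s)
        pieces[[length(pieces) + 1L]] <- as.character(s)
      }
    }
    if (!is.null(pieces)) chrs[[chrom]] <- paste(unlist(pieces), collapse = "")
  }
  agp <- do.call(rbind, rows)
  fasta <- NULL
  if (!is.null(seqs) && length(chrs))
    fasta <- Biostrings::DNAStringSet(unlist(chrs))
  list(agp = agp, fasta = fasta)
}

#' Write an AGP table to a 9-column file
#'
#' @param agp data.frame from [buildAgp()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAgp <- function(agp, path) {
  lines <- apply(agp, 1, function(r) paste(trimws(r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Per-chromosome concordance report
#'
#' Summarizes how well an ordered assembly agrees with its maps: scaffolds
#' anchored and oriented (a scaffold with a single marker is anchored but
#' unoriented), marker counts and Spearman's rho per map, and total anchored
#' length. Also returns layout data for the classic two-panel view: matching
#' lines between map position and chromosome position, and physical-vs-map
#' scatter points.
#'
#' @param sol a [ScaffoldSolution-class] object.
#' @param maps a [MapSet-class] object.
#' @param sizes named numeric of scaffold lengths.
#' @param gap_size gap between scaffolds (bp).
#' @return list with `summary` (per-chromosome data.frame), `rho` (per-map
#'   per-lg table), `scatter` (marker-level physical vs map positions), and
#'   `totals`.
#' @export
concordanceReport <- function(sol, maps, sizes, gap_size = 100) {
  pl <- placements(sol)
  m <- markerTable(maps)
  rho <- solutionRho(sol, maps, sizes, gap_size)
  scatter <- list(); summ <- list()
  for (chrom in unique(pl$chrom)) {
    sub <- pl[pl$chrom == chrom, ]
    sub <- sub[order(sub$position), ]
    ctx <- chromContext(chrom, sub$scaffold, maps, sizes, gap_size)
    phys <- if (length(ctx$pos)) markerPositions(ctx, seq_along(sub$scaffold),
                                                 sub$orientation == "-") else numeric(0)
    if (length(phys)) {
      mm <- m[m$lg == chrom & m$scaffold %in% sub$scaffold, ]
      scatter[[chrom]] <- data.frame(
        chrom = chrom, map = mm$map, scaffold = mm$scaffold,
        physical = phys + 1, cm = mm$cm, stringsAsFactors = FALSE)
    }
    nmark <- table(factor(m$scaffold[m$lg == chrom], levels = sub$scaffold))
    summ[[chrom]] <- data.frame(
      chrom = chrom, n_scaffolds = nrow(sub),
      n_oriented = sum(nmark >= 2L), n_markers = length(ctx$pos),
      anchored_length = sum(as.numeric(sizes[sub$scaffold])),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  list(summary = summary, rho = rho,
       scatter = if (length(scatter)) do.call(rbind, scatter) else data.frame(),
       totals = list(n_scaffolds = sum(summary$n_scaffolds),
                     n_unplaced = length(sol@unplaced),
                     anchored_length = sum(summary$anchored_length),
                     n_markers = sum(summary$n_markers)))
}
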