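## Thin base-graphics renderers over the layout documents. The layout
## documents are the tested surface; these functions only draw them.

openDevice <- function(path, width = 7, height = 7) {
  if (grepl("\\.pdf$", path)) grDevices::pdf(path, width = width, height = height)
  else grDevices::png(path, width = width * 100, height = height * 100)
  invisible(path)
}

#' Render a synteny dot plot
#'
#' @param layout output of [dotplotLayout()].
#' @param path output PNG or PDF path.
#' @return `path`, invisibly.
#' @export
plotDotplot <- function(layout, path) {
  openDevice(path)
  on.exit(grDevices::dev.off())
  pts <- layout$points
  ba <- layout$bounds_a; bb <- layout$bounds_b
  graphics::plot(pts$x, pts$y, pch = 20, cex = 0.4,
                 col = ifelse(pts$orientation == "+", "steelblue", "firebrick"),
                 xlab = "genome A (gene rank)", ylab = "genome B (gene rank)",
                 xlim = c(0, sum(ba$n_genes)), ylim = c(0, sum(bb$n_genes)))
  graphics::abline(v = ba$offset[-1], h = bb$offset[-1], col = "gray80")
  invisible(path)
}

#' Render a karyotype (macro-synteny) ribbon figure
#'
#' @param layout output of [karyotypeLayout()].
#' @param path output PNG or PDF path.
#' @return `path`, invisibly.
#' @export
plotKaryotype <- function(layout, path) {
  openDevice(path, height = 4)
  on.exit(grDevices::dev.off())
  tr <- layout$tracks; rb <- layout$ribbons
  xmax <- max(tr$end)
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, 3), axes = FALSE,
                 xlab = "", ylab = "")
  ya <- 2.5; yb <- 0.5
  for (i in seq_len(nrow(tr))) {
    y <- if (tr$track[i] == "a") ya else yb
    graphics::rect(tr$start[i], y - 0.1, tr$end[i], y + 0.1, col = "gray30")
    graphics::text((tr$start[i] + tr$end[i]) / 2, y + 0.3, tr$seqid[i], cex = 0.7)
  }
  for (i in seq_len(nrow(rb))) {
    col <- grDevices::adjustcolor(rb$color[i], alpha.f = 0.5)
    graphics::polygon(c(rb$a_start[i], rb$a_end[i], rb$b_end[i], rb$b_start[i]),
                      c(ya - 0.1, ya - 0.1, yb + 0.1, yb + 0.1),
                      col = col, border = NA)
  }
  invisible(path)
}

#' Render a micro-synteny gene-level figure
#'
#' Blue boxes are genes on the positive strand, green on the negative strand;
#' ribbons connect matched genes.
#'
#' @param layout output of [microsyntenyLayout()].
#' @param path output PNG or PDF path.
#' @return `path`, invisibly.
#' @export
plotMicrosynteny <- function(layout, path) {
  openDevice(path, height = 4)
  on.exit(grDevices::dev.off())
  ga <- layout$genes_a; gb <- layout$genes_b; rb <- layout$ribbons
  xr <- range(c(ga$rank, gb$rank))
  graphics::plot(NULL, xlim = xr + c(-0.5, 0.5), ylim = c(0, 3), axes = FALSE,
                 xlab = "", ylab = "")
  drawGenes <- function(g, y) {
    if (nrow(g))
      graphics::rect(g$rank - 0.4, y - 0.12, g$rank + 0.4, y + 0.12, col = g$color)
  }
  drawGenes(ga, 2.5); drawGenes(gb, 0.5)
  for (i in seq_len(nrow(rb)))
    graphics::segments(rb$rank_a[i], 2.38, rb$rank_b[i], 0.62,
                       col = grDevices::adjustcolor("gray", alpha.f = 0.6))
  invisible(path)
}

#' Render the per-chromosome concordance panels
#'
#' Scatter of marker physical position versus map location per map, annotated
#' with Spearman's rho.
#'
#' @param report output of [concordanceReport()].
#' @param chrom chromosome to draw.
#' @param path output PNG or PDF path.
#' @return `path`, invisibly.
#' @export
plotConcordance <- function(report, chrom, path) {
  sc <- report$scatter
  sc <- sc[sc$chrom == chrom, , drop = FALSE]
  if (nrow(sc) == 0L) dataError("plotConcordance: no markers for %s", chrom)
  maps <- unique(sc$map)
  openDevice(path, width = 4 * length(maps), height = 4)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, length(maps)))
  for (m in maps) {
    sub <- sc[sc$map == m, ]
    rho <- report$rho$rho[report$rho$map == m & report$rho$lg == chrom]
    graphics::plot(sub$physical, sub$cm, pch = 20, col = "steelblue",
                   xlab = sprintf("%s position (bp)", chrom),
                   ylab = "map location (cM)",
                   main = sprintf("%s  rho = %.3f", m, rho[1]))
  }
  invisible(path)
}

#' Render a k-mer spectrum with fitted mixture components
#'
#' @param spec a [KmerSpectrum-class] object.
#' @param model a [SpectrumModel-class] object from [fitSpectrum()].
#' @param path output PNG or PDF path.
#' @return `path`, invisibly.
#' @export
plotSpectrumFit <- function(spec, model, path) {
  openDevice(path)
  on.exit(grDevices::dev.off())
  j <- spec@multiplicity
  graphics::plot(j, spec@count, type = "h", col = "gray60",
                 xlab = "k-mer multiplicity", ylab = "distinct k-mers")
  G <- mixingMasses(model)
  for (c in seq_along(G)) {
    if (G[c] <= 0) next
    graphics::lines(j, G[c] * nbComponent(j, c, model@n, model@p),
                    col = c + 1, lwd = 1.5)
  }
  graphics::lines(j, modelSpectrum(j, G, model@n, model@p), lwd = 2)
  invisible(path)
}

#' Render an LD r-squared heatmap with chromosome boundaries
#'
#' @param ld output of [ldMatrix()].
#' @param path output PNG or PDF path.
#' @return `path`, invisibly.
#' @export
plotLDHeatmap <- function(ld, path) {
  openDevice(path)
  on.exit(grDevices::dev.off())
  idx <- ld$thinned_index
  m <- ld$r2[idx, idx, drop = FALSE]
  m[is.na(m)] <- 0
  graphics::image(seq_along(idx), seq_along(idx), m, zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "marker", ylab = "marker")
  bd <- match(ld$boundaries, idx)
  graphics::abline(v = bd[!is.na(bd)] - 0.5, h = bd[!is.na(bd)] - 0.5,
                   col = "gray40")
  invisible(path)
}

#' Render a log-scaled Hi-C contact heatmap
#'
#' @param cb a [ContactBins-class] object.
#' @param path output PNG or PDF path.
#' @return `path`, invisibly.
#' @export
plotContactMap <- function(cb, path) {
  openDevice(path)
  on.exit(grDevices::dev.off())
  m <- log1p(contactMatrix(cb))
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::hcl.colors(64, "Reds", rev = TRUE),
                  xlab = "bin", ylab = "bin")
  graphics::abline(v = cb@offsets[-1] - 0.5, h = cb@offsets[-1] - 0.5,
                   col = "gray40")
  invisible(path)
}

#' Render side-by-side normalized depth landscapes
#'
#' @param landscape output of [depthLandscape()].
#' @param path output PNG or PDF path.
#' @return `path`, invisibly.
#' @export
plotDepthLandscape <- function(landscape, path) {
  lay <- landscape$layout
  varieties <- unique(lay$variety)
  openDevice(path, height = 2.5 * length(varieties))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(varieties), 1), mar = c(2, 4, 2, 1))
  for (v in varieties) {
    sub <- lay[lay$variety == v, ]
    x <- seq_len(nrow(sub))
    cols <- ifelse(sub$flag == "loss", "firebrick",
                   ifelse(sub$flag == "gain", "darkorange", "gray50"))
    graphics::plot(x, sub$norm_depth, type = "h", col = cols, ylim = c(0, 2.5),
                   ylab = "normalized depth", main = v)
    graphics::abline(h = 1, col = "gray70")
  }
  invisible(path)
}

#' Render a pedigree with parentage pies and inbreeding coefficients
#'
#' Individuals are laid out by generation (topological depth); each node shows
#' its gene-dropping parentage as a pie over founder colors, labelled with its
#' inbreeding coefficient F.
#'
#' @param ped a [Pedigree-class] object.
#' @param path output PNG or PDF path.
#' @param N gene-dropping replicates per individual.
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
plotPedigree <- function(ped, path, N = 1000L, seed = 0L) {
  e <- pedigreeTable(ped)
  depth <- stats::setNames(integer(nrow(e)), e$name)
  for (i in seq_len(nrow(e))) {
    if (!is.na(e$parent_a[i]))
      depth[e$name[i]] <- max(depth[e$parent_a[i]], depth[e$parent_b[i]]) + 1L
  }
  openDevice(path, height = 5)
  on.exit(grDevices::dev.off())
  maxd <- max(depth)
  xs <- ys <- stats::setNames(numeric(nrow(e)), e$name)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(-0.5, maxd + 0.5), axes = FALSE,
                 xlab = "", ylab = "")
  fnd <- founders(ped)
  cols <- stats::setNames(grDevices::hcl.colors(max(length(fnd), 2), "Dynamic"),
                          fnd)
  for (d in 0:maxd) {
    nms <- names(depth)[depth == d]
    for (k in seq_along(nms)) {
      xs[nms[k]] <- k / (length(nms) + 1)
      ys[nms[k]] <- maxd - d
    }
  }
  for (i in seq_len(nrow(e))) {
    if (is.na(e$parent_a[i])) next
    for (pp in c(e$parent_a[i], e$parent_b[i]))
      graphics::segments(xs[pp], ys[pp] - 0.1, xs[e$name[i]], ys[e$name[i]] + 0.1,
                         col = "gray60")
  }
  for (i in seq_len(nrow(e))) {
    nm <- e$name[i]
    gd <- geneDrop(ped, nm, N = N, seed = seed)
    share <- gd$parentage[gd$parentage > 0]
    ## tiny pie: draw as stacked arc segments on a circle
    theta0 <- 0
    r <- 0.06
    for (f in names(share)) {
      theta1 <- theta0 + share[[f]] * 2 * pi
      tt <- seq(theta0, theta1, length.out = 20)
      graphics::polygon(c(xs[nm], xs[nm] + r * cos(tt)),
                        c(ys[nm], ys[nm] + r * sin(tt)),
                        col = cols[f], border = NA)
      theta0 <- theta1
    }
    graphics::text(xs[nm], ys[nm] - 0.22,
                   sprintf("%s\nF=%.2f", nm, gd$F), cex = 0.6)
  }
  invisible(path)
}
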