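## Layout documents for synteny visualization. Layout documents (plain lists
## of data.frames, serializable to JSON) are the tested surface; the plot*()
## functions in plots.R are thin renderers over them.

## cumulative rank offset per chromosome, natural-sorted
chromOffsets <- function(index) {
  g <- geneTable(index)
  counts <- table(g$seqid)
  ord <- naturalSort(names(counts))
  n <- as.integer(counts[ord])
  offs <- cumsum(c(0L, n[-length(n)]))
  data.frame(seqid = ord, offset = offs, n_genes = n, stringsAsFactors = FALSE)
}

#' Dotplot layout of synteny blocks
#'
#' Places every anchor pair at its cumulative gene-rank coordinates, with
#' chromosome boundary offsets for both genomes, ready for a synteny dot plot.
#'
#' @param blocks a [SyntenyBlocks-class] object.
#' @param index_a,index_b [GeneIndex-class] objects for the two genomes.
#' @return list with `points` (data.frame `x`, `y`, `block_id`, `orientation`)
#'   and `bounds_a`, `bounds_b` (chromosome offset tables).
#' @export
dotplotLayout <- function(blocks, index_a, index_b) {
  offs_a <- chromOffsets(index_a); offs_b <- chromOffsets(index_b)
  p <- pairTable(blocks); b <- blockTable(blocks)
  if (nrow(p)) {
    seq_a <- b$seqid_a[match(p$block_id, b$block_id)]
    seq_b <- b$seqid_b[match(p$block_id, b$block_id)]
    pts <- data.frame(
      x = p$rank_a + offs_a$offset[match(seq_a, offs_a$seqid)],
      y = p$rank_b + offs_b$offset[match(seq_b, offs_b$seqid)],
      block_id = p$block_id,
      orientation = b$orientation[match(p$block_id, b$block_id)],
      stringsAsFactors = FALSE)
  } else {
    pts <- data.frame(x = numeric(0), y = numeric(0), block_id = integer(0),
                      orientation = character(0))
  }
  list(points = pts, bounds_a = offs_a, bounds_b = offs_b)
}

#' Karyotype (macro-synteny) layout
#'
#' Two parallel chromosome tracks with one ribbon per block connecting its
#' rank spans. Blocks listed in `highlight` get the highlight color (regions
#' of interest); all others are gray.
#'
#' @param blocks a [SyntenyBlocks-class] object.
#' @param index_a,index_b [GeneIndex-class] objects for the two genomes.
#' @param highlight integer vector of block ids to highlight.
#' @param highlight_color color for highlighted ribbons (default yellow).
#' @return list with `tracks` (chromosome extents per track) and `ribbons`
#'   (per-block quad endpoints in cumulative rank units + color).
#' @export
karyotypeLayout <- function(blocks, index_a, index_b, highlight = integer(0),
                            highlight_color = "yellow") {
  offs_a <- chromOffsets(index_a); offs_b <- chromOffsets(index_b)
  tracks <- rbind(
    data.frame(track = "a", seqid = offs_a$seqid, start = offs_a$offset,
               end = offs_a$offset + offs_a$n_genes, stringsAsFactors = FALSE),
    data.frame(track = "b", seqid = offs_b$seqid, start = offs_b$offset,
               end = offs_b$offset + offs_b$n_genes, stringsAsFactors = FALSE))
  b <- blockTable(blocks)
  if (nrow(b)) {
    oa <- offs_a$offset[match(b$seqid_a, offs_a$seqid)]
    ob <- offs_b$offset[match(b$seqid_b, offs_b$seqid)]
    ribbons <- data.frame(
      block_id = b$block_id,
      a_start = b$span_a_lo + oa, a_end = b$span_a_hi + oa,
      b_start = b$span_b_lo + ob, b_end = b$span_b_hi + ob,
      orientation = b$orientation,
      color = ifelse(b$block_id %in% highlight, highlight_color, "gray"),
      stringsAsFactors = FALSE)
  } else {
    ribbons <- data.frame(block_id = integer(0), a_start = numeric(0),
                          a_end = numeric(0), b_start = numeric(0),
                          b_end = numeric(0), orientation = character(0),
                          color = character(0))
  }
  list(tracks = tracks, ribbons = ribbons)
}

#' Micro-synteny layout for a local window
#'
#' Gene-scale view: one glyph box per gene in the window on each genome
#' (blue for "+" strand, green for "-"), with ribbons connecting matched
#' genes of blocks intersecting the window.
#'
#' @param blocks a [SyntenyBlocks-class] object.
#' @param index_a,index_b [GeneIndex-class] objects.
#' @param seqid_a chromosome of genome A defining the window.
#' @param rank_lo,rank_hi inclusive rank window on `seqid_a`.
#' @return list with `genes_a`, `genes_b` (glyph tables: `accn`, `rank`,
#'   `strand`, `color`) and `ribbons` (`gene_a`, `gene_b`, `rank_a`, `rank_b`,
#'   `block_id`).
#' @export
microsyntenyLayout <- function(blocks, index_a, index_b, seqid_a,
                               rank_lo, rank_hi) {
  ga <- geneTable(index_a); gb <- geneTable(index_b)
  win_a <- ga[ga$seqid == seqid_a & ga$rank >= rank_lo & ga$rank <= rank_hi, ]
  if (nrow(win_a) == 0L)
    dataError("microsyntenyLayout: window contains no genes")
  p <- pairTable(blocks); b <- blockTable(blocks)
  sel <- p$gene_a %in% win_a$accn
  rib <- p[sel, c("gene_a", "gene_b", "rank_a", "rank_b", "block_id")]
  gb_show <- gb[gb$accn %in% rib$gene_b, ]
  glyph <- function(g) data.frame(
    accn = g$accn, seqid = g$seqid, rank = g$rank, strand = g$strand,
    color = ifelse(g$strand == "+", "blue", "green"), stringsAsFactors = FALSE)
  list(genes_a = glyph(win_a), genes_b = glyph(gb_show), ribbons = rib)
}

#' Write a layout document as JSON
#'
#' @param layout any layout document (list of data.frames).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLayout <- function(layout, path) {
  jsonlite::write_json(layout, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
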