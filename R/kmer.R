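## Genome survey from a k-mer spectrum. Default model: the observed spectrum
## K_j (distinct k-mers at multiplicity j) is a mixture of negative binomial
## components, one per genome copy number c, with mixing masses G_c:
##   K_j = sum_c G_c * NB(j; size = c * n, prob = p)
## so the component for copy number c peaks at c-fold coverage. A simpler
## three-class (haploid/diploid/repeat) peak model is also provided.

#' Negative binomial mixture component
#'
#' Probability mass at multiplicity `j` of the copy-number-`c` component: a
#' negative binomial with size `c * n` and success probability `p`. Its mean
#' is `c * n * (1 - p) / p`, i.e. coverage scales linearly with copy number.
#'
#' @param j integer multiplicity (>= 0); vectorized.
#' @param c genome copy number (>= 1).
#' @param n shape parameter of the copy-number-1 component.
#' @param p success probability in (0, 1).
#' @return probability mass values.
#' @export
nbComponent <- function(j, c, n, p) {
  if (p <= 0 || p >= 1) dataError("nbComponent: p must lie in (0,1)")
  if (n <= 0) dataError("nbComponent: n must be positive")
  if (c < 1) dataError("nbComponent: copy number must be >= 1")
  stats::dnbinom(j, size = c * n, prob = p)
}

## model spectrum over given multiplicities
modelSpectrum <- function(j, G, n, p) {
  M <- vapply(seq_along(G), function(c) nbComponent(j, c, n, p), numeric(length(j)))
  if (!is.matrix(M)) M <- matrix(M, nrow = length(j))
  as.numeric(M %*% G)
}

## first local minimum of the smoothed spectrum, scanning from the left;
## multiplicities below it are treated as sequencing-error k-mers
errorValley <- function(spec, window = 5L) {
  j <- spec@multiplicity
  full <- numeric(max(j))
  full[j] <- spec@count
  s <- runningMean(full, window)
  if (length(s) < 3L || s[1] <= s[2]) return(1L)  # no descending error tail
  for (i in 2:(length(s) - 1L)) {
    if (s[i] <= s[i - 1L] && s[i] < s[i + 1L]) return(i)
  }
  1L
}

#' Fit a negative binomial mixture to a k-mer spectrum
#'
#' Minimizes the L2 distance between the observed spectrum and the mixture
#' model by alternating estimation: given (n, p), the mixing masses G_c are
#' solved by non-negative least squares; given G, (n, p) are updated by
#' bounded quasi-Newton minimization. Iteration stops when the relative L2
#' improvement falls below `tol` or after `max_rounds` rounds; an (n, p)
#' update is kept only if it improves the objective, so the L2 trace is
#' non-increasing. Multiplicities below the first local minimum of the
#' smoothed spectrum (the error valley) are excluded from the fit.
#'
#' Initialization: the main peak is located by argmax of the smoothed
#' spectrum above the error valley; (n, p) start so that the copy-number-1
#' component has mean equal to the peak multiplicity and variance twice its
#' mean (p = 0.5, n = peak).
#'
#' @param spec a [KmerSpectrum-class] object.
#' @param c_max highest modeled copy number (default 8).
#' @param tol relative L2 convergence tolerance.
#' @param max_rounds maximum alternating rounds.
#' @return a [SpectrumModel-class] object; its `estimate` holds genome size
#'   (sum of c * G_c), coverage (copy-number-1 component mean), repeat
#'   fraction, heterozygosity proxy, and a heuristic ploidy call.
#' @export
fitSpectrum <- function(spec, c_max = 8L, tol = 1e-6, max_rounds = 200L) {
  if (length(spec@multiplicity) < 2L)
    dataError("fitSpectrum: degenerate spectrum (fewer than 2 bins)")
  valley <- errorValley(spec)
  keep <- spec@multiplicity >= valley
  j <- spec@multiplicity[keep]
  K <- spec@count[keep]
  if (length(j) < 2L || sum(K) == 0)
    dataError("fitSpectrum: no signal above the error valley")

  ## initialize from the smoothed main peak
  sm <- runningMean(K, 5L)
  peak <- j[which.max(sm)]
  p <- 0.5
  n <- max(peak * p / (1 - p), 1e-3)

  design <- function(n, p)
    vapply(seq_len(c_max), function(c) nbComponent(j, c, n, p), numeric(length(j)))
  solveG <- function(n, p) {
    M <- design(n, p)
    fit <- pracma::lsqnonneg(M, K)
    list(G = fit$x, l2 = sqrt(sum((M %*% fit$x - K)^2)))
  }
  obj_np <- function(par, G) {
    nn <- exp(par[1]); pp <- stats::plogis(par[2])
    sqrt(sum((modelSpectrum(j, G, nn, pp) - K)^2))
  }

  g <- solveG(n, p)
  G <- g$G; l2 <- g$l2
  trace <- l2
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    opt <- stats::optim(c(log(n), stats::qlogis(p)), obj_np, G = G,
                        method = "L-BFGS-B", lower = c(-7, -12), upper = c(12, 12))
    if (opt$value < l2) {    # keep only improving updates: monotone L2
      n <- exp(opt$par[1]); p <- stats::plogis(opt$par[2])
    }
    g <- solveG(n, p)
    if (g$l2 <= l2) { G <- g$G; l2_new <- g$l2 } else l2_new <- l2
    trace <- c(trace, l2_new)
    if (l2 - l2_new < tol * max(l2, 1e-12)) {
      l2 <- l2_new
      converged <- TRUE
      break
    }
    l2 <- l2_new
  }

  names(G) <- as.character(seq_len(c_max))
  genome_size <- sum(seq_len(c_max) * G)
  coverage <- n * (1 - p) / p
  repeat_fraction <- if (genome_size > 0) sum((2:c_max) * G[2:c_max]) / genome_size else 0
  ## proxy only: mass of the half-coverage (copy-1) peak relative to a diploid
  ## interpretation; no explicit heterozygosity model is fitted
  het_proxy <- if ((G[1] + 2 * G[2]) > 0) G[1] / (G[1] + 2 * G[2]) else 0
  cw <- seq_len(c_max) * G
  ploidy_call <- min(which.max(cw), 4L)
  new("SpectrumModel", G = G, n = n, p = p, c_max = as.integer(c_max),
      l2 = l2, converged = converged, trace = trace,
      estimate = list(genome_size = genome_size, coverage = coverage,
                      repeat_fraction = repeat_fraction,
                      het_proxy = as.numeric(het_proxy),
                      ploidy_call = as.integer(ploidy_call)))
}

#' Three-class (haploid/diploid/repeat) spectrum classification
#'
#' The simpler peak-based model: the multiplicity axis is split at the error
#' valley (first local minimum of the smoothed spectrum), and k-mers above it
#' are classed as haploid (below `hap_hi` times the main peak), diploid
#' (around the main peak), or repeat (above `rep_lo` times the main peak).
#' Genome size is the total k-mer count above the error valley divided by the
#' main-peak coverage. Less suited to polyploids but cheap and robust.
#'
#' @param spec a [KmerSpectrum-class] object.
#' @param hap_hi upper bound of the haploid class as a fraction of the main
#'   peak (default 0.75).
#' @param rep_lo lower bound of the repeat class as a multiple of the main
#'   peak (default 1.5).
#' @return list with `classes` (named masses: error, haploid, diploid,
#'   repeat), `peak` (main-peak multiplicity), `valley`, and `estimate`
#'   (genome_size, coverage, repeat_fraction, het_proxy).
#' @export
allpathsClassify <- function(spec, hap_hi = 0.75, rep_lo = 1.5) {
  if (length(spec@multiplicity) < 2L)
    dataError("allpathsClassify: degenerate spectrum")
  valley <- errorValley(spec)
  j <- spec@multiplicity; K <- spec@count
  above <- j >= valley
  if (!any(above) || sum(K[above]) == 0)
    dataError("allpathsClassify: no detectable peak above the error valley")
  sm <- runningMean(K[above], 5L)
  peak <- j[above][which.max(sm)]
  if (peak <= valley)
    dataError("allpathsClassify: no detectable peak above the error valley")
  cls <- ifelse(!above, "error",
         ifelse(j < hap_hi * peak, "haploid",
         ifelse(j <= rep_lo * peak, "diploid", "repeat")))
  masses <- tapply(K, factor(cls, levels = c("error", "haploid", "diploid", "repeat")), sum)
  masses[is.na(masses)] <- 0
  total_kmers <- sum(as.numeric(j[above]) * K[above])
  genome_size <- total_kmers / peak
  hap <- masses[["haploid"]]; dip <- masses[["diploid"]]
  list(classes = masses, peak = peak, valley = valley,
       estimate = list(genome_size = genome_size, coverage = peak,
                       repeat_fraction = masses[["repeat"]] / sum(masses[-1]),
                       het_proxy = if ((hap + dip) > 0) hap / (hap + dip) else 0))
}
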