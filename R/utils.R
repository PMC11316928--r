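## Internal helpers shared across modules.

#' Natural (alphanumeric) sort of character labels
#'
#' Sorts labels such as chromosome or linkage-group names so that embedded
#' integers compare numerically: `chr2` before `chr10`, `LG1 < LG2 < LG10`.
#'
#' @param x character vector.
#' @return `x` reordered.
#' @examples
#' naturalSort(c("chr10", "chr2", "chr1"))
#' @export
naturalSort <- function(x) {
  x <- as.character(x)
  if (length(x) < 2L) return(x)
  ## split each label into alternating non-digit / digit runs and pad digits
  key <- vapply(x, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    parts <- vapply(parts, function(p) {
      if (grepl("^[0-9]+$", p)) formatC(p, width = 20, flag = "0") else p
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  x[order(key, x, method = "radix")]
}

## Disjoint-set (union-find) with path compression; used by single-linkage
## chaining and proximal-duplicate grouping. Returns component labels 1..k.
unionFindComponents <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(a) {
    root <- a
    while (parent[root] != root) root <- parent[root]
    while (parent[a] != root) { nxt <- parent[a]; parent[a] <<- root; a <- nxt }
    root
  }
  for (e in seq_along(edges_i)) {
    ra <- find(edges_i[e]); rb <- find(edges_j[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## Running-mean smoother with odd window, edges handled by shrinking window.
runningMean <- function(x, window = 5L) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- as.integer(window) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

## stop() with a consistent prefix for user-facing data errors
dataError <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

## Modal value of an integer vector (smallest wins ties); NA if empty
modalValue <- function(x) {
  if (length(x) == 0L) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}
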