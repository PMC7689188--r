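#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, M, K)`: the chance of drawing at
#' least `x` interesting elements when `K` elements are drawn without
#' replacement from a universe of `N` containing `M` interesting ones.
#' Equivalently `1 - sum_{t=0}^{x-1} C(M,t) C(N-M,K-t) / C(N,K)`, evaluated
#' stably in log space.
#'
#' @param N Universe size.
#' @param K Size of the investigated (drawn) set.
#' @param M Size of the interesting set.
#' @param x Observed overlap.
#' @return Probability in `(0, 1]`; `x = 0` gives exactly 1.
#' @export
hypergeom_upper_tail <- function(N, K, M, x) {
  stopifnot(length(N) == 1, length(K) == 1, length(M) == 1, length(x) == 1)
  if (any(c(N, K, M, x) < 0) || any(c(N, K, M, x) != floor(c(N, K, M, x)))) {
    stop("N, K, M, x must be non-negative integers")
  }
  if (K > N || M > N) stop("K and M must not exceed N")
  if (x > min(K, M)) stop("x must not exceed min(K, M)")
  if (x == 0) return(1.0)
  # phyper computes the tail via stable log-space recursions
  stats::phyper(x - 1, M, N - M, K, lower.tail = FALSE)
}

#' Overlap test between two sets over a finite universe
#'
#' Computes the intersection size and its upper-tail hypergeometric
#' p-value, plus the expected overlap `K*M/N`, fold enrichment and the
#' overlap as a percentage of the investigated set `A`. Elements of `A` or
#' `B` outside the universe are dropped with a warning (they never inflate
#' `N`).
#'
#' @param setA Investigated set (character vector of ids).
#' @param setB Interesting set.
#' @param universe Universe of ids both sets are judged against.
#' @return List of class `OverlapResult`: `N`, `K`, `M`, `x`, `expected`,
#'   `fold_enrichment`, `overlap_percent` (0-100 scale), `p_upper`.
#' @export
overlap_test <- function(setA, setB, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  dropA <- setdiff(setA, universe)
  dropB <- setdiff(setB, universe)
  if (length(dropA) || length(dropB)) {
    warning(sprintf("dropped %d elements of A and %d of B absent from the universe",
                    length(dropA), length(dropB)))
  }
  A <- intersect(setA, universe)
  B <- intersect(setB, universe)
  N <- length(universe); K <- length(A); M <- length(B)
  x <- length(intersect(A, B))
  expected <- K * M / N
  structure(list(N = N, K = K, M = M, x = x,
                 expected = expected,
                 fold_enrichment = if (expected > 0) x / expected else NA_real_,
                 overlap_percent = if (K > 0) 100 * x / K else NA_real_,
                 p_upper = hypergeom_upper_tail(N, K, M, x)),
            class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("Overlap %d/%d (%.2f%%) against %d of %d; expected %.2f, P = %.3g\n",
              x$x, x$K, x$overlap_percent, x$M, x$N, x$expected, x$p_upper))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted values in the input order, capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Read gene sets in GMT format
#'
#' Tab-delimited: term, description, then member ids.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (term -> members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  out
}

#' Hypergeometric enrichment of a query set against an annotation
#'
#' One [overlap_test()] per annotation term, with BH adjustment across
#' terms of this run only (q-values are never pooled across screens).
#'
#' @param query Character vector of ids of interest.
#' @param annotation Named list of term member vectors (e.g. [read_gmt()]).
#' @param universe Background id set.
#' @param alpha Significance level on the adjusted p, default 0.05.
#' @return Data frame: `term`, `x`, `K`, `M`, `expected`, `p`, `q`,
#'   `significant`, ordered by increasing `p`.
#' @export
enrich <- function(query, annotation, universe, alpha = 0.05) {
  if (!length(annotation)) stop("empty annotation")
  if (is.null(names(annotation)) || any(!nzchar(names(annotation)))) {
    stop("annotation terms must be named")
  }
  rows <- lapply(names(annotation), function(term) {
    r <- suppressWarnings(overlap_test(query, annotation[[term]], universe))
    data.frame(term = term, x = r$x, K = r$K, M = r$M,
               expected = r$expected, p = r$p_upper,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
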