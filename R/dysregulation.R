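#' Spearman rank correlation of two vectors
#'
#' Average ranks are used for ties. A constant vector makes the correlation
#' undefined and raises an error; callers screening many pairs should catch
#' it and drop the pair.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Correlation in `[-1, 1]`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  stats::cor(x, y, method = method)
}

#' Dysregulation scores for candidate miRNA-mRNA pairs
#'
#' For each candidate pair the within-condition rank correlation is computed
#' across tumor and across normal samples; the dysregulation score is
#' `S = |rho_tumor - rho_normal|`, in `[0, 2]`. Pairs whose ids are missing
#' from the matrices, or whose expression is constant within a condition,
#' are skipped and recorded in the `skipped` attribute of the result.
#'
#' @param em_mirna,em_gene [expression_matrix()] objects sharing the same
#'   samples.
#' @param pairs A [candidate_pairs()] list.
#' @param groups A [group_assignment()]; both conditions need >= 3 samples.
#' @param method Correlation flavor, `"spearman"` (default) or `"pearson"`.
#' @return Data frame of class `DysregulationTable` with columns `mirna`,
#'   `gene`, `rho_tumor`, `rho_normal`, `score` (and `p_perm`, `n_perm` once
#'   [permutation_pvalues()] has run). Attribute `skipped` lists dropped
#'   pairs with a reason.
#' @export
dysregulation_scores <- function(em_mirna, em_gene, pairs, groups,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!identical(sample_ids(em_mirna), sample_ids(em_gene))) {
    stop("miRNA and gene matrices must share the same samples in the same order")
  }
  cond <- condition_of(groups, em_mirna)
  it <- which(cond == "tumor")
  in_ <- which(cond == "normal")
  if (length(it) < 3 || length(in_) < 3) {
    stop("need at least 3 tumor and 3 normal samples")
  }

  mi <- match(pairs$mirna, feature_ids(em_mirna))
  gi <- match(pairs$gene, feature_ids(em_gene))
  present <- !is.na(mi) & !is.na(gi)
  skipped <- data.frame(mirna = pairs$mirna[!present],
                        gene = pairs$gene[!present],
                        reason = if (any(!present)) "id not in expression" else character(0),
                        stringsAsFactors = FALSE)

  mi <- mi[present]; gi <- gi[present]
  if (!length(mi)) stop("no evaluable pair: all ids missing from the matrices")

  corr_block <- function(cols) {
    xm <- em_mirna[unique(mi), cols, drop = FALSE]
    gm <- em_gene[unique(gi), cols, drop = FALSE]
    if (method == "spearman") {
      xm <- t(apply(xm, 1L, rank)); gm <- t(apply(gm, 1L, rank))
    }
    xa <- xm - rowMeans(xm); ga <- gm - rowMeans(gm)
    xs <- rowSums(xa * xa);  gs <- rowSums(ga * ga)
    a <- xa[match(mi, unique(mi)), , drop = FALSE]
    b <- ga[match(gi, unique(gi)), , drop = FALSE]
    num <- rowSums(a * b)
    den <- sqrt(xs[match(mi, unique(mi))] * gs[match(gi, unique(gi))])
    ifelse(den > 0, num / den, NA_real_)
  }
  rho_t <- corr_block(it)
  rho_n <- corr_block(in_)

  ok <- !is.na(rho_t) & !is.na(rho_n)
  if (any(!ok)) {
    skipped <- rbind(skipped, data.frame(
      mirna = pairs$mirna[present][!ok], gene = pairs$gene[present][!ok],
      reason = "constant expression within a condition",
      stringsAsFactors = FALSE))
  }
  out <- data.frame(mirna = pairs$mirna[present][ok],
                    gene = pairs$gene[present][ok],
                    rho_tumor = rho_t[ok], rho_normal = rho_n[ok],
                    score = abs(rho_t[ok] - rho_n[ok]),
                    stringsAsFactors = FALSE)
  if (!nrow(out)) stop("no evaluable pair after dropping degenerate ones")
  structure(out, skipped = skipped,
            class = c("DysregulationTable", "data.frame"))
}

#' Permutation p-values for dysregulation scores
#'
#' The tumor/normal partition is permuted jointly for the miRNA and mRNA
#' vectors of each pair (sample identity is preserved, group sizes fixed)
#' and the score recomputed. `p_perm` is the fraction of permutations whose
#' score meets or exceeds the observed one; ties count against the observed
#' score so the p-value stays valid. Per-pair random streams derive from
#' `(seed, pair index)`, so results are reproducible regardless of pair
#' subsetting order.
#'
#' @param records A `DysregulationTable` from [dysregulation_scores()].
#' @param em_mirna,em_gene The expression matrices the records came from.
#' @param groups The same [group_assignment()].
#' @param n_perm Number of label permutations, default 10000.
#' @param seed Integer seed controlling all permutations.
#' @param exhaustive If `TRUE`, enumerate all distinct tumor-subset choices
#'   instead of sampling (only allowed when `choose(n, n_tumor) <= cap`).
#' @param cap Maximum partition count for exhaustive mode, default 10000.
#' @param pseudo If `TRUE`, use the `(count + 1)/(n_perm + 1)` variant that
#'   never returns exactly zero. Default off: the plain fraction.
#' @return `records` with `p_perm` and `n_perm` columns filled in.
#' @export
permutation_pvalues <- function(records, em_mirna, em_gene, groups,
                                n_perm = 10000L, seed = 1L,
                                exhaustive = FALSE, cap = 10000L,
                                pseudo = FALSE) {
  stopifnot(inherits(records, "DysregulationTable"))
  cond <- condition_of(groups, em_mirna)
  cond01 <- as.integer(cond == "tumor")
  mi <- match(records$mirna, feature_ids(em_mirna))
  gi <- match(records$gene, feature_ids(em_gene))
  if (anyNA(mi) || anyNA(gi)) stop("record ids missing from expression matrices")

  if (exhaustive) {
    n <- length(cond01); nt <- sum(cond01)
    n_part <- choose(n, nt)
    if (n_part > cap) {
      stop(sprintf("exhaustive enumeration needs %d partitions (> cap %d)",
                   n_part, cap))
    }
    subsets <- utils::combn(n, nt)
    p <- vapply(seq_along(mi), function(k) {
      x <- em_mirna[mi[k], ]; y <- em_gene[gi[k], ]
      s_obs <- records$score[k]
      s_perm <- apply(subsets, 2L, function(ti) {
        ni <- setdiff(seq_len(n), ti)
        abs(stats::cor(x[ti], y[ti], method = "spearman") -
              stats::cor(x[ni], y[ni], method = "spearman"))
      })
      mean(s_perm >= s_obs)
    }, numeric(1))
    records$p_perm <- p
    records$n_perm <- as.integer(n_part)
    return(records)
  }

  if (n_perm < 1) stop("n_perm must be >= 1")
  res <- cpp_perm_pvalues(em_mirna, em_gene, mi - 1L, gi - 1L, cond01,
                          as.integer(n_perm), as.integer(seed),
                          isTRUE(pseudo))
  if (max(abs(res$score - records$score), na.rm = TRUE) > 1e-8) {
    stop("internal inconsistency: permuted and observed scores disagree")
  }
  records$p_perm <- res$p_perm
  records$n_perm <- as.integer(n_perm)
  records
}

#' Construct a bipartite miRNA-target network
#'
#' @param mirna,gene Character vectors defining directed miRNA -> gene edges.
#' @return Object of class `BipartiteNetwork`: list with `edges` (data frame
#'   `mirna`, `gene`), `mirnas` and `genes` node sets. Duplicate edges are
#'   collapsed; isolated nodes are not representable.
#' @export
bipartite_network <- function(mirna, gene) {
  edges <- unique(data.frame(mirna = as.character(mirna),
                             gene = as.character(gene),
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  both <- intersect(edges$mirna, edges$gene)
  if (length(both)) {
    stop("id(s) on both sides of the bipartite network: ",
         paste(both, collapse = ", "))
  }
  structure(list(edges = edges,
                 mirnas = sort(unique(edges$mirna)),
                 genes = sort(unique(edges$gene))),
            class = "BipartiteNetwork")
}

#' @export
print.BipartiteNetwork <- function(x, ...) {
  cat(sprintf("BipartiteNetwork: %d miRNAs, %d genes, %d edges\n",
              length(x$mirnas), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Build the dysregulated miRNA-target network (DMTN)
#'
#' Retains the edges whose permutation p-value is strictly below `alpha`
#' (raw p-values by default, matching the screen's P < 0.05 rule; set
#' `adjust = TRUE` for a BH-adjusted variant).
#'
#' @param records A `DysregulationTable` with `p_perm` filled in.
#' @param alpha Significance cutoff, default 0.05 (strict `<`).
#' @param adjust Apply Benjamini-Hochberg before thresholding. Default off.
#' @return A [bipartite_network()].
#' @export
build_dmtn <- function(records, alpha = 0.05, adjust = FALSE) {
  if (is.null(records$p_perm)) stop("records carry no p_perm; run permutation_pvalues first")
  p <- records$p_perm
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  keep <- !is.na(p) & p < alpha
  if (!any(keep)) {
    return(structure(list(edges = data.frame(mirna = character(0),
                                             gene = character(0),
                                             stringsAsFactors = FALSE),
                          mirnas = character(0), genes = character(0)),
                     class = "BipartiteNetwork"))
  }
  bipartite_network(records$mirna[keep], records$gene[keep])
}

#' Out-degree distribution of the miRNA side
#'
#' Tabulates how many miRNAs have each out-degree and fits an ordinary
#' least-squares line to `log10(count)` vs `log10(degree)` over non-empty
#' bins — a descriptive check for the heavy-tailed degree profile typical
#' of regulatory networks, not a formal power-law test.
#'
#' @param net A [bipartite_network()].
#' @return List with `histogram` (data frame `degree`, `count`) and `slope`
#'   (`NA` when fewer than two distinct degrees exist).
#' @export
out_degree_distribution <- function(net) {
  stopifnot(inherits(net, "BipartiteNetwork"))
  if (!nrow(net$edges)) stop("empty network")
  deg <- table(net$edges$mirna)
  h <- as.data.frame(table(as.integer(deg)), stringsAsFactors = FALSE)
  names(h) <- c("degree", "count")
  h$degree <- as.integer(h$degree)
  h$count <- as.integer(h$count)
  h <- h[order(h$degree), , drop = FALSE]
  rownames(h) <- NULL
  slope <- NA_real_
  if (nrow(h) >= 2) {
    slope <- unname(stats::coef(stats::lm(log10(h$count) ~ log10(h$degree)))[2L])
  }
  list(histogram = h, slope = slope)
}

.as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = c(net$mirnas, net$genes),
                          side = rep(c("miRNA", "gene"),
                                     c(length(net$mirnas), length(net$genes)))))
}

#' Pairwise shortest-path lengths between miRNA nodes
#'
#' Distances are counted in edges on the undirected view of the bipartite
#' graph, so two miRNAs sharing a target are at distance 2. Unreachable
#' pairs are reported separately, never as a histogram bin.
#'
#' @param net A [bipartite_network()].
#' @return List with `histogram` (data frame `length`, `count` over miRNA
#'   pairs) and `unreachable_pairs` (count of miRNA pairs in different
#'   components).
#' @export
mirna_shortest_paths <- function(net) {
  stopifnot(inherits(net, "BipartiteNetwork"))
  if (length(net$mirnas) < 2) {
    return(list(histogram = data.frame(length = integer(0), count = integer(0)),
                unreachable_pairs = 0L))
  }
  g <- .as_igraph(net)
  d <- igraph::distances(g, v = net$mirnas, to = net$mirnas)
  d <- d[upper.tri(d)]
  finite <- d[is.finite(d)]
  h <- if (length(finite)) {
    tb <- table(as.integer(finite))
    data.frame(length = as.integer(names(tb)), count = as.integer(tb))
  } else {
    data.frame(length = integer(0), count = integer(0))
  }
  list(histogram = h, unreachable_pairs = sum(!is.finite(d)))
}

#' Write a dysregulation edge table to TSV
#' @param records A `DysregulationTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(records, path) {
  write_tsv(as.data.frame(records), path)
}
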