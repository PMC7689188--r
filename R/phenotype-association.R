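#' Read a sample-by-cell-type immune abundance table
#'
#' Rows are samples, columns cell types (deconvolution output consumed as
#' input). If `fractional = TRUE`, each row must sum to 1 within 1e-6.
#'
#' @param path Path to the TSV file (first column = sample ids).
#' @param fractional Enforce rows summing to one. Default `TRUE`.
#' @return Numeric matrix samples x cell types.
#' @export
read_abundance <- function(path, fractional = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  abundance_matrix(m, fractional = fractional)
}

#' Validate an abundance matrix
#' @param m Numeric matrix, samples x cell types, values >= 0.
#' @param fractional Enforce unit row sums (tolerance 1e-6). Default `TRUE`.
#' @return The validated matrix.
#' @export
abundance_matrix <- function(m, fractional = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("abundance must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) stop("abundance needs sample and cell-type names")
  if (any(m < 0)) stop("abundances must be non-negative")
  if (fractional && any(abs(rowSums(m) - 1) > 1e-6)) {
    stop("abundance rows must sum to 1 (declared fractional)")
  }
  m
}

#' Read a cell-line-by-drug IC50 matrix (empty cell = missing)
#'
#' Values are assumed already log-transformed IC50s; lower means more
#' sensitive.
#'
#' @param path Path to the TSV file (first column = cell-line ids).
#' @return Numeric matrix cell lines x drugs, `NA` for missing entries.
#' @export
read_drug_response <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}

# shared correlation screen over all (feature, phenotype-column) pairs
.correlation_screen <- function(em, pheno, method, r_min, alpha, min_n) {
  shared <- intersect(sample_ids(em), rownames(pheno))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  X <- em[, shared, drop = FALSE]
  P <- pheno[shared, , drop = FALSE]
  rows <- list()
  skipped <- list()
  for (f in rownames(X)) {
    xv <- X[f, ]
    for (ph in colnames(P)) {
      yv <- P[, ph]
      ok <- !is.na(xv) & !is.na(yv)
      n <- sum(ok)
      key <- paste(f, ph, sep = "\r")
      if (n < min_n) { skipped[[key]] <- "too few paired observations"; next }
      if (stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0) {
        skipped[[key]] <- "constant values"; next
      }
      ct <- suppressWarnings(stats::cor.test(xv[ok], yv[ok], method = method,
                                             exact = FALSE))
      rows[[key]] <- data.frame(feature = f, phenotype = ph, method = method,
                                n = n, r = unname(ct$estimate), p = ct$p.value,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable (feature, phenotype) pair")
  out$q <- bh_adjust(out$p)
  out$significant <- abs(out$r) >= r_min & out$q < alpha
  rownames(out) <- NULL
  sk <- data.frame(pair = names(skipped),
                   reason = unlist(skipped, use.names = FALSE),
                   stringsAsFactors = FALSE)
  structure(out, skipped = sk, class = c("AssociationTable", "data.frame"))
}

#' Immune-infiltration association screen
#'
#' Spearman correlation between each feature's expression and each immune
#' cell type's abundance across shared samples, with BH adjustment across
#' the whole screen. Constant abundance columns are skipped with a reason.
#'
#' @param em An [expression_matrix()].
#' @param abundance Samples x cell types matrix (see [abundance_matrix()]).
#' @param r_min Minimum absolute correlation for the `significant` flag,
#'   default 0 (no magnitude filter for the immune screen).
#' @param alpha FDR level, default 0.05.
#' @param method Correlation flavor, default `"spearman"`.
#' @return Data frame of class `AssociationTable`: `feature`, `phenotype`,
#'   `method`, `n`, `r`, `p`, `q`, `significant`.
#' @export
immune_associations <- function(em, abundance, r_min = 0, alpha = 0.05,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  .correlation_screen(em, abundance, method = method, r_min = r_min,
                      alpha = alpha, min_n = 3L)
}

#' Drug-response association screen
#'
#' Pearson correlation (per the GDSC-style convention of log-IC50 values)
#' between each feature's expression and each drug's IC50 across shared
#' cell lines, pairwise-complete with a minimum-n guard. A pair is flagged
#' significant when `|r| >= r_min` (the threshold is inclusive) and the BH
#' q-value is below `alpha`. Negative `r` means high expression tracks
#' lower IC50, i.e. more sensitive lines.
#'
#' @param em An [expression_matrix()] over cell lines.
#' @param drugs Cell lines x drugs IC50 matrix, `NA` = missing.
#' @param method Correlation flavor, default `"pearson"`.
#' @param r_min Absolute-correlation threshold, default 0.2.
#' @param alpha FDR level, default 0.05.
#' @param min_n Minimum paired observations per (feature, drug), default 20.
#' @return Data frame of class `AssociationTable` (see
#'   [immune_associations()]); skipped pairs in the `skipped` attribute.
#' @export
drug_associations <- function(em, drugs, method = c("pearson", "spearman"),
                              r_min = 0.2, alpha = 0.05, min_n = 20L) {
  method <- match.arg(method)
  .correlation_screen(em, drugs, method = method, r_min = r_min,
                      alpha = alpha, min_n = min_n)
}

#' Summary of an association screen
#'
#' Counts significant pairs and the share with positive correlation — the
#' headline consistency number of a drug screen.
#'
#' @param assoc An `AssociationTable`.
#' @return List `n_tested`, `n_significant`, `n_positive`,
#'   `positive_percent` (0-100, among significant pairs).
#' @export
summarize_associations <- function(assoc) {
  sig <- assoc[assoc$significant, , drop = FALSE]
  n_pos <- sum(sig$r > 0)
  list(n_tested = nrow(assoc),
       n_significant = nrow(sig),
       n_positive = n_pos,
       positive_percent = if (nrow(sig)) 100 * n_pos / nrow(sig) else NA_real_)
}

#' High-vs-low group comparison of a phenotype
#'
#' Two-sided Wilcoxon rank-sum test of `values` between two groups (for
#' panel-style comparisons of, e.g., immune abundance or IC50 between
#' median-split expression groups).
#'
#' @param values Numeric phenotype values.
#' @param groups Two-level grouping (character/factor/logical) aligned with
#'   `values`; both groups need >= 3 observations.
#' @return List `statistic` (rank-sum W), `p`.
#' @export
group_compare <- function(values, groups) {
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("groups must have exactly two levels")
  if (min(table(g)) < 3) stop("degenerate group: fewer than 3 observations")
  wt <- suppressWarnings(stats::wilcox.test(values[g == levels(g)[1L]],
                                            values[g == levels(g)[2L]],
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
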