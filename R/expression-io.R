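#' Construct an expression matrix
#'
#' A validated features-by-samples table of non-negative normalized
#' expression values with a feature-kind tag (`"miRNA"` or `"mRNA"`).
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row names are feature ids, column names sample ids; both must be
#'   unique and non-empty.
#' @param kind Feature kind, `"miRNA"` or `"mRNA"`.
#' @return An object of class `ExpressionMatrix`: the matrix with a
#'   `kind` attribute.
#' @export
expression_matrix <- function(values, kind = c("miRNA", "mRNA")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("`values` must have row names (features) and column names (samples)")
  }
  if (anyDuplicated(fid)) {
    stop("duplicate feature ids: ", paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (any(!nzchar(fid)) || any(!nzchar(sid))) stop("empty feature or sample id")
  if (anyNA(values)) stop("missing values in expression matrix")
  if (any(values < 0)) stop("negative expression values are not allowed")
  structure(values, kind = kind, class = c("ExpressionMatrix", "matrix", "array"))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s): %d features x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

feature_ids <- function(em) rownames(em)
sample_ids <- function(em) colnames(em)
feature_kind <- function(em) attr(em, "kind")

#' Read an expression table from TSV
#'
#' Expects a tab-delimited UTF-8 file whose header row holds sample ids and
#' whose first column holds feature ids. Duplicated ids and negative or
#' non-numeric cells are errors, never silently repaired.
#'
#' @param path Path to the TSV file.
#' @param kind Feature kind tag, `"miRNA"` or `"mRNA"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, kind = c("miRNA", "mRNA")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a feature-id column plus samples: ", path)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  num <- vapply(body, is.numeric, logical(1L))
  if (!all(num)) {
    stop("non-numeric expression column(s): ", paste(names(body)[!num], collapse = ", "))
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  expression_matrix(m, kind = kind)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: first column `feature`, remaining columns
#' one per sample. Full double precision is kept so a round-trip is
#' bit-faithful.
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(feature = rownames(em), em, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

# shared TSV writer: tab-separated, no quoting, full precision
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA_character_, formatC(v, digits = 17, format = "g"))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Construct a sample-to-condition assignment
#'
#' @param sample Character vector of sample ids.
#' @param condition Character vector, `"tumor"` or `"normal"`, one per sample.
#' @return A data frame of class `GroupAssignment` with columns `sample` and
#'   `condition`.
#' @export
group_assignment <- function(sample, condition) {
  sample <- as.character(sample)
  condition <- as.character(condition)
  if (length(sample) != length(condition)) stop("sample/condition length mismatch")
  if (anyDuplicated(sample)) stop("duplicate sample ids in group assignment")
  bad <- setdiff(unique(condition), c("tumor", "normal"))
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  structure(data.frame(sample = sample, condition = condition,
                       stringsAsFactors = FALSE),
            class = c("GroupAssignment", "data.frame"))
}

#' Read a sample-condition table (columns `sample`, `condition`) from TSV
#' @param path Path to the TSV file.
#' @return A [group_assignment()].
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df))) {
    stop("group TSV must have columns `sample` and `condition`")
  }
  group_assignment(df$sample, df$condition)
}

# named condition vector for the samples of `em`; errors on missing samples
condition_of <- function(groups, em) {
  idx <- match(sample_ids(em), groups$sample)
  if (anyNA(idx)) {
    stop("samples without condition label: ",
         paste(sample_ids(em)[is.na(idx)], collapse = ", "))
  }
  stats::setNames(groups$condition[idx], sample_ids(em))
}

#' Construct a candidate miRNA-mRNA pair list
#'
#' Pairs are de-duplicated; an optional non-negative `support` count (e.g.
#' number of CLIP experiments backing the interaction) is carried along.
#'
#' @param mirna,gene Character vectors of equal length.
#' @param support Optional integer vector of support counts.
#' @return Data frame of class `CandidatePairList` with columns `mirna`,
#'   `gene` and (optionally) `support`.
#' @export
candidate_pairs <- function(mirna, gene, support = NULL) {
  mirna <- as.character(mirna)
  gene <- as.character(gene)
  if (length(mirna) != length(gene)) stop("mirna/gene length mismatch")
  if (any(!nzchar(mirna)) || any(!nzchar(gene))) stop("empty id in pair list")
  df <- data.frame(mirna = mirna, gene = gene, stringsAsFactors = FALSE)
  if (!is.null(support)) {
    support <- as.integer(support)
    if (any(is.na(support)) || any(support < 0)) stop("support must be integer >= 0")
    df$support <- support
  }
  df <- df[!duplicated(df[c("mirna", "gene")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("CandidatePairList", "data.frame"))
}

#' Read a candidate pair list (columns `miRNA`, `gene`, optional `support`)
#' @param path Path to the TSV file.
#' @return A [candidate_pairs()] list.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  mcol <- intersect(c("mirna", "mir"), names(df))[1L]
  if (is.na(mcol) || !"gene" %in% names(df)) {
    stop("pair TSV must have columns `miRNA` and `gene`")
  }
  candidate_pairs(df[[mcol]], df$gene,
                  support = if ("support" %in% names(df)) df$support)
}

#' Remove features with too many zeros in normal samples
#'
#' Drops every feature whose fraction of exactly-zero values among normal
#' samples exceeds `max_zero_frac` (strict: a feature at exactly the
#' threshold is kept). Tumor samples never influence the decision unless
#' `scope = "all"`.
#'
#' @param em An [expression_matrix()].
#' @param groups A [group_assignment()] covering the samples of `em`.
#' @param max_zero_frac Maximum tolerated zero fraction, default 0.10.
#' @param scope Which samples the zero fraction is computed on: `"normal"`
#'   (default) or `"all"`.
#' @return The filtered `ExpressionMatrix`; feature order preserved.
#' @export
filter_zero_fraction <- function(em, groups, max_zero_frac = 0.10,
                                 scope = c("normal", "all")) {
  scope <- match.arg(scope)
  cond <- condition_of(groups, em)
  use <- if (scope == "normal") cond == "normal" else rep(TRUE, length(cond))
  if (!any(use)) stop("no normal samples to filter on")
  zero_frac <- rowMeans(em[, use, drop = FALSE] == 0)
  keep <- zero_frac <= max_zero_frac
  expression_matrix(em[keep, , drop = FALSE], kind = feature_kind(em))
}
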