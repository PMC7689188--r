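#' True-positive miRNA set from curated disease lists
#'
#' Merges one or more curated miRNA lists (union, de-duplicated) and keeps
#' only miRNAs present in the network, i.e. candidates the classifier can
#' actually score.
#'
#' @param curated_lists A list of character vectors of miRNA ids.
#' @param net A [bipartite_network()].
#' @return Character vector of TP miRNA ids (sorted).
#' @export
select_true_positives <- function(curated_lists, net) {
  if (!is.list(curated_lists)) curated_lists <- list(curated_lists)
  if (!length(curated_lists) || any(!lengths(curated_lists))) {
    stop("curated lists must be non-empty")
  }
  merged <- unique(unlist(curated_lists, use.names = FALSE))
  tp <- sort(intersect(merged, net$mirnas))
  if (!length(tp)) warning("no curated miRNA found in the network; training will be impossible")
  tp
}

#' Rank-sum selection of true-negative candidates
#'
#' For each of three sample sets (all samples, tumor only, normal only) the
#' miRNAs are ranked by mean expression and by variance across samples
#' (rank 1 = smallest). The sum of the six ranks orders the miRNAs; the `k`
#' with the smallest sums — consistently low and flat, hence presumed
#' functionless — are returned. Ties are broken lexicographically by id.
#'
#' @param em_mirna An [expression_matrix()] of miRNAs.
#' @param groups A [group_assignment()]; both conditions must be present.
#' @param k Number of candidates, default 95.
#' @return Character vector of `k` miRNA ids, in increasing rank-sum order.
#' @export
rank_sum_negatives <- function(em_mirna, groups, k = 95L) {
  if (k > nrow(em_mirna)) stop("k exceeds the number of miRNAs")
  cond <- condition_of(groups, em_mirna)
  if (!any(cond == "tumor") || !any(cond == "normal")) {
    stop("both conditions must be present")
  }
  sets <- list(all = rep(TRUE, length(cond)),
               tumor = cond == "tumor",
               normal = cond == "normal")
  rank_sum <- numeric(nrow(em_mirna))
  for (s in sets) {
    sub <- em_mirna[, s, drop = FALSE]
    rank_sum <- rank_sum + rank(rowMeans(sub), ties.method = "average") +
      rank(apply(sub, 1L, stats::var), ties.method = "average")
  }
  ids <- feature_ids(em_mirna)
  ord <- order(rank_sum, ids)
  ids[ord][seq_len(k)]
}

#' Finalize the true-negative set
#'
#' Removes candidates that are in the TP set and those absent from the
#' network; candidate order is preserved.
#'
#' @param candidates Ordered candidate ids (from [rank_sum_negatives()]).
#' @param tp TP miRNA ids.
#' @param net A [bipartite_network()].
#' @return Character vector of TN miRNA ids.
#' @export
finalize_negatives <- function(candidates, tp, net) {
  tn <- candidates[!(candidates %in% tp) & candidates %in% net$mirnas]
  if (!length(tn)) warning("empty TN set; training will be impossible")
  tn
}

#' TP/TN label sets
#' @param tp,tn Disjoint character vectors of miRNA ids.
#' @return List of class `LabelSets`.
#' @export
label_sets <- function(tp, tn) {
  tp <- unique(as.character(tp)); tn <- unique(as.character(tn))
  if (length(intersect(tp, tn))) stop("TP and TN sets overlap")
  structure(list(tp = tp, tn = tn), class = "LabelSets")
}

#' Five per-miRNA network/expression features
#'
#' For every miRNA node of the network: out-degree; number of co-regulating
#' miRNAs (others sharing at least one target); percentage of those
#' co-regulators that are disease miRNAs (0 when there are none); number of
#' its targets also targeted by at least one disease miRNA other than
#' itself; and log2 fold change of mean tumor vs mean normal expression
#' with a pseudo-count.
#'
#' @param net A [bipartite_network()].
#' @param em_mirna Expression of (at least) all network miRNAs.
#' @param groups A [group_assignment()].
#' @param disease_set Character vector of known disease miRNA ids.
#' @param pseudocount Added to both means before the ratio, default 1.
#' @return Data frame of class `FeatureTable`: `mirna`, `out_degree`,
#'   `n_coreg`, `pct_coreg_disease`, `n_genes_disease_reg`, `log2_fc`.
#' @export
compute_features <- function(net, em_mirna, groups, disease_set,
                             pseudocount = 1.0) {
  miss <- setdiff(net$mirnas, feature_ids(em_mirna))
  if (length(miss)) {
    stop("network miRNA(s) missing from expression: ", paste(miss, collapse = ", "))
  }
  cond <- condition_of(groups, em_mirna)
  targets <- split(net$edges$gene, net$edges$mirna)
  regulators <- split(net$edges$mirna, net$edges$gene)
  disease_set <- unique(as.character(disease_set))

  rows <- lapply(net$mirnas, function(m) {
    tg <- targets[[m]]
    coreg <- setdiff(unique(unlist(regulators[tg], use.names = FALSE)), m)
    n_coreg <- length(coreg)
    pct <- if (n_coreg) length(intersect(coreg, disease_set)) / n_coreg else 0
    dis_reg <- vapply(tg, function(g) {
      length(intersect(setdiff(regulators[[g]], m), disease_set)) > 0
    }, logical(1))
    mu_t <- mean(em_mirna[m, cond == "tumor"])
    mu_n <- mean(em_mirna[m, cond == "normal"])
    data.frame(mirna = m, out_degree = length(tg), n_coreg = n_coreg,
               pct_coreg_disease = pct, n_genes_disease_reg = sum(dis_reg),
               log2_fc = log2((mu_t + pseudocount) / (mu_n + pseudocount)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("FeatureTable", "data.frame"))
}

#' Area under the ROC curve
#'
#' Rank formulation: the Mann-Whitney U statistic normalized by the number
#' of positive-negative pairs; ties contribute 1/2.
#'
#' @param scores Numeric scores, larger = more positive-like.
#' @param labels Logical (or 0/1) vector, `TRUE` = positive.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Genetic-algorithm settings for SVM hyperparameter search
#'
#' Real-coded genome over `log10(cost)` and `log10(gamma)` of the RBF
#' kernel; tournament selection, uniform crossover, Gaussian mutation,
#' elitism.
#'
#' @param pop Population size, default 20.
#' @param generations Generations, default 15.
#' @param tournament Tournament size, default 3.
#' @param p_cross Per-gene crossover probability, default 0.5.
#' @param sigma_mut Mutation standard deviation (log10 units), default 0.3.
#' @param elitism Elites carried over unchanged, default 2.
#' @param cost_range,gamma_range `log10` search ranges.
#' @return List of class `GAConfig`.
#' @export
ga_config <- function(pop = 20L, generations = 15L, tournament = 3L,
                      p_cross = 0.5, sigma_mut = 0.3, elitism = 2L,
                      cost_range = c(-2, 3), gamma_range = c(-3, 1)) {
  stopifnot(pop > elitism, generations >= 1, tournament >= 1)
  structure(list(pop = as.integer(pop), generations = as.integer(generations),
                 tournament = as.integer(tournament), p_cross = p_cross,
                 sigma_mut = sigma_mut, elitism = as.integer(elitism),
                 cost_range = cost_range, gamma_range = gamma_range),
            class = "GAConfig")
}

# feature matrix (rows = labeled miRNAs) and 0/1 response from a FeatureTable
.feature_matrix <- function(features, ids) {
  idx <- match(ids, features$mirna)
  if (anyNA(idx)) {
    stop("miRNA(s) missing from the feature table: ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  m <- as.matrix(features[idx, c("out_degree", "n_coreg", "pct_coreg_disease",
                                 "n_genes_disease_reg", "log2_fc")])
  rownames(m) <- ids
  m
}

# z-score columns with given (or own) center/scale; constant columns scale 1
.standardize <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0] <- 1
  }
  list(X = sweep(sweep(X, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

# oriented decision values of an e1071 svm fit: larger = more TP-like
.decision_values <- function(fit, X, y_train = NULL, X_train = NULL) {
  dv <- attr(stats::predict(fit, X, decision.values = TRUE), "decision.values")[, 1L]
  if (!is.null(y_train)) {
    dv_tr <- attr(stats::predict(fit, X_train, decision.values = TRUE),
                  "decision.values")[, 1L]
    if (evaluate_auc(dv_tr, y_train == "TP") < 0.5) dv <- -dv
  }
  dv
}

# stratified fold assignment, reproducible under the current RNG state
.stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

# mean cross-validated AUC (and per-fold values) for one (cost, gamma);
# standardization is fit on the training folds only
.cv_auc <- function(X, y, fold, log10_cost, log10_gamma, kernel) {
  folds <- max(fold)
  auc <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- fold != k
    st <- .standardize(X[tr, , drop = FALSE])
    Xte <- .standardize(X[!tr, , drop = FALSE], st$center, st$scale)$X
    fit <- e1071::svm(st$X, factor(y[tr], levels = c("TN", "TP")),
                      kernel = kernel, cost = 10^log10_cost,
                      gamma = 10^log10_gamma, scale = FALSE)
    dv <- .decision_values(fit, Xte, y_train = y[tr], X_train = st$X)
    auc[k] <- evaluate_auc(dv, y[!tr] == "TP")
  }
  auc
}

#' Train the risk-miRNA SVM with GA-tuned hyperparameters
#'
#' Fits an RBF-kernel SVM on the five features of the TP/TN miRNAs. A
#' real-coded genetic algorithm searches `(log10 cost, log10 gamma)`
#' maximizing the mean stratified `folds`-fold cross-validated AUC;
#' features are z-scored inside each training fold only. Scores are mapped
#' to `[0, 1]` by a Platt-style sigmoid fitted on the out-of-fold decision
#' values of the winning hyperparameters, then the model is refit on all
#' labeled data. Fully deterministic given `seed`.
#'
#' @param features A [compute_features()] table covering all labeled miRNAs.
#' @param labels A [label_sets()] object; both sets need at least `folds`
#'   members.
#' @param folds Cross-validation folds, default 5.
#' @param ga A [ga_config()].
#' @param seed Integer seed for fold assignment and the GA.
#' @param search `"ga"` (default) or `"grid"` (a coarse 3x3 log-grid over
#'   the same ranges, as a baseline).
#' @param kernel SVM kernel, default `"radial"`; `"linear"` available.
#' @return Object of class `RiskClassifier`: the fitted svm, feature
#'   standardization, Platt coefficients, chosen hyperparameters, per-fold
#'   AUCs and `cv_auc`.
#' @export
train_classifier <- function(features, labels, folds = 5L, ga = ga_config(),
                             seed = 1L, search = c("ga", "grid"),
                             kernel = c("radial", "linear")) {
  search <- match.arg(search)
  kernel <- match.arg(kernel)
  stopifnot(inherits(labels, "LabelSets"))
  if (!length(labels$tp) || !length(labels$tn)) stop("single class: need both TP and TN")
  if (folds < 2) stop("folds must be >= 2")
  if (length(labels$tp) < folds || length(labels$tn) < folds) {
    stop("each class needs at least `folds` members")
  }
  ids <- c(labels$tp, labels$tn)
  y <- rep(c("TP", "TN"), c(length(labels$tp), length(labels$tn)))
  X <- .feature_matrix(features, ids)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- .stratified_folds(y, folds)

  fitness <- function(g) mean(.cv_auc(X, y, fold, g[1L], g[2L], kernel))
  lo <- c(ga$cost_range[1L], ga$gamma_range[1L])
  hi <- c(ga$cost_range[2L], ga$gamma_range[2L])

  if (search == "grid") {
    grid <- expand.grid(c = seq(lo[1L], hi[1L], length.out = 3),
                        g = seq(lo[2L], hi[2L], length.out = 3))
    fit_vals <- apply(grid, 1L, fitness)
    best <- as.numeric(grid[which.max(fit_vals), ])
  } else {
    pop <- cbind(stats::runif(ga$pop, lo[1L], hi[1L]),
                 stats::runif(ga$pop, lo[2L], hi[2L]))
    fit_vals <- apply(pop, 1L, fitness)
    for (gen in seq_len(ga$generations)) {
      ord <- order(fit_vals, decreasing = TRUE)
      new_pop <- pop[ord[seq_len(ga$elitism)], , drop = FALSE]
      while (nrow(new_pop) < ga$pop) {
        pick <- function() {
          cand <- sample.int(ga$pop, ga$tournament, replace = TRUE)
          pop[cand[which.max(fit_vals[cand])], ]
        }
        p1 <- pick(); p2 <- pick()
        use1 <- stats::runif(2) < ga$p_cross
        child <- ifelse(use1, p1, p2) + stats::rnorm(2, 0, ga$sigma_mut)
        child <- pmin(pmax(child, lo), hi)
        new_pop <- rbind(new_pop, child)
      }
      pop <- new_pop
      fit_vals <- apply(pop, 1L, fitness)
    }
    best <- pop[which.max(fit_vals), ]
  }

  fold_auc <- .cv_auc(X, y, fold, best[1L], best[2L], kernel)

  # out-of-fold decision values of the winning genome -> Platt sigmoid
  oof <- numeric(length(y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    st <- .standardize(X[tr, , drop = FALSE])
    Xte <- .standardize(X[!tr, , drop = FALSE], st$center, st$scale)$X
    fit_k <- e1071::svm(st$X, factor(y[tr], levels = c("TN", "TP")),
                        kernel = kernel, cost = 10^best[1L],
                        gamma = 10^best[2L], scale = FALSE)
    oof[!tr] <- .decision_values(fit_k, Xte, y_train = y[tr], X_train = st$X)
  }
  platt <- suppressWarnings(
    stats::glm((y == "TP") ~ oof, family = stats::binomial()))
  platt_ab <- unname(stats::coef(platt))

  st <- .standardize(X)
  fit <- e1071::svm(st$X, factor(y, levels = c("TN", "TP")), kernel = kernel,
                    cost = 10^best[1L], gamma = 10^best[2L], scale = FALSE)
  dv_tr <- attr(stats::predict(fit, st$X, decision.values = TRUE),
                "decision.values")[, 1L]
  flip <- evaluate_auc(dv_tr, y == "TP") < 0.5

  structure(list(svm = fit, center = st$center, scale = st$scale,
                 platt = platt_ab, flip = flip,
                 log10_cost = unname(best[1L]), log10_gamma = unname(best[2L]),
                 kernel = kernel, fold_auc = fold_auc,
                 cv_auc = mean(fold_auc), folds = folds, seed = seed,
                 feature_names = colnames(X), train_ids = ids, train_y = y),
            class = "RiskClassifier")
}

# RNG bookkeeping so training does not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.RiskClassifier <- function(x, ...) {
  cat(sprintf("RiskClassifier: %s SVM, cost 10^%.2f, gamma 10^%.2f, cv AUC %.3f\n",
              x$kernel, x$log10_cost, x$log10_gamma, x$cv_auc))
  invisible(x)
}

#' Probability-like risk scores for a feature table
#'
#' @param model A [train_classifier()] fit.
#' @param features A `FeatureTable` (any set of miRNAs).
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
risk_scores <- function(model, features) {
  stopifnot(inherits(model, "RiskClassifier"))
  X <- .feature_matrix(features, features$mirna)
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature names do not match the training features")
  }
  Xs <- .standardize(X, model$center, model$scale)$X
  dv <- attr(stats::predict(model$svm, Xs, decision.values = TRUE),
             "decision.values")[, 1L]
  if (model$flip) dv <- -dv
  stats::setNames(stats::plogis(model$platt[1L] + model$platt[2L] * dv),
                  features$mirna)
}

#' Recognition threshold: the smallest cutoff calling no TN positive
#'
#' The maximum score the model assigns to any TN example, nudged up by one
#' representable increment; predicting risk with `score > threshold` is
#' then guaranteed to label zero TN miRNAs positive.
#'
#' @param model A [train_classifier()] fit.
#' @param tn_features `FeatureTable` rows of the TN miRNAs.
#' @return Threshold in `[0, 1]`.
#' @export
recognition_threshold <- function(model, tn_features) {
  if (!nrow(tn_features)) stop("tn_features must be non-empty")
  s <- risk_scores(model, tn_features)
  cpp_nextafter(max(s))
}

#' Predict risk miRNAs
#'
#' @param model A [train_classifier()] fit.
#' @param features `FeatureTable` of the miRNAs to score.
#' @param threshold Score cutoff; a miRNA is called risk iff
#'   `score > threshold`.
#' @return Data frame `mirna`, `score`, `risk`, sorted by descending score.
#' @export
predict_risk <- function(model, features, threshold) {
  s <- risk_scores(model, features)
  out <- data.frame(mirna = names(s), score = unname(s),
                    risk = unname(s) > threshold, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
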