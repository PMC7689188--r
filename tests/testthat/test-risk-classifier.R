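test_that("TP selection is union-then-network set algebra", {
  net <- bipartite_network(c("B", "C", "D"), c("g1", "g2", "g3"))
  expect_setequal(select_true_positives(list(c("A", "B"), c("B", "C")), net),
                  c("B", "C"))
  expect_warning(tp <- select_true_positives(list("Z"), net), "no curated")
  expect_length(tp, 0)
  # seeded oracle
  set.seed(13)
  for (rep in 1:10) {
    l1 <- sample(LETTERS, 8); l2 <- sample(LETTERS, 8)
    netm <- sample(LETTERS, 12)
    net2 <- bipartite_network(netm, paste0("g", seq_along(netm)))
    got <- select_true_positives(list(l1, l2), net2)
    expect_setequal(got, intersect(union(l1, l2), netm))
  }
})

test_that("rank-sum negative selection matches a hand ranking", {
  # 6 miRNAs x 8 samples with hand-computable means and variances
  vals <- rbind(
    low1 = rep(1, 8) + c(0, 0.1, 0, 0.1, 0, 0.1, 0, 0.1),
    low2 = rep(2, 8) + c(0, 0.2, 0, 0.2, 0, 0.2, 0, 0.2),
    mid = rep(5, 8) + c(0, 1, 0, 1, 0, 1, 0, 1),
    hi1 = rep(9, 8) + c(0, 2, 0, 2, 0, 2, 0, 2),
    hi2 = rep(12, 8) + c(0, 3, 0, 3, 0, 3, 0, 3),
    hi3 = rep(15, 8) + c(0, 4, 0, 4, 0, 4, 0, 4))
  colnames(vals) <- sprintf("s%d", 1:8)
  em <- expression_matrix(vals, "miRNA")
  groups <- group_assignment(colnames(vals), rep(c("tumor", "normal"), each = 4))
  # low1 dominates every ranking; low2 is second everywhere
  expect_equal(rank_sum_negatives(em, groups, k = 2), c("low1", "low2"))
  expect_true("low1" %in% rank_sum_negatives(em, groups, k = 1))

  # all-identical rows: selection is the k lexicographically smallest ids
  flat <- matrix(1, 4, 8, dimnames = list(c("d", "b", "a", "c"), colnames(vals)))
  em2 <- expression_matrix(flat, "miRNA")
  expect_equal(rank_sum_negatives(em2, groups, k = 2), c("a", "b"))
  expect_error(rank_sum_negatives(em2, groups, k = 10), "exceeds")
})

test_that("negative finalization removes TP and off-network candidates", {
  net <- bipartite_network(c("A", "C", "D"), c("g1", "g2", "g3"))
  expect_equal(finalize_negatives(c("A", "B", "C"), tp = "B", net), c("A", "C"))
  expect_warning(out <- finalize_negatives(c("A", "C"), tp = c("A", "C"), net),
                 "empty TN")
  expect_length(out, 0)
})

test_that("the five features match a hand trace of the toy graph", {
  net <- bipartite_network(c("m1", "m2", "m3"), c("g1", "g1", "g2"))
  vals <- rbind(m1 = c(3, 3, 1, 1), m2 = c(2, 2, 2, 2), m3 = c(0, 0, 4, 4))
  colnames(vals) <- sprintf("s%d", 1:4)
  em <- expression_matrix(vals, "miRNA")
  groups <- group_assignment(colnames(vals), c("tumor", "tumor", "normal", "normal"))
  f <- compute_features(net, em, groups, disease_set = "m2")
  m1 <- f[f$mirna == "m1", ]
  expect_equal(m1$out_degree, 1L)
  expect_equal(m1$n_coreg, 1L)              # m2 shares g1
  expect_equal(m1$pct_coreg_disease, 1.0)
  expect_equal(m1$n_genes_disease_reg, 1L)  # g1 also hit by disease miRNA m2
  expect_equal(m1$log2_fc, log2((3 + 1) / (1 + 1)))
  # isolated-in-projection miRNA
  m3 <- f[f$mirna == "m3", ]
  expect_equal(m3$n_coreg, 0L)
  expect_equal(m3$pct_coreg_disease, 0)
  expect_equal(m3$n_genes_disease_reg, 0L)
  # equal means -> zero fold change
  expect_equal(f[f$mirna == "m2", "log2_fc"], 0)
  expect_error(compute_features(net, expression_matrix(vals[1:2, ], "miRNA"),
                                groups, "m2"), "missing from expression")
})

test_that("n_genes_disease_reg never exceeds out_degree on random graphs", {
  set.seed(14)
  for (rep in 1:100) {
    ne <- sample(5:40, 1)
    mir <- sprintf("m%02d", sample.int(12, ne, TRUE))
    gen <- sprintf("g%02d", sample.int(15, ne, TRUE))
    net <- bipartite_network(mir, gen)
    n <- 6
    vals <- matrix(exp(rnorm(length(net$mirnas) * n)), length(net$mirnas), n,
                   dimnames = list(net$mirnas, sprintf("s%d", 1:n)))
    em <- expression_matrix(vals, "miRNA")
    groups <- group_assignment(colnames(vals), rep(c("tumor", "normal"), each = 3))
    disease <- sample(net$mirnas, min(3, length(net$mirnas)))
    f <- compute_features(net, em, groups, disease)
    expect_true(all(f$n_genes_disease_reg <= f$out_degree))
    expect_true(all(f$pct_coreg_disease[f$n_coreg == 0] == 0))
  }
})

test_that("AUC follows the rank formulation with tie handling", {
  expect_equal(evaluate_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(evaluate_auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  # 4 pairs, 3 concordant, 1 discordant -> 0.75
  expect_equal(evaluate_auc(c(0.9, 0.2, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_error(evaluate_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # complement symmetry
  set.seed(15)
  s <- rnorm(40); l <- runif(40) > 0.5; l[1:2] <- c(TRUE, FALSE)
  expect_equal(evaluate_auc(s, l), 1 - evaluate_auc(-s, l), tolerance = 1e-12)
  # independent oracle
  skip_if_not_installed("pROC")
  expect_equal(evaluate_auc(s, l),
               as.numeric(suppressMessages(pROC::auc(pROC::roc(l, s)))),
               tolerance = 1e-12)
})

test_that("training separates well-separated Gaussian clusters and is deterministic", {
  set.seed(16)
  n <- 50
  pos <- matrix(rnorm(5 * n, 3, 1), n, 5)
  neg <- matrix(rnorm(5 * n, -3, 1), n, 5)
  ids <- sprintf("m%03d", 1:(2 * n))
  feats <- structure(data.frame(
    mirna = ids,
    out_degree = c(pos[, 1], neg[, 1]), n_coreg = c(pos[, 2], neg[, 2]),
    pct_coreg_disease = c(pos[, 3], neg[, 3]),
    n_genes_disease_reg = c(pos[, 4], neg[, 4]),
    log2_fc = c(pos[, 5], neg[, 5]), stringsAsFactors = FALSE),
    class = c("FeatureTable", "data.frame"))
  labels <- label_sets(ids[1:n], ids[(n + 1):(2 * n)])
  ga <- ga_config(pop = 8, generations = 3)
  m1 <- train_classifier(feats, labels, ga = ga, seed = 5)
  expect_gte(m1$cv_auc, 0.95)
  m2 <- train_classifier(feats, labels, ga = ga, seed = 5)
  expect_identical(m1$log10_cost, m2$log10_cost)
  expect_identical(m1$log10_gamma, m2$log10_gamma)
  expect_identical(m1$cv_auc, m2$cv_auc)

  expect_error(train_classifier(feats, label_sets(ids[1:n], character(0))),
               "single class")
})

test_that("the recognition threshold admits no TN positive by construction", {
  run <- classifier_run()
  tn_scores <- risk_scores(run$model, run$feats[run$feats$mirna %in% run$tn, ])
  expect_true(all(tn_scores <= run$threshold))
  expect_gt(run$threshold, max(tn_scores) - 1e-12)
  pred_tn <- run$pred[run$pred$mirna %in% run$tn, ]
  expect_false(any(pred_tn$risk))
  # property over random score draws: no TN at or above its nudged max
  set.seed(17)
  for (rep in 1:100) {
    s <- runif(sample(3:30, 1))
    thr <- max(s)
    expect_false(any(s > thr))
  }
})

test_that("prediction respects threshold extremes and ordering", {
  run <- classifier_run()
  all_pred <- predict_risk(run$model, run$feats, threshold = 0)
  none_pred <- predict_risk(run$model, run$feats, threshold = 1)
  expect_false(any(none_pred$risk))
  expect_true(all(all_pred$risk[all_pred$score > 0]))
  expect_true(!is.unsorted(rev(all_pred$score)))
})

test_that("the planted risk scenario is recovered end to end", {
  run <- classifier_run()
  expect_gte(run$model$cv_auc, 0.9)
  risk_called <- run$pred$mirna[run$pred$risk]
  expect_gte(mean(run$risk$expected_tp %in% risk_called), 0.8)
  expect_equal(sum(run$tn %in% risk_called), 0L)
})

test_that("GA matches or beats a coarse grid search", {
  run <- classifier_run()
  grid <- train_classifier(run$feats, label_sets(run$tp, run$tn),
                           seed = 42L, search = "grid")
  expect_gte(run$model$cv_auc, grid$cv_auc - 0.02)
})
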