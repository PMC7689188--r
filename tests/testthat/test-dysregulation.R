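test_that("rank correlation matches hand-computed values", {
  expect_equal(rank_correlation(c(1, 2, 3), c(2, 4, 6)), 1.0)
  # d^2 = (4, 1, 1): 1 - 6*6/(3*8) = -0.5
  expect_equal(rank_correlation(c(1, 2, 3), c(3, 1, 2)), -0.5)
  # ties: ranks of (1,1,2) are (1.5,1.5,3); Pearson of ranks by hand
  expect_equal(rank_correlation(c(1, 1, 2), c(1, 2, 3)), 1.5 / sqrt(3))
  expect_error(rank_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(rank_correlation(1:2, 1:2), "at least 3")
})

test_that("dysregulation scores hit the closed-form extremes", {
  # same monotone relation in both conditions -> S = 0;
  # opposite monotone relations -> S = 2
  xm <- rbind(m1 = c(1, 2, 3, 4, 1, 2, 3, 4))
  gm <- rbind(g_same = c(2, 3, 4, 5, 2, 3, 4, 5),
              g_flip = c(2, 3, 4, 5, 5, 4, 3, 2))
  colnames(xm) <- colnames(gm) <- sprintf("s%d", 1:8)
  em_m <- expression_matrix(xm, "miRNA")
  em_g <- expression_matrix(gm, "mRNA")
  groups <- group_assignment(colnames(xm), rep(c("tumor", "normal"), each = 4))
  pairs <- candidate_pairs(c("m1", "m1"), c("g_same", "g_flip"))
  rec <- dysregulation_scores(em_m, em_g, pairs, groups)
  expect_equal(rec$score[rec$gene == "g_same"], 0)
  expect_equal(rec$rho_tumor[rec$gene == "g_flip"], 1)
  expect_equal(rec$rho_normal[rec$gene == "g_flip"], -1)
  expect_equal(rec$score[rec$gene == "g_flip"], 2)
})

test_that("vectorized scores equal a per-pair recomputation and the C++ path", {
  set.seed(5)
  em_m <- toy_expression(10, 20, "miRNA", seed = 5)
  em_g <- toy_expression(15, 20, "mRNA", seed = 6)
  groups <- group_assignment(colnames(em_m), rep(c("tumor", "normal"), each = 10))
  pairs <- candidate_pairs(sample(rownames(em_m), 20, replace = TRUE),
                           sample(rownames(em_g), 20, replace = TRUE))
  rec <- dysregulation_scores(em_m, em_g, pairs, groups)
  # independent per-pair oracle via stats::cor
  for (k in seq_len(nrow(rec))) {
    x <- em_m[rec$mirna[k], ]; y <- em_g[rec$gene[k], ]
    rt <- cor(x[1:10], y[1:10], method = "spearman")
    rn <- cor(x[11:20], y[11:20], method = "spearman")
    expect_equal(rec$rho_tumor[k], rt, tolerance = 1e-12)
    expect_equal(rec$rho_normal[k], rn, tolerance = 1e-12)
    expect_equal(rec$score[k], abs(rt - rn), tolerance = 1e-12)
  }
  # the C++ permutation engine recomputes the same observed quantities
  withp <- permutation_pvalues(rec, em_m, em_g, groups, n_perm = 10, seed = 1)
  expect_equal(withp$score, rec$score, tolerance = 1e-12)
})

test_that("missing-id and constant pairs are skipped with reasons", {
  em_m <- toy_expression(3, 8, "miRNA")
  gm <- rbind(gc = rep(2, 8), gv = c(1, 5, 2, 6, 3, 7, 4, 8))
  colnames(gm) <- colnames(em_m)
  em_g <- expression_matrix(gm, "mRNA")
  groups <- group_assignment(colnames(em_m), rep(c("tumor", "normal"), each = 4))
  pairs <- candidate_pairs(c("f01", "f01", "absent"), c("gv", "gc", "gv"))
  rec <- dysregulation_scores(em_m, em_g, pairs, groups)
  expect_equal(nrow(rec), 1L)
  sk <- attr(rec, "skipped")
  expect_setequal(sk$reason, c("id not in expression",
                               "constant expression within a condition"))
})

test_that("a zero observed score yields permutation p = 1", {
  xm <- rbind(m1 = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  gm <- rbind(g1 = c(2, 3, 4, 5, 6, 2, 3, 4, 5, 6))
  colnames(xm) <- colnames(gm) <- sprintf("s%d", 1:10)
  em_m <- expression_matrix(xm, "miRNA"); em_g <- expression_matrix(gm, "mRNA")
  groups <- group_assignment(colnames(xm), rep(c("tumor", "normal"), each = 5))
  rec <- dysregulation_scores(em_m, em_g, candidate_pairs("m1", "g1"), groups)
  expect_equal(rec$score, 0)
  rec <- permutation_pvalues(rec, em_m, em_g, groups, n_perm = 200, seed = 3)
  expect_equal(rec$p_perm, 1)
})

test_that("scores are invariant under swapping the condition labels", {
  em_m <- toy_expression(5, 12, "miRNA", seed = 8)
  em_g <- toy_expression(5, 12, "mRNA", seed = 9)
  g1 <- group_assignment(colnames(em_m), rep(c("tumor", "normal"), each = 6))
  g2 <- group_assignment(colnames(em_m), rep(c("normal", "tumor"), each = 6))
  pairs <- candidate_pairs(rownames(em_m), rownames(em_g))
  r1 <- dysregulation_scores(em_m, em_g, pairs, g1)
  r2 <- dysregulation_scores(em_m, em_g, pairs, g2)
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
  expect_equal(r1$rho_tumor, r2$rho_normal, tolerance = 1e-12)
})

test_that("Monte-Carlo p converges to the exhaustive enumeration", {
  set.seed(21)
  n_pairs <- 8
  xm <- matrix(rnorm(n_pairs * 6, 5, 1)^2, n_pairs, 6,
               dimnames = list(sprintf("m%d", 1:n_pairs), sprintf("s%d", 1:6)))
  gm <- matrix(rnorm(n_pairs * 6, 5, 1)^2, n_pairs, 6,
               dimnames = list(sprintf("g%d", 1:n_pairs), sprintf("s%d", 1:6)))
  em_m <- expression_matrix(xm, "miRNA"); em_g <- expression_matrix(gm, "mRNA")
  groups <- group_assignment(colnames(xm), rep(c("tumor", "normal"), each = 3))
  pairs <- candidate_pairs(rownames(xm), rownames(gm))
  rec <- dysregulation_scores(em_m, em_g, pairs, groups)

  ex <- permutation_pvalues(rec, em_m, em_g, groups, exhaustive = TRUE)
  expect_equal(unique(ex$n_perm), choose(6, 3))

  mc5k <- permutation_pvalues(rec, em_m, em_g, groups, n_perm = 5000, seed = 2)
  expect_lt(mean(abs(mc5k$p_perm - ex$p_perm)), 0.02)

  expect_error(permutation_pvalues(rec, em_m, em_g, groups, exhaustive = TRUE,
                                   cap = 5L), "partitions")
})

test_that("permutation p-values are uniform under the exchangeable null", {
  rec <- null_run()
  expect_gte(nrow(rec), 1000L)
  expect_lt(ks_distance_uniform(rec$p_perm), 0.05)
})

test_that("the DMTN keeps exactly the strictly significant edges", {
  rec <- structure(
    data.frame(mirna = c("m1", "m2", "m3"), gene = c("g1", "g2", "g3"),
               rho_tumor = 0.5, rho_normal = 0, score = 0.5,
               p_perm = c(0.04, 0.05, 1), stringsAsFactors = FALSE),
    class = c("DysregulationTable", "data.frame"))
  net <- build_dmtn(rec, alpha = 0.05)
  expect_equal(net$edges$mirna, "m1")   # p = 0.05 excluded, strict <

  rec$p_perm <- rep(1, 3)
  empty <- build_dmtn(rec)
  expect_equal(nrow(empty$edges), 0L)

  # recount oracle on a seeded record set
  set.seed(4)
  n <- 500
  rec2 <- structure(
    data.frame(mirna = sprintf("m%03d", 1:n), gene = sprintf("g%03d", 1:n),
               rho_tumor = 0, rho_normal = 0, score = 0,
               p_perm = runif(n), stringsAsFactors = FALSE),
    class = c("DysregulationTable", "data.frame"))
  expect_equal(nrow(build_dmtn(rec2, 0.05)$edges), sum(rec2$p_perm < 0.05))
})

test_that("degree histogram and log-log slope behave on known graphs", {
  star <- bipartite_network(rep("m1", 5), sprintf("g%d", 1:5))
  d <- out_degree_distribution(star)
  expect_equal(d$histogram, data.frame(degree = 5L, count = 1L))
  expect_true(is.na(d$slope))

  two <- bipartite_network(c("m1", "m2", "m2", "m2"), c("g1", "g2", "g3", "g4"))
  expect_equal(out_degree_distribution(two)$histogram,
               data.frame(degree = c(1L, 3L), count = c(1L, 1L)))

  # heavy-tailed planted degrees give a negative slope
  set.seed(10)
  degs <- pmax(1L, as.integer(round(1 / runif(80)^0.8)))
  degs <- pmin(degs, 40L)
  mirna <- rep(sprintf("m%02d", seq_along(degs)), degs)
  gene <- sprintf("g%04d", unlist(lapply(degs, sample.int, n = 5000)))
  net <- bipartite_network(mirna, gene)
  expect_lt(out_degree_distribution(net)$slope, 0)
})

test_that("miRNA shortest paths match a per-source BFS oracle", {
  # two miRNAs sharing one target sit at distance 2
  net <- bipartite_network(c("m1", "m2"), c("g1", "g1"))
  sp <- mirna_shortest_paths(net)
  expect_equal(sp$histogram, data.frame(length = 2L, count = 1L))
  expect_equal(sp$unreachable_pairs, 0L)

  # two components -> unreachable pair
  net2 <- bipartite_network(c("m1", "m2"), c("g1", "g2"))
  expect_equal(mirna_shortest_paths(net2)$unreachable_pairs, 1L)

  # random bipartite graph vs a hand-rolled BFS
  set.seed(11)
  edges <- unique(data.frame(m = sprintf("m%02d", sample.int(30, 120, TRUE)),
                             g = sprintf("g%02d", sample.int(40, 120, TRUE)),
                             stringsAsFactors = FALSE))
  net3 <- bipartite_network(edges$m, edges$g)
  sp3 <- mirna_shortest_paths(net3)

  adj <- list()
  for (i in seq_len(nrow(edges))) {
    adj[[edges$m[i]]] <- c(adj[[edges$m[i]]], edges$g[i])
    adj[[edges$g[i]]] <- c(adj[[edges$g[i]]], edges$m[i])
  }
  bfs <- function(src) {
    dist <- setNames(rep(Inf, length(adj)), names(adj))
    dist[src] <- 0; queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (dist[w] == Inf) {
        dist[w] <- dist[v] + 1; queue <- c(queue, w)
      }
    }
    dist
  }
  mir <- net3$mirnas
  oracle <- c()
  for (i in seq_along(mir)) {
    d <- bfs(mir[i])
    for (j in seq_along(mir)) if (j > i) oracle <- c(oracle, d[[mir[j]]])
  }
  expect_equal(sp3$unreachable_pairs, sum(!is.finite(oracle)))
  expect_equal(sp3$histogram$count,
               as.integer(table(oracle[is.finite(oracle)])))
})
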