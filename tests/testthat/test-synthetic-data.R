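test_that("generators are pure functions of the seed", {
  cfg <- scenario_config(n_mirna = 30, n_gene = 60, n_pairs = 80, n_dysreg = 40,
                         n_tumor = 10, n_normal = 10, seed = 77)
  s1 <- gen_paired_expression(cfg)
  s2 <- gen_paired_expression(cfg)
  expect_identical(unclass(s1$em_mirna), unclass(s2$em_mirna))
  expect_identical(unclass(s1$em_gene), unclass(s2$em_gene))
  expect_identical(s1$pairs, s2$pairs)
  s3 <- gen_paired_expression(scenario_config(n_mirna = 30, n_gene = 60,
                                              n_pairs = 80, n_dysreg = 40,
                                              n_tumor = 10, n_normal = 10,
                                              seed = 78))
  expect_false(identical(unclass(s1$em_mirna), unclass(s3$em_mirna)))
})

test_that("planted copula correlations realize their Spearman targets", {
  cfg <- scenario_config(n_tumor = 500, n_normal = 500, n_mirna = 200,
                         n_gene = 200, n_pairs = 200, n_dysreg = 200,
                         rho_tumor = 0.6, rho_normal = 0.0,
                         risk_frac = 0, tn_frac = 0, risk_lfc = 0, seed = 55)
  scen <- gen_paired_expression(cfg)
  rec <- dysregulation_scores(scen$em_mirna, scen$em_gene, scen$pairs, scen$groups)
  expect_lt(abs(mean(rec$rho_tumor) - 0.6), 0.05)
  expect_lt(abs(mean(rec$rho_normal) - 0.0), 0.05)
})

test_that("an equal-correlation scenario has vanishing mean dysregulation", {
  cfg <- null_scenario_config(n_pairs = 200, n_tumor = 200, n_normal = 200,
                              rho = 0.4, seed = 56)
  scen <- gen_paired_expression(cfg)
  rec <- dysregulation_scores(scen$em_mirna, scen$em_gene, scen$pairs, scen$groups)
  expect_lt(mean(rec$score), 0.1)
})

test_that("risk scenario plants separable TP/TN structure", {
  run <- default_run()
  scen <- run$scen
  truth <- scen$truth
  expect_length(intersect(truth$risk_mirnas, truth$tn_block), 0)
  # the low block is strictly dominated in mean and variance, so the
  # rank-sum selection finds it
  cand <- rank_sum_negatives(scen$em_mirna, scen$groups,
                             k = length(truth$tn_block))
  expect_setequal(cand, truth$tn_block)
  # curated lists recover the planted risk set inside the network
  risk <- gen_risk_scenario(scen)
  expect_setequal(intersect(unique(unlist(risk$curated_lists)),
                            truth$risk_mirnas), truth$risk_mirnas)
  expect_true(all(grepl("^decoy", setdiff(unlist(risk$curated_lists),
                                          truth$risk_mirnas))))
})

test_that("survival generator hits the target censoring fraction", {
  set.seed(57)
  n <- 400
  vals <- matrix(exp(rnorm(2 * n, 3, 0.8)), 2, n,
                 dimnames = list(c("fA", "fB"), sprintf("s%03d", 1:n)))
  em <- expression_matrix(vals, "miRNA")
  clin <- gen_survival(em, drivers = "fA", hazard_coef = 0.8, seed = 58)
  expect_lt(abs((1 - mean(clin$event)) - 0.30), 0.07)
  # null generator: no association anywhere
  clin0 <- gen_survival(em, drivers = character(0), hazard_coef = 0, seed = 59)
  expect_equal(nrow(clin0), n)
})

test_that("driving features are detectable with the promised power", {
  set.seed(60)
  n <- 200
  hits <- 0L
  for (rep in 1:50) {
    vals <- matrix(exp(rnorm(n, 3, 0.8)), 1, n,
                   dimnames = list("drv", sprintf("s%03d", 1:n)))
    em <- expression_matrix(vals, "miRNA")
    clin <- gen_survival(em, drivers = "drv", hazard_coef = 0.8, seed = rep)
    g <- median_split(vals[1, ])
    lo <- g == "low"
    p <- logrank_test(clin$time[lo], clin$event[lo],
                      clin$time[!lo], clin$event[!lo])$p
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.8)
})

test_that("abundance rows are compositional and planting hits its target", {
  set.seed(61)
  n <- 300
  vals <- matrix(exp(rnorm(10 * n, 3, 0.8)), 10, n,
                 dimnames = list(sprintf("f%02d", 1:10), sprintf("s%03d", 1:n)))
  em <- expression_matrix(vals, "miRNA")
  rs <- c()
  for (s in 1:4) {
    ab <- gen_abundance(em, n_celltypes = 10,
                        planted = data.frame(feature = sprintf("f%02d", 1:5),
                                             celltype = 3:7, rho = 0.5),
                        seed = s)
    expect_true(all(abs(rowSums(ab$abundance) - 1) < 1e-6))
    rs <- c(rs, sapply(1:5, function(i)
      cor(vals[i, ], ab$abundance[, 2 + i], method = "spearman")))
  }
  expect_lt(abs(mean(rs) - 0.5), 0.07)
  expect_error(gen_abundance(em, planted = data.frame(feature = "f01",
                                                      celltype = 3, rho = 0.99)),
               "infeasible")
})

test_that("drug generator plants correlations and missingness as configured", {
  dr <- gen_drug_response(sprintf("f%02d", 1:10), n_lines = 400, n_drugs = 20,
                          planted = data.frame(feature = sprintf("f%02d", 1:5),
                                               drug = 1:5, r = 0.6),
                          seed = 62)
  expect_lt(abs(mean(is.na(dr$ic50)) - 0.10), 0.02)
  got <- sapply(1:5, function(i) {
    ok <- !is.na(dr$ic50[, i])
    cor(dr$em_lines[sprintf("f%02d", i), ok], dr$ic50[ok, i])
  })
  expect_lt(abs(mean(got) - 0.6), 0.1)
  expect_error(gen_drug_response("f1", planted = data.frame(feature = "f1",
                                                            drug = 1, r = 0.96)),
               "infeasible")
})

test_that("simulate_scenario writes a complete, machine-readable bundle", {
  dir <- withr::local_tempdir()
  cfg <- scenario_config(n_mirna = 40, n_gene = 80, n_pairs = 100,
                         n_dysreg = 50, n_tumor = 10, n_normal = 10,
                         n_lines = 50, n_drugs = 5, seed = 63)
  simulate_scenario(cfg, dir)
  expected <- c("mirna_expression.tsv", "gene_expression.tsv", "groups.tsv",
                "candidate_pairs.tsv", "truth_dysreg_pairs.tsv",
                "disease_list_1.txt", "disease_list_2.txt",
                "truth_risk_mirnas.txt", "truth_tn_block.txt", "clinical.tsv",
                "abundance.tsv", "cellline_expression.tsv", "ic50.tsv",
                "config.tsv")
  expect_true(all(file.exists(file.path(dir, expected))))
  em <- read_expression(file.path(dir, "mirna_expression.tsv"), "miRNA")
  expect_equal(dim(em), c(40L, 20L))
  truth <- readLines(file.path(dir, "truth_risk_mirnas.txt"))
  expect_true(all(truth %in% rownames(em)))
})
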