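# Shared fixtures, built once per test run and cached: the heavy pieces
# (permutation runs on full scenarios) are reused by several test files.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# desk-scale risk scenario with permutation p-values and the DMTN
default_run <- function() with_cache("default_run", {
  cfg <- scenario_config(seed = 42L)
  scen <- gen_paired_expression(cfg)
  rec <- dysregulation_scores(scen$em_mirna, scen$em_gene, scen$pairs, scen$groups)
  rec <- permutation_pvalues(rec, scen$em_mirna, scen$em_gene, scen$groups,
                             n_perm = 1000L, seed = 42L)
  list(cfg = cfg, scen = scen, records = rec, net = build_dmtn(rec))
})

# exchangeable null: 1000 independent pairs, equal correlation in both arms
null_run <- function() with_cache("null_run", {
  cfg <- null_scenario_config(n_pairs = 1000L, n_tumor = 50L, n_normal = 50L,
                              rho = 0.3, seed = 101L)
  scen <- gen_paired_expression(cfg)
  rec <- dysregulation_scores(scen$em_mirna, scen$em_gene, scen$pairs, scen$groups)
  permutation_pvalues(rec, scen$em_mirna, scen$em_gene, scen$groups,
                      n_perm = 1000L, seed = 101L)
})

# 200 planted rewired pairs (0.6 vs 0.0) at 100+100 samples, one pair per
# miRNA/gene so detections are independent
planted_run <- function() with_cache("planted_run", {
  cfg <- scenario_config(n_tumor = 100L, n_normal = 100L, n_mirna = 200L,
                         n_gene = 200L, n_pairs = 200L, n_dysreg = 200L,
                         rho_tumor = 0.6, rho_normal = 0.0,
                         risk_frac = 0, tn_frac = 0, risk_lfc = 0, seed = 7L)
  scen <- gen_paired_expression(cfg)
  rec <- dysregulation_scores(scen$em_mirna, scen$em_gene, scen$pairs, scen$groups)
  permutation_pvalues(rec, scen$em_mirna, scen$em_gene, scen$groups,
                      n_perm = 1000L, seed = 7L)
})

# full classifier pipeline on the default scenario
classifier_run <- function() with_cache("classifier_run", {
  run <- default_run()
  scen <- run$scen
  risk <- gen_risk_scenario(scen)
  tp <- select_true_positives(risk$curated_lists, run$net)
  tn <- finalize_negatives(rank_sum_negatives(scen$em_mirna, scen$groups, k = 40L),
                           tp, run$net)
  feats <- compute_features(run$net, scen$em_mirna, scen$groups,
                            disease_set = risk$disease_set)
  model <- train_classifier(feats, label_sets(tp, tn), seed = 42L)
  thr <- recognition_threshold(model, feats[feats$mirna %in% tn, ])
  pred <- predict_risk(model, feats, thr)
  list(scen = scen, net = run$net, risk = risk, tp = tp, tn = tn,
       feats = feats, model = model, threshold = thr, pred = pred)
})

# tiny deterministic expression matrix for unit tests
toy_expression <- function(n_feat = 4, n_samp = 6, kind = "miRNA", seed = 1) {
  set.seed(seed)
  m <- matrix(round(exp(rnorm(n_feat * n_samp, 2, 1)), 4), n_feat, n_samp,
              dimnames = list(sprintf("f%02d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  expression_matrix(m, kind)
}

toy_groups <- function(n_tumor = 3, n_normal = 3) {
  group_assignment(sprintf("s%02d", seq_len(n_tumor + n_normal)),
                   rep(c("tumor", "normal"), c(n_tumor, n_normal)))
}

# empirical cdf max distance to U(0,1)
ks_distance_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(seq_len(n) / n - p), abs((seq_len(n) - 1) / n - p))
}
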