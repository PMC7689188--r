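#' Scenario configuration for the synthetic-data generator
#'
#' Defines a desk-scale study: paired tumor/normal expression with planted
#' correlation-rewired miRNA->gene pairs, a risk-miRNA block with elevated
#' network degree and fold change, a low-expression/low-variance block the
#' rank-sum negative selection should find, survival times driven by chosen
#' features, compositional immune abundances and an IC50 matrix with
#' planted correlations.
#'
#' @param n_tumor,n_normal Sample sizes per condition (>= 3 each).
#' @param n_mirna,n_gene Feature counts.
#' @param n_pairs Candidate miRNA-mRNA pairs (planted + null fillers).
#' @param n_dysreg Planted pairs carrying the (rho_tumor, rho_normal)
#'   rewiring; each uses its own target gene, so `n_dysreg <= n_gene`.
#' @param rho_tumor,rho_normal Target Spearman correlations of planted
#'   pairs per condition, in (-1, 1). Equal values give a null scenario.
#' @param risk_frac Fraction of miRNAs planted as risk (high degree,
#'   disease-list membership, fold change).
#' @param tn_frac Fraction of miRNAs in the low-mean/low-variance block.
#' @param meanlog,sdlog Log-normal marginal parameters of background
#'   expression (unitless normalized scale).
#' @param tn_meanlog,tn_sdlog Marginals of the low block (must sit below
#'   the background in both mean and variance).
#' @param risk_lfc Planted log2 fold change (tumor vs normal mean) of risk
#'   miRNAs.
#' @param hazard_coef Log-hazard slope per SD of the driving feature.
#' @param censor_frac Target censoring fraction of the survival generator.
#' @param n_celltypes,n_drugs,n_lines Sizes of the immune and drug screens.
#' @param seed Master seed; every generator derives its own substream.
#' @return List of class `ScenarioConfig`.
#' @export
scenario_config <- function(n_tumor = 60L, n_normal = 60L,
                            n_mirna = 150L, n_gene = 600L,
                            n_pairs = 2000L, n_dysreg = 200L,
                            rho_tumor = 0.6, rho_normal = 0.0,
                            risk_frac = 0.2, tn_frac = 0.25,
                            meanlog = 3, sdlog = 0.8,
                            tn_meanlog = 0.3, tn_sdlog = 0.15,
                            risk_lfc = 1.5,
                            hazard_coef = 0.8, censor_frac = 0.3,
                            n_celltypes = 10L, n_drugs = 30L, n_lines = 300L,
                            seed = 1L) {
  cfg <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_mirna = as.integer(n_mirna), n_gene = as.integer(n_gene),
              n_pairs = as.integer(n_pairs), n_dysreg = as.integer(n_dysreg),
              rho_tumor = rho_tumor, rho_normal = rho_normal,
              risk_frac = risk_frac, tn_frac = tn_frac,
              meanlog = meanlog, sdlog = sdlog,
              tn_meanlog = tn_meanlog, tn_sdlog = tn_sdlog,
              risk_lfc = risk_lfc, hazard_coef = hazard_coef,
              censor_frac = censor_frac,
              n_celltypes = as.integer(n_celltypes),
              n_drugs = as.integer(n_drugs), n_lines = as.integer(n_lines),
              seed = as.integer(seed))
  if (cfg$n_tumor < 3 || cfg$n_normal < 3) stop("group sizes must be >= 3")
  if (cfg$n_dysreg > cfg$n_pairs) stop("n_dysreg must not exceed n_pairs")
  if (cfg$n_dysreg > cfg$n_gene) stop("n_dysreg must not exceed n_gene")
  if (abs(rho_tumor) >= 1 || abs(rho_normal) >= 1) stop("infeasible rho")
  structure(cfg, class = "ScenarioConfig")
}

#' Null scenario: planted pairs with equal correlation in both conditions
#'
#' One miRNA and one gene per pair (pairs mutually independent), identical
#' marginals in both conditions, no risk or low-expression blocks — the
#' exchangeable setting under which permutation p-values must be uniform.
#'
#' @param n_pairs Number of independent pairs.
#' @param n_tumor,n_normal Group sizes.
#' @param rho Common Spearman target in both conditions.
#' @param seed Master seed.
#' @return A [scenario_config()].
#' @export
null_scenario_config <- function(n_pairs = 1000L, n_tumor = 50L,
                                 n_normal = 50L, rho = 0.3, seed = 1L) {
  scenario_config(n_tumor = n_tumor, n_normal = n_normal,
                  n_mirna = n_pairs, n_gene = n_pairs, n_pairs = n_pairs,
                  n_dysreg = n_pairs, rho_tumor = rho, rho_normal = rho,
                  risk_frac = 0, tn_frac = 0, risk_lfc = 0, seed = seed)
}

# deterministic substream seed for a named stage, < 2^31
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# Pearson copula parameter giving a bivariate-Gaussian Spearman of rho
.spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Generate paired tumor/normal expression with planted rewired pairs
#'
#' miRNA expression is drawn from a Gaussian copula with log-normal
#' marginals. Each planted pair couples its own target gene to the miRNA
#' with per-condition Pearson parameter `2*sin(pi*rho/6)`, so the realized
#' Spearman correlation approximates the configured target. Null filler
#' pairs link independent features. Risk-block miRNAs receive most of the
#' planted out-degree plus a tumor-side fold change; the low block gets
#' exactly one planted pair each (so it appears in the network) and
#' strictly dominated mean/variance marginals.
#'
#' @param cfg A [scenario_config()].
#' @return List of class `SyntheticScenario`: `em_mirna`, `em_gene`,
#'   `groups`, `pairs`, `truth` (planted pair table, `risk_mirnas`,
#'   `tn_block`, per-miRNA marginals).
#' @export
gen_paired_expression <- function(cfg) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, "expression"))

  n <- cfg$n_tumor + cfg$n_normal
  cond <- rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal))
  samples <- sprintf("%s%03d", ifelse(cond == "tumor", "T", "N"),
                     c(seq_len(cfg$n_tumor), seq_len(cfg$n_normal)))
  mirnas <- sprintf("mir%04d", seq_len(cfg$n_mirna))
  genes <- sprintf("g%05d", seq_len(cfg$n_gene))

  n_risk <- round(cfg$risk_frac * cfg$n_mirna)
  n_tn <- round(cfg$tn_frac * cfg$n_mirna)
  risk <- mirnas[seq_len(n_risk)]
  tn_block <- mirnas[n_risk + seq_len(n_tn)]
  background <- setdiff(mirnas, c(risk, tn_block))

  # planted out-degree plan: low block gets 1 each, risk miRNAs take most of
  # the rest (heavy-ish tail), background absorbs the remainder
  stopifnot(cfg$n_dysreg >= n_tn + 3L * n_risk)
  deg <- stats::setNames(integer(cfg$n_mirna), mirnas)
  deg[tn_block] <- 1L
  remaining <- cfg$n_dysreg - n_tn
  if (n_risk > 0) {
    n_risk_pairs <- min(remaining, round(0.75 * remaining))
    w <- 1 / seq_len(n_risk)           # rank-weighted: a few hubs
    extra <- table(factor(sample(risk, n_risk_pairs - 3L * n_risk,
                                 replace = TRUE, prob = w), levels = risk))
    deg[risk] <- 3L + as.integer(extra)
    remaining <- remaining - n_risk_pairs
  }
  if (remaining > 0) {
    if (!length(background)) stop("risk fraction too large for n_dysreg")
    bg <- sample(background, remaining, replace = remaining > length(background))
    tb <- table(factor(bg, levels = background))
    deg[background] <- as.integer(tb)
  }

  planted_mirna <- rep(names(deg), deg)
  planted_gene <- genes[seq_along(planted_mirna)]

  # latent Gaussians
  zm <- matrix(stats::rnorm(cfg$n_mirna * n), cfg$n_mirna, n,
               dimnames = list(mirnas, samples))
  zg <- matrix(stats::rnorm(cfg$n_gene * n), cfg$n_gene, n,
               dimnames = list(genes, samples))
  rt <- .spearman_to_pearson(cfg$rho_tumor)
  rn <- .spearman_to_pearson(cfg$rho_normal)
  tum <- cond == "tumor"
  for (k in seq_along(planted_mirna)) {
    zmk <- zm[planted_mirna[k], ]
    eps <- zg[planted_gene[k], ]
    zg[planted_gene[k], tum] <- rt * zmk[tum] + sqrt(1 - rt^2) * eps[tum]
    zg[planted_gene[k], !tum] <- rn * zmk[!tum] + sqrt(1 - rn^2) * eps[!tum]
  }

  # log-normal marginals; low block dominated, risk block shifted in tumor
  ml <- stats::setNames(rep(cfg$meanlog, cfg$n_mirna), mirnas)
  sl <- stats::setNames(rep(cfg$sdlog, cfg$n_mirna), mirnas)
  ml[tn_block] <- cfg$tn_meanlog
  sl[tn_block] <- cfg$tn_sdlog
  xm <- exp(ml + sl * zm)
  if (length(risk) && cfg$risk_lfc != 0) {
    xm[risk, tum] <- xm[risk, tum] * 2^cfg$risk_lfc
  }
  xg <- exp(cfg$meanlog + cfg$sdlog * zg)

  # candidate list: planted pairs plus independent null fillers
  n_null <- cfg$n_pairs - cfg$n_dysreg
  pair_key <- paste(planted_mirna, planted_gene)
  null_m <- character(0); null_g <- character(0)
  while (length(null_m) < n_null) {
    need <- n_null - length(null_m)
    cm <- sample(mirnas, need, replace = TRUE)
    cg <- sample(genes, need, replace = TRUE)
    keep <- !(paste(cm, cg) %in% c(pair_key, paste(null_m, null_g)))
    keep <- keep & !duplicated(paste(cm, cg))
    null_m <- c(null_m, cm[keep]); null_g <- c(null_g, cg[keep])
  }
  pairs <- candidate_pairs(c(planted_mirna, null_m), c(planted_gene, null_g))

  truth <- list(
    dysreg_pairs = data.frame(mirna = planted_mirna, gene = planted_gene,
                              rho_tumor = cfg$rho_tumor,
                              rho_normal = cfg$rho_normal,
                              stringsAsFactors = FALSE),
    risk_mirnas = risk, tn_block = tn_block, background = background)

  structure(list(em_mirna = expression_matrix(xm, "miRNA"),
                 em_gene = expression_matrix(xg, "mRNA"),
                 groups = group_assignment(samples, cond),
                 pairs = pairs, truth = truth, cfg = cfg),
            class = "SyntheticScenario")
}

#' Curated disease lists for the planted risk miRNAs
#'
#' Emulates merging two partially overlapping disease databases: both lists
#' cover complementary slices of the planted risk set plus a few decoy ids
#' absent from the expression data, so the TP construction (union, then
#' intersection with the network) has a known correct answer.
#'
#' @param scen A [gen_paired_expression()] scenario.
#' @param n_decoys Decoy ids per list, default 5.
#' @return List: `curated_lists` (two character vectors), `disease_set`
#'   (their union), `expected_tp` (risk miRNAs, the in-network truth).
#' @export
gen_risk_scenario <- function(scen, n_decoys = 5L) {
  stopifnot(inherits(scen, "SyntheticScenario"))
  risk <- scen$truth$risk_mirnas
  if (!length(risk)) stop("scenario has no planted risk miRNAs (risk_frac = 0)")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(scen$cfg$seed, "risk-lists"))
  cut1 <- ceiling(0.6 * length(risk))
  cut2 <- floor(0.4 * length(risk))
  decoys1 <- sprintf("decoy%03d", seq_len(n_decoys))
  decoys2 <- sprintf("decoy%03d", n_decoys + seq_len(n_decoys))
  lists <- list(sample(c(risk[seq_len(cut1)], decoys1)),
                sample(c(risk[seq(cut2, length(risk))], decoys2)))
  list(curated_lists = lists,
       disease_set = unique(unlist(lists)),
       expected_tp = risk)
}

#' Generate survival times driven by chosen features
#'
#' Exponential event times whose log-hazard is linear in the standardized
#' log-expression of the driving features (mean over drivers); independent
#' exponential censoring with its rate tuned (deterministically, by root
#' finding on the expected censoring probability) to the target fraction.
#'
#' @param em An [expression_matrix()]; survival is generated for all its
#'   samples.
#' @param drivers Feature ids driving the hazard (empty = pure null).
#' @param hazard_coef Log-hazard units per SD, default 0.8.
#' @param censor_frac Target expected censoring fraction, default 0.3.
#' @param base_rate Baseline event rate per day, default 1/1000.
#' @param seed Seed.
#' @return A [clinical_table()] for the samples of `em`.
#' @export
gen_survival <- function(em, drivers = character(0), hazard_coef = 0.8,
                         censor_frac = 0.3, base_rate = 1 / 1000, seed = 1L) {
  miss <- setdiff(drivers, feature_ids(em))
  if (length(miss)) stop("driver(s) missing from expression: ",
                         paste(miss, collapse = ", "))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "survival"))
  n <- ncol(em)
  z <- if (length(drivers)) {
    zs <- scale(t(log1p(em[drivers, , drop = FALSE])))
    rowMeans(zs)
  } else rep(0, n)
  rate <- base_rate * exp(hazard_coef * z)
  t_event <- stats::rexp(n, rate)
  if (censor_frac > 0) {
    f <- function(lc) mean(exp(lc) / (exp(lc) + rate)) - censor_frac
    lc <- stats::uniroot(f, c(log(base_rate) - 12, log(base_rate) + 12))$root
    t_cens <- stats::rexp(n, exp(lc))
  } else {
    t_cens <- rep(Inf, n)
  }
  clinical_table(sample_ids(em), pmin(t_event, t_cens),
                 as.integer(t_event <= t_cens))
}

#' Generate immune abundances with planted rank correlations
#'
#' Per-sample compositions are drawn from a Dirichlet with a dominated
#' concentration profile (one or two large cell types, the rest sparse),
#' by normalizing independent Gamma draws. For each planted
#' (feature, cell type, rho) the corresponding Gamma variate is coupled to
#' the feature's normal score through a Gaussian copula before
#' normalization, so the realized Spearman correlation with the fraction
#' approaches `rho`.
#'
#' @param em An [expression_matrix()] (samples define the rows).
#' @param n_celltypes Number of cell types.
#' @param planted Data frame `feature`, `celltype` (integer index), `rho`
#'   with `|rho| < 0.95`; may be empty.
#' @param concentration Optional Dirichlet concentration vector.
#' @param seed Seed.
#' @return List: `abundance` (samples x cell types, rows summing to 1),
#'   `planted` (echo with cell-type names).
#' @export
gen_abundance <- function(em, n_celltypes = 10L, planted = NULL,
                          concentration = NULL, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "abundance"))
  n <- ncol(em)
  cells <- sprintf("cell_type_%02d", seq_len(n_celltypes))
  if (is.null(concentration)) {
    concentration <- c(8, 4, rep(0.8, max(0L, n_celltypes - 2L)))[seq_len(n_celltypes)]
  }
  G <- sapply(concentration, function(a) stats::rgamma(n, shape = a, rate = 1))
  dimnames(G) <- list(sample_ids(em), cells)
  if (!is.null(planted) && nrow(planted)) {
    if (any(abs(planted$rho) >= 0.95)) stop("infeasible planted correlation (|rho| >= 0.95)")
    for (i in seq_len(nrow(planted))) {
      f <- planted$feature[i]; k <- planted$celltype[i]; rho <- planted$rho[i]
      # row normalization attenuates the coupled component's rank
      # correlation; estimate the attenuation by Monte Carlo and inflate
      # the latent coupling so the realized fraction hits the target
      m <- 4000L
      gk <- stats::rgamma(m, shape = concentration[k], rate = 1)
      rest <- rowSums(sapply(concentration[-k],
                             function(a) stats::rgamma(m, shape = a, rate = 1)))
      atten <- stats::cor(gk, gk / (gk + rest), method = "spearman")
      rho_lat <- sign(rho) * min(0.949, abs(rho) / atten)
      zf <- stats::qnorm((rank(em[f, ]) - 0.5) / n)
      zc <- rho_lat * zf + sqrt(1 - rho_lat^2) * stats::rnorm(n)
      G[, k] <- stats::qgamma(stats::pnorm(zc), shape = concentration[k], rate = 1)
    }
  }
  ab <- G / rowSums(G)
  pl <- if (is.null(planted)) data.frame() else
    data.frame(feature = planted$feature, celltype = cells[planted$celltype],
               rho_target = planted$rho, stringsAsFactors = FALSE)
  list(abundance = abundance_matrix(ab), planted = pl)
}

#' Generate cell-line expression and an IC50 matrix with planted correlations
#'
#' Cell-line expression uses log-normal marginals from latent normals; each
#' planted (feature, drug, r) makes the drug's log-IC50 a linear Gaussian
#' mix with the feature's latent score (Pearson correlation r by
#' construction); remaining entries are independent. A fraction of entries
#' is set missing completely at random.
#'
#' @param features Feature ids to simulate across cell lines.
#' @param n_lines,n_drugs Matrix dimensions.
#' @param planted Data frame `feature`, `drug` (integer index), `r` with
#'   `|r| < 0.95`; may be empty.
#' @param missing_frac Fraction of missing IC50 entries, default 0.10.
#' @param meanlog,sdlog Expression marginals.
#' @param seed Seed.
#' @return List: `em_lines` (miRNA [expression_matrix()] across cell
#'   lines), `ic50` (cell lines x drugs with `NA`s), `planted` (echo with
#'   drug names).
#' @export
gen_drug_response <- function(features, n_lines = 300L, n_drugs = 30L,
                              planted = NULL, missing_frac = 0.10,
                              meanlog = 3, sdlog = 0.8, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "drugs"))
  lines <- sprintf("CL%04d", seq_len(n_lines))
  drugs <- sprintf("drug_%03d", seq_len(n_drugs))
  Z <- matrix(stats::rnorm(length(features) * n_lines), length(features),
              n_lines, dimnames = list(features, lines))
  X <- exp(meanlog + sdlog * Z)
  ic50 <- matrix(stats::rnorm(n_lines * n_drugs), n_lines, n_drugs,
                 dimnames = list(lines, drugs))
  if (!is.null(planted) && nrow(planted)) {
    if (any(abs(planted$r) >= 0.95)) stop("infeasible planted correlation (|r| >= 0.95)")
    for (i in seq_len(nrow(planted))) {
      f <- planted$feature[i]; d <- planted$drug[i]; r <- planted$r[i]
      # couple to the expression values themselves so the screen's Pearson
      # correlation targets r without marginal attenuation
      xs <- as.vector(scale(X[f, ]))
      ic50[, d] <- r * xs + sqrt(1 - r^2) * stats::rnorm(n_lines)
    }
  }
  if (missing_frac > 0) {
    drop <- stats::runif(length(ic50)) < missing_frac
    ic50[drop] <- NA_real_
  }
  em_lines <- expression_matrix(X, "miRNA")
  pl <- if (is.null(planted)) data.frame() else
    data.frame(feature = planted$feature, drug = drugs[planted$drug],
               r_target = planted$r, stringsAsFactors = FALSE)
  list(em_lines = em_lines, ic50 = ic50, planted = pl)
}

#' Generate the immune and drug inputs for a scenario
#'
#' Convenience wrapper planting associations between the scenario's risk
#' miRNAs and a subset of cell types / drugs.
#'
#' @param scen A [gen_paired_expression()] scenario.
#' @param rho_immune Planted Spearman target for immune associations.
#' @param r_drug Planted Pearson target for drug associations.
#' @return List: `abundance`, `immune_planted`, `em_lines`, `ic50`,
#'   `drug_planted`.
#' @export
gen_abundance_and_drugs <- function(scen, rho_immune = 0.5, r_drug = 0.6) {
  stopifnot(inherits(scen, "SyntheticScenario"))
  cfg <- scen$cfg
  risk <- scen$truth$risk_mirnas
  if (!length(risk)) risk <- scen$truth$background
  n_pl <- min(5L, length(risk), cfg$n_celltypes - 2L)
  # plant on the sparse cell types: the dominant compositional components
  # attenuate rank correlations through row normalization
  ab <- gen_abundance(scen$em_mirna, n_celltypes = cfg$n_celltypes,
                      planted = data.frame(feature = risk[seq_len(n_pl)],
                                           celltype = 2L + seq_len(n_pl),
                                           rho = rho_immune,
                                           stringsAsFactors = FALSE),
                      seed = cfg$seed)
  n_pd <- min(10L, length(risk), cfg$n_drugs)
  dr <- gen_drug_response(sort(unique(c(risk, scen$truth$background))),
                          n_lines = cfg$n_lines, n_drugs = cfg$n_drugs,
                          planted = data.frame(feature = risk[seq_len(n_pd)],
                                               drug = seq_len(n_pd),
                                               r = r_drug,
                                               stringsAsFactors = FALSE),
                          seed = cfg$seed)
  list(abundance = ab$abundance, immune_planted = ab$planted,
       em_lines = dr$em_lines, ic50 = dr$ic50, drug_planted = dr$planted)
}

#' Write a full synthetic scenario (inputs + ground truth) to a directory
#'
#' Emits every pipeline input as TSV plus machine-readable truth files and
#' the resolved configuration as a flat key-value file.
#'
#' @param cfg A [scenario_config()].
#' @param dir Output directory (created if needed).
#' @return The scenario list, invisibly; files under `dir`.
#' @export
simulate_scenario <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scen <- gen_paired_expression(cfg)
  p <- function(...) file.path(dir, ...)
  write_expression(scen$em_mirna, p("mirna_expression.tsv"))
  write_expression(scen$em_gene, p("gene_expression.tsv"))
  write_tsv(as.data.frame(scen$groups), p("groups.tsv"))
  pr <- as.data.frame(scen$pairs); names(pr)[1:2] <- c("miRNA", "gene")
  write_tsv(pr, p("candidate_pairs.tsv"))
  write_tsv(scen$truth$dysreg_pairs, p("truth_dysreg_pairs.tsv"))

  risk <- NULL
  if (length(scen$truth$risk_mirnas)) {
    risk <- gen_risk_scenario(scen)
    writeLines(risk$curated_lists[[1L]], p("disease_list_1.txt"))
    writeLines(risk$curated_lists[[2L]], p("disease_list_2.txt"))
    writeLines(scen$truth$risk_mirnas, p("truth_risk_mirnas.txt"))
    writeLines(scen$truth$tn_block, p("truth_tn_block.txt"))
  }

  drivers <- scen$truth$risk_mirnas[seq_len(min(2L, length(scen$truth$risk_mirnas)))]
  clin <- gen_survival(scen$em_mirna, drivers, hazard_coef = cfg$hazard_coef,
                       censor_frac = cfg$censor_frac, seed = cfg$seed)
  write_tsv(as.data.frame(clin), p("clinical.tsv"))
  writeLines(drivers, p("truth_survival_drivers.txt"))

  ph <- gen_abundance_and_drugs(scen)
  write_tsv(data.frame(sample = rownames(ph$abundance), ph$abundance,
                       check.names = FALSE), p("abundance.tsv"))
  write_expression(ph$em_lines, p("cellline_expression.tsv"))
  write_tsv(data.frame(cell_line = rownames(ph$ic50), ph$ic50,
                       check.names = FALSE), p("ic50.tsv"))
  write_tsv(ph$immune_planted, p("truth_immune_planted.tsv"))
  write_tsv(ph$drug_planted, p("truth_drug_planted.tsv"))

  writeLines(paste(names(unclass(cfg)),
                   vapply(unclass(cfg), format, ""), sep = "\t"),
             p("config.tsv"))
  invisible(c(scen, list(risk = risk, clinical = clin, phenotypes = ph)))
}
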