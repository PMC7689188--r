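#' Pipeline configuration
#'
#' Paths plus stage parameters for the end-to-end run. Input files follow
#' the layout written by [simulate_scenario()]; any real dataset arranged
#' the same way works identically.
#'
#' @param input_dir Directory with the input TSVs (`mirna_expression.tsv`,
#'   `gene_expression.tsv`, `groups.tsv`, `candidate_pairs.tsv`,
#'   `disease_list_*.txt`, `clinical.tsv`, `abundance.tsv`,
#'   `cellline_expression.tsv`, `ic50.tsv`, optional `annotation.gmt`).
#' @param output_dir Directory for all stage outputs and the manifest.
#' @param max_zero_frac Low-expression filter threshold, default 0.10.
#' @param n_perm Label permutations per pair, default 1000 at desk scale.
#' @param alpha Edge significance level, default 0.05.
#' @param k_negatives Rank-sum TN candidates, default 40 (desk scale).
#' @param folds Cross-validation folds, default 5.
#' @param ga A [ga_config()].
#' @param r_min,min_n Drug-screen thresholds (see [drug_associations()]).
#' @param seed Global seed; stages derive named substreams from it.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(input_dir, output_dir, max_zero_frac = 0.10,
                            n_perm = 1000L, alpha = 0.05,
                            k_negatives = 40L, folds = 5L, ga = ga_config(),
                            r_min = 0.2, min_n = 20L, seed = 1L) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 max_zero_frac = max_zero_frac, n_perm = as.integer(n_perm),
                 alpha = alpha, k_negatives = as.integer(k_negatives),
                 folds = as.integer(folds), ga = ga, r_min = r_min,
                 min_n = as.integer(min_n), seed = as.integer(seed)),
            class = "PipelineConfig")
}

.stage_defs <- function(cfg) {
  ip <- function(...) file.path(cfg$input_dir, ...)
  op <- function(...) file.path(cfg$output_dir, ...)
  list(
    filter = list(
      inputs = c(ip("mirna_expression.tsv"), ip("gene_expression.tsv"),
                 ip("groups.tsv")),
      outputs = c(op("filtered_mirna.tsv"), op("filtered_gene.tsv")),
      fun = function() {
        g <- read_groups(ip("groups.tsv"))
        m <- filter_zero_fraction(read_expression(ip("mirna_expression.tsv"), "miRNA"),
                                  g, cfg$max_zero_frac)
        e <- filter_zero_fraction(read_expression(ip("gene_expression.tsv"), "mRNA"),
                                  g, cfg$max_zero_frac)
        write_expression(m, op("filtered_mirna.tsv"))
        write_expression(e, op("filtered_gene.tsv"))
      }),
    dysreg = list(
      inputs = c(op("filtered_mirna.tsv"), op("filtered_gene.tsv"),
                 ip("candidate_pairs.tsv"), ip("groups.tsv")),
      outputs = op("dysregulation.tsv"),
      fun = function() {
        g <- read_groups(ip("groups.tsv"))
        m <- read_expression(op("filtered_mirna.tsv"), "miRNA")
        e <- read_expression(op("filtered_gene.tsv"), "mRNA")
        rec <- dysregulation_scores(m, e, read_pairs(ip("candidate_pairs.tsv")), g)
        rec <- permutation_pvalues(rec, m, e, g, n_perm = cfg$n_perm,
                                   seed = derive_seed(cfg$seed, "dysreg"))
        write_edges(rec, op("dysregulation.tsv"))
      }),
    network = list(
      inputs = op("dysregulation.tsv"),
      outputs = c(op("network_edges.tsv"), op("degree_histogram.tsv"),
                  op("path_histogram.tsv")),
      fun = function() {
        rec <- utils::read.delim(op("dysregulation.tsv"), stringsAsFactors = FALSE)
        class(rec) <- c("DysregulationTable", "data.frame")
        net <- build_dmtn(rec, alpha = cfg$alpha)
        write_tsv(net$edges, op("network_edges.tsv"))
        write_tsv(out_degree_distribution(net)$histogram, op("degree_histogram.tsv"))
        write_tsv(mirna_shortest_paths(net)$histogram, op("path_histogram.tsv"))
      }),
    labels_features = list(
      inputs = c(op("network_edges.tsv"), op("filtered_mirna.tsv"),
                 ip("groups.tsv")),
      outputs = c(op("labels.tsv"), op("features.tsv")),
      fun = function() {
        net <- .read_network(op("network_edges.tsv"))
        m <- read_expression(op("filtered_mirna.tsv"), "miRNA")
        g <- read_groups(ip("groups.tsv"))
        lists <- lapply(sort(Sys.glob(ip("disease_list_*.txt"))), readLines)
        if (!length(lists)) stop("no disease_list_*.txt in input_dir")
        tp <- select_true_positives(lists, net)
        tn <- finalize_negatives(rank_sum_negatives(m, g, cfg$k_negatives),
                                 tp, net)
        write_tsv(data.frame(mirna = c(tp, tn),
                             class = rep(c("TP", "TN"), c(length(tp), length(tn)))),
                  op("labels.tsv"))
        feats <- compute_features(net, m, g,
                                  disease_set = unique(unlist(lists)))
        write_tsv(as.data.frame(feats), op("features.tsv"))
      }),
    train_predict = list(
      inputs = c(op("labels.tsv"), op("features.tsv")),
      outputs = c(op("predictions.tsv"), op("model_summary.json")),
      fun = function() {
        lab <- utils::read.delim(op("labels.tsv"), stringsAsFactors = FALSE)
        feats <- utils::read.delim(op("features.tsv"), stringsAsFactors = FALSE)
        class(feats) <- c("FeatureTable", "data.frame")
        labels <- label_sets(lab$mirna[lab$class == "TP"],
                             lab$mirna[lab$class == "TN"])
        model <- train_classifier(feats, labels, folds = cfg$folds,
                                  ga = cfg$ga,
                                  seed = derive_seed(cfg$seed, "train"))
        thr <- recognition_threshold(model,
                                     feats[feats$mirna %in% labels$tn, ])
        pred <- predict_risk(model, feats, thr)
        write_tsv(pred, op("predictions.tsv"))
        jsonlite::write_json(
          list(log10_cost = model$log10_cost, log10_gamma = model$log10_gamma,
               fold_auc = model$fold_auc, cv_auc = model$cv_auc,
               threshold = thr, n_risk = sum(pred$risk)),
          op("model_summary.json"), auto_unbox = TRUE, digits = NA)
      }),
    overlap = list(
      inputs = c(op("predictions.tsv"), op("filtered_mirna.tsv")),
      outputs = op("overlap.tsv"),
      fun = function() {
        pred <- utils::read.delim(op("predictions.tsv"), stringsAsFactors = FALSE)
        m <- read_expression(op("filtered_mirna.tsv"), "miRNA")
        lists <- lapply(sort(Sys.glob(ip("disease_list_*.txt"))), readLines)
        universe <- feature_ids(m)
        risk <- pred$mirna[pred$risk]
        rows <- lapply(seq_along(lists), function(i) {
          r <- suppressWarnings(overlap_test(risk, lists[[i]], universe))
          data.frame(set = sprintf("disease_list_%d", i), x = r$x, K = r$K,
                     M = r$M, expected = r$expected,
                     overlap_percent = r$overlap_percent, p = r$p_upper)
        })
        ov <- do.call(rbind, rows)
        ov$q <- bh_adjust(ov$p)
        write_tsv(ov, op("overlap.tsv"))
        gmt <- ip("annotation.gmt")
        if (file.exists(gmt)) {
          write_tsv(enrich(risk, read_gmt(gmt), universe), op("enrichment.tsv"))
        }
      }),
    survive = list(
      inputs = c(op("predictions.tsv"), op("filtered_mirna.tsv"),
                 ip("clinical.tsv")),
      outputs = op("survival_screen.tsv"),
      fun = function() {
        pred <- utils::read.delim(op("predictions.tsv"), stringsAsFactors = FALSE)
        m <- read_expression(op("filtered_mirna.tsv"), "miRNA")
        clin <- read_clinical(ip("clinical.tsv"))
        risk <- pred$mirna[pred$risk]
        if (!length(risk)) stop("no predicted risk miRNA to screen")
        scr <- survival_screen(expression_matrix(m[risk, , drop = FALSE], "miRNA"),
                               clin)
        write_tsv(as.data.frame(scr), op("survival_screen.tsv"))
      }),
    associate = list(
      inputs = c(op("predictions.tsv"), op("filtered_mirna.tsv"),
                 ip("abundance.tsv"), ip("cellline_expression.tsv"),
                 ip("ic50.tsv")),
      outputs = c(op("immune_associations.tsv"), op("drug_associations.tsv")),
      fun = function() {
        pred <- utils::read.delim(op("predictions.tsv"), stringsAsFactors = FALSE)
        risk <- pred$mirna[pred$risk]
        m <- read_expression(op("filtered_mirna.tsv"), "miRNA")
        ab <- read_abundance(ip("abundance.tsv"))
        imm <- immune_associations(
          expression_matrix(m[intersect(risk, rownames(m)), , drop = FALSE], "miRNA"), ab)
        write_tsv(as.data.frame(imm), op("immune_associations.tsv"))
        cl <- read_expression(ip("cellline_expression.tsv"), "miRNA")
        ic <- read_drug_response(ip("ic50.tsv"))
        keep <- intersect(risk, feature_ids(cl))
        if (!length(keep)) keep <- feature_ids(cl)
        dr <- drug_associations(expression_matrix(cl[keep, , drop = FALSE], "miRNA"),
                                ic, r_min = cfg$r_min, min_n = cfg$min_n)
        write_tsv(as.data.frame(dr), op("drug_associations.tsv"))
      })
  )
}

.read_network <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  bipartite_network(e$mirna, e$gene)
}

#' Run the full pipeline
#'
#' Executes filter -> dysregulation -> network -> labels/features ->
#' train/predict -> overlap/enrichment -> survival -> associations, each
#' stage reading and writing files under the configured directories so a
#' run is resumable from on-disk intermediates. A manifest (JSON) records,
#' per stage, the parameter echo, input/output MD5 checksums and wall-clock
#' time; identical inputs, config and seed give identical output checksums.
#'
#' @param cfg A [pipeline_config()].
#' @param resume If `TRUE`, stages whose outputs already exist (and whose
#'   upstream stages did not re-run) are skipped.
#' @return The manifest, invisibly; also written to
#'   `output_dir/manifest.json`.
#' @export
run_pipeline <- function(cfg, resume = FALSE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- .stage_defs(cfg)
  manifest <- list(parameters = unclass(cfg)[setdiff(names(unclass(cfg)), "ga")],
                   stages = list())
  upstream_ran <- FALSE
  for (nm in names(stages)) {
    st <- stages[[nm]]
    have <- all(file.exists(st$outputs))
    skip <- resume && have && !upstream_ran
    t0 <- proc.time()[["elapsed"]]
    if (!skip) {
      ok <- tryCatch({ st$fun(); TRUE },
                     error = function(e) {
                       stop(sprintf("stage `%s` failed: %s", nm,
                                    conditionMessage(e)), call. = FALSE)
                     })
      upstream_ran <- TRUE
    }
    manifest$stages[[nm]] <- list(
      status = if (skip) "skipped (resume)" else "completed",
      inputs = as.list(tools::md5sum(st$inputs[file.exists(st$inputs)])),
      outputs = as.list(tools::md5sum(st$outputs[file.exists(st$outputs)])),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
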