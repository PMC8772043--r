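# End-to-end orchestration: stratified split -> per-condition pruning ->
# differential network -> communities -> per-module LR-RFE -> evaluation,
# with a manifest of every artifact and parameter.

#' Assemble and validate a pipeline configuration
#'
#' Inputs may be given as file paths (read through the package's readers) or
#' as in-memory objects. Every parameter of every stage is recorded in the
#' run manifest. Unknown arguments are rejected.
#'
#' The single `seed` fans out deterministically to the stages (split, fold
#' assignment per module, random-panel draws) as `seed + stage offset`, so a
#' whole run is reproducible from the configuration alone.
#'
#' @param expression an [expression_dataset()], or the path of an expression
#'   matrix (then `labels` must be the label-file path).
#' @param background a `grn_network`, or the path of an edge-list TSV.
#' @param labels label-file path when `expression` is a path.
#' @param out_dir directory for artifacts (`NULL` = keep everything in
#'   memory).
#' @param bins_n,bins_strategy binning of the MI/CMI estimators.
#' @param threshold,max_order,max_sets path-consistency pruning controls.
#' @param split_fraction fraction of samples (stratified) used for training;
#'   the rest is the internal validation set.
#' @param n_folds,lambda cross-validation folds and ridge penalty of the
#'   LR-RFE stage.
#' @param min_module_size smallest module passed to biomarker selection.
#' @param n_random_draws random panels per module in the comparison test.
#' @param seed global seed.
#' @return a validated `run_config` list.
#' @export
run_config <- function(expression, background, labels = NULL, out_dir = NULL,
                       bins_n = 3L, bins_strategy = "equal_frequency",
                       threshold = 0.03, max_order = 1L, max_sets = 50L,
                       split_fraction = 0.6, n_folds = 10L, lambda = 1,
                       min_module_size = 1L, n_random_draws = 10L, seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1, threshold >= 0,
            max_order >= 0, lambda > 0, n_folds >= 2, n_random_draws >= 1,
            min_module_size >= 1)
  if (is.character(expression) && is.null(labels))
    stop("labels path required when expression is given as a path")
  structure(
    list(expression = expression, background = background, labels = labels,
         out_dir = out_dir,
         bins_n = as.integer(bins_n), bins_strategy = bins_strategy,
         threshold = threshold, max_order = as.integer(max_order),
         max_sets = as.integer(max_sets),
         split_fraction = split_fraction, n_folds = as.integer(n_folds),
         lambda = lambda, min_module_size = as.integer(min_module_size),
         n_random_draws = as.integer(n_random_draws),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "run_config")
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes, in order: stratified train/validation split; path-consistency
#' pruning of the background network separately on the training samples of
#' each phenotype; differential-network extraction; greedy community
#' detection; per-module biomarker selection by LR-RFE on the training split;
#' panel evaluation (F1, AUC) on the validation split; and the size-matched
#' random-panel comparison. When `out_dir` is set, all intermediate artifacts
#' (condition networks, differential network, module GMT, metrics and
#' manifest JSON) are persisted; identical configuration and seed produce
#' byte-identical metrics files.
#'
#' When the two condition networks show no rewiring the run exits gracefully
#' with status `"no rewiring detected"`.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the fitted objects (`normal_grn`,
#'   `disease_grn`, `dgrn`, `partition`, `panels`), the train/validation
#'   sample split, `metrics`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifact <- function(name) if (is.null(out)) NULL else file.path(out, name)

  data <- if (is.character(config$expression)) {
    read_expression(config$expression, config$labels)
  } else config$expression
  stopifnot(inherits(data, "expression_dataset"))
  background <- if (is.character(config$background)) {
    read_edge_list(config$background)
  } else as_grn_network(config$background)
  log_stage("load", "%d genes, %d samples; background %d nodes / %d edges",
            nrow(data$values), ncol(data$values), length(background$nodes),
            nrow(background$edges))

  # stage 1: stratified split
  train_ids <- with_rng(stage_seed(seed, 1L), {
    unlist(lapply(c(0L, 1L), function(cls) {
      ids <- names(data$labels)[data$labels == cls]
      sample(ids, round(config$split_fraction * length(ids)))
    }), use.names = FALSE)
  })
  valid_ids <- setdiff(names(data$labels), train_ids)
  train <- subset_samples(data, samples = train_ids)
  log_stage("split", "%d training / %d validation samples",
            length(train_ids), length(valid_ids))

  # stage 2: per-condition pruning on training samples
  scheme <- binning_scheme(config$bins_n, config$bins_strategy)
  grns <- lapply(c(normal = 0L, disease = 1L), function(cls) {
    pc_prune(background, subset_samples(train, label = cls),
             threshold = config$threshold, max_order = config$max_order,
             scheme = scheme, max_sets = config$max_sets)
  })
  for (cond in names(grns)) {
    log_stage("prune", "%s GRN: %d nodes, %d edges", cond,
              length(grns[[cond]]$network$nodes),
              nrow(grns[[cond]]$network$edges))
    if (!is.null(out))
      write_network(grns[[cond]], artifact(paste0(cond, "_grn.tsv")))
  }

  # stage 3: differential network
  overlap <- compare_networks(grns$normal, grns$disease)
  dgrn <- withCallingHandlers(
    build_dgrn(grns$normal, grns$disease),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!length(dgrn$seed_nodes)) {
    log_stage("diffnet", "no rewiring detected")
    manifest <- list(status = "no rewiring detected",
                     config = manifest_config(config))
    if (!is.null(out)) write_json_artifact(manifest, artifact("manifest.json"))
    return(invisible(list(status = "no rewiring detected",
                          normal_grn = grns$normal,
                          disease_grn = grns$disease, dgrn = dgrn,
                          manifest = manifest)))
  }
  log_stage("diffnet", "D-GRN: %d nodes (%d seeds), %d edges",
            length(dgrn$network$nodes), length(dgrn$seed_nodes),
            nrow(dgrn$network$edges))
  if (!is.null(out)) {
    write_network(dgrn, artifact("dgrn.tsv"))
    write_json_artifact(overlap$counts, artifact("overlap.json"))
  }

  # stage 4: community detection on the untagged collapse
  partition <- greedy_communities(dgrn)
  modules <- split(names(partition$membership), partition$membership)
  modules <- modules[order(-lengths(modules), names(modules))]
  log_stage("modules", "%d modules, Q = %.4f (sizes: %s)",
            length(modules), partition$modularity,
            paste(lengths(modules), collapse = "/"))
  if (!is.null(out)) {
    write_modules(partition, artifact("modules.gmt"))
    write_json_artifact(partition$merge_history,
                        artifact("merge_history.json"))
  }

  # stage 5: per-module LR-RFE on the training split, evaluated on validation
  Xtr <- t(train$values)
  ytr <- train$labels
  Xva <- t(data$values[, valid_ids, drop = FALSE])
  yva <- data$labels[valid_ids]
  eligible <- modules[lengths(modules) >= config$min_module_size]
  panels <- list()
  for (mid in names(eligible)) {
    genes <- intersect(eligible[[mid]], colnames(Xtr))
    if (length(genes) < 1L) next
    p <- rfe_select(Xtr[, genes, drop = FALSE], ytr, lambda = config$lambda,
                    n_folds = config$n_folds,
                    seed = stage_seed(seed, 10L + match(mid, names(eligible))),
                    module_id = mid)
    p$metrics <- evaluate_panel(p, Xva, yva)
    log_stage("select", "%s: %d -> %d genes, validation F1 %.3f, AUC %.3f",
              mid, length(genes), length(p$genes), p$metrics$f1,
              p$metrics$auc)
    panels[[mid]] <- p
  }

  # stage 6: random-panel comparison
  rnd <- NULL
  if (length(panels) >= 2L) {
    rnd <- random_panel_test(panels, universe = rownames(data$values),
                             X_train = Xtr, y_train = ytr,
                             X_eval = Xva, y_eval = yva,
                             lambda = config$lambda,
                             n_draws = config$n_random_draws,
                             seed = stage_seed(seed, 30L))
    log_stage("random", "signed-rank p = %.4g over %d modules",
              rnd$p_value, length(panels))
  }

  metrics <- list(
    networks = list(
      normal = list(nodes = length(grns$normal$network$nodes),
                    edges = nrow(grns$normal$network$edges)),
      disease = list(nodes = length(grns$disease$network$nodes),
                     edges = nrow(grns$disease$network$edges)),
      overlap = overlap$counts,
      dgrn = list(nodes = length(dgrn$network$nodes),
                  edges = nrow(dgrn$network$edges),
                  seed_genes = length(dgrn$seed_nodes))),
    modularity = partition$modularity,
    module_sizes = as.list(lengths(modules)),
    panels = lapply(panels, function(p) list(
      module = p$module_id, genes = p$genes, n_genes = length(p$genes),
      f1 = p$metrics$f1, auc = p$metrics$auc)),
    random_panel = if (is.null(rnd)) NULL else
      list(p_value = rnd$p_value,
           panel_aucs = rnd$panel_aucs, random_aucs = rnd$random_aucs)
  )
  files <- c("normal_grn.tsv", "disease_grn.tsv", "dgrn.tsv", "modules.gmt",
             "metrics.json")
  manifest <- list(status = "ok", config = manifest_config(config),
                   artifacts = if (is.null(out)) list() else
                     as.list(stats::setNames(file.path(out, files), files)),
                   summary = metrics["networks"])
  if (!is.null(out)) {
    write_json_artifact(metrics, artifact("metrics.json"))
    write_json_artifact(manifest, artifact("manifest.json"))
  }
  invisible(list(status = "ok", train_ids = sort(train_ids),
                 valid_ids = sort(valid_ids),
                 normal_grn = grns$normal, disease_grn = grns$disease,
                 overlap = overlap, dgrn = dgrn, partition = partition,
                 panels = panels, random_panel = rnd, metrics = metrics,
                 manifest = manifest))
}

manifest_config <- function(config) {
  cfg <- unclass(config)
  for (field in c("expression", "background")) {
    if (!is.character(cfg[[field]])) cfg[[field]] <- "<in-memory>"
  }
  cfg
}

# Precision/recall/F1 between two edge-key sets. An empty prediction has
# precision 1 by convention (no false positives were asserted); empty truth
# has recall 1.
edge_set_metrics <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  precision <- if (!length(predicted)) 1 else tp / length(predicted)
  recall <- if (!length(truth)) 1 else tp / length(truth)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(tp = tp, predicted = length(predicted), truth = length(truth),
       precision = precision, recall = recall, f1 = f1)
}

#' Recovery of a condition network against the planted truth
#'
#' Undirected edge-set precision/recall/F1 of an inferred network against a
#' planted true network. An empty inferred network scores precision 1 and
#' recall 0 by convention.
#'
#' @param inferred inferred network (`condition_grn` or `grn_network`).
#' @param truth_net planted true network.
#' @return list with `tp`, `predicted`, `truth`, `precision`, `recall`, `f1`.
#' @export
edge_recovery <- function(inferred, truth_net) {
  edge_set_metrics(undirected_keys(as_grn_network(inferred)),
                   undirected_keys(as_grn_network(truth_net)))
}

#' Score a pipeline run against the synthetic ground truth
#'
#' For a run on an instance from [make_instance()]: undirected edge-recovery
#' precision/recall/F1 of each condition network, detection
#' precision/recall of the planted rewired edges among the differential
#' network's exclusive-tagged edges, the fraction of driver genes captured by
#' the selected panels, and the held-out panel AUCs.
#'
#' @param result return value of [run_pipeline()].
#' @param truth the `synthetic_truth` of the instance.
#' @return list of recovery metrics.
#' @export
evaluate_recovery <- function(result, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  truth_genes <- truth$true_normal$nodes
  seen_genes <- unique(c(as_grn_network(result$normal_grn)$nodes,
                         as_grn_network(result$disease_grn)$nodes))
  if (length(seen_genes) && !length(intersect(truth_genes, seen_genes)))
    stop("gene ids in the run do not match the synthetic truth")
  rec <- list(
    normal = edge_recovery(result$normal_grn, truth$true_normal),
    disease = edge_recovery(result$disease_grn, truth$true_disease))
  true_rw <- pair_key(pmin(truth$rewired_edges$from, truth$rewired_edges$to),
                      pmax(truth$rewired_edges$from, truth$rewired_edges$to))
  dg_ed <- as_grn_network(result$dgrn)$edges
  excl <- dg_ed[dg_ed$condition %in% c("normal_only", "disease_only"), ,
                drop = FALSE]
  rec$rewired <- edge_set_metrics(unique(pair_key(excl$from, excl$to)),
                                  unique(true_rw))
  panel_genes <- unique(unlist(lapply(result$panels, `[[`, "genes")))
  rec$driver_fraction_in_panels <- if (!length(truth$driver_genes)) NA_real_
    else mean(truth$driver_genes %in% panel_genes)
  aucs <- vapply(result$panels, function(p) p$metrics$auc, numeric(1))
  rec$panel_aucs <- aucs
  rec$best_panel_auc <- if (length(aucs)) max(aucs) else NA_real_
  rec$random_panel_p <- if (is.null(result$random_panel)) NA_real_
    else result$random_panel$p_value
  rec
}
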