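# Synthetic benchmark instances: a sparse directed backbone, a pair of
# condition-specific true networks with controlled rewiring, a noisy superset
# background network, and linear-Gaussian structural-equation expression for
# both phenotypes, with the full ground truth retained.

#' Random directed acyclic backbone network
#'
#' Draws `n_edges` edges uniformly at random among the forward pairs of a
#' random topological ordering of `n_genes` genes (`G001`, `G002`, ...), so the
#' result is acyclic by construction.
#'
#' @param n_genes number of genes.
#' @param n_edges number of directed edges (at most `n_genes*(n_genes-1)/2`).
#' @param seed RNG seed; the backbone is bit-identical given it.
#' @return a directed `grn_network`.
#' @export
make_backbone <- function(n_genes = 50L, n_edges = 75L, seed = NULL) {
  n_genes <- as.integer(n_genes); n_edges <- as.integer(n_edges)
  max_edges <- n_genes * (n_genes - 1) / 2
  if (n_edges > max_edges)
    stop("n_edges (", n_edges, ") exceeds the acyclic maximum (", max_edges, ")")
  ids <- sprintf("G%03d", seq_len(n_genes))
  with_rng(seed, {
    topo <- sample(ids)
    picks <- sample.int(max_edges, n_edges)
    # decode the k-th upper-triangular pair (i < j) of the topological order
    j <- ceiling((1 + sqrt(1 + 8 * picks)) / 2)
    i <- picks - (j - 1) * (j - 2) / 2
    grn_network(data.frame(from = topo[i], to = topo[j],
                           type = rep("true", length(i)),
                           stringsAsFactors = FALSE),
                nodes = ids, directed = TRUE)
  })
}

#' Planted condition-specific rewiring of a backbone
#'
#' The normal network is the backbone itself; the disease network replaces
#' `ceiling(rewire_fraction * |E|)` randomly chosen backbone edges with the
#' same number of new random forward edges (with respect to the backbone's
#' topological order, so acyclicity is preserved). The symmetric difference of
#' the two networks is returned tagged `normal_only` / `disease_only`.
#'
#' @param backbone a directed acyclic `grn_network` from [make_backbone()].
#' @param rewire_fraction fraction of backbone edges rewired, in `[0, 1]`.
#' @param seed RNG seed.
#' @return list with `true_normal`, `true_disease` (directed networks) and
#'   `rewired_edges` (data frame `from`, `to`, `tag`).
#' @export
rewire_conditions <- function(backbone, rewire_fraction = 0.2, seed = NULL) {
  stopifnot(rewire_fraction >= 0, rewire_fraction <= 1)
  net <- as_grn_network(backbone)
  topo <- topological_order(net)
  if (is.null(topo)) stop("backbone must be acyclic")
  ed <- net$edges
  n_rw <- ceiling(rewire_fraction * nrow(ed))
  if (n_rw == 0L) {
    return(list(true_normal = net, true_disease = net,
                rewired_edges = data.frame(from = character(),
                                           to = character(),
                                           tag = character(),
                                           stringsAsFactors = FALSE)))
  }
  pos <- match(c(ed$from, ed$to), topo)
  with_rng(seed, {
    removed <- sort(sample.int(nrow(ed), n_rw))
    new_edges <- sample_forward_pairs(topo, n_rw,
                                      exclude = directed_key(ed$from, ed$to))
    dis <- rbind(ed[-removed, c("from", "to")], new_edges)
    dis$type <- "true"
    list(
      true_normal = net,
      true_disease = grn_network(dis, nodes = net$nodes, directed = TRUE),
      rewired_edges = rbind(
        data.frame(from = ed$from[removed], to = ed$to[removed],
                   tag = "normal_only", stringsAsFactors = FALSE),
        data.frame(from = new_edges$from, to = new_edges$to,
                   tag = "disease_only", stringsAsFactors = FALSE))
    )
  })
}

# Draw `n` distinct forward pairs (w.r.t. `topo`) whose directed keys are not
# in `exclude`.
sample_forward_pairs <- function(topo, n, exclude = character()) {
  ng <- length(topo)
  max_edges <- ng * (ng - 1) / 2
  out <- data.frame(from = character(), to = character(),
                    stringsAsFactors = FALSE)
  seen <- exclude
  guard <- 0L
  while (nrow(out) < n) {
    guard <- guard + 1L
    if (guard > 1000L) stop("cannot place ", n, " new acyclic edges")
    picks <- sample.int(max_edges, min(max_edges, 2L * (n - nrow(out))))
    j <- ceiling((1 + sqrt(1 + 8 * picks)) / 2)
    i <- picks - (j - 1) * (j - 2) / 2
    cand <- data.frame(from = topo[i], to = topo[j], stringsAsFactors = FALSE)
    keys <- directed_key(cand$from, cand$to)
    keep <- !(keys %in% seen) & !duplicated(keys)
    cand <- cand[keep, , drop = FALSE]
    seen <- c(seen, keys[keep])
    out <- rbind(out, cand)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate expression from a linear-Gaussian structural-equation model
#'
#' Each gene is a weighted sum of its network parents plus independent
#' Gaussian noise, evaluated in topological order; root genes are pure noise.
#' Unless supplied, edge weights are drawn once per call, uniformly in
#' `[weight_range[1], weight_range[2]]` in magnitude with random sign. An
#' optional per-gene `baseline` (intercept) shifts a gene's mean — and,
#' through the network, the means of its descendants.
#'
#' @param net a directed acyclic `grn_network`.
#' @param n_samples number of samples to draw.
#' @param weight_range magnitude range of edge weights.
#' @param noise_sd standard deviation of every gene's noise term (> 0).
#' @param seed RNG seed; output is bit-identical given it.
#' @param weights optional named vector of edge weights, names
#'   `"from\x1fto"` as produced by internal edge keys; missing edges are drawn.
#' @param baseline optional named per-gene intercept vector (default 0).
#' @param label phenotype label (0/1) assigned to every sample.
#' @param sample_prefix prefix for generated sample ids.
#' @return an [expression_dataset()] (genes x samples); the drawn weights are
#'   attached as attribute `"weights"`.
#' @export
simulate_expression <- function(net, n_samples = 200L,
                                weight_range = c(0.6, 1.2), noise_sd = 1,
                                seed = NULL, weights = NULL, baseline = NULL,
                                label = 0L, sample_prefix = "S") {
  net <- as_grn_network(net)
  stopifnot(noise_sd > 0)
  topo <- topological_order(net)
  if (is.null(topo)) stop("expression simulation requires an acyclic network")
  ed <- net$edges
  keys <- directed_key(ed$from, ed$to)
  with_rng(seed, {
    w <- stats::setNames(
      stats::runif(nrow(ed), weight_range[1], weight_range[2]) *
        sample(c(-1, 1), nrow(ed), replace = TRUE),
      keys)
    if (!is.null(weights)) {
      have <- intersect(keys, names(weights))
      w[have] <- weights[have]
    }
    b <- stats::setNames(numeric(length(net$nodes)), net$nodes)
    if (!is.null(baseline)) b[names(baseline)] <- baseline
    X <- matrix(stats::rnorm(length(net$nodes) * n_samples, sd = noise_sd),
                nrow = length(net$nodes),
                dimnames = list(net$nodes,
                                paste0(sample_prefix, seq_len(n_samples))))
    X <- X + b
    parents <- split(seq_len(nrow(ed)), ed$to)
    for (g in topo) {
      for (r in parents[[g]]) {
        X[g, ] <- X[g, ] + w[r] * X[ed$from[r], ]
      }
    }
    ds <- expression_dataset(X, rep(as.integer(label), n_samples))
    attr(ds, "weights") <- w
    ds
  })
}

#' Closed-form covariance of the structural-equation model
#'
#' For `x = A x + b + e` with `A[child, parent]` the weight matrix and
#' independent noise of standard deviation `noise_sd`, the population
#' covariance is `(I - A)^-1 (noise_sd^2 I) (I - A)^-T`. Used to validate the
#' simulator against its own generative law.
#'
#' @param net a directed acyclic `grn_network`.
#' @param weights named edge-weight vector as attached by
#'   [simulate_expression()].
#' @param noise_sd noise standard deviation.
#' @return covariance matrix over `net$nodes`.
#' @export
sem_covariance <- function(net, weights, noise_sd = 1) {
  net <- as_grn_network(net)
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  ed <- net$edges
  keys <- directed_key(ed$from, ed$to)
  A[cbind(match(ed$to, net$nodes), match(ed$from, net$nodes))] <- weights[keys]
  M <- solve(diag(n) - A)
  noise_sd^2 * M %*% t(M)
}

#' Generate a complete synthetic benchmark instance
#'
#' Builds a backbone, plants condition-specific rewiring, adds spurious
#' background edges (random forward pairs used by neither generative model),
#' and simulates labeled expression for both phenotypes. Edge weights are
#' drawn once over the union of true edges and shared across conditions, so
#' the between-class distributional shift is carried by the rewired edges and
#' by the driver genes, which additionally receive a disease-condition
#' baseline shift of magnitude `shift_magnitude` (random sign) — emulating the
#' differential expression of rewired-module genes in case-control data.
#'
#' @param n_genes,n_edges backbone size.
#' @param rewire_fraction fraction of backbone edges rewired in disease.
#' @param spurious_fraction spurious background edges as a fraction of
#'   backbone edges.
#' @param n_samples samples per condition.
#' @param weight_range,noise_sd structural-equation parameters.
#' @param shift_magnitude disease-condition baseline shift applied to driver
#'   genes, in the same units as the expression values.
#' @param seed RNG seed; the whole instance is reproducible from the
#'   parameters plus this seed.
#' @return list with `background` (`grn_network`, edge attribute `type` in
#'   `{true, spurious}`), `data` (an [expression_dataset()] holding both
#'   conditions), and `truth` (class `synthetic_truth`: `true_normal`,
#'   `true_disease`, `background`, `rewired_edges`, `driver_genes`, `weights`,
#'   `params`).
#' @export
make_instance <- function(n_genes = 50L, n_edges = 75L, rewire_fraction = 0.2,
                          spurious_fraction = 0.5, n_samples = 200L,
                          weight_range = c(0.6, 1.2), noise_sd = 1,
                          shift_magnitude = 1, seed = NULL) {
  params <- list(n_genes = as.integer(n_genes), n_edges = as.integer(n_edges),
                 rewire_fraction = rewire_fraction,
                 spurious_fraction = spurious_fraction,
                 n_samples = as.integer(n_samples),
                 weight_range = weight_range, noise_sd = noise_sd,
                 shift_magnitude = shift_magnitude, seed = seed)
  backbone <- make_backbone(n_genes, n_edges, seed = stage_seed(seed, 0L))
  rw <- rewire_conditions(backbone, rewire_fraction,
                          seed = stage_seed(seed, 1L))
  union_ed <- rbind(rw$true_normal$edges[, c("from", "to")],
                    rw$true_disease$edges[, c("from", "to")])
  union_ed <- union_ed[!duplicated(directed_key(union_ed$from, union_ed$to)), ]
  topo <- topological_order(backbone)
  n_spur <- ceiling(spurious_fraction * nrow(backbone$edges))
  spurious <- with_rng(stage_seed(seed, 2L), {
    if (n_spur > 0L)
      sample_forward_pairs(topo, n_spur,
                           exclude = directed_key(union_ed$from, union_ed$to))
    else data.frame(from = character(), to = character(),
                    stringsAsFactors = FALSE)
  })
  bg_ed <- rbind(
    data.frame(union_ed, type = "true", stringsAsFactors = FALSE),
    if (nrow(spurious))
      data.frame(spurious, type = "spurious", stringsAsFactors = FALSE))
  background <- grn_network(bg_ed, nodes = backbone$nodes, directed = TRUE)

  # one weight per union edge, shared across conditions
  weights <- with_rng(stage_seed(seed, 3L), {
    stats::setNames(
      stats::runif(nrow(union_ed), weight_range[1], weight_range[2]) *
        sample(c(-1, 1), nrow(union_ed), replace = TRUE),
      directed_key(union_ed$from, union_ed$to))
  })
  drivers <- sort(unique(c(rw$rewired_edges$from, rw$rewired_edges$to)))
  shift <- with_rng(stage_seed(seed, 4L), {
    stats::setNames(shift_magnitude *
                      sample(c(-1, 1), length(drivers), replace = TRUE),
                    drivers)
  })
  normal <- simulate_expression(rw$true_normal, n_samples, weight_range,
                                noise_sd, seed = stage_seed(seed, 5L),
                                weights = weights, label = 0L,
                                sample_prefix = "N")
  disease <- simulate_expression(rw$true_disease, n_samples, weight_range,
                                 noise_sd, seed = stage_seed(seed, 6L),
                                 weights = weights, baseline = shift,
                                 label = 1L, sample_prefix = "D")
  data <- expression_dataset(cbind(normal$values, disease$values),
                             c(normal$labels, disease$labels))
  truth <- structure(
    list(true_normal = rw$true_normal, true_disease = rw$true_disease,
         background = background, rewired_edges = rw$rewired_edges,
         driver_genes = drivers, weights = weights, baseline_shift = shift,
         params = params),
    class = "synthetic_truth")
  list(background = background, data = data, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic_truth: %d genes; normal %d / disease %d true edges, %d rewired; background %d edges\n",
    x$params$n_genes, nrow(x$true_normal$edges), nrow(x$true_disease$edges),
    nrow(x$rewired_edges), nrow(x$background$edges)))
  invisible(x)
}

#' Write a synthetic instance to disk in the pipeline's input formats
#'
#' Emits `background.tsv`, `expression.tsv`, `labels.tsv` and `truth.json`
#' into a directory, so the file-based pipeline runs unchanged on synthetic
#' instances.
#'
#' @param instance result of [make_instance()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_instance <- function(instance, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(instance$background, file.path(dir, "background.tsv"))
  vals <- instance$data$values
  df <- data.frame(gene = rownames(vals), vals, check.names = FALSE)
  utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(instance$data$labels),
               label = instance$data$labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  tr <- instance$truth
  write_json_artifact(list(
    params = tr$params,
    true_normal = tr$true_normal$edges[, c("from", "to")],
    true_disease = tr$true_disease$edges[, c("from", "to")],
    rewired_edges = tr$rewired_edges,
    driver_genes = tr$driver_genes
  ), file.path(dir, "truth.json"))
  invisible(dir)
}
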