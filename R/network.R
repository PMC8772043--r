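#' Gene regulatory network container
#'
#' A light-weight edge-list container for regulatory networks. Edges are stored
#' as a data frame with columns `from` and `to` plus optional attribute columns
#' (`type`, `condition`, ...). Direction is kept as metadata: all analysis
#' operations in this package (mutual-information pruning, differential-network
#' extraction, community detection) work on the undirected collapse, one edge
#' per unordered pair, because the information-theoretic statistics are
#' symmetric.
#'
#' Self-loops are dropped and exact duplicate `(from, to)` rows are
#' de-duplicated on construction; the node set is the union of `nodes` and all
#' edge endpoints.
#'
#' @param edges data frame with character columns `from` and `to` (may have
#'   zero rows), plus optional attribute columns.
#' @param nodes optional character vector of node ids to include even when
#'   isolated.
#' @param directed logical; whether the `from -> to` orientation is meaningful.
#' @return an object of class `grn_network` with elements `nodes`, `edges`,
#'   `directed`.
#' @examples
#' net <- grn_network(data.frame(from = c("A", "B"), to = c("B", "C")))
#' net$nodes
#' @export
grn_network <- function(edges = NULL, nodes = NULL, directed = TRUE) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges$from <- trimws(as.character(edges$from))
  edges$to <- trimws(as.character(edges$to))
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  edges <- edges[!duplicated(directed_key(edges$from, edges$to)), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(trimws(as.character(nodes %||% character())),
                         edges$from, edges$to)))
  structure(
    list(nodes = nodes, edges = edges, directed = isTRUE(directed)),
    class = "grn_network"
  )
}

#' Coerce to a grn_network
#'
#' Extracts the plain network from richer objects such as pruned
#' condition-specific networks ([pc_prune()]) or differential networks
#' ([build_dgrn()]).
#'
#' @param x object to coerce.
#' @return a `grn_network`.
#' @export
as_grn_network <- function(x) {
  if (inherits(x, "grn_network")) return(x)
  if (inherits(x, c("condition_grn", "differential_grn"))) return(x$network)
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("grn_network: %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

# Undirected collapse: unique unordered pairs with u < v (lexicographic).
# Attribute columns are carried from the first occurrence of each pair.
undirected_edges <- function(net) {
  net <- as_grn_network(net)
  ed <- net$edges
  if (nrow(ed) == 0L) {
    return(data.frame(u = character(), v = character(),
                      stringsAsFactors = FALSE))
  }
  u <- pmin(ed$from, ed$to)
  v <- pmax(ed$from, ed$to)
  keep <- !duplicated(paste(u, v, sep = "\x1f"))
  out <- data.frame(u = u[keep], v = v[keep], stringsAsFactors = FALSE)
  extra <- setdiff(names(ed), c("from", "to"))
  for (col in extra) out[[col]] <- ed[[col]][keep]
  out <- out[order(out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

undirected_keys <- function(net) {
  ue <- undirected_edges(net)
  pair_key(ue$u, ue$v)
}

# Named list: node -> sorted character vector of undirected neighbors.
# Nodes without edges map to character(0).
adjacency_list <- function(net) {
  net <- as_grn_network(net)
  ue <- undirected_edges(net)
  adj <- stats::setNames(
    lapply(net$nodes, function(n) character()), net$nodes)
  if (nrow(ue)) {
    for (i in seq_len(nrow(ue))) {
      adj[[ue$u[i]]] <- c(adj[[ue$u[i]]], ue$v[i])
      adj[[ue$v[i]]] <- c(adj[[ue$v[i]]], ue$u[i])
    }
    adj <- lapply(adj, sort)
  }
  adj
}

#' Topological order of a directed network
#'
#' Kahn's algorithm on the directed edge set. Used to verify acyclicity of
#' simulated backbones and to evaluate the structural-equation model in
#' ancestral order.
#'
#' @param net a directed `grn_network`.
#' @return character vector of node ids in topological order, or `NULL` when
#'   the network contains a directed cycle.
#' @export
topological_order <- function(net) {
  net <- as_grn_network(net)
  if (!net$directed) stop("topological order is defined for directed networks")
  nodes <- net$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  out <- stats::setNames(lapply(nodes, function(n) character()), nodes)
  for (i in seq_len(nrow(net$edges))) {
    f <- net$edges$from[i]; t <- net$edges$to[i]
    indeg[[t]] <- indeg[[t]] + 1L
    out[[f]] <- c(out[[f]], t)
  }
  queue <- sort(names(indeg)[indeg == 0L])
  order <- character(0)
  while (length(queue)) {
    n <- queue[1L]; queue <- queue[-1L]
    order <- c(order, n)
    for (m in out[[n]]) {
      indeg[[m]] <- indeg[[m]] - 1L
      if (indeg[[m]] == 0L) queue <- sort(c(queue, m))
    }
  }
  if (length(order) != length(nodes)) return(NULL)
  order
}

#' Expression dataset with binary phenotype labels
#'
#' Container for a genes-by-samples numeric matrix and a per-sample binary
#' phenotype (0 = normal, 1 = disease). Values are expected on a continuous,
#' pre-normalized scale (e.g. mean-centered log expression); the package never
#' normalizes raw counts.
#'
#' Genes whose expression is constant across all samples are flagged (attribute
#' `zero_variance`): they carry no information for any downstream statistic.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All entries must be finite.
#' @param labels integer/numeric vector of 0/1, either named by sample id or in
#'   column order of `values`.
#' @return an object of class `expression_dataset` with elements `values`,
#'   `labels` (named integer vector) and `zero_variance` (character vector).
#' @export
expression_dataset <- function(values, labels) {
  stopifnot(is.matrix(values), is.numeric(values))
  genes <- rownames(values); samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(samples)) stop("duplicate sample ids in expression matrix")
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (is.null(names(labels))) {
    if (length(labels) != ncol(values))
      stop("unnamed labels must match the number of samples")
    names(labels) <- samples
  }
  missing <- setdiff(samples, names(labels))
  if (length(missing))
    stop("no phenotype label for sample(s): ", paste(missing, collapse = ", "))
  labels <- labels[samples]
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0 (normal) / 1 (disease)")
  zv <- genes[apply(values, 1L, function(r) diff(range(r)) == 0)]
  structure(
    list(values = values, labels = stats::setNames(as.integer(labels), samples),
         zero_variance = zv),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes x %d samples (%d normal / %d disease)\n",
    nrow(x$values), ncol(x$values), sum(x$labels == 0L), sum(x$labels == 1L)))
  if (length(x$zero_variance))
    cat(" zero-variance genes:", length(x$zero_variance), "\n")
  invisible(x)
}

#' Subset an expression dataset by phenotype or by sample ids
#'
#' @param data an `expression_dataset`.
#' @param label keep samples with this phenotype label (0 or 1); ignored when
#'   `samples` is given.
#' @param samples character vector of sample ids to keep.
#' @return an `expression_dataset` restricted to the selected samples.
#' @export
subset_samples <- function(data, label = NULL, samples = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  if (is.null(samples)) {
    stopifnot(!is.null(label))
    samples <- names(data$labels)[data$labels == label]
  }
  expression_dataset(data$values[, samples, drop = FALSE],
                     data$labels[samples])
}
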