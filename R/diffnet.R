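# Differential-network extraction: compare the two condition-specific GRNs and
# build the rewired network (seed genes with changed connections, plus their
# neighbors, with condition-tagged edges).

#' Overlap report between two condition-specific networks
#'
#' Counts shared and exclusive nodes and undirected edges between the normal
#' and disease networks. Swapping the arguments exchanges the two exclusive
#' sets and nothing else.
#'
#' @param normal,disease `grn_network` or `condition_grn` objects.
#' @return list with `shared_nodes`, `shared_edges` (data frame `u`, `v`),
#'   `normal_only_edges`, `disease_only_edges`, and a `counts` summary.
#' @export
compare_networks <- function(normal, disease) {
  n <- as_grn_network(normal)
  d <- as_grn_network(disease)
  if (!nrow(n$edges) || !nrow(d$edges))
    stop("both networks must be non-empty")
  nk <- undirected_keys(n)
  dk <- undirected_keys(d)
  shared <- intersect(nk, dk)
  res <- list(
    shared_nodes = intersect(n$nodes, d$nodes),
    shared_edges = split_pair_key(shared),
    normal_only_edges = split_pair_key(setdiff(nk, dk)),
    disease_only_edges = split_pair_key(setdiff(dk, nk))
  )
  res$counts <- list(
    normal_nodes = length(n$nodes), disease_nodes = length(d$nodes),
    shared_nodes = length(res$shared_nodes),
    normal_edges = length(nk), disease_edges = length(dk),
    shared_edges = length(shared),
    normal_only = nrow(res$normal_only_edges),
    disease_only = nrow(res$disease_only_edges)
  )
  res
}

#' Build the differential gene regulatory network (D-GRN)
#'
#' Seed genes are genes present in *both* condition networks whose undirected
#' neighbor sets differ — the genes whose regulation is rewired between
#' phenotypes. The D-GRN node set is the seeds plus all their neighbors in
#' either network; its edge set is every edge of either network induced on
#' that node set, tagged `common`, `normal_only` or `disease_only` by
#' condition membership.
#'
#' When no gene is rewired the result is an empty network (with a warning).
#'
#' @param normal,disease `grn_network` or `condition_grn` objects.
#' @return object of class `differential_grn`: `network` (undirected, with a
#'   `condition` edge attribute), `seed_nodes`, `neighbor_nodes`.
#' @export
build_dgrn <- function(normal, disease) {
  n <- as_grn_network(normal)
  d <- as_grn_network(disease)
  adj_n <- adjacency_list(n)
  adj_d <- adjacency_list(d)
  shared <- intersect(n$nodes, d$nodes)
  seeds <- shared[vapply(shared, function(g) {
    !identical(adj_n[[g]], adj_d[[g]])
  }, logical(1))]
  if (!length(seeds)) {
    warning("no rewiring detected: condition networks have identical ",
            "connections for all shared genes")
    return(structure(
      list(network = grn_network(directed = FALSE),
           seed_nodes = character(), neighbor_nodes = character()),
      class = "differential_grn"))
  }
  neighbors <- unique(c(unlist(adj_n[seeds], use.names = FALSE),
                        unlist(adj_d[seeds], use.names = FALSE)))
  nodes <- sort(unique(c(seeds, neighbors)))
  nk <- undirected_keys(n)
  dk <- undirected_keys(d)
  all_edges <- split_pair_key(union(nk, dk))
  keep <- all_edges$u %in% nodes & all_edges$v %in% nodes
  ed <- all_edges[keep, , drop = FALSE]
  keys <- pair_key(ed$u, ed$v)
  ed$condition <- ifelse(keys %in% nk & keys %in% dk, "common",
                         ifelse(keys %in% nk, "normal_only", "disease_only"))
  net <- grn_network(
    data.frame(from = ed$u, to = ed$v, condition = ed$condition,
               stringsAsFactors = FALSE),
    directed = FALSE)
  structure(
    list(network = net, seed_nodes = sort(seeds),
         neighbor_nodes = sort(setdiff(nodes, seeds))),
    class = "differential_grn")
}

#' @export
print.differential_grn <- function(x, ...) {
  tab <- table(factor(x$network$edges$condition,
                      levels = c("common", "normal_only", "disease_only")))
  cat(sprintf(
    "differential_grn: %d nodes (%d rewired seeds), %d edges (%d common, %d normal-only, %d disease-only)\n",
    length(x$network$nodes), length(x$seed_nodes), nrow(x$network$edges),
    tab[["common"]], tab[["normal_only"]], tab[["disease_only"]]))
  invisible(x)
}
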