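# Module detection by greedy agglomerative modularity maximization
# (merge-from-singletons, pick the partition along the merge path with the
# largest Q).

#' Modularity of a partition
#'
#' `Q = sum_i (e_ii - a_i^2)` on the undirected, unweighted collapse of the
#' graph, where `e_ii` is the fraction of edges inside module `i`, a
#' cross-module edge contributes 1/2 to `e_ij` and 1/2 to `e_ji`, and
#' `a_i = sum_j e_ij` (the fraction of edge endpoints in module `i`).
#'
#' @param graph a `grn_network` (or coercible object) with at least one edge.
#' @param membership named vector mapping every node of `graph` to a module
#'   id.
#' @return modularity Q in `[-1, 1]`.
#' @export
modularity_q <- function(graph, membership) {
  net <- as_grn_network(graph)
  ue <- undirected_edges(net)
  if (!nrow(ue)) stop("modularity is undefined on an edgeless graph")
  missing <- setdiff(net$nodes, names(membership))
  if (length(missing))
    stop("membership does not cover node(s): ", paste(missing, collapse = ", "))
  m <- nrow(ue)
  mods <- unique(as.character(membership[net$nodes]))
  mu <- as.character(membership[ue$u])
  mv <- as.character(membership[ue$v])
  e_ii <- vapply(mods, function(g) sum(mu == g & mv == g), numeric(1)) / m
  # a_i: fraction of edge endpoints in module i
  ends <- table(factor(c(mu, mv), levels = mods))
  a_i <- as.numeric(ends) / (2 * m)
  sum(e_ii - a_i^2)
}

#' Greedy community detection by modularity maximization
#'
#' Starts from singleton modules and repeatedly merges the connected module
#' pair with the largest modularity gain `dQ = 2 (e_ij - a_i a_j)` until no
#' connected pair remains (disconnected modules are never merged: their gain
#' is always negative). The returned partition is the one along the merge
#' path with maximum Q. Ties in `dQ` are broken deterministically toward the
#' lexicographically smallest module pair, modules being identified by their
#' smallest contained node id.
#'
#' @param graph a `grn_network` (or coercible, e.g. a `differential_grn`,
#'   whose condition tags are ignored) with at least one edge.
#' @return object of class `module_partition`: `membership` (named vector
#'   node -> module id `"M1" ...`, modules numbered by decreasing size),
#'   `modularity` (Q of the returned partition), and `merge_history` (data
#'   frame `module_a`, `module_b`, `q_after`).
#' @export
greedy_communities <- function(graph) {
  net <- as_grn_network(graph)
  ue <- undirected_edges(net)
  if (!nrow(ue)) stop("community detection needs at least one edge")
  nodes <- net$nodes
  n <- length(nodes)
  m <- nrow(ue)
  iu <- match(ue$u, nodes)
  iv <- match(ue$v, nodes)

  # e[i, j]: half the fraction of edges between modules i and j (off-diagonal),
  # fraction within module i on the diagonal.
  e <- matrix(0, n, n)
  for (r in seq_len(m)) {
    e[iu[r], iv[r]] <- e[iu[r], iv[r]] + 0.5 / m
    e[iv[r], iu[r]] <- e[iv[r], iu[r]] + 0.5 / m
  }
  a <- rowSums(e)
  active <- rep(TRUE, n)
  label <- nodes                      # smallest contained node id per module
  comp <- seq_len(n)                  # node -> module slot
  q <- sum(diag(e)[active] - a[active]^2)

  best_q <- q
  best_comp <- comp
  hist_a <- character(0); hist_b <- character(0); hist_q <- numeric(0)

  repeat {
    dq <- 2 * (e - outer(a, a))
    cand <- which(upper.tri(e) & e > 0 & outer(active, active, `&`),
                  arr.ind = TRUE)
    if (!nrow(cand)) break
    gains <- dq[cand]
    top <- which(gains == max(gains))
    if (length(top) > 1L) {
      la <- pmin(label[cand[top, 1L]], label[cand[top, 2L]])
      lb <- pmax(label[cand[top, 1L]], label[cand[top, 2L]])
      top <- top[order(la, lb)][1L]
    }
    i <- cand[top, 1L]; j <- cand[top, 2L]
    if (label[j] < label[i]) { tmp <- i; i <- j; j <- tmp }
    q <- q + dq[i, j]
    hist_a <- c(hist_a, label[i]); hist_b <- c(hist_b, label[j])
    hist_q <- c(hist_q, q)
    # merge module j into i
    new_row <- e[i, ] + e[j, ]
    new_row[i] <- e[i, i] + e[j, j] + 2 * e[i, j]
    new_row[j] <- 0
    e[i, ] <- new_row; e[, i] <- new_row
    e[j, ] <- 0; e[, j] <- 0
    a[i] <- a[i] + a[j]; a[j] <- 0
    active[j] <- FALSE
    comp[comp == j] <- i
    if (q > best_q + 1e-15) { best_q <- q; best_comp <- comp }
  }

  # relabel best partition: M1.. by decreasing size, ties by smallest node id
  groups <- split(nodes, best_comp)
  ord <- order(-lengths(groups),
               vapply(groups, function(g) min(g), character(1)))
  groups <- groups[ord]
  membership <- character(n); names(membership) <- nodes
  for (k in seq_along(groups)) membership[groups[[k]]] <- paste0("M", k)
  structure(
    list(membership = membership,
         modularity = modularity_q(net, membership),
         merge_history = data.frame(module_a = hist_a, module_b = hist_b,
                                    q_after = hist_q,
                                    stringsAsFactors = FALSE)),
    class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- sort(table(x$membership), decreasing = TRUE)
  cat(sprintf("module_partition: %d modules over %d nodes, Q = %.4f\n",
              length(sizes), length(x$membership), x$modularity))
  cat(" sizes:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
      "\n")
  invisible(x)
}
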