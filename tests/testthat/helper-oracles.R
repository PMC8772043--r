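# Independent oracles used across the suite. These re-derive expected values
# by brute force / enumeration and must stay independent of the package's
# implementation paths.

# Brute-force plug-in MI over every cell of the empirical joint table of two
# 0-based index vectors.
brute_mi <- function(ix, iy) {
  n <- length(ix)
  total <- 0
  for (a in sort(unique(ix))) {
    for (b in sort(unique(iy))) {
      pij <- sum(ix == a & iy == b) / n
      if (pij == 0) next
      total <- total + pij * log(pij / ((sum(ix == a) / n) * (sum(iy == b) / n)))
    }
  }
  total
}

# Brute-force plug-in CMI via the direct triple sum
# sum_{ijk} p(i,j,k) log[ p(k) p(i,j,k) / (p(i,k) p(j,k)) ].
brute_cmi <- function(ix, iy, iz) {
  n <- length(ix)
  total <- 0
  for (a in sort(unique(ix))) {
    for (b in sort(unique(iy))) {
      for (c in sort(unique(iz))) {
        pijk <- sum(ix == a & iy == b & iz == c) / n
        if (pijk == 0) next
        pk <- sum(iz == c) / n
        pik <- sum(ix == a & iz == c) / n
        pjk <- sum(iy == b & iz == c) / n
        total <- total + pijk * log(pk * pijk / (pik * pjk))
      }
    }
  }
  total
}

# Brute-force AUC: concordance over all positive-negative pairs, ties 1/2.
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# All set partitions of a vector (restricted-growth enumeration); feasible up
# to ~10 elements. Returns a list of integer membership vectors.
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxval) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxval + 1L)) grow(c(prefix, v), max(maxval, v))
  }
  grow(integer(0), 0L)
  out
}

# Exhaustive-search maximum modularity over all partitions of a small graph.
exhaustive_best_partition <- function(graph) {
  nodes <- graph$nodes
  best_q <- -Inf
  best <- NULL
  for (memb in all_partitions(length(nodes))) {
    q <- modularity_q(graph, stats::setNames(memb, nodes))
    if (q > best_q) { best_q <- q; best <- memb }
  }
  list(q = best_q, membership = stats::setNames(best, nodes))
}

# Canonical form of a partition for comparisons up to relabeling: sorted list
# of sorted member groups.
partition_groups <- function(membership) {
  unname(lapply(sort(vapply(split(names(membership), membership),
                            function(g) paste(sort(g), collapse = ","),
                            character(1))),
                identity))
}

# Tiny deterministic toy networks used in several files.
toy_net <- function(pairs, directed = TRUE) {
  grn_network(data.frame(from = vapply(pairs, `[`, character(1), 1L),
                         to = vapply(pairs, `[`, character(1), 2L),
                         stringsAsFactors = FALSE),
              directed = directed)
}

two_triangles <- function() {
  toy_net(list(c("A", "B"), c("B", "C"), c("A", "C"),
               c("D", "E"), c("E", "F"), c("D", "F")), directed = FALSE)
}
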