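# Spanning tree of strongest PLI connections (Kruskal) and the global and
# regional tree metrics: degree, leaf number/fraction L_f = L/m, diameter d
# (bounded by d_max = m - L + 2), betweenness centrality (BC, normalized so
# the hub of a star attains exactly 1), Newman degree correlation R, and
# regional (anterior/posterior) mean BC.

#' Spanning tree container
#'
#' A labelled tree on `N` nodes with exactly `N - 1` weighted edges;
#' connectivity and acyclicity are validated on construction.
#'
#' @param labels character vector of node labels.
#' @param edges data frame with columns `from`, `to` (labels) and `weight`.
#' @return Object of class `spanning_tree`.
#' @export
spanning_tree <- function(labels, edges) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 2L) stop("a tree needs at least 2 nodes")
  if (anyDuplicated(labels)) stop("duplicate node labels")
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "weight") %in% names(edges)))
  if (nrow(edges) != n - 1L)
    stop("tree on ", n, " nodes must have ", n - 1L, " edges, got ", nrow(edges))
  fi <- match(edges$from, labels)
  ti <- match(edges$to, labels)
  if (anyNA(fi) || anyNA(ti)) stop("edge endpoint not among node labels")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_len(nrow(edges))) {
    a <- find(fi[e]); b <- find(ti[e])
    if (a == b) stop("edges contain a cycle; not a tree")
    parent[a] <- b
  }
  structure(list(labels = labels,
                 edges = data.frame(from = as.character(edges$from),
                                    to = as.character(edges$to),
                                    weight = as.numeric(edges$weight),
                                    stringsAsFactors = FALSE),
                 n = n),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat("<spanning_tree>", x$n, "nodes,", nrow(x$edges), "edges, total weight",
      round(sum(x$edges$weight), 4), "\n")
  invisible(x)
}

# Integer adjacency list.
tree_adjacency <- function(tree) {
  fi <- match(tree$edges$from, tree$labels)
  ti <- match(tree$edges$to, tree$labels)
  adj <- vector("list", tree$n)
  for (e in seq_along(fi)) {
    adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
    adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
  }
  adj
}

#' Maximum spanning tree of a connectivity matrix (Kruskal)
#'
#' Orders all edges by weight and greedily connects the strongest ones,
#' skipping any edge that would close a loop, until all nodes are joined by
#' `N - 1` edges.  Equal weights are broken lexicographically by the label
#' pair, making the tree reproducible across platforms.  The result equals
#' the minimum spanning tree under the weight transform `w -> 1 - w`.
#'
#' @param mat a [conn_matrix()] or symmetric numeric matrix with dimnames.
#' @return A [spanning_tree()]; for 19-channel PLI matrices, 19 nodes and
#'   18 edges.
#' @export
max_spanning_tree <- function(mat) {
  if (inherits(mat, "conn_matrix")) {
    labels <- mat$labels
    v <- mat$values
  } else {
    v <- as.matrix(mat)
    labels <- rownames(v)
    if (is.null(labels)) labels <- paste0("N", seq_len(nrow(v)))
  }
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 nodes")
  idx <- which(upper.tri(v), arr.ind = TRUE)
  w <- v[upper.tri(v)]
  pos <- w > 0
  idx <- idx[pos, , drop = FALSE]
  w <- w[pos]
  ord <- order(-w, labels[idx[, 1L]], labels[idx[, 2L]], method = "radix")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  keep <- integer(0L)
  for (e in ord) {
    a <- find(idx[e, 1L]); b <- find(idx[e, 2L])
    if (a != b) {
      parent[a] <- b
      keep <- c(keep, e)
      if (length(keep) == n - 1L) break
    }
  }
  if (length(keep) != n - 1L)
    stop("graph is disconnected at positive weights; no spanning tree")
  spanning_tree(labels,
                data.frame(from = labels[idx[keep, 1L]],
                           to = labels[idx[keep, 2L]],
                           weight = w[keep], stringsAsFactors = FALSE))
}

#' Node degrees and maximum degree
#'
#' @param tree a [spanning_tree()].
#' @return List with `degrees` (named integer vector, summing to
#'   `2 (N - 1)`) and `max_degree`.
#' @export
degree_metrics <- function(tree) {
  stopifnot(inherits(tree, "spanning_tree"))
  deg <- tabulate(c(match(tree$edges$from, tree$labels),
                    match(tree$edges$to, tree$labels)), nbins = tree$n)
  names(deg) <- tree$labels
  list(degrees = deg, max_degree = max(deg))
}

#' Leaf number and leaf fraction
#'
#' Leaves are degree-1 nodes; the leaf fraction is `L_f = L / m` with
#' `m = N - 1` edges.  `L` ranges from 2 (path) to `m` (star).
#'
#' @param tree a [spanning_tree()].
#' @return List with `leaf_number` and `leaf_fraction`.
#' @export
leaf_metrics <- function(tree) {
  deg <- degree_metrics(tree)$degrees
  L <- sum(deg == 1L)
  list(leaf_number = L, leaf_fraction = L / (tree$n - 1L))
}

# Hop distances from one node by BFS.
bfs_hops <- function(adj, start, n) {
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- start
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[u]]) if (is.na(dist[v])) {
      dist[v] <- dist[u] + 1L
      queue <- c(queue, v)
    }
  }
  dist
}

#' Tree diameter in hops
#'
#' Largest shortest-path edge count between any two nodes; satisfies
#' `d <= m - L + 2`.
#'
#' @param tree a [spanning_tree()].
#' @return Integer number of hops.
#' @export
tree_diameter <- function(tree) {
  adj <- tree_adjacency(tree)
  # double BFS: farthest node from an arbitrary start, then its eccentricity
  d1 <- bfs_hops(adj, 1L, tree$n)
  far <- which.max(d1)
  max(bfs_hops(adj, far, tree$n))
}

#' Betweenness centrality on a tree
#'
#' On a tree the path between any node pair is unique, so the BC of node `u`
#' is the number of pairs whose path crosses `u`, divided by the number of
#' pairs not involving `u`, `(N - 1)(N - 2) / 2`.  Leaves score 0 and the
#' hub of a star scores exactly 1.
#'
#' @param tree a [spanning_tree()].
#' @return List with `bc` (named vector in \[0, 1\]), `bc_max` and
#'   `bc_global` (mean over all `N` nodes, leaves included).
#' @export
betweenness_tree <- function(tree) {
  adj <- tree_adjacency(tree)
  n <- tree$n
  norm <- (n - 1) * (n - 2) / 2
  bc <- numeric(n)
  for (u in seq_len(n)) {
    # component sizes after deleting u; pairs crossing u straddle components
    sizes <- integer(0L)
    seen <- rep(FALSE, n)
    seen[u] <- TRUE
    for (v in adj[[u]]) if (!seen[v]) {
      queue <- v
      seen[v] <- TRUE
      cs <- 0L
      while (length(queue)) {
        w <- queue[1L]; queue <- queue[-1L]
        cs <- cs + 1L
        for (z in adj[[w]]) if (!seen[z]) { seen[z] <- TRUE; queue <- c(queue, z) }
      }
      sizes <- c(sizes, cs)
    }
    bc[u] <- (sum(sizes)^2 - sum(sizes^2)) / 2 / norm
  }
  names(bc) <- tree$labels
  list(bc = bc, bc_max = max(bc), bc_global = mean(bc))
}

#' Degree correlation (Newman assortativity)
#'
#' Pearson correlation of endpoint degrees over all edges, counted in both
#' orientations.  Negative values (disassortative) mean hubs attach to
#' low-degree nodes; a star yields exactly -1.  Returns `NA` when endpoint
#' degrees have zero variance (the correlation is then undefined).
#'
#' @param tree a [spanning_tree()].
#' @return Scalar in \[-1, 1\] or `NA`.
#' @export
degree_correlation <- function(tree) {
  deg <- degree_metrics(tree)$degrees
  x <- deg[tree$edges$from]
  y <- deg[tree$edges$to]
  a <- c(x, y)
  b <- c(y, x)
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Regional betweenness centrality
#'
#' Mean node BC over the anterior and posterior electrode sets; central
#' electrodes belong to neither region.
#'
#' @param tree a [spanning_tree()].
#' @param regions a [region_config()].
#' @return List with `bc_anterior` and `bc_posterior`.
#' @export
regional_bc <- function(tree, regions = region_config()) {
  stopifnot(inherits(regions, "region_config"))
  bc <- betweenness_tree(tree)$bc
  for (set in c("anterior", "posterior")) {
    missing <- setdiff(regions[[set]], tree$labels)
    if (length(missing))
      stop(set, " region label(s) not in tree: ",
           paste(missing, collapse = ", "))
  }
  list(bc_anterior = mean(bc[regions$anterior]),
       bc_posterior = mean(bc[regions$posterior]))
}

#' All tree metrics of one spanning tree
#'
#' @param tree a [spanning_tree()].
#' @param regions a [region_config()], or `NULL` to skip regional BC.
#' @return One-row data frame: `max_degree`, `leaf_number`, `leaf_fraction`,
#'   `diameter` (hops), `diameter_norm` (`d / m`, for cross-study
#'   comparison), `bc_max`, `bc_global`, `degree_correlation`,
#'   `bc_anterior`, `bc_posterior`.
#' @export
mst_metrics <- function(tree, regions = region_config()) {
  deg <- degree_metrics(tree)
  lf <- leaf_metrics(tree)
  d <- tree_diameter(tree)
  bc <- betweenness_tree(tree)
  reg <- if (is.null(regions)) list(bc_anterior = NA_real_, bc_posterior = NA_real_)
         else regional_bc(tree, regions)
  data.frame(max_degree = deg$max_degree,
             leaf_number = lf$leaf_number,
             leaf_fraction = lf$leaf_fraction,
             diameter = d,
             diameter_norm = d / (tree$n - 1L),
             bc_max = bc$bc_max,
             bc_global = bc$bc_global,
             degree_correlation = degree_correlation(tree),
             bc_anterior = reg$bc_anterior,
             bc_posterior = reg$bc_posterior)
}

#' Per-subject, per-band tree metrics averaged over epochs
#'
#' For every epoch: PLI matrix, spanning tree of strongest connections, tree
#' metrics; every metric (and the global PLI) is then averaged arithmetically
#' across epochs, matching the per-subject averaging of the per-epoch
#' results.  `degree_correlation` may be undefined (NA) for single epochs
#' and is averaged over the epochs where it exists.
#'
#' @param epochs an [epoch_set()] (already band-filtered).
#' @param regions a [region_config()] or `NULL`.
#' @return One-row data frame of averaged metrics, with `pli` (global PLI)
#'   and `n_epochs` prepended.
#' @export
subject_band_metrics <- function(epochs, regions = region_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  ne <- n_epochs(epochs)
  if (ne < 1L) stop("need at least one epoch")
  rows <- vector("list", ne)
  pli <- numeric(ne)
  for (e in seq_len(ne)) {
    m <- pli_matrix(epochs$data[, , e], labels = epochs$labels,
                    band = epochs$band)
    pli[e] <- global_pli(m)
    rows[[e]] <- mst_metrics(max_spanning_tree(m), regions)
  }
  all <- do.call(rbind, rows)
  out <- as.data.frame(lapply(all, mean, na.rm = TRUE))
  cbind(data.frame(pli = mean(pli), n_epochs = ne), out)
}
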