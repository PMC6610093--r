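# Planted tree topologies: the ground truth the connectivity + tree stages
# must recover from synthetic recordings.

#' Tree specification for planted coupling topologies
#'
#' A `tree_spec` describes an undirected labelled tree on `n_nodes` nodes
#' (indices `1..n_nodes`) together with a per-edge coupling strength in
#' (0, 1].  It is the ground-truth object consumed by
#' [simulate_coupled_eeg()] and the reference shape for the tree metrics.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param edges two-column integer matrix of node index pairs; exactly
#'   `n_nodes - 1` rows forming a connected, acyclic graph.
#' @param edge_strengths numeric vector of per-edge coupling strengths in
#'   (0, 1]; recycled scalar allowed.  Default 0.9.
#' @param kind character tag describing the topology family.
#' @return An object of class `tree_spec` with elements `n_nodes`, `edges`
#'   (always stored with the smaller index first), `edge_strengths`, `kind`.
#' @seealso [make_reference_tree()], [simulate_coupled_eeg()]
#' @export
tree_spec <- function(n_nodes, edges, edge_strengths = 0.9, kind = "custom") {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L)
    stop("a tree needs at least 2 nodes")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) != n_nodes - 1L)
    stop("a tree on ", n_nodes, " nodes must have exactly ", n_nodes - 1L,
         " edges, got ", nrow(edges))
  if (any(edges < 1L) || any(edges > n_nodes))
    stop("edge node indices must lie in [1, n_nodes]")
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loops are not allowed in a tree")
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L])))
    stop("duplicate edges are not allowed in a tree")
  # n-1 edges and no cycle => connected tree
  parent <- seq_len(n_nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    if (a == b) stop("edges contain a cycle; not a tree")
    parent[a] <- b
  }
  edge_strengths <- rep_len(as.numeric(edge_strengths), nrow(edges))
  if (any(!is.finite(edge_strengths)) || any(edge_strengths <= 0) ||
      any(edge_strengths > 1))
    stop("edge strengths must lie in (0, 1]")
  structure(list(n_nodes = n_nodes, edges = edges,
                 edge_strengths = edge_strengths, kind = kind),
            class = "tree_spec")
}

#' @export
print.tree_spec <- function(x, ...) {
  cat("<tree_spec>", x$kind, "tree:", x$n_nodes, "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Canonical reference tree topologies
#'
#' Builds the named extremal/reference shapes used to benchmark tree
#' metrics: a `star` (one hub of degree n-1, all other nodes leaves), a
#' `path` (single chain, exactly two leaves), a `balanced` tree (binary-heap
#' parent structure: two directly connected hubs at small n, the
#' "rich-club"-like shape), or a uniformly `random` labelled tree (drawn via
#' a random Pruefer sequence).
#'
#' @param kind one of `"star"`, `"path"`, `"balanced"`, `"random"`.
#' @param n_nodes number of nodes (>= 2).
#' @param edge_strengths per-edge coupling strengths, see [tree_spec()].
#' @param seed optional integer seed, only used for `kind = "random"`.
#' @return A [tree_spec()].
#' @examples
#' make_reference_tree("star", 19)   # hub degree 18, 18 leaves
#' make_reference_tree("path", 19)   # leaf number 2, diameter 18
#' @export
make_reference_tree <- function(kind = c("star", "path", "balanced", "random"),
                                n_nodes, edge_strengths = 0.9, seed = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n_nodes)
  if (is.na(n) || n < 2L) stop("n_nodes must be at least 2")
  edges <- switch(kind,
    star = cbind(1L, 2:n),
    path = cbind(seq_len(n - 1L), 2:n),
    balanced = cbind(seq.int(2L, n) %/% 2L, seq.int(2L, n)),
    random = {
      if (!is.null(seed)) set.seed(seed)
      if (n == 2L) cbind(1L, 2L)
      else prufer_to_edges(sample.int(n, n - 2L, replace = TRUE), n)
    })
  tree_spec(n, edges, edge_strengths, kind = kind)
}

# Decode a Pruefer sequence into the edge list of the labelled tree it
# encodes.  O(n^2); trees here are tiny.
prufer_to_edges <- function(prufer, n) {
  stopifnot(length(prufer) == n - 2L, all(prufer >= 1L), all(prufer <= n))
  deg <- tabulate(prufer, nbins = n) + 1L
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  for (i in seq_along(prufer)) {
    leaf <- which(deg == 1L)[1L]
    edges[i, ] <- c(leaf, prufer[i])
    deg[leaf] <- 0L
    deg[prufer[i]] <- deg[prufer[i]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

# Relabel a tree_spec onto electrode labels, yielding a spanning_tree whose
# edge weights are the coupling strengths.  Used to compare recovered trees
# with the planted truth and to compute metrics of reference shapes.

#' Convert a planted tree specification to a labelled spanning tree
#'
#' @param tree a [tree_spec()].
#' @param labels node labels; defaults to `N1..Nk`.
#' @return A [spanning_tree()] with the coupling strengths as edge weights.
#' @export
as_spanning_tree <- function(tree, labels = NULL) {
  stopifnot(inherits(tree, "tree_spec"))
  if (is.null(labels)) labels <- paste0("N", seq_len(tree$n_nodes))
  if (length(labels) != tree$n_nodes) stop("need one label per node")
  spanning_tree(labels,
                data.frame(from = labels[tree$edges[, 1L]],
                           to = labels[tree$edges[, 2L]],
                           weight = tree$edge_strengths,
                           stringsAsFactors = FALSE))
}
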