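#' Build the edge-filtered coancestry network
#'
#' Nodes are individuals; the weight between i and j is the symmetrized
#' chunkcount (arithmetic mean of the two directed counts). An edge is kept
#' only when `low < w < high`, both bounds strict: the lower bound removes
#' deep (population-average) relationships, the upper bound removes close
#' relatives from the last few generations. Isolated nodes are retained.
#'
#' @param chunkcounts a `coancestry` object or a square matrix with zero
#'   diagonal.
#' @param low,high strict filter bounds (defaults 2 and 25).
#' @return an [igraph::graph] with vertex attribute `name` and edge
#'   attribute `weight`.
#' @export
build_graph <- function(chunkcounts, low = 2, high = 25) {
  M <- if (inherits(chunkcounts, "coancestry")) chunkcounts$chunkcounts
       else as.matrix(chunkcounts)
  if (nrow(M) != ncol(M)) stopf("chunkcounts must be square")
  W <- (M + t(M)) / 2
  W[!(W > low & W < high)] <- 0
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
  if (is.null(igraph::V(g)$name))
    g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(nrow(M))))
  g
}

leiden_once <- function(graph, resolution, n_iterations) {
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  memb <- igraph::membership(cl)
  w <- igraph::E(graph)$weight
  q <- if (igraph::ecount(graph) == 0L) 0
       else igraph::modularity(graph, memb, weights = w)
  list(membership = memb, modularity = q)
}

#' Recursive Leiden clustering of a coancestry network
#'
#' Applies Leiden community detection (weighted modularity) to the full
#' graph, then re-applies it within each community's induced subgraph,
#' recursively to `max_depth`. A community is not subdivided when it has
#' fewer than `min_size` members, or when the candidate subdivision is a
#' single community or has modularity below `min_modularity` (guarding
#' against the spurious communities Leiden finds in unstructured dense
#' graphs). Deterministic under `seed`.
#'
#' @param graph from [build_graph()].
#' @param max_depth maximum recursion depth (default 4).
#' @param min_size communities smaller than this are never subdivided
#'   (default 100).
#' @param resolution modularity resolution (default 1).
#' @param seed integer seed.
#' @param min_modularity minimum modularity a subdivision must reach to be
#'   accepted (default 0.2).
#' @param n_iterations Leiden iterations per call (default 5).
#' @return object of class `cluster_tree`: `tree` (nested list), `leaves`
#'   (named list of member ids), `assignment` (named character vector,
#'   individual -> leaf label; labels are dot-separated paths in the tree).
#' @export
leiden_recursive <- function(graph, max_depth = 4L, min_size = 100L,
                             resolution = 1, seed = 1L,
                             min_modularity = 0.2, n_iterations = 5L) {
  if (igraph::vcount(graph) == 0L) stopf("empty graph")
  recurse <- function(g, depth, path, seed) {
    members <- igraph::V(g)$name
    make_leaf <- function() list(label = path, members = members)
    if (depth > max_depth || length(members) < min_size || length(members) < 2L)
      return(make_leaf())
    fit <- with_seed(seed, leiden_once(g, resolution, n_iterations))
    k <- length(unique(fit$membership))
    if (k < 2L || fit$modularity < min_modularity)
      return(make_leaf())
    children <- vector("list", k)
    comm <- sort(unique(fit$membership))
    for (i in seq_len(k)) {
      sub <- igraph::induced_subgraph(g, which(fit$membership == comm[i]))
      children[[i]] <- recurse(sub, depth + 1L,
                               paste0(path, if (nzchar(path)) "." else "", i),
                               derive_seed(seed, 97L * i + depth))
    }
    list(label = path, modularity = fit$modularity, children = children)
  }
  tree <- recurse(graph, 1L, "", seed)
  if (is.null(tree$children)) tree$label <- "1"
  leaves <- list()
  collect <- function(node) {
    if (is.null(node$children)) {
      lab <- if (nzchar(node$label)) node$label else "1"
      leaves[[lab]] <<- node$members
    } else for (ch in node$children) collect(ch)
  }
  collect(tree)
  assignment <- setNames(rep(names(leaves), lengths(leaves)), unlist(leaves))
  assignment <- assignment[igraph::V(graph)$name]
  structure(list(tree = tree, leaves = leaves, assignment = assignment,
                 max_depth = max_depth, min_size = min_size),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d leaves over %d individuals (sizes %s)\n",
              length(x$leaves), length(x$assignment),
              paste(lengths(x$leaves), collapse = ", ")))
  invisible(x)
}

#' Partition at a given depth of a cluster tree
#'
#' Truncates leaf labels to their first `depth` path components, giving the
#' coarser partition formed at that level of the recursion.
#' @param tree a `cluster_tree`.
#' @param depth tier (1 = first split).
#' @return named character vector, individual -> cluster label.
#' @export
cut_tree <- function(tree, depth = 1L) {
  lab <- vapply(strsplit(tree$assignment, ".", fixed = TRUE),
                function(p) paste(head(p, depth), collapse = "."), character(1L))
  setNames(lab, names(tree$assignment))
}

tree_newick <- function(node) {
  if (is.null(node$children)) {
    lab <- if (nzchar(node$label)) node$label else "1"
    return(sprintf("%s_n%d", gsub("\\.", "_", lab), length(node$members)))
  }
  paste0("(", paste(vapply(node$children, tree_newick, character(1L)),
                    collapse = ","), ")")
}

#' Write cluster assignment and tree
#'
#' Writes a TSV (individual, leaf label, path in tree) and the cluster tree
#' in Newick format.
#' @param tree a `cluster_tree`.
#' @param dir output directory.
#' @return file paths, invisibly.
#' @export
write_clusters <- function(tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "clusters.tsv")
  p2 <- file.path(dir, "cluster_tree.nwk")
  write.table(data.frame(id = names(tree$assignment),
                         cluster = unname(tree$assignment),
                         path = gsub(".", "/", unname(tree$assignment), fixed = TRUE)),
              p1, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0(tree_newick(tree$tree), ";"), p2)
  invisible(c(p1, p2))
}
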