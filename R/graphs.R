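#' Markov-rate graph of a fitted model
#'
#' Interprets \eqn{P} as a continuous-time Markov rate matrix: entry
#' \eqn{P_{ij}} is the rate at which state \eqn{j} transitions into state
#' \eqn{i}, drawn as a directed edge \eqn{j \to i}.  Nodes carry the basis
#' means as positions, their source time point, and a size proportional to
#' \eqn{|P_{ii}|} (the rate at which state \eqn{i} is left).  A reproducible
#' force-directed layout is computed with attraction weights inversely
#' proportional to the mass-matrix entries, so components that overlap little
#' are placed far apart.
#'
#' @param model A `ddd_pf_model` fitted with a basis (or supply `means`).
#' @param min_weight Edges with rate below this are omitted *for display
#'   only*; analysis functions always receive the full matrix.
#' @param seed Layout seed.
#' @param means Optional \eqn{N \times d} node coordinates when the model
#'   carries no basis.
#' @return An `igraph` directed graph with vertex attributes `x`, `y`
#'   (first two mean coordinates), `lx`, `ly` (force-directed layout),
#'   `size` (min--max scaled \eqn{|P_{ii}|}), `source_time`, and edge
#'   attribute `weight`.
#' @export
rate_graph <- function(model, min_weight = 0, seed = 1L, means = NULL) {
  stopifnot(inherits(model, "ddd_pf_model"))
  P <- model$P
  N <- nrow(P)
  if (is.null(means) && !is.null(model$basis)) means <- model$basis$means
  # adjacency for edge j -> i with weight P[i, j]
  A <- t(P)
  diag(A) <- 0
  A[A < max(min_weight, 0)] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed",
                                           weighted = TRUE)
  decay <- abs(diag(P))
  rng <- range(decay)
  igraph::V(g)$size <- if (diff(rng) > 0) (decay - rng[1]) / diff(rng)
    else rep(0, N)
  if (!is.null(model$basis))
    igraph::V(g)$source_time <- model$basis$source_time
  if (!is.null(means)) {
    igraph::V(g)$x <- means[, 1]
    igraph::V(g)$y <- means[, 2]
  }
  set.seed(seed)
  lw <- if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    1 / pmax(model$M[el], 1e-12)
  } else numeric(0)
  coords <- igraph::layout_with_fr(g, weights = lw)
  igraph::V(g)$lx <- coords[, 1]
  igraph::V(g)$ly <- coords[, 2]
  g
}

#' Prune a rate graph to an interpretable branching structure
#'
#' Drops edges below `weight_floor`, then repeatedly removes leaf nodes
#' (total degree \eqn{\le 1}) that are not in `annotated` until a fixpoint,
#' leaving the annotated states connected through surviving transit nodes.
#' The operation is idempotent.
#'
#' @param graph An `igraph` graph from [rate_graph()].
#' @param annotated Vertex indices (or names) that must never be pruned.
#' @param weight_floor Minimum edge weight retained.
#' @return The pruned `igraph` graph.  If pruning disconnects some annotated
#'   nodes from the rest a warning is issued (never a silent drop).
#' @export
prune_to_branching <- function(graph, annotated, weight_floor = 0) {
  stopifnot(igraph::is_igraph(graph))
  ann_ids <- igraph::V(graph)[annotated]$name
  if (is.null(ann_ids)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
    ann_ids <- igraph::V(graph)[annotated]$name
  }
  g <- igraph::delete_edges(graph,
                            igraph::E(graph)[igraph::E(graph)$weight < weight_floor])
  repeat {
    deg <- igraph::degree(g, mode = "all")
    drop <- which(deg <= 1 & !(igraph::V(g)$name %in% ann_ids))
    if (length(drop) == 0) break
    g <- igraph::delete_vertices(g, drop)
  }
  comp <- igraph::components(g, mode = "weak")
  ann_membership <- comp$membership[igraph::V(g)$name %in% ann_ids]
  if (length(unique(ann_membership)) > 1)
    warning("annotated nodes are disconnected after pruning")
  g
}

#' Count transition edges above a threshold
#'
#' Convenience for comparing fitted topologies (e.g. Lasso vs unpenalised):
#' the number of off-diagonal rates exceeding `threshold`.
#'
#' @param model A `ddd_pf_model`.
#' @param threshold Rate threshold.
#' @return Integer edge count.
#' @export
count_edges <- function(model, threshold = 1e-6) {
  P <- model$P
  diag(P) <- 0
  sum(P > threshold)
}

#' Export a graph to GraphML or DOT
#'
#' Node attributes (positions, size, source time) travel with the file so
#' downstream tools can reproduce the embedding.
#'
#' @param graph An `igraph` graph.
#' @param path Output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(graph, path, format = format)
  invisible(path)
}
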