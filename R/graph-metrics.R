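# Graph-theory indices on (Bonferroni-filtered) weighted networks.
# Edge weights are correlation distances and are used directly as path
# lengths; set `as_correlation = TRUE` in modularity_index() to use the
# correlation itself as connection strength instead.

# igraph object from present (non-NA) edges, weights as given
net_to_igraph <- function(network) {
  w <- network$weights
  ut <- which(upper.tri(w) & !is.na(w), arr.ind = TRUE)
  if (nrow(ut) == 0L) stop("network has no edges")
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$roi_labels[ut[, 1L]],
               to = network$roi_labels[ut[, 2L]],
               weight = w[ut]),
    directed = FALSE,
    vertices = data.frame(name = network$roi_labels))
  g
}

all_shortest_distances <- function(network) {
  g <- net_to_igraph(network)
  # zero-weight edges are legitimate distances here
  igraph::distances(g, weights = igraph::E(g)$weight, algorithm = "dijkstra")
}

#' Characteristic path length (CPL)
#'
#' The mean shortest-path distance over all ordered pairs of distinct nodes,
#' with edge weights used as path lengths.  Pairs in different components
#' (infinite distance) are excluded from the average.
#'
#' @param network a [weighted_network], usually Bonferroni-filtered.
#' @return Scalar CPL.
#' @seealso [network_diameter()], [modularity_index()], [bonferroni_filter()]
#' @export
cpl <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  d <- all_shortest_distances(network)
  vals <- d[row(d) != col(d)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no finite-distance pair in the network")
  mean(vals)
}

#' Network diameter (ND)
#'
#' The greatest shortest-path distance between any pair of nodes; for
#' disconnected networks the maximum is over finite distances only,
#' matching the CPL exclusion rule.
#'
#' @inheritParams cpl
#' @return Scalar diameter.
#' @export
network_diameter <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  d <- all_shortest_distances(network)
  vals <- d[row(d) != col(d)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no finite-distance pair in the network")
  max(vals)
}

#' Modularity (Mod) and community partition
#'
#' Finds a module partition by greedy agglomerative modularity maximization
#' (deterministic Clauset-Newman-Moore heuristic) and evaluates
#' \deqn{Mod = \sum_{i \in M} [c_{ii} - (\sum_{j \in M} c_{ij})^2]}
#' where `c` is the matrix of proportions of total edge weight falling
#' within/between modules.  Note `Mod <= 1` under this proportion formula.
#'
#' @inheritParams cpl
#' @param seed integer seed taken before community detection; the greedy
#'   heuristic itself is deterministic, the seed merely pins any future
#'   stochastic refinement.
#' @param as_correlation if `TRUE`, edges enter as correlation strength
#'   `max(1 - w, 0)` instead of distance `w` (the alternative convention in
#'   which the correlation itself is the edge weight).
#' @return Object of class `community_partition`: list with `mod` (the
#'   scalar index), `assignment` (named module id per ROI) and `c_matrix`
#'   (the module-by-module weight-proportion matrix).
#' @export
modularity_index <- function(network, seed = 1L, as_correlation = FALSE) {
  stopifnot(inherits(network, "weighted_network"))
  w <- network$weights
  if (as_correlation) {
    w <- 1 - w
    w[w < 0] <- 0
    w[is.na(network$weights)] <- NA_real_
    diag(w) <- 0
    network <- weighted_network(w, network$roi_labels, network$meta)
  }
  g <- net_to_igraph(network)
  ew <- igraph::E(g)$weight
  if (all(ew == 0)) stop("all edge weights are zero; modularity undefined")
  set.seed(seed)
  cm <- igraph::cluster_fast_greedy(g, weights = ew)
  membership <- igraph::membership(cm)
  assignment <- as.integer(membership)
  names(assignment) <- igraph::V(g)$name
  assignment <- assignment[network$roi_labels]
  part <- community_partition(network, assignment)
  part
}

#' @rdname modularity_index
#' @param assignment named integer vector mapping each ROI to a module id.
#' @export
community_partition <- function(network, assignment) {
  stopifnot(inherits(network, "weighted_network"))
  assignment <- assignment[network$roi_labels]
  if (anyNA(assignment)) stop("`assignment` must cover every ROI")
  mods <- sort(unique(assignment))
  w <- network$weights
  w[is.na(w)] <- 0
  total <- sum(w)  # both triangles: proportions of edge ends
  if (total == 0) stop("network has no edge weight")
  cmat <- matrix(0, length(mods), length(mods),
                 dimnames = list(mods, mods))
  for (a in seq_along(mods)) for (b in seq_along(mods)) {
    cmat[a, b] <- sum(w[assignment == mods[a], assignment == mods[b]]) / total
  }
  mod <- sum(diag(cmat) - rowSums(cmat)^2)
  structure(list(mod = mod, assignment = assignment, c_matrix = cmat),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d modules over %d ROIs, Mod = %.4f\n",
              nrow(x$c_matrix), length(x$assignment), x$mod))
  invisible(x)
}

#' All three graph-theory indices at once
#'
#' @inheritParams cpl
#' @param seed passed to [modularity_index()].
#' @return Named list with `cpl`, `nd` and `mod`.
#' @export
graph_metrics <- function(network, seed = 1L) {
  list(cpl = cpl(network), nd = network_diameter(network),
       mod = modularity_index(network, seed = seed)$mod)
}
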