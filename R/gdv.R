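#' Graphlet degree vectors
#'
#' Counts, for every node, the automorphism orbits of connected induced
#' subgraphs on at most `max_graphlet_nodes` nodes that touch it.  With
#' the default size 4 the columns follow the standard 15-orbit indexing
#' (orbit 0 = edge, 1/2 = path end/middle, 3 = triangle, 4/5 = 4-path
#' end/middle, 6/7 = claw leaf/centre, 8 = 4-cycle, 9/10/11 = paw, 12/13 =
#' diamond, 14 = K4); size 5 extends this to 73 orbits using the same
#' deterministic canonical enumeration.
#'
#' @param g a cleaned graph.
#' @param max_graphlet_nodes 4 (15 orbits) or 5 (73 orbits).
#' @return integer matrix, one row per node (rownames = node labels), one
#'   column per orbit (`orbit0`, `orbit1`, ...).
#' @export
gdv_counts <- function(g, max_graphlet_nodes = 4L) {
  if (!max_graphlet_nodes %in% c(4L, 5L)) {
    stop("max_graphlet_nodes must be 4 or 5")
  }
  if (igraph::vcount(g) == 0L) stop("empty graph")
  counts <- gdv_counts_cpp(graph_adjacency_0(g), as.integer(max_graphlet_nodes))
  dimnames(counts) <- list(igraph::V(g)$name,
                           paste0("orbit", seq_len(ncol(counts)) - 1L))
  counts
}

#' Orbit weights for graphlet-degree-vector similarity
#'
#' Weight of orbit i is \eqn{w_i = 1 - \log(o_i)/\log(73)} where
#' \eqn{o_i} counts the orbits that affect orbit i.  The dependency counts
#' are derived from the orbit registry itself: orbit j affects orbit i
#' when j's graphlet arises from i's by deleting non-touched nodes while
#' staying connected (transitively closed, including i itself).  The
#' 73-orbit normalization is kept even in 15-orbit mode so that the first
#' 15 weights agree between the two modes.
#'
#' @param max_graphlet_nodes 4 or 5.
#' @return numeric vector of per-orbit weights.
#' @export
gdv_orbit_weights <- function(max_graphlet_nodes = 4L) {
  info <- gdv_orbit_info_cpp(as.integer(max_graphlet_nodes))
  1 - log(info$dependencies) / log(73)
}

#' Similarity of two graphlet degree vectors
#'
#' One minus the weighted mean over orbits of the log-scaled orbit-count
#' distance
#' \eqn{D_i = w_i |\log(u_i+1) - \log(v_i+1)| / \log(\max(u_i, v_i) + 2)};
#' symmetric, in \[0, 1\], and equal to 1 exactly when the vectors are
#' identical.  The +1/+2 shifts keep every logarithm finite, so no epsilon
#' is needed.
#'
#' @param u_vec,v_vec equal-length orbit-count vectors.
#' @param weights per-orbit weights; defaults to [gdv_orbit_weights()] for
#'   the matching registry size.
#' @return similarity in \[0, 1\].
#' @export
gdv_similarity <- function(u_vec, v_vec, weights = NULL) {
  if (length(u_vec) != length(v_vec)) stop("orbit vectors differ in length")
  if (is.null(weights)) {
    weights <- gdv_orbit_weights(if (length(u_vec) > 15L) 5L else 4L)
  }
  d <- weights * abs(log(u_vec + 1) - log(v_vec + 1)) /
    log(pmax(u_vec, v_vec) + 2)
  1 - sum(d) / sum(weights)
}

#' @keywords internal
gdv_similarity_matrix <- function(d1, d2, weights) {
  n1 <- nrow(d1)
  n2 <- nrow(d2)
  out <- matrix(0, n1, n2)
  l1 <- log(d1 + 1)
  l2 <- log(d2 + 1)
  for (j in seq_len(n2)) {
    num <- abs(l1 - matrix(l2[j, ], n1, ncol(d1), byrow = TRUE))
    den <- log(pmax(d1, matrix(d2[j, ], n1, ncol(d1), byrow = TRUE)) + 2)
    out[, j] <- 1 - (num / den) %*% weights / sum(weights)
  }
  out
}
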