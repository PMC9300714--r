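#' Alignments and topological objective functions
#'
#' A pairwise global network alignment is an injective mapping from every
#' node of the smaller network `g1` into the nodes of the larger network
#' `g2`.  It is represented as a named character vector: names are `g1`
#' node labels, values the `g2` node labels they map to.
#'
#' @name alignment
NULL

#' @keywords internal
validate_alignment <- function(g1, g2, a) {
  v1 <- igraph::V(g1)$name
  v2 <- igraph::V(g2)$name
  if (is.null(names(a)) || !setequal(names(a), v1) ||
      anyDuplicated(names(a)) > 0L) {
    stop("alignment must be total on the nodes of g1")
  }
  if (anyDuplicated(a) > 0L) stop("alignment must be injective")
  if (!all(a %in% v2)) stop("alignment image must lie in g2")
  a[v1]
}

#' @keywords internal
alignment_to_index0 <- function(g1, g2, a) {
  a <- validate_alignment(g1, g2, a)
  match(a, igraph::V(g2)$name) - 1L
}

#' Number of conserved edges under an alignment
#'
#' An edge (u, v) of `g1` is conserved when its image (a(u), a(v)) is an
#' edge of `g2`.
#'
#' @param g1,g2 cleaned graphs with `vcount(g1) <= vcount(g2)` not
#'   required here, but the alignment must be total on `g1` and injective.
#' @param a alignment (named character vector, see [alignment]).
#' @return integer count of conserved edges.
#' @export
conserved_edges <- function(g1, g2, a) {
  a <- validate_alignment(g1, g2, a)
  el <- igraph::as_edgelist(g1)
  if (nrow(el) == 0L) return(0L)
  vp <- as.vector(t(cbind(a[el[, 1]], a[el[, 2]])))
  sum(igraph::get_edge_ids(g2, vp) > 0)
}

#' Edge correctness (EC) of an alignment
#'
#' Conserved edges as a fraction of the smaller network's edges:
#' \eqn{EC = |aligned\ edges| / m_1}.
#'
#' @inheritParams conserved_edges
#' @return a value in \[0, 1\].
#' @export
ec_score <- function(g1, g2, a) {
  m1 <- igraph::ecount(g1)
  if (m1 < 1L) stop("g1 has no edges")
  conserved_edges(g1, g2, a) / m1
}

#' Symmetric substructure score (S3) of an alignment
#'
#' Conserved edges divided by all edges, of either network, that run
#' between aligned nodes: \eqn{S^3 = c / (m_1 + |E_2[image]| - c)} where
#' \eqn{c} is the conserved-edge count and \eqn{E_2[image]} the edges of
#' `g2` induced on the image of the alignment.  Always satisfies
#' \eqn{S^3 \le EC}.
#'
#' @inheritParams conserved_edges
#' @return a value in \[0, 1\].
#' @export
s3_score <- function(g1, g2, a) {
  a <- validate_alignment(g1, g2, a)
  cns <- conserved_edges(g1, g2, a)
  ind <- igraph::ecount(igraph::induced_subgraph(g2, a))
  den <- igraph::ecount(g1) + ind - cns
  if (den <= 0) stop("S3 denominator is zero")
  cns / den
}

#' Specify a topological objective
#'
#' @param name one of `"ec"`, `"s3"`, `"importance"`, `"gdv"`.
#' @param max_graphlet_nodes graphlet size for the `gdv` objective (4 or
#'   5; 4 gives the 15-orbit signature, 5 the 73-orbit one).
#' @param elimination_bound degree bound for the `importance` objective's
#'   minimum-degree elimination (default 2).
#' @return an object of class `objective_spec`.
#' @export
objective_spec <- function(name = c("ec", "s3", "importance", "gdv"),
                           max_graphlet_nodes = 4L,
                           elimination_bound = 2L) {
  name <- match.arg(name)
  if (!max_graphlet_nodes %in% c(4L, 5L)) {
    stop("max_graphlet_nodes must be 4 or 5")
  }
  if (elimination_bound < 1L) stop("elimination_bound must be >= 1")
  structure(list(name = name,
                 max_graphlet_nodes = as.integer(max_graphlet_nodes),
                 elimination_bound = as.integer(elimination_bound)),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat("objective:", x$name, "\n")
  if (x$name == "gdv") cat("  max graphlet nodes:", x$max_graphlet_nodes, "\n")
  if (x$name == "importance") cat("  elimination bound:", x$elimination_bound, "\n")
  invisible(x)
}

#' Node importance by minimum-degree elimination
#'
#' A deterministic importance score in the spirit of elimination-based hub
#' scoring: node weights start at 0 and every edge carries weight 1;
#' repeatedly remove the lexicographically smallest node whose current
#' degree is at most `elimination_bound`, redistributing its accumulated
#' weight (node weight plus incident edge weights) to its neighbourhood --
#' onto the single neighbour when degree is 1, onto the (created if
#' absent) edge joining the two neighbours when degree is 2, discarded
#' when degree is 0.  A node's importance is its node weight plus half the
#' weight of its incident edges, evaluated at the moment of its removal
#' (at termination for survivors).
#'
#' This scheme is deterministic and relabelling-invariant up to the
#' documented lexicographic tie-break; it is this package's own concrete
#' choice of an "importance" driver, not a re-implementation of any
#' published aligner's internal scorer.
#'
#' @param g a cleaned graph.
#' @param elimination_bound maximum degree at which a node may be
#'   eliminated; with the default 2 the redistribution rules above cover
#'   every removal.
#' @return named numeric vector of non-negative importance scores.
#' @export
importance_scores <- function(g, elimination_bound = 2L) {
  if (elimination_bound > 2L) {
    stop("elimination_bound > 2 is not supported by the redistribution rules")
  }
  nodes <- igraph::V(g)$name
  nw <- stats::setNames(numeric(length(nodes)), nodes)
  el <- igraph::as_edgelist(g)
  ew <- new.env(parent = emptyenv())
  adj <- new.env(parent = emptyenv())
  ekey <- function(x, y) paste0(pmin(x, y), "\r", pmax(x, y))
  for (v in nodes) assign(v, character(0), envir = adj)
  for (i in seq_len(nrow(el))) {
    x <- el[i, 1]; y <- el[i, 2]
    assign(ekey(x, y), 1, envir = ew)
    assign(x, c(get(x, envir = adj), y), envir = adj)
    assign(y, c(get(y, envir = adj), x), envir = adj)
  }
  alive <- sort(nodes)
  importance <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  half_incident <- function(v) {
    nb <- get(v, envir = adj)
    if (length(nb) == 0L) return(0)
    sum(vapply(nb, function(u) get(ekey(v, u), envir = ew), numeric(1))) / 2
  }
  repeat {
    degs <- vapply(alive, function(v) length(get(v, envir = adj)), integer(1))
    cand <- alive[degs <= elimination_bound]
    if (length(cand) == 0L) break
    v <- cand[1L]  # alive is sorted: lexicographically smallest
    nb <- get(v, envir = adj)
    inc <- if (length(nb)) {
      vapply(nb, function(u) get(ekey(v, u), envir = ew), numeric(1))
    } else numeric(0)
    importance[v] <- nw[v] + sum(inc) / 2
    s <- nw[v] + sum(inc)
    if (length(nb) == 1L) {
      nw[nb] <- nw[nb] + s
    } else if (length(nb) == 2L) {
      k <- ekey(nb[1], nb[2])
      old <- if (exists(k, envir = ew)) get(k, envir = ew) else {
        assign(nb[1], c(get(nb[1], envir = adj), nb[2]), envir = adj)
        assign(nb[2], c(get(nb[2], envir = adj), nb[1]), envir = adj)
        0
      }
      assign(k, old + s, envir = ew)
    }
    for (u in nb) {
      assign(u, setdiff(get(u, envir = adj), v), envir = adj)
    }
    alive <- setdiff(alive, v)
  }
  for (v in alive) importance[v] <- nw[v] + half_incident(v)
  importance[nodes]
}

#' Pairwise node-similarity matrix for a node-level objective
#'
#' For the `gdv` objective, entry (u, q) is the graphlet-degree-vector
#' similarity of u and q; for `importance`, it is
#' `1 - |I1(u) - I2(q)|` with importances max-normalized per network.
#'
#' @param g1,g2 cleaned graphs.
#' @param spec an [objective_spec()] with name `"gdv"` or `"importance"`.
#' @return numeric matrix of dimension `vcount(g1) x vcount(g2)` with
#'   dimnames set to the node labels.
#' @export
node_similarity_matrix <- function(g1, g2, spec) {
  if (spec$name == "gdv") {
    d1 <- gdv_counts(g1, spec$max_graphlet_nodes)
    d2 <- gdv_counts(g2, spec$max_graphlet_nodes)
    w <- gdv_orbit_weights(spec$max_graphlet_nodes)
    m <- gdv_similarity_matrix(d1, d2, w)
  } else if (spec$name == "importance") {
    i1 <- importance_scores(g1, spec$elimination_bound)
    i2 <- importance_scores(g2, spec$elimination_bound)
    i1 <- i1 / max(i1)
    i2 <- i2 / max(i2)
    m <- 1 - abs(outer(i1, i2, `-`))
  } else {
    stop("node similarity is defined for the gdv and importance objectives")
  }
  dimnames(m) <- list(igraph::V(g1)$name, igraph::V(g2)$name)
  m
}

#' Score an alignment under a named objective
#'
#' `ec` and `s3` delegate to the edge-based scores; `gdv` and `importance`
#' return the mean, over aligned node pairs, of the pairwise node
#' similarity.
#'
#' @inheritParams conserved_edges
#' @param spec an [objective_spec()].
#' @param sim optional precomputed [node_similarity_matrix()] (computed on
#'   the fly when omitted).
#' @return a real score in \[0, 1\].
#' @export
alignment_objective <- function(g1, g2, a, spec, sim = NULL) {
  a <- validate_alignment(g1, g2, a)
  switch(spec$name,
         ec = ec_score(g1, g2, a),
         s3 = s3_score(g1, g2, a),
         {
           if (is.null(sim)) sim <- node_similarity_matrix(g1, g2, spec)
           mean(sim[cbind(names(a), unname(a))])
         })
}
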