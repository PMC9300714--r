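#' Random initial alignment
#'
#' Draws a uniformly random injective mapping from the nodes of `g1` into
#' the nodes of `g2`, deterministically for a given seed.
#'
#' @param g1,g2 cleaned graphs with `vcount(g1) <= vcount(g2)`.
#' @param seed integer seed.
#' @return an alignment (named character vector).
#' @export
initial_alignment <- function(g1, g2, seed) {
  v1 <- igraph::V(g1)$name
  v2 <- igraph::V(g2)$name
  if (length(v1) > length(v2)) stop("n1 > n2: swap input order")
  img <- withr::with_seed(as.integer(seed), sample(v2, length(v1)))
  stats::setNames(img, v1)
}

#' @keywords internal
objective_code <- function(spec) {
  switch(spec$name, ec = 0L, s3 = 1L, 2L)
}

#' @keywords internal
sa_inputs <- function(g1, g2, spec, sim = NULL) {
  if (objective_code(spec) == 2L && is.null(sim)) {
    sim <- node_similarity_matrix(g1, g2, spec)
  }
  if (is.null(sim)) sim <- matrix(0, 0, 0)
  list(adj1 = graph_adjacency_0(g1), adj2 = graph_adjacency_0(g2),
       m1 = igraph::ecount(g1), obj = objective_code(spec), sim = sim)
}

#' Annealing schedule
#'
#' @param iterations total number of move proposals.
#' @param t_initial,t_final initial and final temperatures
#'   (`t_initial >= t_final > 0`); the temperature decays geometrically
#'   between them.
#' @param probe_size number of probe moves used by [auto_schedule()].
#' @return an object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(iterations = 1e7, t_initial = 1,
                            t_final = 1e-6, probe_size = 200L) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (!(t_initial >= t_final) || !(t_final > 0)) {
    stop("need t_initial >= t_final > 0")
  }
  structure(list(iterations = iterations, t_initial = t_initial,
                 t_final = t_final, probe_size = as.integer(probe_size)),
            class = "anneal_schedule")
}

#' Auto-tuned annealing schedule
#'
#' Runs a short random walk from a seeded random alignment, applying every
#' proposed move and recording the score deltas.  The initial temperature
#' is set so that at least 99% of probe moves would be accepted
#' (`t_initial = max|delta| / -log(0.99)`), and the final temperature so
#' that a move of the probe's mean magnitude is accepted with probability
#' at most 1e-6 (`t_final = mean|delta| / log(1e6)`).  If every probe
#' delta is zero the documented fallback constants (1, 1e-6) are used.
#'
#' @inheritParams initial_alignment
#' @param spec an [objective_spec()].
#' @param iterations iteration budget stored in the returned schedule.
#' @param probe_size number of probe moves.
#' @param sim optional precomputed node-similarity matrix.
#' @return an `anneal_schedule`.
#' @export
auto_schedule <- function(g1, g2, spec, seed, iterations = 1e7,
                          probe_size = 200L, sim = NULL) {
  inp <- sa_inputs(g1, g2, spec, sim)
  init <- alignment_to_index0(g1, g2, initial_alignment(g1, g2, seed))
  deltas <- abs(sa_probe_cpp(inp$adj1, inp$adj2, inp$m1, inp$obj, inp$sim,
                             init, as.integer(probe_size), as.integer(seed)))
  if (all(deltas == 0)) {
    return(anneal_schedule(iterations, 1, 1e-6, probe_size))
  }
  t_init <- max(deltas) / -log(0.99)
  t_final <- mean(deltas) / log(1e6)
  if (t_final > t_init) t_final <- t_init
  anneal_schedule(iterations, t_init, t_final, probe_size)
}

#' Propose a single move and its score delta
#'
#' From the state defined by an alignment, draws one random move -- a
#' "swap" exchanging the images of two `g1` nodes, or (only when
#' `n1 < n2`) a "change" remapping one `g1` node to an unused `g2` node --
#' and returns the incremental score change, which equals a full
#' recomputation of the objective after the move.
#'
#' @inheritParams auto_schedule
#' @param a current alignment.
#' @return list with `type` (`"swap"`/`"change"`), the nodes involved, and
#'   `delta`.
#' @export
propose_and_delta <- function(g1, g2, a, spec, seed, sim = NULL) {
  inp <- sa_inputs(g1, g2, spec, sim)
  idx <- alignment_to_index0(g1, g2, a)
  mv <- sa_propose_cpp(inp$adj1, inp$adj2, inp$m1, inp$obj, inp$sim, idx,
                       as.integer(seed))
  v1 <- igraph::V(g1)$name
  v2 <- igraph::V(g2)$name
  list(type = mv$type,
       u = v1[mv$u + 1L],
       v = if (mv$type == "swap") v1[mv$v + 1L] else NA_character_,
       q = if (mv$type == "change") v2[mv$q + 1L] else NA_character_,
       delta = mv$delta)
}

#' Simulated-annealing search for a high-scoring alignment
#'
#' Metropolis sampling over injective mappings: a move is always accepted
#' when it does not decrease the score, and otherwise with probability
#' `exp(delta / T)` under a geometrically decaying temperature.  The
#' cached incremental score is verified against a from-scratch
#' recomputation on return (tolerance 1e-9).
#'
#' Distinct seeds follow distinct random walks and so end in different
#' near-optimal alignments with almost identical scores; an ensemble of
#' such runs is the raw material for the alignment-frequency table
#' ([compute_naf()]).
#'
#' @inheritParams auto_schedule
#' @param schedule an [anneal_schedule()]; `NULL` auto-tunes via
#'   [auto_schedule()].
#' @return object of class `anneal_result`: list with `alignment`,
#'   `final_score`, `best_score`, `seed`, `accepted_moves`,
#'   `proposed_moves`, `objective`.
#' @export
anneal <- function(g1, g2, spec, schedule = NULL, seed = 1L, sim = NULL) {
  if (igraph::vcount(g1) > igraph::vcount(g2)) {
    stop("n1 > n2: swap input order")
  }
  inp <- sa_inputs(g1, g2, spec, sim)
  if (is.null(schedule)) schedule <- auto_schedule(g1, g2, spec, seed, sim = inp$sim)
  init <- alignment_to_index0(g1, g2, initial_alignment(g1, g2, seed))
  res <- sa_anneal_cpp(inp$adj1, inp$adj2, inp$m1, inp$obj, inp$sim, init,
                       schedule$iterations, schedule$t_initial,
                       schedule$t_final, as.integer(seed))
  v2 <- igraph::V(g2)$name
  a <- stats::setNames(v2[res$alignment + 1L], igraph::V(g1)$name)
  structure(list(alignment = a,
                 final_score = res$final_score,
                 best_score = res$best_score,
                 seed = as.integer(seed),
                 accepted_moves = res$accepted_moves,
                 proposed_moves = res$proposed_moves,
                 objective = spec$name),
            class = "anneal_result")
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf("anneal_result: %s objective, seed %d\n", x$objective, x$seed))
  cat(sprintf("  final score %.6f (best %.6f), %s/%s moves accepted\n",
              x$final_score, x$best_score,
              format(x$accepted_moves, big.mark = ","),
              format(x$proposed_moves, big.mark = ",")))
  invisible(x)
}

#' Audit incremental deltas against full recomputation
#'
#' Applies `n_moves` random moves, comparing each incremental delta with
#' the score difference obtained by recomputing the objective from
#' scratch.
#'
#' @inheritParams auto_schedule
#' @param n_moves number of audited moves.
#' @return the largest absolute discrepancy observed.
#' @export
anneal_delta_audit <- function(g1, g2, spec, seed, n_moves = 1000L,
                               sim = NULL) {
  inp <- sa_inputs(g1, g2, spec, sim)
  init <- alignment_to_index0(g1, g2, initial_alignment(g1, g2, seed))
  sa_delta_audit_cpp(inp$adj1, inp$adj2, inp$m1, inp$obj, inp$sim, init,
                     as.integer(n_moves), as.integer(seed))
}

#' Write an alignment to a two-column TSV file
#'
#' One `g1_node TAB g2_node` line per `g1` node, preceded by comment
#' lines recording the run metadata.
#'
#' @param result an `anneal_result` (or a bare alignment vector).
#' @param path output path.
#' @param extra optional extra header lines.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(result, path, extra = NULL) {
  if (inherits(result, "anneal_result")) {
    a <- result$alignment
    header <- c(sprintf("seed=%d objective=%s iterations=%s final_score=%.6f",
                        result$seed, result$objective,
                        format(result$proposed_moves, scientific = FALSE),
                        result$final_score), extra)
  } else {
    a <- result
    header <- extra
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(a), unname(a), sep = "\t"), con)
  invisible(path)
}
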