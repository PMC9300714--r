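# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately naive (enumeration / from-scratch recomputation) and share no
# code with the package internals they check.

triangle_graph <- function() read_edgelist(c("a b", "b c", "c a"), text = TRUE)
path3_graph <- function() read_edgelist(c("a b", "b c"), text = TRUE)
cycle4_graph <- function() read_edgelist(c("w x", "x y", "y z", "z w"),
                                         text = TRUE)
complete_graph <- function(n, prefix = "k") {
  v <- paste0(prefix, seq_len(n))
  pairs <- t(combn(v, 2))
  read_edgelist(paste(pairs[, 1], pairs[, 2]), text = TRUE)
}

# all permutations of a vector (small n)
perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(list(v))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# exhaustive-search maximum EC over all injective mappings V1 -> V2
oracle_best_ec <- function(g1, g2) {
  v1 <- igraph::V(g1)$name
  v2 <- igraph::V(g2)$name
  el1 <- igraph::as_edgelist(g1)
  e2 <- paste0(pmin(igraph::as_edgelist(g2)[, 1], igraph::as_edgelist(g2)[, 2]),
               "\r",
               pmax(igraph::as_edgelist(g2)[, 1], igraph::as_edgelist(g2)[, 2]))
  best <- 0
  for (subset in asplit(combn(v2, length(v1)), 2)) {
    for (img in perms(as.character(subset))) {
      a <- stats::setNames(img, v1)
      cons <- sum(paste0(pmin(a[el1[, 1]], a[el1[, 2]]), "\r",
                         pmax(a[el1[, 1]], a[el1[, 2]])) %in% e2)
      best <- max(best, cons / nrow(el1))
    }
  }
  best
}

# brute-force graphlet degree vector (<=4 nodes, standard 15 orbits) by
# enumerating node subsets and classifying with degree sequences -- a
# classification scheme independent of the canonical-form machinery
oracle_gdv4 <- function(g) {
  v <- igraph::V(g)$name
  n <- length(v)
  adj <- lapply(igraph::adjacent_vertices(g, v), function(x) x$name)
  names(adj) <- v
  has <- function(x, y) y %in% adj[[x]]
  counts <- matrix(0L, n, 15, dimnames = list(v, NULL))
  classify <- function(nodes, touched) {
    r <- length(nodes)
    degs <- vapply(nodes, function(x) sum(vapply(setdiff(nodes, x), has,
                                                 logical(1), x = x)),
                   integer(1))
    m <- sum(degs) / 2
    if (any(degs == 0)) return(NA_integer_)  # disconnected
    d <- degs[touched]
    sorted <- paste(sort(degs, decreasing = TRUE), collapse = "")
    if (r == 2) return(0L)
    if (r == 3) {
      if (m == 2) return(if (d == 1) 1L else 2L)
      if (m == 3) return(3L)
    }
    if (r == 4) {
      if (m == 3 && sorted == "2211") return(if (d == 1) 4L else 5L)
      if (m == 3 && sorted == "3111") return(if (d == 1) 6L else 7L)
      if (m == 4 && sorted == "2222") return(8L)
      if (m == 4 && sorted == "3221") return(c(9L, 10L, 11L)[d])
      if (m == 5) return(if (d == 2) 12L else 13L)
      if (m == 6) return(14L)
    }
    NA_integer_
  }
  for (r in 2:4) {
    if (n < r) next
    for (nodes in asplit(combn(v, r), 2)) {
      nodes <- as.character(nodes)
      # connectivity check via reachability
      seen <- nodes[1]
      repeat {
        nxt <- unique(unlist(lapply(seen, function(x) intersect(adj[[x]], nodes))))
        nxt <- union(seen, nxt)
        if (length(nxt) == length(seen)) break
        seen <- nxt
      }
      if (length(seen) < r) next
      for (t in nodes) {
        o <- classify(nodes, t)
        if (!is.na(o)) counts[t, o + 1L] <- counts[t, o + 1L] + 1L
      }
    }
  }
  colnames(counts) <- paste0("orbit", 0:14)
  counts
}

# random injective alignment (plain R, independent of initial_alignment)
random_injection <- function(g1, g2) {
  stats::setNames(sample(igraph::V(g2)$name, igraph::vcount(g1)),
                  igraph::V(g1)$name)
}

# naive transfer-accumulation oracle: explicit triple loop over pairs,
# source records and the exclusion/known checks
oracle_accumulate <- function(naf, floor, source_store, target_known,
                              excl_pairs, whitelist) {
  scores <- list()
  known <- paste0(target_known$protein, "\r", target_known$term)
  ex <- if (is.null(excl_pairs)) character(0) else {
    c(paste0(excl_pairs[, 1], "\r", excl_pairs[, 2]),
      paste0(excl_pairs[, 2], "\r", excl_pairs[, 1]))
  }
  for (i in seq_len(nrow(naf))) {
    if (naf$percent[i] < floor) next
    p <- naf$g1[i]; q <- naf$g2[i]
    if (paste0(p, "\r", q) %in% ex) next
    recs <- source_store[source_store$protein == p, , drop = FALSE]
    for (j in seq_len(nrow(recs))) {
      g <- recs$term[j]; e <- recs$evidence[j]
      if (!(e %in% whitelist)) next
      if (paste0(q, "\r", g) %in% known) next
      key <- paste0(q, "\r", g, "\r", e)
      scores[[key]] <- (if (is.null(scores[[key]])) 0 else scores[[key]]) +
        naf$percent[i]
    }
  }
  scores
}

# small deterministic ensemble shared by several tests (computed lazily once)
.fixture_env <- new.env()
small_ensemble <- function() {
  if (is.null(.fixture_env$ens)) {
    g <- random_graph(40, 0.12, seed = 2)
    pr <- noisy_copy(g, 1, 0.1, seed = 3)
    ens <- run_ensemble(pr$g1, pr$g2, objective_spec("ec"), n_runs = 10L,
                        iterations = 4e5, base_seed = 100L)
    .fixture_env$ens <- list(pair = pr, ens = ens)
  }
  .fixture_env$ens
}
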