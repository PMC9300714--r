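#' Random benchmark graph
#'
#' Deterministic (seeded) Erdos-Renyi or Barabasi-Albert graph with
#' zero-padded string labels, cleaned to the package's graph invariants
#' (no loops, no duplicate edges, no isolated nodes).
#'
#' @param n number of nodes (>= 2).
#' @param edge_prob edge probability for the `er` model.
#' @param degree_exponent preferential-attachment power for the `ba`
#'   model.
#' @param model `"er"` or `"ba"`.
#' @param seed integer seed.
#' @param prefix node-label prefix.
#' @return a cleaned graph.
#' @export
random_graph <- function(n, edge_prob = 0.1, degree_exponent = 1,
                         model = c("er", "ba"), seed = 1L, prefix = "n") {
  model <- match.arg(model)
  if (n < 2L) stop("need n >= 2")
  g <- withr::with_seed(as.integer(seed), {
    if (model == "er") {
      igraph::sample_gnp(n, edge_prob)
    } else {
      igraph::as_undirected(igraph::sample_pa(n, power = degree_exponent,
                                              m = 2))
    }
  })
  igraph::V(g)$name <- sprintf("%s%0*d", prefix, nchar(as.character(n)),
                               seq_len(n))
  g <- tryCatch(validate_ppi_graph(g),
                error = function(e) stop("parameters yield an empty graph"))
  g
}

#' Noisy copy of a graph with known node correspondence
#'
#' Emulates a pair of incompletely observed interactomes of related
#' species: `g2` is a relabelled copy of `g` with each edge deleted with
#' probability `edge_delete_p` and each non-edge added with probability
#' `edge_add_p`; `g1` is the original induced on a random
#' `node_keep_fraction` of the nodes.  The true correspondence between
#' surviving `g1` nodes and their relabelled counterparts is recorded.
#' Both graphs are cleaned; `g1` is restricted to nodes whose partner
#' survived cleaning so the truth mapping stays total and injective.
#' With zero noise and full retention the truth mapping attains EC = 1.
#'
#' @param g source graph.
#' @param node_keep_fraction fraction of nodes retained on the `g1` side.
#' @param edge_delete_p,edge_add_p edge noise probabilities in \[0, 1\].
#' @param relabel_prefix prefix for `g2` labels.
#' @param seed integer seed.
#' @return object of class `synthetic_pair`: list with `g1`, `g2`,
#'   `truth` (named character vector g1 -> g2), `noise_params`, `seed`.
#' @export
noisy_copy <- function(g, node_keep_fraction = 1, edge_delete_p = 0.15,
                       edge_add_p = 0, relabel_prefix = "m", seed = 1L) {
  stopifnot(node_keep_fraction >= 0, node_keep_fraction <= 1,
            edge_delete_p >= 0, edge_delete_p <= 1,
            edge_add_p >= 0, edge_add_p <= 1)
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  twin <- stats::setNames(paste0(relabel_prefix, nodes), nodes)
  res <- withr::with_seed(as.integer(seed), {
    kept <- sort(sample(nodes, round(node_keep_fraction * n)))
    el <- igraph::as_edgelist(g)
    keep_edge <- stats::runif(nrow(el)) >= edge_delete_p
    el2 <- el[keep_edge, , drop = FALSE]
    if (edge_add_p > 0) {
      all_pairs <- t(utils::combn(nodes, 2L))
      key <- paste0(pmin(el[, 1], el[, 2]), "\r", pmax(el[, 1], el[, 2]))
      non <- all_pairs[!(paste0(pmin(all_pairs[, 1], all_pairs[, 2]), "\r",
                                pmax(all_pairs[, 1], all_pairs[, 2])) %in% key),
                       , drop = FALSE]
      add <- non[stats::runif(nrow(non)) < edge_add_p, , drop = FALSE]
      el2 <- rbind(el2, add)
    }
    list(kept = kept, el2 = el2)
  })
  if (nrow(res$el2) == 0L) stop("noise parameters leave an empty graph")
  g2 <- ppi_graph_from_edges(twin[res$el2[, 1]], twin[res$el2[, 2]])
  # g1: original induced on kept nodes, then restricted to nodes whose
  # twin survived g2 cleaning (iterate, since restriction can isolate)
  kept <- res$kept
  g1 <- NULL
  repeat {
    sub <- igraph::induced_subgraph(g, kept)
    sub <- igraph::delete_vertices(sub, which(igraph::degree(sub) == 0L))
    if (igraph::vcount(sub) == 0L) stop("noise parameters leave an empty graph")
    alive <- igraph::V(sub)$name
    ok <- alive[twin[alive] %in% igraph::V(g2)$name]
    if (length(ok) == length(kept) && setequal(ok, kept)) {
      g1 <- validate_ppi_graph(sub)
      break
    }
    kept <- ok
    if (length(kept) < 2L) stop("noise parameters leave an empty graph")
  }
  v1 <- igraph::V(g1)$name
  structure(list(g1 = g1, g2 = g2,
                 truth = stats::setNames(unname(twin[v1]), v1),
                 noise_params = list(node_keep_fraction = node_keep_fraction,
                                     edge_delete_p = edge_delete_p,
                                     edge_add_p = edge_add_p),
                 seed = as.integer(seed)),
            class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf("synthetic_pair: n1=%d m1=%d, n2=%d m2=%d, %d truth pairs\n",
              igraph::vcount(x$g1), igraph::ecount(x$g1),
              igraph::vcount(x$g2), igraph::ecount(x$g2), length(x$truth)))
  invisible(x)
}

#' Synthetic GO world for a graph pair
#'
#' Builds a toy ontology and dated annotation releases around a
#' [noisy_copy()] pair so the full transfer pipeline can be exercised
#' end to end.  A random tree-shaped DAG of `n_terms` terms (depth at
#' most `dag_depth`) is grown under a single biological_process root.
#' Each true pair shares, with probability `share_prob`, one specific
#' term: the source protein carries it in the earlier source release,
#' while the target acquires it only in the later target release (with a
#' non-sequence evidence code) -- these are the planted transfers the
#' pipeline should recover.  All proteins additionally carry decoy terms
#' at rate `decoy_rate` with evidence codes drawn from `evidence_mix`,
#' populating both earlier releases.
#'
#' @param pair a `synthetic_pair`.
#' @param n_terms number of ontology terms below the root.
#' @param dag_depth maximum depth of the term tree (<= n_terms).
#' @param share_prob probability that a true pair has a planted shared
#'   term.
#' @param decoy_rate expected number of decoy annotations per protein.
#' @param evidence_mix named numeric vector of evidence-code
#'   probabilities for source/decoy annotations; the default
#'   `c(EXP = .4, IPI = .3, IDA = .2, IEA = .1)` exercises both the
#'   whitelist and the sequence-filter paths.
#' @param seed integer seed.
#' @return object of class `synthetic_go_world`: list with `dag`,
#'   `earlier_source`, `earlier_target`, `later_target` (annotation
#'   stores) and `planted` (data frame of target/term ground truth).
#' @export
synth_go_world <- function(pair, n_terms = 40L, dag_depth = 4L,
                           share_prob = 0.8, decoy_rate = 0.2,
                           evidence_mix = c(EXP = 0.4, IPI = 0.3,
                                            IDA = 0.2, IEA = 0.1),
                           seed = 1L) {
  stopifnot(share_prob >= 0, share_prob <= 1)
  if (n_terms < dag_depth) stop("n_terms must be at least dag_depth")
  root <- "GO:0000001"
  term_ids <- sprintf("GO:%07d", seq_len(n_terms) + 1L)
  src_prot <- names(pair$truth)
  tgt_prot <- igraph::V(pair$g2)$name
  nonseq <- c("EXP", "IDA", "IPI")
  w <- withr::with_seed(as.integer(seed), {
    depth <- stats::setNames(integer(n_terms), term_ids)
    parent <- stats::setNames(character(n_terms), term_ids)
    for (i in seq_len(n_terms)) {
      shallow <- term_ids[seq_len(i - 1L)][depth[seq_len(i - 1L)] < dag_depth - 1L]
      cand <- c(root, shallow)
      parent[i] <- sample(cand, 1L)
      depth[i] <- if (parent[i] == root) 1L else depth[parent[i]] + 1L
    }
    deep <- term_ids[depth >= max(1L, min(dag_depth - 1L, max(depth)))]
    draw_ev <- function(k) sample(names(evidence_mix), k, replace = TRUE,
                                  prob = evidence_mix)
    # planted shared terms on true pairs
    shared <- src_prot[stats::runif(length(src_prot)) < share_prob]
    planted_term <- if (length(shared)) sample(deep, length(shared),
                                               replace = TRUE) else character(0)
    # decoys: per protein, Poisson(decoy_rate) random terms
    decoys <- function(prots) {
      k <- stats::rpois(length(prots), decoy_rate)
      data.frame(protein = rep(prots, k),
                 term = if (sum(k)) sample(term_ids, sum(k), replace = TRUE)
                        else character(0),
                 evidence = if (sum(k)) draw_ev(sum(k)) else character(0),
                 stringsAsFactors = FALSE)
    }
    list(parent = parent, shared = shared, planted_term = planted_term,
         src_decoys = decoys(src_prot), tgt_decoys = decoys(tgt_prot),
         shared_ev = draw_ev(length(shared)),
         planted_ev = if (length(shared)) sample(nonseq, length(shared),
                                                 replace = TRUE)
                      else character(0))
  })
  obo <- c("format-version: 1.2",
           "default-namespace: biological_process", "",
           "[Term]", paste0("id: ", root), "name: root",
           unlist(lapply(seq_along(term_ids), function(i) {
             c("", "[Term]", paste0("id: ", term_ids[i]),
               paste0("name: term ", i),
               paste0("is_a: ", w$parent[i]))
           })))
  dag <- load_obo(obo, text = TRUE)
  planted <- data.frame(target = unname(pair$truth[w$shared]),
                        term = w$planted_term, stringsAsFactors = FALSE)
  planted <- unique(planted)
  earlier_source <- annotation_store(
    c(w$shared, w$src_decoys$protein),
    c(w$planted_term, w$src_decoys$term),
    c(w$shared_ev, w$src_decoys$evidence),
    "S1")
  # earlier target: decoys only, minus anything that would pre-empt a plant
  tg <- w$tgt_decoys
  tg <- tg[!(paste0(tg$protein, "\r", tg$term) %in%
               paste0(planted$target, "\r", planted$term)), , drop = FALSE]
  earlier_target <- annotation_store(tg$protein, tg$term, tg$evidence, "S2")
  later_target <- annotation_store(
    c(tg$protein, unname(pair$truth[w$shared])),
    c(tg$term, w$planted_term),
    c(tg$evidence, w$planted_ev),
    "S2")
  structure(list(dag = dag, earlier_source = earlier_source,
                 earlier_target = earlier_target,
                 later_target = later_target, planted = planted,
                 seed = as.integer(seed)),
            class = "synthetic_go_world")
}

#' @export
print.synthetic_go_world <- function(x, ...) {
  cat(sprintf(paste0("synthetic_go_world: %d terms, %d planted transfers, ",
                     "%d/%d/%d earlier-source/earlier-target/later-target records\n"),
              length(x$dag$terms), nrow(x$planted),
              nrow(x$earlier_source), nrow(x$earlier_target),
              nrow(x$later_target)))
  invisible(x)
}

#' Write a synthetic annotation store as a GAF 2.2 file
#'
#' Round-trips through [load_gaf()].
#'
#' @param store an `annotation_store`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(store, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  if (nrow(store)) {
    writeLines(paste("DB", store$protein, store$protein, "enables",
                     store$term, "REF", store$evidence, "", "P", "", "",
                     "protein", paste0("taxon:", store$species),
                     "20260101", "DB", sep = "\t"), con)
  }
  invisible(path)
}
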