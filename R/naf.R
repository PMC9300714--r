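#' Network alignment frequency (NAF) table
#'
#' Tallies, over an ensemble of independently generated alignments, how
#' often each (g1 node, g2 node) pair is aligned together.  Pairs that
#' never co-align have an implicit count of zero.  Because every
#' alignment maps each g1 node exactly once, the counts of any g1 node
#' across its partners always sum to the ensemble size `N`.
#'
#' @param alignments a list of alignments (named character vectors over
#'   identical g1 node sets) or of `anneal_result` objects.
#' @return object of class `naf_table`: a data frame with columns `g1`,
#'   `g2`, `count` and `percent` (`100 * count / n_runs`), sorted by
#'   percent descending then lexicographically, with attribute `n_runs`.
#' @export
compute_naf <- function(alignments) {
  if (length(alignments) < 1L) stop("need at least one alignment")
  aligns <- lapply(alignments, function(x) {
    if (inherits(x, "anneal_result")) x$alignment else x
  })
  base_nodes <- sort(names(aligns[[1L]]))
  for (a in aligns) {
    if (!identical(sort(names(a)), base_nodes)) {
      stop("alignments cover inconsistent node sets")
    }
  }
  n_runs <- length(aligns)
  g1 <- unlist(lapply(aligns, names), use.names = FALSE)
  g2 <- unlist(lapply(aligns, unname), use.names = FALSE)
  key <- paste0(g1, "\t", g2)
  tab <- table(key)
  parts <- strsplit(names(tab), "\t", fixed = TRUE)
  out <- data.frame(g1 = vapply(parts, `[[`, character(1), 1L),
                    g2 = vapply(parts, `[[`, character(1), 2L),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$count / n_runs
  out <- out[order(-out$percent, out$g1, out$g2), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_runs = n_runs, class = c("naf_table", "data.frame"))
}

#' @export
print.naf_table <- function(x, ...) {
  cat(sprintf("NAF table: %d pairs over %d runs\n", nrow(x), attr(x, "n_runs")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Aligned pairs at or above a NAF threshold
#'
#' @param naf a [compute_naf()] table.
#' @param threshold_percent NAF threshold in percent (0 < t <= 100); a
#'   pair qualifies when `100 * count / n_runs >= threshold_percent`.
#' @return data frame of qualifying pairs (columns `g1`, `g2`, `count`,
#'   `percent`).  Raising the threshold always yields a subset.
#' @export
pairs_at_threshold <- function(naf, threshold_percent) {
  if (!(threshold_percent > 0)) stop("threshold must be positive")
  out <- as.data.frame(naf)[naf$percent >= threshold_percent, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Common connected subgraph (CCS) of a pair set
#'
#' The CCS has one node per aligned pair; two pairs (p, q) and (p', q')
#' are joined when (p, p') is an edge of `g1` **and** (q, q') is an edge
#' of `g2` -- i.e. the edges conserved in both networks among the aligned
#' nodes.  Its mean degree gauges how much real common topology backs the
#' pair set: the degree-3 criterion requires mean degree >= 3 before
#' trusting annotation transfers from an ensemble.
#'
#' Pairs may share proteins (a many-to-many pair set is allowed); each
#' pair is its own CCS node.
#'
#' @param g1,g2 the aligned graphs.
#' @param pairs data frame with columns `g1`, `g2` (e.g. from
#'   [pairs_at_threshold()]).
#' @return list with `pair_nodes` (the input pairs), `ccs_edges`,
#'   `mean_degree` (`2 * edges / pairs`, 0 when empty), `ec_at_threshold`
#'   (CCS edges over the `g1` edges induced on the pairs' g1-side nodes, 0
#'   when that denominator is 0) and `passes_degree3`.
#' @export
build_ccs <- function(g1, g2, pairs) {
  k <- nrow(pairs)
  if (k == 0L) {
    return(list(pair_nodes = pairs, ccs_edges = 0L, mean_degree = 0,
                ec_at_threshold = 0, passes_degree3 = FALSE))
  }
  stopifnot(all(pairs$g1 %in% igraph::V(g1)$name),
            all(pairs$g2 %in% igraph::V(g2)$name))
  # candidate CCS edges: g1 edges with both endpoints among the pairs
  el1 <- igraph::as_edgelist(igraph::induced_subgraph(g1, unique(pairs$g1)))
  edges <- 0L
  if (nrow(el1) > 0L) {
    by_p <- split(pairs$g2, pairs$g1)
    for (i in seq_len(nrow(el1))) {
      qa <- by_p[[el1[i, 1]]]
      qb <- by_p[[el1[i, 2]]]
      grid <- expand.grid(qa = qa, qb = qb, stringsAsFactors = FALSE)
      if (nrow(grid) > 0L) {
        vp <- as.vector(t(grid))
        edges <- edges + sum(igraph::get_edge_ids(g2, vp) > 0)
      }
    }
  }
  mean_degree <- 2 * edges / k
  m1_induced <- nrow(el1)
  ec_thr <- if (m1_induced > 0L) edges / m1_induced else 0
  list(pair_nodes = pairs, ccs_edges = as.integer(edges),
       mean_degree = mean_degree, ec_at_threshold = ec_thr,
       passes_degree3 = mean_degree >= 3)
}

#' Alignment-quality product at a NAF threshold
#'
#' The product of the NAF threshold (as a fraction), the EC restricted to
#' the thresholded pairs, and the mean degree of the induced CCS.  High
#' values indicate thresholds at which many mutually interacting nodes are
#' robustly co-aligned; low values flag ensembles whose high NAF pairs
#' share little real topology.
#'
#' @param naf_threshold_percent the NAF threshold, in percent.
#' @inheritParams build_ccs
#' @param ccs optional precomputed [build_ccs()] result for these pairs.
#' @return `(threshold/100) * ec_at_threshold * mean_degree`.
#' @export
alignment_quality <- function(naf_threshold_percent, g1, g2, pairs,
                              ccs = NULL) {
  if (is.null(ccs)) ccs <- build_ccs(g1, g2, pairs)
  (naf_threshold_percent / 100) * ccs$ec_at_threshold * ccs$mean_degree
}

#' CCS report across one threshold
#'
#' Convenience wrapper bundling [pairs_at_threshold()], [build_ccs()] and
#' [alignment_quality()].
#'
#' @inheritParams pairs_at_threshold
#' @param g1,g2 the aligned graphs.
#' @return list with `threshold`, `n_pairs`, `ccs_edges`, `mean_degree`,
#'   `ec_at_threshold`, `quality`, `passes_degree3`.
#' @export
ccs_report <- function(naf, g1, g2, threshold_percent) {
  pairs <- pairs_at_threshold(naf, threshold_percent)
  ccs <- build_ccs(g1, g2, pairs)
  list(threshold = threshold_percent,
       n_pairs = nrow(pairs),
       ccs_edges = ccs$ccs_edges,
       mean_degree = ccs$mean_degree,
       ec_at_threshold = ccs$ec_at_threshold,
       quality = alignment_quality(threshold_percent, g1, g2, pairs, ccs),
       passes_degree3 = ccs$passes_degree3)
}

#' Write a NAF table as TSV
#'
#' Columns `g1_node`, `g2_node`, `count`, `percent`, sorted by percent
#' descending then lexicographically.
#'
#' @param naf a [compute_naf()] table.
#' @param path output path.
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
write_naf <- function(naf, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c(sprintf("n_runs=%d", attr(naf, "n_runs")), header)),
             con)
  writeLines("g1_node\tg2_node\tcount\tpercent", con)
  writeLines(sprintf("%s\t%s\t%d\t%g", naf$g1, naf$g2, naf$count, naf$percent),
             con)
  invisible(path)
}

#' Read a NAF table written by [write_naf()]
#'
#' @param path input path.
#' @return a `naf_table`.
#' @export
read_naf <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^# n_runs=", lines)]
  if (length(meta) != 1L) stop("missing n_runs header")
  n_runs <- as.integer(sub("^# n_runs=", "", meta))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  out <- data.frame(g1 = df$g1_node, g2 = df$g2_node,
                    count = as.integer(df$count),
                    percent = as.numeric(df$percent),
                    stringsAsFactors = FALSE)
  structure(out, n_runs = n_runs, class = c("naf_table", "data.frame"))
}
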