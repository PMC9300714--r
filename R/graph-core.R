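#' Read a protein-protein interaction network from an edge list
#'
#' Reads a two-column whitespace- or tab-separated edge list and returns a
#' cleaned undirected [igraph][igraph::igraph-package] graph: duplicate
#' edges and self-loops are removed, and any node left with degree zero
#' after cleaning is dropped (a degree-zero protein carries no topological
#' information).  Extra columns beyond the first two are ignored, as are
#' empty lines and lines starting with `#`.
#'
#' Node labels are opaque, case-sensitive strings.  Vertices are stored in
#' lexicographic order so that seeded downstream computations are
#' reproducible regardless of the input row order.
#'
#' @param source path to a file, or a connection, or a character vector of
#'   lines when `text = TRUE`.
#' @param text logical; if `TRUE`, `source` is taken to be the lines
#'   themselves rather than a path.
#' @return an undirected `igraph` object satisfying the cleaning
#'   invariants (no loops, no multi-edges, no isolated nodes).
#' @seealso [graph_stats()], [write_edgelist()]
#' @examples
#' g <- read_edgelist(c("a b", "b c", "c a", "a b"), text = TRUE)
#' graph_stats(g)
#' @export
read_edgelist <- function(source, text = FALSE) {
  lines <- if (text) as.character(source) else readLines(source)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty graph")
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("malformed edge-list row at line %d: need 2 fields",
                 which(nf < 2L)[1L]))
  }
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, `[[`, character(1), 2L)
  ppi_graph_from_edges(from, to)
}

#' @keywords internal
ppi_graph_from_edges <- function(from, to) {
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  if (length(from) == 0L) stop("empty graph")
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste0(a, "\r", b)
  dup <- duplicated(key)
  a <- a[!dup]
  b <- b[!dup]
  nodes <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(data.frame(from = a, to = b,
                                                stringsAsFactors = FALSE),
                                     directed = FALSE,
                                     vertices = nodes)
  validate_ppi_graph(g)
}

#' @keywords internal
validate_ppi_graph <- function(g) {
  g <- igraph::simplify(g)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
  if (igraph::vcount(g) == 0L) stop("empty graph")
  # keep vertex order lexicographic for reproducible iteration
  g <- igraph::permute(g, order(order(igraph::V(g)$name)))
  g
}

#' Summary statistics of a cleaned network
#'
#' @param g a cleaned graph as returned by [read_edgelist()].
#' @return a list with `n` (nodes), `m` (edges), `mean_degree` (`2m/n`) and
#'   `max_degree`.
#' @export
graph_stats <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n == 0L) stop("empty graph")
  deg <- igraph::degree(g)
  list(n = n, m = m, mean_degree = 2 * m / n, max_degree = max(deg))
}

#' Write a network as a two-column edge list
#'
#' Inverse of [read_edgelist()]: writing then re-reading reproduces the
#' identical node and edge sets.
#'
#' @param g graph to serialize.
#' @param path output file path.
#' @param header optional character vector of comment lines (written with a
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path, header = NULL) {
  el <- igraph::as_edgelist(g)
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  o <- order(a, b)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(a[o], b[o], sep = "\t"), con)
  invisible(path)
}

#' @keywords internal
graph_adjacency_0 <- function(g) {
  lapply(igraph::adjacent_vertices(g, igraph::V(g)),
         function(v) as.integer(v) - 1L)
}
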