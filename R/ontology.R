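#' Load a GO-style ontology from an OBO 1.2 file
#'
#' Minimal reader for the term stanzas of an OBO 1.2 ontology: `is_a`
#' links (and optionally `relationship: part_of`) define the DAG,
#' obsolete terms are skipped, and `alt_id`s are resolved to their primary
#' identifiers.  Each namespace (e.g. biological_process) has a single
#' root, the one term without parents.
#'
#' @param source file path, connection, or character vector of lines when
#'   `text = TRUE`.
#' @param part_of logical; also treat `relationship: part_of` as a parent
#'   link (off by default -- the smallest defensible closure).
#' @param text logical; treat `source` as the lines themselves.
#' @return an object of class `go_dag`: list with `terms`, `parents`
#'   (named list), `namespace` (named character), `roots` (named by
#'   namespace), `alt` (alt id -> primary id), and a memoised ancestor
#'   lookup.
#' @export
load_obo <- function(source, part_of = FALSE, text = FALSE) {
  lines <- if (text) as.character(source) else readLines(source)
  starts <- grep("^\\[", lines)
  starts <- c(starts, length(lines) + 1L)
  terms <- character(0)
  parents <- list()
  namespace <- character(0)
  alt <- character(0)
  default_ns <- sub("^default-namespace: *", "",
                    grep("^default-namespace:", lines, value = TRUE)[1])
  if (is.na(default_ns)) default_ns <- "biological_process"
  i <- 1L
  while (i < length(starts)) {
    block <- lines[starts[i]:(starts[i + 1L] - 1L)]
    i <- i + 1L
    if (!grepl("^\\[Term\\]", block[1L])) next
    field <- function(key) {
      sub(paste0("^", key, ": *"), "",
          grep(paste0("^", key, ":"), block, value = TRUE))
    }
    if (length(field("is_obsolete")) && any(field("is_obsolete") == "true")) next
    id <- field("id")[1]
    if (is.na(id) || !nzchar(id)) next
    ns <- field("namespace")[1]
    if (is.na(ns)) ns <- default_ns
    isa <- sub(" *!.*$", "", field("is_a"))
    if (part_of) {
      rel <- field("relationship")
      po <- sub(" *!.*$", "", sub("^part_of *", "", rel[grepl("^part_of ", rel)]))
      isa <- c(isa, po)
    }
    terms <- c(terms, id)
    parents[[id]] <- isa
    namespace[id] <- ns
    for (aid in field("alt_id")) alt[aid] <- id
  }
  if (length(terms) == 0L) stop("no terms found")
  unknown <- setdiff(unlist(parents), terms)
  if (length(unknown)) {
    stop("unknown parent id(s): ", paste(unknown, collapse = ", "))
  }
  dag <- structure(list(terms = terms, parents = parents,
                        namespace = namespace, alt = alt,
                        anc_cache = new.env(parent = emptyenv())),
                   class = "go_dag")
  # acyclicity + per-namespace roots
  anc <- lapply(terms, function(t) term_ancestors(dag, t))
  names(anc) <- terms
  rootless <- terms[lengths(parents[terms]) == 0L]
  roots <- character(0)
  for (ns in unique(namespace)) {
    r <- rootless[namespace[rootless] == ns]
    if (length(r) != 1L) {
      stop(sprintf("namespace %s must have exactly one root, found %d",
                   ns, length(r)))
    }
    roots[ns] <- r
    non_root <- setdiff(terms[namespace[terms] == ns], r)
    bad <- non_root[!vapply(non_root, function(t) r %in% anc[[t]], logical(1))]
    if (length(bad)) {
      stop("term(s) cannot reach the namespace root: ",
           paste(bad, collapse = ", "))
    }
  }
  dag$roots <- roots
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d namespace(s): %s\n",
              length(x$terms), length(x$roots),
              paste(names(x$roots), collapse = ", ")))
  invisible(x)
}

#' Write an ontology back to OBO 1.2
#'
#' Serializes the term stanzas (`is_a` links only); round-trips through
#' [load_obo()].
#'
#' @param dag a [load_obo()] ontology.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2",
               paste0("default-namespace: ", names(dag$roots)[1L])), con)
  for (t in dag$terms) {
    isa <- dag$parents[[t]]
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("namespace: ", dag$namespace[[t]]),
                 if (length(isa)) paste0("is_a: ", isa)), con)
  }
  invisible(path)
}

#' Resolve a term id (following alt_id mappings)
#'
#' @param dag a [load_obo()] ontology.
#' @param term term identifier(s).
#' @return primary identifier(s); `NA` for unknown terms.
#' @export
resolve_term <- function(dag, term) {
  out <- ifelse(term %in% dag$terms, term, unname(dag$alt[term]))
  out[!out %in% dag$terms] <- NA_character_
  out
}

#' Proper ancestors of a term
#'
#' @param dag a [load_obo()] ontology.
#' @param term a single term id.
#' @return character vector of ancestors (excluding the term itself).
#' @export
term_ancestors <- function(dag, term) {
  cache <- dag$anc_cache
  if (!is.null(cache[[term]])) return(cache[[term]])
  seen <- character(0)
  frontier <- dag$parents[[term]]
  guard <- 0L
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(dag$parents[frontier])), seen)
    guard <- guard + 1L
    if (guard > length(dag$terms) + 1L) stop("cycle detected in ontology")
  }
  if (term %in% seen) stop("cycle detected in ontology at ", term)
  cache[[term]] <- seen
  seen
}
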