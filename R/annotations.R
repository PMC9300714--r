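#' Sequence-based GO evidence codes
#'
#' Default set of evidence codes disallowed under "NOSEQ" filtering: any
#' code through which sequence comparison could have influenced the
#' annotation, including manually curated sequence transfer.
#'
#' @return character vector of evidence codes.
#' @export
disallowed_evidence <- function() {
  c("IBA", "IEA", "ISM", "ISA", "ISO", "IGC", "RCA", "ISS")
}

#' @keywords internal
new_annotation_store <- function(df, propagated = FALSE) {
  df <- df[, c("protein", "term", "evidence", "species"), drop = FALSE]
  df <- unique(df)
  rownames(df) <- NULL
  structure(df, propagated = propagated,
            class = c("annotation_store", "data.frame"))
}

#' Build an annotation store from records
#'
#' @param protein,term,evidence,species equal-length character vectors of
#'   annotation records (one `(protein, term, evidence)` triple per
#'   entry); `species` tags each protein's species.
#' @return object of class `annotation_store`: a data frame of unique
#'   triples with a `propagated` attribute.
#' @export
annotation_store <- function(protein, term, evidence, species) {
  if (length(protein) == 0L) {
    return(new_annotation_store(data.frame(protein = character(0),
                                           term = character(0),
                                           evidence = character(0),
                                           species = character(0),
                                           stringsAsFactors = FALSE)))
  }
  stopifnot(grepl("^[A-Z]{2,3}$", evidence))
  new_annotation_store(data.frame(protein = protein, term = term,
                                  evidence = evidence,
                                  species = rep_len(species, length(protein)),
                                  stringsAsFactors = FALSE))
}

#' @export
print.annotation_store <- function(x, ...) {
  cat(sprintf("annotation_store: %d records, %d proteins, %d terms (%s)\n",
              nrow(x), length(unique(x$protein)), length(unique(x$term)),
              if (isTRUE(attr(x, "propagated"))) "propagated" else "direct"))
  invisible(x)
}

#' Load annotations from a GAF 2.x file
#'
#' Reads the tab-separated Gene Association File format: comment lines
#' (`!`) are ignored, rows carrying a `NOT` qualifier are dropped, and
#' each remaining row yields one (protein, term, evidence) record.
#'
#' @param source path, connection, or lines when `text = TRUE`.
#' @param species species tag to assign to these proteins (defaults to
#'   GAF column 13, first taxon, when present).
#' @param id_column which column identifies the protein: 2 (DB object id)
#'   or 3 (DB object symbol).
#' @param text logical; treat `source` as lines.
#' @return an `annotation_store` (unpropagated).
#' @export
load_gaf <- function(source, species = NULL, id_column = 2L, text = FALSE) {
  lines <- if (text) as.character(source) else readLines(source)
  lines <- lines[!grepl("^!", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(annotation_store(character(0), character(0), character(0),
                            character(0)))
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(rows) < 7L)
  if (length(bad)) {
    stop(sprintf("malformed GAF row at line %d: fewer than 7 columns", bad[1L]))
  }
  col <- function(k) vapply(rows, function(r) r[[k]], character(1))
  qualifier <- col(4L)
  keep <- !grepl("(^|\\|)NOT(\\||$)", qualifier)
  if (!any(keep)) {
    return(annotation_store(character(0), character(0), character(0),
                            character(0)))
  }
  rows <- rows[keep]
  protein <- vapply(rows, function(r) r[[id_column]], character(1))
  term <- vapply(rows, function(r) r[[5L]], character(1))
  evidence <- vapply(rows, function(r) r[[7L]], character(1))
  if (is.null(species)) {
    taxa <- vapply(rows, function(r) if (length(r) >= 13L) r[[13L]] else "",
                   character(1))
    species <- sub("\\|.*$", "", taxa[1L])
    if (!nzchar(species)) species <- "unknown"
  }
  annotation_store(protein, term, evidence, species)
}

#' Remove annotations backed by sequence-based evidence
#'
#' In `"record"` mode only the offending (protein, term, evidence)
#' triples are dropped.  In `"strict"` mode (the default, and the rule
#' used for transfer scoring) any (protein, term) association supported
#' by at least one disallowed code is removed entirely -- including its
#' non-sequence records -- so that no annotation that sequence evidence
#' ever touched survives.
#'
#' @param store an unpropagated `annotation_store`.
#' @param disallowed evidence codes to treat as sequence-based
#'   ([disallowed_evidence()] by default).
#' @param mode `"strict"` or `"record"`.
#' @return filtered `annotation_store`.  Strict output is always a subset
#'   of record-mode output, which is a subset of the input.
#' @export
filter_noseq <- function(store, disallowed = disallowed_evidence(),
                         mode = c("strict", "record")) {
  mode <- match.arg(mode)
  if (isTRUE(attr(store, "propagated"))) {
    stop("filter before propagating, not after")
  }
  if (nrow(store) == 0L) return(store)
  if (mode == "record") {
    keep <- !(store$evidence %in% disallowed)
  } else {
    bad_pair <- unique(paste0(store$protein, "\r", store$term)[
      store$evidence %in% disallowed])
    keep <- !(paste0(store$protein, "\r", store$term) %in% bad_pair)
  }
  new_annotation_store(as.data.frame(store)[keep, , drop = FALSE])
}

#' Propagate annotations up the ontology
#'
#' Each (protein, term) record also annotates every ancestor of the term
#' within its namespace (the true-path rule), carrying its evidence code
#' along.  Idempotent.  Terms not found in the ontology (after alt-id
#' resolution) are skipped with a warning that counts them.
#'
#' @param store an unpropagated `annotation_store`.
#' @param dag a [load_obo()] ontology.
#' @return a propagated `annotation_store`.
#' @export
propagate <- function(store, dag) {
  if (isTRUE(attr(store, "propagated"))) return(store)
  if (nrow(store) == 0L) {
    return(new_annotation_store(as.data.frame(store), propagated = TRUE))
  }
  df <- as.data.frame(store)
  df$term <- resolve_term(dag, df$term)
  n_bad <- sum(is.na(df$term))
  if (n_bad > 0L) {
    warning(sprintf("skipping %d record(s) with terms absent from the ontology",
                    n_bad))
    df <- df[!is.na(df$term), , drop = FALSE]
    if (nrow(df) == 0L) {
      return(new_annotation_store(df, propagated = TRUE))
    }
  }
  anc <- lapply(unique(df$term), function(t) c(t, term_ancestors(dag, t)))
  names(anc) <- unique(df$term)
  reps <- lengths(anc)[df$term]
  out <- data.frame(protein = rep(df$protein, reps),
                    term = unlist(anc[df$term], use.names = FALSE),
                    evidence = rep(df$evidence, reps),
                    species = rep(df$species, reps),
                    stringsAsFactors = FALSE)
  new_annotation_store(out, propagated = TRUE)
}

#' Information content of ontology terms
#'
#' For a propagated annotation corpus, `IC(t) = -ln(n_t / n_root)` where
#' `n_t` is the number of distinct proteins annotated with `t` and
#' `n_root` the number annotated with the root of `t`'s namespace.  The
#' root always has IC 0; terms annotating no protein in the corpus have
#' no defined IC and are absent from the result.
#'
#' @param corpus a propagated, non-empty `annotation_store` (the IC
#'   corpus; by convention the union of both species' filtered,
#'   propagated annotations).
#' @param dag a [load_obo()] ontology.
#' @return named numeric vector of information contents.
#' @export
information_content <- function(corpus, dag) {
  if (!isTRUE(attr(corpus, "propagated"))) stop("corpus must be propagated")
  if (nrow(corpus) == 0L) stop("empty corpus")
  pt <- unique(data.frame(protein = corpus$protein, term = corpus$term,
                          stringsAsFactors = FALSE))
  counts <- table(pt$term)
  ic <- numeric(0)
  for (ns in names(dag$roots)) {
    root <- dag$roots[[ns]]
    n_root <- counts[root]
    if (is.na(n_root)) next
    ns_terms <- intersect(names(counts), dag$terms[dag$namespace == ns])
    ic[ns_terms] <- -log(as.numeric(counts[ns_terms]) / as.numeric(n_root))
  }
  ic
}

#' Max-variant Resnik semantic similarity of two proteins
#'
#' The maximum, over pairs of terms annotating the two proteins within a
#' shared namespace, of the information content of the pair's most
#' informative common ancestor.  Because the annotation sets are
#' propagated, the most informative common ancestor over all term pairs
#' is simply the highest-IC term annotating both proteins.
#'
#' @param p,q protein identifiers.
#' @param corpus propagated `annotation_store` holding both proteins'
#'   annotations (also the IC corpus unless `ic` is supplied).
#' @param dag a [load_obo()] ontology.
#' @param ic optional precomputed [information_content()] vector.
#' @param namespace_filter optional namespace name(s) to restrict to.
#' @return non-negative similarity, or `NA` ("no score") when either
#'   protein has no usable annotation -- such pairs are excluded from
#'   curves rather than scored 0.
#' @export
resnik_max <- function(p, q, corpus, dag, ic = NULL, namespace_filter = NULL) {
  if (is.null(ic)) ic <- information_content(corpus, dag)
  tp <- corpus$term[corpus$protein == p]
  tq <- corpus$term[corpus$protein == q]
  if (!is.null(namespace_filter)) {
    keep <- dag$namespace[tp] %in% namespace_filter
    tp <- tp[keep]
    tq <- tq[dag$namespace[tq] %in% namespace_filter]
  }
  common <- intersect(tp, tq)
  common <- common[common %in% names(ic)]
  if (length(tp) == 0L || length(tq) == 0L) return(NA_real_)
  if (length(common) == 0L) return(NA_real_)
  max(ic[common])
}

#' @keywords internal
resnik_for_pairs <- function(pairs, corpus, dag, ic = NULL,
                             namespace_filter = NULL) {
  if (is.null(ic)) ic <- information_content(corpus, dag)
  terms_by_protein <- split(corpus$term, corpus$protein)
  if (!is.null(namespace_filter)) {
    keep_ns <- names(dag$namespace)[dag$namespace %in% namespace_filter]
    terms_by_protein <- lapply(terms_by_protein, intersect, keep_ns)
  }
  vapply(seq_len(nrow(pairs)), function(i) {
    tp <- terms_by_protein[[pairs$g1[i]]]
    tq <- terms_by_protein[[pairs$g2[i]]]
    if (is.null(tp) || is.null(tq) || !length(tp) || !length(tq)) {
      return(NA_real_)
    }
    common <- intersect(tp, tq)
    common <- common[common %in% names(ic)]
    if (!length(common)) return(NA_real_)
    max(ic[common])
  }, numeric(1))
}

#' Is a protein well-annotated at level (S, M)?
#'
#' A protein passes the (S, M) filter when at least `S` distinct GO terms
#' annotate it, each of which annotates at most `M` proteins in its
#' species.  Small `M` demands specific terms; large `S` demands many of
#' them.  Counts use direct (unpropagated) annotations.
#'
#' @param protein protein identifier(s).
#' @param store unpropagated `annotation_store` containing the protein's
#'   species.
#' @param S,M filter parameters (integers >= 1).
#' @param per_species_counts optional precomputed
#'   [species_term_counts()] result.
#' @return logical vector.
#' @export
well_annotated <- function(protein, store, S, M, per_species_counts = NULL) {
  stopifnot(S >= 1, M >= 1)
  if (is.null(per_species_counts)) {
    per_species_counts <- species_term_counts(store)
  }
  pt <- unique(data.frame(protein = store$protein, term = store$term,
                          species = store$species, stringsAsFactors = FALSE))
  pt$cnt <- per_species_counts[paste0(pt$species, "\r", pt$term)]
  ok <- pt[pt$cnt <= M, , drop = FALSE]
  n_specific <- table(ok$protein)
  cnt <- as.integer(n_specific[protein])
  cnt[is.na(cnt)] <- 0L
  cnt >= S
}

#' Per-species term annotation counts
#'
#' Number of distinct proteins each term directly annotates, per species.
#'
#' @param store unpropagated `annotation_store`.
#' @return named integer vector keyed by `species\rterm`.
#' @export
species_term_counts <- function(store) {
  pt <- unique(data.frame(protein = store$protein, term = store$term,
                          species = store$species, stringsAsFactors = FALSE))
  tab <- table(paste0(pt$species, "\r", pt$term))
  stats::setNames(as.integer(tab), names(tab))
}
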