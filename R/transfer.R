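#' Cross-species exclusion sets
#'
#' Pairs of cross-species proteins that must never source a transfer:
#' sequence-similar pairs (e.g. from a precomputed BLAST run) and known
#' ortholog pairs (even distant ones).  Membership tests are symmetric in
#' the pair order.
#'
#' @param seq_similar_pairs,ortholog_pairs data frames (or 2-column
#'   matrices) of cross-species protein label pairs; `NULL` for none.
#' @return object of class `exclusion_sets`.
#' @export
exclusion_sets <- function(seq_similar_pairs = NULL, ortholog_pairs = NULL) {
  norm <- function(x) {
    if (is.null(x) || NROW(x) == 0L) return(character(0))
    x <- as.matrix(x)[, 1:2, drop = FALSE]
    c(paste0(x[, 1], "\r", x[, 2]), paste0(x[, 2], "\r", x[, 1]))
  }
  structure(list(keys = unique(c(norm(seq_similar_pairs),
                                 norm(ortholog_pairs)))),
            class = "exclusion_sets")
}

#' @keywords internal
is_excluded <- function(exclusions, p, q) {
  if (is.null(exclusions) || length(exclusions$keys) == 0L ||
      length(p) == 0L) {
    return(rep(FALSE, length(p)))
  }
  paste0(p, "\r", q) %in% exclusions$keys
}

#' Read a 2-column pair list (e.g. precomputed BLAST hits or orthologs)
#'
#' @param path TSV file of cross-species protein pairs; `#` comments
#'   ignored.
#' @return data frame with columns `a`, `b`.
#' @export
read_pair_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  data.frame(a = vapply(parts, `[[`, character(1), 1L),
             b = vapply(parts, `[[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Accumulate NAF-weighted annotation transfers
#'
#' For every aligned pair (p, q) with NAF at or above the floor and not
#' excluded, every (term g, evidence e) annotating source protein p with
#' whitelisted evidence contributes the pair's NAF percentage to the
#' cumulative score of the candidate annotation (q, g, e) -- unless q
#' already carried g at the earlier date under *any* evidence code, in
#' which case nothing is transferred (it would not be a novel
#' prediction).  Contributions from multiple source proteins aligned to
#' the same target add up.
#'
#' @param naf a [compute_naf()] table whose `g1` side is the source
#'   species and `g2` side the target.
#' @param naf_floor_percent minimum NAF (percent) for a pair to
#'   contribute (default 2, the conventional reporting floor).
#' @param source_store unpropagated, strict-NOSEQ-filtered annotations of
#'   the source species at the earlier date.
#' @param target_known unpropagated annotations of the target species at
#'   the earlier date, any evidence (used only to suppress already-known
#'   annotations).
#' @param exclusions an [exclusion_sets()] (or `NULL`).
#' @param evidence_whitelist source evidence codes allowed to drive
#'   transfers; default `c("IPI", "EXP", "IDA")`, the experimentally
#'   grounded codes with the greatest predictive power.
#' @return object of class `prediction_ledger`: data frame with columns
#'   `target`, `term`, `evidence`, `score` (cumulative NAF percent),
#'   `n_sources`; attributes `naf_floor` and `n_runs`.
#' @export
accumulate <- function(naf, naf_floor_percent = 2, source_store,
                       target_known, exclusions = NULL,
                       evidence_whitelist = c("IPI", "EXP", "IDA")) {
  if (isTRUE(attr(source_store, "propagated")) ||
      isTRUE(attr(target_known, "propagated"))) {
    stop("accumulate expects unpropagated stores")
  }
  pairs <- pairs_at_threshold(naf, naf_floor_percent)
  pairs <- pairs[!is_excluded(exclusions, pairs$g1, pairs$g2), , drop = FALSE]
  src <- as.data.frame(source_store)
  src <- src[src$evidence %in% evidence_whitelist, , drop = FALSE]
  empty <- data.frame(target = character(0), term = character(0),
                      evidence = character(0), score = numeric(0),
                      n_sources = integer(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L || nrow(src) == 0L) {
    return(structure(empty, naf_floor = naf_floor_percent,
                     n_runs = attr(naf, "n_runs"),
                     class = c("prediction_ledger", "data.frame")))
  }
  merged <- merge(pairs, src, by.x = "g1", by.y = "protein")
  if (nrow(merged) == 0L) {
    return(structure(empty, naf_floor = naf_floor_percent,
                     n_runs = attr(naf, "n_runs"),
                     class = c("prediction_ledger", "data.frame")))
  }
  known <- unique(paste0(target_known$protein, "\r", target_known$term))
  merged <- merged[!(paste0(merged$g2, "\r", merged$term) %in% known), ,
                   drop = FALSE]
  if (nrow(merged) == 0L) {
    return(structure(empty, naf_floor = naf_floor_percent,
                     n_runs = attr(naf, "n_runs"),
                     class = c("prediction_ledger", "data.frame")))
  }
  key <- paste0(merged$g2, "\r", merged$term, "\r", merged$evidence)
  score <- tapply(merged$percent, key, sum)
  n_src <- tapply(merged$g1, key, function(x) length(unique(x)))
  parts <- strsplit(names(score), "\r", fixed = TRUE)
  out <- data.frame(target = vapply(parts, `[[`, character(1), 1L),
                    term = vapply(parts, `[[`, character(1), 2L),
                    evidence = vapply(parts, `[[`, character(1), 3L),
                    score = as.numeric(score),
                    n_sources = as.integer(n_src),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$target, out$term, out$evidence), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, naf_floor = naf_floor_percent, n_runs = attr(naf, "n_runs"),
            class = c("prediction_ledger", "data.frame"))
}

#' @export
print.prediction_ledger <- function(x, ...) {
  cat(sprintf("prediction_ledger: %d candidate annotations (NAF floor %g%%)\n",
              nrow(x), attr(x, "naf_floor")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Predictable-in-principle membership
#'
#' A (target protein, term) association is predictable in principle from
#' the earlier data when (a) the target protein occurs in the earlier
#' target network (otherwise it could never be aligned), and (b) at least
#' one non-excluded source protein carried the term at the earlier date.
#' When every source protein carrying the term is excluded against this
#' particular target, the association is not predictable for it.
#'
#' @param target_protein,term vectors (recycled to common length).
#' @param earlier_target_graph the earlier-dated target network.
#' @param earlier_source_store unpropagated, strict-filtered source
#'   annotations at the earlier date.
#' @param exclusions an [exclusion_sets()] (or `NULL`).
#' @return logical vector.
#' @export
p12_membership <- function(target_protein, term, earlier_target_graph,
                           earlier_source_store, exclusions = NULL) {
  n <- max(length(target_protein), length(term))
  target_protein <- rep_len(target_protein, n)
  term <- rep_len(term, n)
  in_net <- target_protein %in% igraph::V(earlier_target_graph)$name
  carriers <- split(earlier_source_store$protein, earlier_source_store$term)
  has_source <- vapply(seq_len(n), function(i) {
    ps <- unique(carriers[[term[i]]])
    if (is.null(ps) || !length(ps)) return(FALSE)
    any(!is_excluded(exclusions, ps, rep(target_protein[i], length(ps))))
  }, logical(1))
  in_net & has_source
}

#' Evaluation sets for time-split validation
#'
#' Materializes the validated ground truth: the later release's
#' (protein, term) annotations that carry at least one non-sequence
#' evidence code (optionally discarding any association that sequence
#' evidence touched by the later date), intersected with the
#' predictable-in-principle set.  The size of that intersection is the
#' recall denominator.
#'
#' @param later_store unpropagated target-species annotations at the
#'   later date (unfiltered; filtering happens here).
#' @param earlier_target_graph earlier target network.
#' @param earlier_source_store unpropagated strict-filtered source
#'   annotations at the earlier date.
#' @param exclusions an [exclusion_sets()] (or `NULL`).
#' @param seq_discard `"any"` (default): drop later associations carrying
#'   any sequence evidence, even alongside experimental evidence;
#'   `"only"`: drop only those whose every evidence code is
#'   sequence-based.
#' @param disallowed sequence evidence codes.
#' @return object of class `evaluation_sets`: list with `validated_keys`
#'   (set of `target\rterm`), `discarded_keys` (associations removed by
#'   the sequence rule, excluded from numerator and denominator) and
#'   `denominator`.
#' @export
evaluation_sets <- function(later_store, earlier_target_graph,
                            earlier_source_store, exclusions = NULL,
                            seq_discard = c("any", "only"),
                            disallowed = disallowed_evidence()) {
  seq_discard <- match.arg(seq_discard)
  df <- as.data.frame(later_store)
  key <- paste0(df$protein, "\r", df$term)
  is_seq <- df$evidence %in% disallowed
  has_seq <- unique(key[is_seq])
  has_nonseq <- unique(key[!is_seq])
  discarded <- if (seq_discard == "any") has_seq else setdiff(has_seq, has_nonseq)
  validated <- setdiff(has_nonseq, discarded)
  vparts <- strsplit(validated, "\r", fixed = TRUE)
  vp <- vapply(vparts, `[[`, character(1), 1L)
  vt <- vapply(vparts, `[[`, character(1), 2L)
  ok <- p12_membership(vp, vt, earlier_target_graph, earlier_source_store,
                       exclusions)
  structure(list(validated_keys = validated[ok],
                 discarded_keys = discarded,
                 denominator = sum(ok)),
            class = "evaluation_sets")
}

#' Precision and recall at a score threshold
#'
#' Predictions are the distinct (target, term) associations whose
#' cumulative transfer score reaches `Phi` (optionally within selected
#' evidence codes).  A prediction is validated when it appears in the
#' later release with non-sequence evidence; associations the sequence
#' rule discarded count in neither numerator nor denominator.
#'
#' @param ledger a [accumulate()] ledger.
#' @param Phi cumulative-score threshold (> 0).
#' @param eval_sets an [evaluation_sets()] object.
#' @param evidence optional evidence code(s) to restrict the ledger to.
#' @return list with `n_pred`, `n_valid`, `precision` (`NA` when there
#'   are no predictions) and `recall`.
#' @export
evaluate_at_threshold <- function(ledger, Phi, eval_sets, evidence = NULL) {
  if (!(Phi > 0)) stop("Phi must be positive")
  df <- as.data.frame(ledger)
  if (!is.null(evidence)) df <- df[df$evidence %in% evidence, , drop = FALSE]
  df <- df[df$score >= Phi, , drop = FALSE]
  keys <- if (nrow(df)) unique(paste0(df$target, "\r", df$term)) else character(0)
  keys <- setdiff(keys, eval_sets$discarded_keys)
  n_pred <- length(keys)
  n_valid <- sum(keys %in% eval_sets$validated_keys)
  list(n_pred = n_pred, n_valid = n_valid,
       precision = if (n_pred > 0L) n_valid / n_pred else NA_real_,
       recall = if (eval_sets$denominator > 0L) {
         n_valid / eval_sets$denominator
       } else 0)
}

#' Precision-recall sweep, AUPR and F*
#'
#' Sweeps the distinct cumulative scores in descending order, computing
#' precision and recall at each.  AUPR is the right-continuous step sum
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} (with \eqn{R_0 = 0}); F* is the best
#' F1 over the sweep.
#'
#' @inheritParams evaluate_at_threshold
#' @return list with `curve` (data frame `threshold`, `n_pred`,
#'   `n_valid`, `precision`, `recall`), `aupr`, `f_star`,
#'   `phi_at_f_star`.
#' @export
pr_curve_and_summary <- function(ledger, eval_sets, evidence = NULL) {
  df <- as.data.frame(ledger)
  if (!is.null(evidence)) df <- df[df$evidence %in% evidence, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty prediction ledger")
  if (eval_sets$denominator == 0L) stop("no validatable ground truth")
  thresholds <- sort(unique(df$score), decreasing = TRUE)
  rows <- lapply(thresholds, function(phi) {
    ev <- evaluate_at_threshold(ledger, phi, eval_sets, evidence)
    data.frame(threshold = phi, n_pred = ev$n_pred, n_valid = ev$n_valid,
               precision = ev$precision, recall = ev$recall)
  })
  curve <- do.call(rbind, rows)
  prec <- ifelse(is.na(curve$precision), 0, curve$precision)
  rec <- curve$recall
  aupr <- sum((rec - c(0, rec[-length(rec)])) * prec)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  best <- which.max(f1)
  list(curve = curve, aupr = aupr, f_star = f1[best],
       phi_at_f_star = curve$threshold[best])
}

#' Write a prediction ledger as TSV
#'
#' @param ledger a [accumulate()] ledger.
#' @param path output path.
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(ledger, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", c(sprintf("naf_floor=%g", attr(ledger, "naf_floor")),
                            header)), con)
  writeLines("target_protein\tgo_id\tevidence_code\tcumulative_score\tn_source_proteins",
             con)
  writeLines(sprintf("%s\t%s\t%s\t%g\t%d", ledger$target, ledger$term,
                     ledger$evidence, ledger$score, ledger$n_sources), con)
  invisible(path)
}
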