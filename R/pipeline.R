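#' Run an alignment ensemble and tally NAF
#'
#' Runs `n_runs` independent simulated-annealing alignments (run r uses
#' seed `base_seed + r - 1`) and tallies the alignment-frequency table.
#' If `n1 > n2` the inputs are swapped automatically with a warning.
#'
#' @param g1,g2 cleaned graphs.
#' @param spec an [objective_spec()].
#' @param n_runs ensemble size (the conventional choice is 100;
#'   fixture-scale work uses fewer).
#' @param iterations proposals per run.
#' @param base_seed integer base seed.
#' @param schedule optional shared [anneal_schedule()]; by default a
#'   schedule is auto-tuned once (from `base_seed`) and reused for every
#'   run.
#' @param out_dir optional directory to write per-run alignment files and
#'   the NAF TSV into.
#' @param verbose log per-run final scores to stderr.
#' @return list with `alignments` (list of `anneal_result`), `naf` (a
#'   `naf_table`), `scores` (per-run final scores), `spec`, `swapped`.
#' @export
run_ensemble <- function(g1, g2, spec = objective_spec("ec"), n_runs = 100L,
                         iterations = 1e7, base_seed = 1L, schedule = NULL,
                         out_dir = NULL, verbose = FALSE) {
  swapped <- FALSE
  if (igraph::vcount(g1) > igraph::vcount(g2)) {
    warning("n1 > n2: swapping input order")
    tmp <- g1; g1 <- g2; g2 <- tmp
    swapped <- TRUE
  }
  sim <- if (objective_code(spec) == 2L) node_similarity_matrix(g1, g2, spec)
         else NULL
  if (is.null(schedule)) {
    schedule <- auto_schedule(g1, g2, spec, base_seed,
                              iterations = iterations, sim = sim)
  }
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    seed_r <- as.integer(base_seed) + r - 1L
    runs[[r]] <- anneal(g1, g2, spec, schedule, seed = seed_r, sim = sim)
    if (verbose) {
      message(sprintf("run %d/%d seed=%d final=%.6f", r, n_runs, seed_r,
                      runs[[r]]$final_score))
    }
  }
  naf <- compute_naf(runs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- sprintf("objective=%s n_runs=%d iterations=%s base_seed=%d",
                   spec$name, n_runs,
                   format(iterations, scientific = FALSE), base_seed)
    for (r in seq_len(n_runs)) {
      write_alignment(runs[[r]],
                      file.path(out_dir, sprintf("alignment_%03d.tsv", r)),
                      extra = cfg)
    }
    write_naf(naf, file.path(out_dir, "naf.tsv"), header = cfg)
  }
  list(alignments = runs, naf = naf,
       scores = vapply(runs, `[[`, numeric(1), "final_score"),
       spec = spec, swapped = swapped)
}

#' Transfer annotations and evaluate against a later release
#'
#' Chains the prediction stages: strict sequence-evidence filtering of
#' the source annotations, NAF-weighted accumulation of candidate
#' transfers, materialization of the predictable-in-principle ground
#' truth from the later release, and the precision-recall sweep.  Also
#' reports the CCS degree-3 diagnostic and alignment-quality product at
#' the NAF floor.
#'
#' @param naf a [compute_naf()] table (source side = `g1`).
#' @param g1,g2 the aligned earlier-dated networks (source, target).
#' @param earlier_source,earlier_target,later_target unpropagated
#'   annotation stores.
#' @param exclusions an [exclusion_sets()] or `NULL`.
#' @param naf_floor_percent NAF floor for transfers (default 2).
#' @param evidence_whitelist source evidence codes allowed to drive
#'   transfers.
#' @param seq_discard later-release sequence-evidence rule (see
#'   [evaluation_sets()]).
#' @param out_dir optional directory for the predictions TSV, PR curve
#'   CSV and JSON summary.
#' @return list with `ledger`, `eval_sets`, `pr` (curve + AUPR + F*),
#'   `ccs` (report at the floor), `summary` (flat list of headline
#'   numbers).
#' @export
run_predict_evaluate <- function(naf, g1, g2, earlier_source, earlier_target,
                                 later_target, exclusions = NULL,
                                 naf_floor_percent = 2,
                                 evidence_whitelist = c("IPI", "EXP", "IDA"),
                                 seq_discard = "any", out_dir = NULL) {
  src <- filter_noseq(earlier_source, mode = "strict")
  ledger <- accumulate(naf, naf_floor_percent, src, earlier_target,
                       exclusions, evidence_whitelist)
  eval_sets <- evaluation_sets(later_target, g2, src, exclusions,
                               seq_discard = seq_discard)
  pr <- if (nrow(ledger) > 0L && eval_sets$denominator > 0L) {
    pr_curve_and_summary(ledger, eval_sets)
  } else NULL
  ccs <- ccs_report(naf, g1, g2, naf_floor_percent)
  summary <- list(n_candidates = nrow(ledger),
                  denominator = eval_sets$denominator,
                  aupr = if (is.null(pr)) NA_real_ else pr$aupr,
                  f_star = if (is.null(pr)) NA_real_ else pr$f_star,
                  phi_at_f_star = if (is.null(pr)) NA_real_ else pr$phi_at_f_star,
                  ccs_mean_degree = ccs$mean_degree,
                  passes_degree3 = ccs$passes_degree3,
                  alignment_quality = ccs$quality)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_predictions(ledger, file.path(out_dir, "predictions.tsv"))
    if (!is.null(pr)) {
      utils::write.csv(pr$curve, file.path(out_dir, "pr_curve.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(ledger = ledger, eval_sets = eval_sets, pr = pr, ccs = ccs,
       summary = summary)
}
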