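#' Pearson correlation with t and Fisher r-to-z statistics
#'
#' Product-moment correlation plus the two significance statistics used
#' throughout the analyses: the t-statistic
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} (reported as the "number of
#' sigmas" a correlation sits from zero) and the two-sided p-value from
#' Fisher's r-to-z transformation (\eqn{z = \mathrm{atanh}(\rho)},
#' standard error \eqn{1/\sqrt{n-3}}).
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, non-constant.
#' @return object of class `correlation_result`: list with `rho`, `n`,
#'   `t_stat`, `fisher_p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("undefined correlation: constant input")
  rho <- stats::cor(x, y)
  correlation_result(rho, n)
}

#' Correlation statistics from a coefficient and sample size
#'
#' @param rho Pearson coefficient.
#' @param n sample size.
#' @return a `correlation_result`.
#' @export
correlation_result <- function(rho, n) {
  t_stat <- if (abs(rho) < 1 && n > 2) rho * sqrt((n - 2) / (1 - rho^2)) else Inf * sign(rho)
  fisher_p <- if (n > 3) {
    z <- atanh(rho) * sqrt(n - 3)
    2 * stats::pnorm(-abs(z))
  } else NA_real_
  structure(list(rho = rho, n = as.integer(n), t_stat = t_stat,
                 fisher_p = fisher_p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("rho = %.4f (n = %d), t = %.4f, Fisher p = %.4g\n",
              x$rho, x$n, x$t_stat, x$fisher_p))
  invisible(x)
}

#' Mean semantic similarity as a function of the NAF threshold
#'
#' For each observed NAF value phi, the mean (and sd and count) of the
#' Resnik scores of all pairs aligned with frequency **at least** phi --
#' the cumulative-from-above construction used for threshold curves.
#' Pairs without a Resnik score (`NA`) are excluded.
#'
#' @param naf a [compute_naf()] table.
#' @param resnik_scores numeric vector of Resnik scores aligned row-wise
#'   with `naf` (NA = no score).
#' @param min_count_per_point drop curve points supported by fewer pairs.
#' @return data frame with columns `phi` (percent), `mean`, `sd`,
#'   `n_pairs`, ordered by increasing phi; `n_pairs` is antitone in phi.
#' @export
naf_resnik_curve <- function(naf, resnik_scores, min_count_per_point = 1L) {
  stopifnot(length(resnik_scores) == nrow(naf))
  keep <- !is.na(resnik_scores)
  if (!any(keep)) stop("no scored pairs")
  pct <- naf$percent[keep]
  res <- resnik_scores[keep]
  phis <- sort(unique(pct))
  rows <- lapply(phis, function(phi) {
    v <- res[pct >= phi]
    data.frame(phi = phi, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n_pairs = length(v))
  })
  out <- do.call(rbind, rows)
  out[out$n_pairs >= min_count_per_point, , drop = FALSE]
}

#' (S, M) well-annotation grid of NAF-Resnik correlations
#'
#' For every cell of the (S, M) grid (both axes in powers of 2 from 1 to
#' 1024 by default) the NAF-Resnik Pearson correlation rho(S, M) is
#' computed over the aligned pairs in which **both** proteins pass the
#' [well_annotated()] filter.  Cells whose Fisher p-value misses the
#' significance cutoff are excluded from the second-level ("Pearson^2")
#' correlations of rho(S, M) against S, M and S/M.
#'
#' @param pairs data frame with columns `g1`, `g2`, `percent` (NAF) and
#'   `resnik`.
#' @param store1,store2 unpropagated annotation stores for the two
#'   species.
#' @param S_values,M_values grid axes (powers of 2, 1..1024 by default).
#' @param significance_cutoff Fisher p cutoff for a cell to enter the
#'   second-level correlations (default 5e-6).
#' @param min_pairs minimum pairs for a cell's correlation to be
#'   attempted.
#' @return list with `grid` (data frame `S`, `M`, `n_pairs`, `rho`,
#'   `fisher_p`, `significant`) and `pearson2` (list of
#'   `correlation_result` against `S`, `M`, `S_over_M`, or `NULL` when
#'   fewer than 3 significant cells exist).
#' @export
sm_grid <- function(pairs, store1, store2,
                    S_values = 2^(0:10), M_values = 2^(0:10),
                    significance_cutoff = 5e-6, min_pairs = 5L) {
  counts1 <- species_term_counts(store1)
  counts2 <- species_term_counts(store2)
  prot1 <- unique(pairs$g1)
  prot2 <- unique(pairs$g2)
  rows <- list()
  for (S in S_values) {
    for (M in M_values) {
      ok1 <- prot1[well_annotated(prot1, store1, S, M, counts1)]
      ok2 <- prot2[well_annotated(prot2, store2, S, M, counts2)]
      sel <- pairs$g1 %in% ok1 & pairs$g2 %in% ok2 & !is.na(pairs$resnik)
      n <- sum(sel)
      rho <- NA_real_
      p <- NA_real_
      if (n >= max(3L, min_pairs) &&
          stats::sd(pairs$percent[sel]) > 0 &&
          stats::sd(pairs$resnik[sel]) > 0) {
        cr <- pearson(pairs$percent[sel], pairs$resnik[sel])
        rho <- cr$rho
        p <- cr$fisher_p
      }
      rows[[length(rows) + 1L]] <-
        data.frame(S = S, M = M, n_pairs = n, rho = rho, fisher_p = p,
                   significant = !is.na(p) & p < significance_cutoff)
    }
  }
  grid <- do.call(rbind, rows)
  sig <- grid[grid$significant, , drop = FALSE]
  pearson2 <- NULL
  if (nrow(sig) >= 3L) {
    safe <- function(x, y) {
      if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("undefined correlation: constant input")
      pearson(x, y)
    }
    pearson2 <- list(S = safe(sig$S, sig$rho),
                     M = safe(sig$M, sig$rho),
                     S_over_M = safe(sig$S / sig$M, sig$rho))
  }
  list(grid = grid, pearson2 = pearson2)
}

#' Resnik similarity binned by annotation level
#'
#' Bins aligned pairs (already thresholded at the NAF floor) by the
#' annotation level of the lesser-understood protein -- the number of
#' distinct non-sequence GO terms of whichever protein has fewer -- and
#' summarizes the Resnik scores per bin, separately for pairs flagged as
#' sequence-similar and not.  A two-sided paired t-test across the bins
#' common to both flags asks whether the two curves differ.
#'
#' @param pairs data frame with columns `g1`, `g2`.
#' @param store1,store2 unpropagated, NOSEQ-filtered stores (record mode
#'   suffices) whose term counts define the annotation level.
#' @param resnik numeric Resnik (NOSEQ) score per pair.
#' @param seq_similar logical flag per pair.
#' @return list with `bins` (data frame `level`, `seq_similar`, `mean`,
#'   `sd`, `n`) and `difference_p` (paired t-test p-value across common
#'   bins, `NA` when fewer than 2 common bins).
#' @export
annotation_level_bins <- function(pairs, store1, store2, resnik,
                                  seq_similar) {
  stopifnot(nrow(pairs) == length(resnik),
            nrow(pairs) == length(seq_similar))
  n_terms <- function(store) {
    pt <- unique(data.frame(p = store$protein, t = store$term,
                            stringsAsFactors = FALSE))
    tab <- table(pt$p)
    stats::setNames(as.integer(tab), names(tab))
  }
  t1 <- n_terms(store1)
  t2 <- n_terms(store2)
  lv1 <- t1[pairs$g1]
  lv2 <- t2[pairs$g2]
  lv1[is.na(lv1)] <- 0L
  lv2[is.na(lv2)] <- 0L
  level <- floor(pmin(lv1, lv2))
  keep <- !is.na(resnik)
  df <- data.frame(level = level[keep], resnik = resnik[keep],
                   seq_similar = seq_similar[keep])
  agg <- do.call(rbind, lapply(split(df, list(df$level, df$seq_similar),
                                     drop = TRUE), function(d) {
    data.frame(level = d$level[1L], seq_similar = d$seq_similar[1L],
               mean = mean(d$resnik),
               sd = if (nrow(d) > 1L) stats::sd(d$resnik) else 0,
               n = nrow(d))
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$seq_similar, agg$level), , drop = FALSE]
  with_flag <- agg[agg$seq_similar, c("level", "mean")]
  without_flag <- agg[!agg$seq_similar, c("level", "mean")]
  common <- intersect(with_flag$level, without_flag$level)
  diff_p <- NA_real_
  if (length(common) >= 2L) {
    a <- with_flag$mean[match(common, with_flag$level)]
    b <- without_flag$mean[match(common, without_flag$level)]
    if (stats::sd(a - b) > 0) {
      diff_p <- stats::t.test(a, b, paired = TRUE)$p.value
    } else {
      diff_p <- if (all(a == b)) 1 else 0
    }
  }
  list(bins = agg, difference_p = diff_p)
}
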