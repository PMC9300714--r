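test_that("correlation statistics reproduce the t and Fisher formulas", {
  # published-style worked examples: rho/n pairs with known t
  expect_equal(round(correlation_result(0.5425, 18)$t_stat, 4), 2.5832)
  expect_equal(round(correlation_result(0.7642, 16)$t_stat, 4), 4.4333)
  expect_equal(correlation_result(0, 10)$t_stat, 0)

  withr::with_seed(1, {
    x <- rnorm(40)
    y <- x + rnorm(40)
  })
  cr <- pearson(x, y)
  ct <- stats::cor.test(x, y)  # independent oracle for rho and t
  expect_equal(cr$rho, unname(ct$estimate))
  expect_equal(cr$t_stat, unname(ct$statistic))
  z <- atanh(cr$rho) * sqrt(cr$n - 3)
  expect_equal(cr$fisher_p, 2 * pnorm(-abs(z)))
  expect_error(pearson(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("Fisher p decreases with |rho| and with n", {
  p_by_rho <- vapply(seq(0.1, 0.9, by = 0.1),
                     function(r) correlation_result(r, 20)$fisher_p,
                     numeric(1))
  expect_true(all(diff(p_by_rho) < 0))
  p_by_n <- vapply(c(10, 20, 40, 80),
                   function(n) correlation_result(0.4, n)$fisher_p,
                   numeric(1))
  expect_true(all(diff(p_by_n) < 0))
})

test_that("NAF-Resnik curves are cumulative from above", {
  naf <- compute_naf(list(c(a = "x", b = "y"), c(a = "x", b = "y"),
                          c(a = "x", b = "z"), c(a = "w", b = "y")))
  # counts over N=4: (a,x)=3 75%, (b,y)=3 75%, (a,w)=1 25%, (b,z)=1 25%
  res <- setNames(c(2.0, 2.0, 0.0, 0.0),
                  paste0(naf$g1, "\r", naf$g2))
  res <- unname(res[paste0(naf$g1, "\r", naf$g2)])
  res[naf$percent == 75] <- 2.0
  res[naf$percent == 25] <- 0.0
  curve <- naf_resnik_curve(naf, res)
  expect_equal(curve$mean[curve$phi == 75], 2.0)
  expect_equal(curve$mean[curve$phi == 25], 1.0)
  expect_true(all(diff(curve$n_pairs) <= 0))
  # constant scores give a flat curve with zero sd
  flat <- naf_resnik_curve(naf, rep(1, nrow(naf)))
  expect_true(all(flat$mean == 1))
  expect_true(all(flat$sd == 0))
  # naive filter-and-average oracle
  fx <- small_ensemble()
  rs <- withr::with_seed(3, runif(nrow(fx$ens$naf)))
  rs[sample(length(rs), 20)] <- NA
  curve2 <- naf_resnik_curve(fx$ens$naf, rs)
  for (i in seq_len(nrow(curve2))) {
    sel <- fx$ens$naf$percent >= curve2$phi[i] & !is.na(rs)
    expect_equal(curve2$mean[i], mean(rs[sel]))
    expect_equal(curve2$n_pairs[i], sum(sel))
  }
  expect_error(naf_resnik_curve(naf, rep(NA_real_, nrow(naf))), "no scored")
})

test_that("the (S, M) grid correlates rho(S, M) with annotation specificity", {
  # constructed corpus: proteins with more specific terms get less noisy
  # Resnik, so rho(S, M) should rise with S and fall with M
  withr::with_seed(7, {
    n <- 300
    pairs <- data.frame(g1 = paste0("p", 1:n), g2 = paste0("q", 1:n))
    richness <- sample(1:8, n, replace = TRUE)
    pairs$percent <- runif(n, 2, 100)
    noise <- rnorm(n, sd = 40 / richness)
    pairs$resnik <- pairs$percent * (richness / 8) + noise
    recs <- do.call(rbind, lapply(1:n, function(i) {
      k <- richness[i]
      data.frame(protein = c(rep(pairs$g1[i], k), rep(pairs$g2[i], k)),
                 term = c(sprintf("t%s_%d", pairs$g1[i], 1:k),
                          sprintf("t%s_%d", pairs$g2[i], 1:k)),
                 evidence = "EXP",
                 species = rep(c("S1", "S2"), each = k))
    }))
  })
  st1 <- annotation_store(recs$protein[recs$species == "S1"],
                          recs$term[recs$species == "S1"], "EXP", "S1")
  st2 <- annotation_store(recs$protein[recs$species == "S2"],
                          recs$term[recs$species == "S2"], "EXP", "S2")
  out <- sm_grid(pairs, st1, st2, S_values = 2^(0:3), M_values = 2^(0:3),
                 significance_cutoff = 1e-3)
  expect_true(!is.null(out$pearson2))
  expect_gt(out$pearson2$S$rho, 0)
  # with every term unique to its protein, M has no variation to correlate
  expect_true(all(out$grid$n_pairs[out$grid$S == 1] == n))
  # single significant cell -> second-level correlations undefined
  one <- sm_grid(pairs[1:40, ], st1, st2, S_values = 2, M_values = 1,
                 significance_cutoff = 1)
  expect_null(one$pearson2)
})

test_that("annotation-level binning keys on the lesser-annotated protein", {
  st1 <- annotation_store(c("p1", "p1", "p1", "p2"),
                          c("a1", "a2", "a3", "a4"), "EXP", "S1")
  st2 <- annotation_store(c("q1", "q1", "q1", "q1", "q1", "q1", "q1", "q2"),
                          paste0("b", 1:8), "EXP", "S2")
  pairs <- data.frame(g1 = c("p1", "p2"), g2 = c("q1", "q2"))
  out <- annotation_level_bins(pairs, st1, st2, resnik = c(2, 1),
                               seq_similar = c(FALSE, FALSE))
  # pair 1 has term counts (3, 7) -> bin 3; pair 2 has (1, 1) -> bin 1
  expect_setequal(out$bins$level, c(3, 1))
  # identical distributions for both flags -> difference p ~ 1
  pairs2 <- pairs[c(1, 2, 1, 2), ]
  out2 <- annotation_level_bins(pairs2, st1, st2,
                                resnik = c(2, 1, 2, 1),
                                seq_similar = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out2$difference_p, 1)
  # rising means across bins give a positive correlation on binned means
  withr::with_seed(11, {
    k <- 60
    stA <- annotation_store(rep(paste0("u", 1:k), times = rep(1:6, 10)),
                            paste0("ta", seq_len(sum(rep(1:6, 10)))),
                            "EXP", "S1")
    stB <- annotation_store(rep(paste0("v", 1:k), each = 8),
                            paste0("tb", seq_len(8 * k)), "EXP", "S2")
    prs <- data.frame(g1 = paste0("u", 1:k), g2 = paste0("v", 1:k))
    lvl <- rep(1:6, 10)
    res <- lvl + rnorm(k, sd = 0.1)
    out3 <- annotation_level_bins(prs, stA, stB, res,
                                  seq_similar = rep(FALSE, k))
  })
  binmeans <- out3$bins[order(out3$bins$level), ]
  expect_gt(pearson(binmeans$level, binmeans$mean)$rho, 0.9)
})
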