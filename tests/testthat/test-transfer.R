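mini_naf <- function(df, n_runs) {
  df$percent <- 100 * df$count / n_runs
  df <- df[order(-df$percent, df$g1, df$g2), ]
  rownames(df) <- NULL
  structure(df, n_runs = n_runs, class = c("naf_table", "data.frame"))
}

test_that("transfer scores accumulate NAF across source proteins", {
  naf <- mini_naf(data.frame(g1 = c("p1", "p2", "p3"),
                             g2 = c("q", "q", "q"),
                             count = c(10L, 5L, 1L)), 100L)
  src <- annotation_store(c("p1", "p2", "p3"), "g", c("IPI", "IPI", "IEA"),
                          "S1")
  src <- filter_noseq(src, mode = "strict")
  none_known <- annotation_store(character(0), character(0), character(0),
                                 character(0))
  led <- accumulate(naf, 2, src, none_known)
  expect_equal(nrow(led), 1L)
  expect_equal(led$score, 15)  # 10 + 5; p3 filtered (IEA), floor drops nothing
  expect_equal(led$n_sources, 2L)

  # already-known target annotations contribute nothing
  known <- annotation_store("q", "g", "IEA", "S2")
  expect_equal(nrow(accumulate(naf, 2, src, known)), 0L)

  # excluded pairs contribute nothing regardless of NAF
  excl <- exclusion_sets(seq_similar_pairs = data.frame(a = "p1", b = "q"))
  led2 <- accumulate(naf, 2, src, none_known, excl)
  expect_equal(led2$score, 5)

  # floor drops low-NAF pairs
  led3 <- accumulate(naf, 8, src, none_known)
  expect_equal(led3$score, 10)
})

test_that("accumulation matches the naive triple-loop oracle", {
  fx <- small_ensemble()
  w <- synth_go_world(fx$pair, seed = 21)
  src <- filter_noseq(w$earlier_source, mode = "strict")
  excl <- withr::with_seed(5, data.frame(
    a = sample(names(fx$pair$truth), 8),
    b = sample(igraph::V(fx$pair$g2)$name, 8)))
  led <- accumulate(fx$ens$naf, 10, src, w$earlier_target,
                    exclusion_sets(seq_similar_pairs = excl))
  oracle <- oracle_accumulate(fx$ens$naf, 10, as.data.frame(src),
                              as.data.frame(w$earlier_target),
                              as.matrix(excl), c("IPI", "EXP", "IDA"))
  got <- setNames(led$score, paste0(led$target, "\r", led$term, "\r",
                                    led$evidence))
  expect_equal(sort(names(got)), sort(names(oracle)))
  for (k in names(oracle)) expect_equal(unname(got[k]), oracle[[k]])
})

test_that("predictable-in-principle respects network membership and exclusions", {
  net <- read_edgelist(c("q1 q2", "q2 q3"), text = TRUE)
  src <- annotation_store(c("p1", "p2"), c("g", "g"), "EXP", "S1")
  expect_true(p12_membership("q1", "g", net, src))
  expect_false(p12_membership("q9", "g", net, src))       # not in network
  expect_false(p12_membership("q1", "other", net, src))   # no source carrier
  # sole carrier excluded against this target -> not predictable
  only <- annotation_store("p1", "g", "EXP", "S1")
  excl <- exclusion_sets(seq_similar_pairs = data.frame(a = "p1", b = "q1"))
  expect_false(p12_membership("q1", "g", net, only, excl))
  expect_true(p12_membership("q2", "g", net, only, excl))
  # one excluded carrier among two -> still predictable
  expect_true(p12_membership("q1", "g", net, src, excl))
})

test_that("threshold evaluation reproduces precision/recall arithmetic", {
  net <- read_edgelist(paste("q0", paste0("q", 1:40)), text = TRUE)
  src <- annotation_store("p", "g", "IPI", "S1")
  later <- annotation_store(paste0("q", 1:12), "g", "EXP", "S2")
  ev <- evaluation_sets(later, net, src)
  expect_equal(ev$denominator, 12L)
  led <- structure(data.frame(target = paste0("q", 1:30), term = "g",
                              evidence = "IPI", score = 10,
                              n_sources = 1L),
                   naf_floor = 2, class = c("prediction_ledger", "data.frame"))
  res <- evaluate_at_threshold(led, 5, ev)
  expect_equal(res$n_pred, 30L)
  expect_equal(res$n_valid, 12L)
  expect_equal(res$precision, 12 / 30)
  expect_equal(res$recall, 1)
  none <- evaluate_at_threshold(led, 99, ev)
  expect_equal(none$n_pred, 0L)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
})

test_that("later sequence evidence removes pairs from both numerator and denominator", {
  net <- read_edgelist(c("q1 q2", "q2 q3"), text = TRUE)
  src <- annotation_store("p", "g", "IPI", "S1")
  later <- annotation_store(c("q1", "q1", "q2"), c("g", "g", "g"),
                            c("EXP", "ISS", "EXP"), "S2")
  strict <- evaluation_sets(later, net, src, seq_discard = "any")
  expect_equal(strict$denominator, 1L)  # q1 discarded: ISS alongside EXP
  lax <- evaluation_sets(later, net, src, seq_discard = "only")
  expect_equal(lax$denominator, 2L)
  led <- structure(data.frame(target = c("q1", "q2"), term = "g",
                              evidence = "IPI", score = 10, n_sources = 1L),
                   naf_floor = 2, class = c("prediction_ledger", "data.frame"))
  res <- evaluate_at_threshold(led, 5, strict)
  expect_equal(res$n_pred, 1L)  # q1 dropped from the numerator too
  expect_equal(res$n_valid, 1L)
})

test_that("prediction sets nest and recall is antitone in the threshold", {
  fx <- small_ensemble()
  w <- synth_go_world(fx$pair, seed = 22)
  out <- run_predict_evaluate(fx$ens$naf, fx$pair$g1, fx$pair$g2,
                              w$earlier_source, w$earlier_target,
                              w$later_target)
  led <- out$ledger
  ev <- out$eval_sets
  phis <- sort(unique(led$score))
  prev_keys <- NULL
  prev_recall <- Inf
  for (phi in phis) {
    df <- led[led$score >= phi, ]
    keys <- unique(paste(df$target, df$term))
    if (!is.null(prev_keys)) expect_true(all(keys %in% prev_keys))
    prev_keys <- keys
    r <- evaluate_at_threshold(led, phi, ev)$recall
    expect_lte(r, prev_recall)
    prev_recall <- r
  }
})

test_that("PR sweep yields step-sum AUPR and F*, with clean degenerate cases", {
  net <- read_edgelist(paste("q0", paste0("q", 1:10)), text = TRUE)
  src <- annotation_store("p", "g", "IPI", "S1")
  later <- annotation_store(paste0("q", 1:6), "g", "EXP", "S2")
  ev <- evaluation_sets(later, net, src)
  # perfect ledger: every prediction valid, all ground truth predicted
  led <- structure(data.frame(target = paste0("q", 1:6), term = "g",
                              evidence = "IPI", score = c(30, 30, 20, 20, 10, 10),
                              n_sources = 1L),
                   naf_floor = 2, class = c("prediction_ledger", "data.frame"))
  pr <- pr_curve_and_summary(led, ev)
  expect_equal(pr$aupr, 1)
  expect_equal(pr$f_star, 1)
  # mixed ledger: AUPR equals the hand-computed step sum
  led2 <- structure(data.frame(target = paste0("q", 1:8), term = "g",
                               evidence = "IPI",
                               score = c(40, 30, 20, 10, 40, 30, 20, 10),
                               n_sources = 1L),
                    naf_floor = 2, class = c("prediction_ledger", "data.frame"))
  # thresholds 40,30,20,10 select {q1,q5}, +{q2,q6}, +{q3,q7}, +{q4,q8};
  # q7 and q8 are invalid, so valid counts run 2,4,5,6
  pr2 <- pr_curve_and_summary(led2, ev)
  R <- c(2, 4, 5, 6) / 6
  P <- c(2, 4, 5, 6) / c(2, 4, 6, 8)
  expect_equal(pr2$curve$precision, P)
  expect_equal(pr2$curve$recall, R)
  expect_equal(pr2$aupr, sum((R - c(0, R[-4])) * P))
  expect_equal(pr2$f_star, max(2 * P * R / (P + R)))
  expect_error(pr_curve_and_summary(led[0, ], ev), "empty")
})
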