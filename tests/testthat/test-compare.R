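test_that("variant summaries reproduce the published derived quantities", {
  tab <- cav32_variants()
  wt <- variant_params("WT", tab)
  s <- summarize_variant(variant_params("P2280H", tab), wt)
  expect_equal(s$delta_v_half_act, -14.95, tolerance = 1e-10)
  expect_equal(report_round(s$delta_v_half_act, 1), -15.0)
  expect_equal(report_round(s$delta_v_half_inact, 1), -12.6)
  expect_equal(report_round(summarize_variant(variant_params("E2291K", tab),
                                              wt)$delta_v_half_act, 1), -8.0)
  expect_equal(report_round(summarize_variant(variant_params("A802V", tab),
                                              wt)$recovery_fold, 1), 2.7)
  expect_equal(report_round(summarize_variant(variant_params("Q1049H", tab),
                                              wt)$recovery_fold, 1), 3.5)
  expect_equal(report_round(summarize_variant(variant_params("R1674H", tab),
                                              wt)$g_max_change_pct, 0), -56)
})

test_that("WT against itself is neutral with zero deltas and unit fold", {
  wt <- variant_params("WT")
  s <- summarize_variant(wt, wt)
  expect_equal(s$delta_v_half_act, 0)
  expect_equal(s$delta_v_half_inact, 0)
  expect_equal(s$delta_slope_act, 0)
  expect_equal(s$recovery_fold, 1)
  expect_equal(s$g_max_change_pct, 0)
  expect_equal(s$classification, "neutral")
  expect_false(any(s$flags))
})

test_that("classification follows the stated policy flags", {
  tab <- cav32_variants()
  wt <- variant_params("WT", tab)
  expect_equal(summarize_variant(variant_params("P2280H", tab),
                                 wt)$classification, "GoF")
  expect_equal(summarize_variant(variant_params("Q1049H", tab),
                                 wt)$classification, "GoF")  # 3.5x recovery
  expect_equal(summarize_variant(variant_params("R1674H", tab),
                                 wt)$classification, "LoF")  # -56% Gmax
  expect_equal(summarize_variant(variant_params("P1605H", tab),
                                 wt)$classification, "neutral")
  # significance gate: with insignificant p-values the GoF flags drop,
  # and the inactivation-alone LoF flag stays off because the (effect-
  # size) activation shift is present -> neutral
  s <- summarize_variant(variant_params("P2280H", tab), wt,
                         pvals = c(act_vhalf = 0.5, rec = 0.5,
                                   gmax = 0.5, inact_vhalf = 0.5))
  expect_equal(s$classification, "neutral")
})

test_that("summary table applies report rounding", {
  out <- variant_summary_table()
  expect_equal(out$delta_v_half_act[out$label == "P2280H"], -15.0)
  expect_equal(out$recovery_fold[out$label == "A802V"], 2.7)
  expect_equal(out$g_max_change_pct[out$label == "R1674H"], -56)
})

test_that("identical constant groups give H = 0 and p = 1", {
  g <- list(WT = rep(3, 5), A = rep(3, 5), B = rep(3, 4))
  r <- kruskal_dunn(g)
  expect_equal(r$H, 0)
  expect_equal(r$p_kw, 1)
  expect_equal(r$comparisons$p_adj, c(1, 1))
})

test_that("two fully separated groups reproduce the hand-computed H", {
  g <- list(WT = c(1, 2, 3, 4), A = c(10, 11, 12, 13))
  r <- kruskal_dunn(g)
  # rank sums 10 and 26: H = 12/(8*9) * (100/4 + 676/4) - 27 = 16/3
  expect_equal(r$H, 16 / 3, tolerance = 1e-12)
  # agrees with the base-R implementation including ties handling
  g2 <- list(WT = c(1, 2, 2, 5), A = c(4, 4, 6, 7), B = c(2, 8, 9))
  r2 <- kruskal_dunn(g2)
  k <- kruskal.test(unlist(g2), rep(1:3, lengths(g2)))
  expect_equal(r2$H, unname(k$statistic), tolerance = 1e-12)
  expect_equal(r2$p_kw, k$p.value, tolerance = 1e-12)
})

test_that("exact permutation enumeration matches a brute-force oracle", {
  g <- list(WT = c(0.3, 1.2, 2.5, 0.9), A = c(2.9, 3.4, 1.1, 4.0))
  r <- kruskal_dunn(g, p_method = "permutation")
  expect_equal(r$p_kw, oracle_perm_p(g), tolerance = 1e-12)
  g3 <- list(WT = c(5, 1, 3), A = c(4, 9, 2), B = c(8, 7, 6))
  r3 <- kruskal_dunn(g3, p_method = "permutation")
  expect_equal(r3$p_kw, oracle_perm_p(g3), tolerance = 1e-12)
  # asymptotic p is close to exact for these sizes
  expect_lt(abs(kruskal_dunn(g3)$p_kw - r3$p_kw), 0.06)
  expect_error(kruskal_dunn(list(WT = 1:9, A = 1:9, B = 1:9),
                            p_method = "permutation"),
               "too large")
})

test_that("the test is invariant to strictly monotone transforms", {
  set.seed(13)
  g <- list(WT = rnorm(6), A = rnorm(6, 1), B = rnorm(5, -0.5))
  r1 <- kruskal_dunn(g)
  r2 <- kruskal_dunn(lapply(g, function(x) exp(3 * x + 2)))
  expect_equal(r1$H, r2$H, tolerance = 1e-12)
  expect_equal(r1$comparisons$z, r2$comparisons$z, tolerance = 1e-12)
})

test_that("empty or missing groups are rejected", {
  expect_error(kruskal_dunn(list(WT = 1:3, A = numeric(0))), "empty")
  expect_error(kruskal_dunn(list(A = 1:3, B = 4:6)), "control")
  expect_error(kruskal_dunn(list(WT = 1:3)), "2 groups")
})

test_that("type-I error at alpha 0.05 lies in [0.03, 0.07] under the null", {
  set.seed(2024)
  n_sim <- 1000
  rej <- 0L
  for (i in seq_len(n_sim)) {
    g <- list(WT = rnorm(8), A = rnorm(8), B = rnorm(8))
    if (kruskal_dunn(g)$p_kw <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_sim, 0.03)
  expect_lte(rej / n_sim, 0.07)
})

test_that("Dunn comparisons flag a genuinely shifted group against control", {
  set.seed(99)
  g <- list(WT = rnorm(10), shifted = rnorm(10, 3), same = rnorm(10))
  r <- kruskal_dunn(g)
  cmp <- r$comparisons
  expect_lt(cmp$p_adj[cmp$group == "shifted"], 0.05)
  expect_gt(cmp$p_adj[cmp$group == "same"], 0.05)
})
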