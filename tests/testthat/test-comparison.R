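test_that("rule 1 excludes any strictly positive metric", {
  expect_true(rule1_ineffective(make_response(-5, -3, 0.1)))
  expect_false(rule1_ineffective(make_response(0, 0, 0)))
  expect_false(rule1_ineffective(make_response(-5, -3, -1)))
  expect_true(rule1_ineffective(make_response(2, -30, -1)))
})

test_that("rule 2 needs the 10-point margin and strictly better vasculature", {
  mono <- make_response(-40, -30, -5)
  expect_true(rule2_combined_better(make_response(-55, -42, -6), mono))
  expect_false(rule2_combined_better(make_response(-55, -35, -6), mono))
  expect_false(rule2_combined_better(make_response(-55, -42, -5), mono))
  # margin is inclusive at exactly -10 on both differences
  expect_true(rule2_combined_better(make_response(-50, -40, -5.1), mono))
})

test_that("rule 3 is a strict combined-score comparison", {
  expect_true(rule3_ht_better(make_response(-40, -20, -1, treatment = "H"),
                              make_response(-30, -10, 0)))
  expect_false(rule3_ht_better(make_response(-30, -10, -1,
                                             treatment = "H"),
                               make_response(-30, -10, 0)))
})

test_that("best_treatment composes the three rules", {
  rt <- make_response(-40, -30, 0)
  ht <- make_response(-35, -25, -10, treatment = "H")
  strong_combo <- make_response(-55, -45, -12, treatment = "R_H")
  weak_combo <- make_response(-44, -33, -12, treatment = "R_H")
  expect_identical(best_treatment(rt, ht, strong_combo), "R_H")
  # a < 10-point improvement falls back to the better monotherapy
  expect_identical(best_treatment(rt, ht, weak_combo), "R")
  # HT preferred only on a strictly better score
  ht2 <- make_response(-45, -30, -10, treatment = "H")
  expect_identical(best_treatment(rt, ht2, weak_combo), "H")
  # excluded treatments never win
  bad <- make_response(10, 5, 2)
  expect_identical(best_treatment(bad, bad, bad), "none_effective")
  expect_identical(best_treatment(bad, ht, weak_combo), "H")
  combo_only <- make_response(-20, -10, -1, treatment = "R_H")
  expect_identical(best_treatment(bad, bad, combo_only), "R_H")
  # rule2_both demands the margin against every surviving monotherapy
  mid_combo <- make_response(-52, -41, -12, treatment = "R_H")
  expect_identical(best_treatment(rt, ht2, mid_combo, rule2_both = TRUE),
                   "H")
})

test_that("matched triples reproduce the known RT-favoured SL tumour", {
  # well-oxygenated, fast-regrowing SL tumour: strong RT response,
  # limited HT response, combination worse than RT alone
  tum <- list(id = 1L, q1 = 0.0321, q3 = 9.53, V0 = 0.005)
  fp <- sl_fixed_point(tum$q1, tum$q3, tum$V0)
  tum$T_star <- fp$T_star; tum$c_star <- fp$c_star
  tri <- compare_treatments(tum, 2, 5, 0.005)
  expect_identical(tri$winner, "R")
  expect_lt(tri$rt$combined_score, tri$ht$combined_score)
  expect_gt(tri$combo$combined_score, tri$rt$combined_score)
  # hypoxic NL tumour C1: HT dominates RT outright
  tri2 <- compare_treatments(fx_row("C1"), 2, 5, 0.005)
  expect_identical(tri2$winner, "H")
  expect_lt(tri2$ht$combined_score, tri2$rt$combined_score)
})

test_that("regimen ranking is ordered, consistent and deterministic", {
  grid <- schedule_grid(Ds = 2, N_fracs = 5,
                        beta_tildes = c(0.005, 0.01))
  expect_equal(nrow(grid), 2)
  expect_true(all(grid$N_wks == 8))
  a2 <- fx_row("A2")
  rk <- rank_regimens(a2, grid)
  rk2 <- rank_regimens(a2, grid)
  expect_identical(rk$ranking, rk2$ranking)
  expect_false(is.unsorted(rk$ranking$combined_score))
  expect_identical(rk$best_treatment, rk$ranking$treatment[1])
  expect_identical(rk$best_regimen, rk$ranking$regimen[1])
  # the top-ranked entry agrees with the per-pair winner at its pair
  top <- rk$ranking[1, ]
  tri <- compare_treatments(a2, top$D, top$N_frac, top$beta_tilde)
  expect_identical(tri$winner, top$treatment)
  # the thermal cap prunes the grid
  g2 <- schedule_grid(Ds = 2, N_fracs = 1, beta_tildes = c(0.001, 0.005))
  expect_equal(g2$beta_tilde, 0.001)  # 40 weeks caps beta at 0.002
})
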