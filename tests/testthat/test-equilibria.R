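test_that("space-limited fixed point matches its closed form", {
  fp <- sl_fixed_point(q1 = 0.151, q3 = 0.210, V0 = 0.005)
  expect_equal(fp$T_star, 0.995)
  expect_equal(fp$c_star, 0.14266, tolerance = 1e-4)
  expect_true(fp$c_star >= default_params$c_min)
  # oracle: the same c* from a scalar root-finder on the oxygen balance
  g <- default_params$g
  root <- uniroot(function(cc) g * (1 - cc) * 0.005 - 0.151 * cc * 0.995,
                  c(1e-6, 1), tol = 1e-14)$root
  expect_equal(fp$c_star, root, tolerance = 1e-10)
  # heavy oxygen consumption drives c* below threshold: no SL state
  expect_null(sl_fixed_point(q1 = 10, q3 = 1, V0 = 0.005))
})

test_that("nutrient-limited fixed point is a genuine stable root", {
  nl <- nl_fixed_point(q1 = 0.503, q3 = 0.272, V0 = 0.0005)
  expect_false(is.null(nl))
  expect_true(nl$c_star > 0 && nl$c_star < default_params$c_min)
  expect_true(nl$stable)
  p <- thermorad:::tumour_params(default_params,
                                 list(q1 = 0.503, q3 = 0.272))
  res <- model_rhs(0, c(nl$T_star, 0, 0, 0, 0.0005, nl$c_star, 0), p)
  expect_lt(max(abs(res)), 1e-10)
  # oxygen starvation limit: T* decreases monotonically along a q1 ladder
  q1s <- c(0.5, 1, 2, 4, 8)
  Ts <- vapply(q1s, function(q1)
    nl_fixed_point(q1, 5, 0.0005)$T_star, numeric(1))
  expect_true(all(diff(Ts) < 0))
})

test_that("q1 threshold matches the admissibility-bisection oracle", {
  expect_equal(q1_threshold(0.005), 2.4874, tolerance = 1e-4)
  expect_equal(q1_threshold(0.0005), 0.24762, tolerance = 1e-4)
  # oracle: bisection for the q1 at which the SL-branch oxygen balance
  # crosses the hypoxic threshold (root of the untreated c-equation at
  # full occupancy, independent of the closed form under test)
  sl_c <- function(q1, V0)
    uniroot(function(cc)
      default_params$g * (1 - cc) * V0 - q1 * cc * (1 - V0),
      c(1e-8, 1), tol = 1e-14)$root
  for (V0 in c(0.005, 0.00275)) {
    bis <- uniroot(function(q1) sl_c(q1, V0) - default_params$c_min,
                   c(0.01, 9.99), tol = 1e-12)$root
    expect_equal(q1_threshold(V0), bis, tolerance = 1e-8)
  }
  # the six representative tumours sit on the correct side for their cohort
  expect_true(all(fixture_tumours$q1[fixture_tumours$regime == "NL"] >
                    q1_threshold(0.0005)))
  expect_true(all(fixture_tumours$q1[fixture_tumours$regime == "SL"] <
                    q1_threshold(0.005)))
})

test_that("q3 threshold separates SL-only from bistable", {
  q3b <- q3_threshold(0.005, q1 = 2.14)
  expect_identical(classify_regime(2.14, q3b * 0.99, 0.005), "SL")
  expect_identical(classify_regime(2.14, q3b * 1.01, 0.005), "BS")
  expect_equal(q3b, q3_threshold(0.005, q1 = 2.14), tolerance = 1e-6)
  # representative SL tumour C2 (q3 = 7.61) lies below this boundary
  expect_gt(q3b, 7.61)
  # for small q1 at V0 = 0.005 the boundary leaves the sampling box
  expect_error(q3_threshold(0.005, q1 = 0.151), "bracket")
  expect_error(q3_threshold(0.005, q1 = 5), "q1_threshold")
})

test_that("regimes classify per the representative tumours", {
  expect_identical(classify_regime(0.151, 0.210, 0.005), "SL")
  expect_identical(classify_regime(0.503, 0.272, 0.0005), "NL")
  for (i in seq_len(nrow(fixture_tumours)))
    expect_identical(
      classify_regime(fixture_tumours$q1[i], fixture_tumours$q3[i],
                      fixture_tumours$V0[i]),
      fixture_tumours$regime[i])
  # above the q1 threshold only NL states exist, whatever q3
  q1b <- q1_threshold(0.005)
  for (q3 in c(0.05, 1, 9))
    expect_identical(classify_regime(q1b * 1.01, q3, 0.005), "NL")
})

test_that("integration from perturbed states agrees with the algebra", {
  # monostable cases relax back to the module's fixed point
  a1 <- fx_row("A1")
  st <- steady_state_by_integration(a1$q1, a1$q3, a1$V0,
                                    T0 = a1$T_star * 0.6, c0 = 0.5)
  expect_true(st$converged)
  expect_lt(abs(st$state[["T"]] - a1$T_star), 1e-6)
  expect_lt(abs(st$state[["c"]] - a1$c_star), 1e-6)
  # bistability witness: basin depends on the initial tumour volume
  # (full occupancy is basin-safe for every BS tumour; lower starts can
  # crash oxygen below the hypoxic threshold before the space limit
  # binds and land on the NL branch instead)
  bs <- sample_cohort("BS", N = 1, seed = 11)
  lo <- steady_state_by_integration(bs$q1, bs$q3, bs$V0, T0 = 0.01)
  hi <- steady_state_by_integration(bs$q1, bs$q3, bs$V0, T0 = 1 - bs$V0)
  nl <- nl_fixed_point(bs$q1, bs$q3, bs$V0)
  expect_lt(abs(lo$state[["T"]] - nl$T_star), 1e-6)
  expect_lt(abs(hi$state[["T"]] - (1 - bs$V0)), 1e-6)
  expect_lt(hi$state[["c"]] - sl_fixed_point(bs$q1, bs$q3, bs$V0)$c_star,
            1e-6)
})
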