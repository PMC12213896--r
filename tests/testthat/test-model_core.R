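test_that("heaviside uses the H(0) = 1 convention and rejects non-finite", {
  expect_equal(heaviside(c(0, -0.5, 3, -1e-300)), c(1, 0, 1, 0))
  expect_error(heaviside(NaN), "non-finite")
  expect_error(heaviside(Inf), "non-finite")
})

test_that("forcing functions evaluate D/delta_R and beta inside windows", {
  rt <- build_rt_schedule(2, 5)
  expect_equal(rt_dose_rate(5, rt), 0.2)           # inside first fraction
  expect_equal(rt_dose_rate(0, rt), 0.2)           # closed left endpoint
  expect_equal(rt_dose_rate(10, rt), 0.2)          # closed right endpoint
  expect_equal(rt_dose_rate(500, rt), 0)           # between fractions
  rt5 <- build_rt_schedule(5, 1)
  expect_equal(rt_dose_rate(3, rt5), 0.5)
  ht <- build_ht_schedule(0.005, 8)
  expect_equal(ht_damage_rate(30, ht), 0.005)
  expect_equal(ht_damage_rate(10110, ht), 0.005)   # week-2 fraction
  expect_equal(ht_damage_rate(5000, ht), 0)
  expect_equal(ht_damage_rate(30, rt), 0)          # RT-only: no HT anywhere
  expect_equal(rt_dose_rate(30, ht), 0)
})

test_that("lambda closed form matches its rate-equation oracle", {
  k1 <- 0.5; k2 <- 1e-3; dH <- 60
  # frozen from the saturating-rise expression evaluated independently
  expect_equal(lambda_closed_form(60, 0, dH, k1, k2), 0.99800399,
               tolerance = 1e-7)
  expect_equal(lambda_closed_form(-5, 10, dH, k1, k2), 0)
  expect_equal(lambda_closed_form(5, 10, dH, k1, k2), 0)  # before t_H
  # forward-Euler integration of dL/dt = k1*1_HT*(1-L) - k2*L as oracle
  dt <- 1e-3
  tt <- seq(0, 200, by = dt)
  L <- 0; Lpath <- numeric(length(tt))
  for (i in seq_along(tt)) {
    Lpath[i] <- L
    on_ht <- tt[i] >= 0 && tt[i] <= dH
    L <- L + dt * (k1 * on_ht * (1 - L) - k2 * L)
  }
  idx <- match(c(10, 30, 60, 150), tt)
  expect_equal(lambda_closed_form(tt[idx], 0, dH, k1, k2), Lpath[idx],
               tolerance = 1e-3)
  # continuity at both boundaries and eventual decay
  eps <- 1e-9
  expect_equal(lambda_closed_form(60 - eps, 0, dH, k1, k2),
               lambda_closed_form(60 + eps, 0, dH, k1, k2),
               tolerance = 1e-6)
  expect_lt(lambda_closed_form(1e7, 0, dH, k1, k2), 1e-8)
})

test_that("repair rate is mu0 at Lambda = 0 and decreasing in Lambda", {
  expect_equal(repair_rate(0, 5e-3, 2.5), 5e-3)
  expect_equal(repair_rate(1, 5e-3, 2.5), 5e-3 * exp(-2.5),
               tolerance = 1e-12)          # ~4.104e-4
  expect_equal(repair_rate(0.7, 5e-3, 0), 5e-3)
  lams <- seq(0, 1, by = 0.1)
  expect_true(all(diff(repair_rate(lams, 5e-3, 2.5)) < 0))
  expect_error(repair_rate(1.5, 5e-3, 2.5))
})

test_that("model_rhs reproduces hand-evaluated derivatives", {
  # untreated fixed point: all derivatives vanish
  a1 <- fx_row("A1")
  p <- thermorad:::tumour_params(default_params, a1)
  expect_lt(max(abs(model_rhs(0, baseline_state(a1), p))), 1e-10)
  # zero state: every term carries a state factor
  expect_equal(unname(model_rhs(0, rep(0, 7), p)), rep(0, 7))
  # hand evaluation of the proliferation term with q3 = 1 (q2 = 0.01)
  p2 <- thermorad:::tumour_params(default_params, list(q1 = 1, q3 = 1))
  d <- model_rhs(0, c(0.5, 0, 0, 0, 0.005, 0.5, 0), p2)
  expect_equal(d[["T"]], 0.01 * 0.5 * (1 - 0.505) * 0.5,
               tolerance = 1e-14)   # 1.2375e-3
})

test_that("derived parameters are locked to their defining relations", {
  p <- model_params(q1 = 0.3, q3 = 2.5)
  expect_identical(p$q2, p$k * p$q3)
  expect_identical(p$delta, p$q2)
  expect_identical(p$delta_S, p$theta2 * p$q2)
  expect_identical(p$k1, 0)
  expect_error(model_params(theta2 = 1.5), "theta2")
  expect_error(model_params(c_min = 0), "c_min")
})

test_that("parameters round-trip through flat JSON without derived fields", {
  p <- model_params(q1 = 0.42, q3 = 3.14, mu0 = 4e-3)
  f <- tempfile(fileext = ".json")
  write_params_json(p, f)
  raw <- jsonlite::read_json(f)
  expect_false(any(c("q2", "delta", "delta_S", "k1") %in% names(raw)))
  q <- read_params_json(f)
  expect_equal(q[names(p)], p[names(p)])
})
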