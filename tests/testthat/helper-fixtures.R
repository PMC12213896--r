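# shared fixtures and oracles for the suite

default_params <- model_params()

fixture_tumours <- representative_tumours()

fx_row <- function(label) {
  fixture_tumours[fixture_tumours$label == label, ]
}

# fixed-step classical RK4 on the R-side right-hand side: the independent
# reference route against the compiled adaptive integrator
rk4_reference <- function(y0, params, schedule, t0, t1, dt) {
  y <- unname(y0)
  t <- t0
  nstep <- round((t1 - t0) / dt)
  for (s in seq_len(nstep)) {
    k1 <- model_rhs(t, y, params, schedule)
    k2 <- model_rhs(t + dt / 2, y + dt / 2 * k1, params, schedule)
    k3 <- model_rhs(t + dt / 2, y + dt / 2 * k2, params, schedule)
    k4 <- model_rhs(t + dt, y + dt * k3, params, schedule)
    y <- unname(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    t <- t0 + s * dt
  }
  y
}

# construct a response summary from raw metrics (for rule unit tests)
make_response <- function(delta_viable, delta_total, delta_V,
                          delta_c = 0, treatment = "R") {
  structure(list(delta_viable = delta_viable, delta_total = delta_total,
                 delta_V = delta_V, delta_c = delta_c,
                 combined_score = delta_viable + delta_total,
                 treatment = treatment),
            class = "rht_response")
}

# box invariants every stored trajectory must satisfy
expect_trajectory_invariants <- function(traj) {
  expect_true(all(diff(traj$t) > 0))
  for (comp in c("T", "T_S", "T_R", "T_H", "V"))
    expect_true(all(traj[[comp]] >= 0), label = paste(comp, ">= 0"))
  expect_true(all(traj$c >= 0 & traj$c <= 1))
  expect_true(all(traj$Lambda >= 0 & traj$Lambda <= 1))
  expect_true(all(traj$Sigma <= 1 + 1e-6))
}
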