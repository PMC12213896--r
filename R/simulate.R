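# Trajectory integration over a treatment schedule.

#' Solver options
#'
#' @param rtol,atol relative/absolute integration tolerances.
#' @param coarse_dt output spacing (min) outside the last treatment week.
#' @param fine_dt output spacing (min) inside the last treatment week.
#' @return a list of class `rht_solver_options`.
#' @export
solver_options <- function(rtol = 1e-8, atol = 1e-10, coarse_dt = 10,
                           fine_dt = 1) {
  stopifnot(rtol > 0, atol > 0, coarse_dt > 0, fine_dt > 0)
  structure(list(rtol = rtol, atol = atol, coarse_dt = coarse_dt,
                 fine_dt = fine_dt), class = "rht_solver_options")
}

# output grid: <= coarse_dt spacing early, fine_dt over the final week,
# plus every forcing breakpoint; strictly increasing, ends at t_end
output_grid <- function(schedule, opts) {
  t_end <- schedule$t_end
  wk <- max(0, t_end - WEEK_MIN)
  tt <- c(0,
          if (wk > 0) seq(0, wk, by = opts$coarse_dt),
          seq(wk, t_end, by = opts$fine_dt),
          t_end, event_times(schedule))
  sort(unique(tt))
}

#' Simulate a virtual tumour over a schedule
#'
#' Integrates the augmented seven-component system from the tumour's
#' baseline steady state, restarting at every treatment-window boundary so
#' that each segment sees constant forcing (the restart is exact for
#' piecewise-constant dose rates). The repair-protein inactivation rate is
#' coupled to the schedule: `k1 = 100 * beta_tilde`, 0 for RT-only
#' schedules.
#'
#' @param tumour a one-row slice of an `rht_cohort` (or a list with `q1`,
#'   `q3`, `V0`, `T_star`, `c_star`).
#' @param schedule an `rht_schedule`.
#' @param params cohort-level `rht_params`; the tumour's `q1`, `q3` are
#'   substituted in.
#' @param opts an [solver_options()] list.
#' @return an `rht_trajectory`: data.frame with columns `t`, the seven
#'   state components, and `Sigma`, plus solver statistics in attributes.
#' @export
#' @examples
#' fx <- representative_tumours()
#' tr <- simulate_tumour(fx[fx$label == "A2", ], build_ht_schedule(0.005, 1))
#' tail(tr, 1)
simulate_tumour <- function(tumour, schedule, params = model_params(),
                            opts = solver_options()) {
  stopifnot(inherits(schedule, "rht_schedule"))
  p <- tumour_params(params, tumour, beta_tilde = schedule$beta_tilde)
  y0 <- baseline_state(tumour)
  segs <- schedule_segments(schedule)
  grid <- output_grid(schedule, opts)
  res <- .dp45_run(unname(y0), param_vec(p), segs, grid,
                   opts$rtol, opts$atol)
  states <- res$states
  colnames(states) <- state_names
  traj <- data.frame(t = grid, states)
  traj$Sigma <- rowSums(states[, 1:5, drop = FALSE])
  if (res$nclip_hard > 0)
    warning(sprintf("%d state clips above round-off magnitude",
                    res$nclip_hard))
  if (any(traj$Sigma > 1 + 1e-6))
    warning("total volume exceeded 1 + 1e-6: model-regime violation")
  structure(traj, class = c("rht_trajectory", "data.frame"),
            schedule_ref = schedule_descriptor(schedule),
            t_end = schedule$t_end,
            solver_stats = res[c("naccept", "nreject", "nclip_soft",
                                 "nclip_hard")],
            rtol = opts$rtol, atol = opts$atol)
}

#' Time-averaged state over the final treatment week
#'
#' Trapezoidal means of each component over `[t_end - 10080, t_end]`, the
#' window from which all response metrics are computed.
#'
#' @param traj an `rht_trajectory`.
#' @param schedule the schedule it was produced under.
#' @return a list with `T_bar, TS_bar, TR_bar, TH_bar, V_bar, c_bar`.
#' @export
last_week_means <- function(traj, schedule) {
  t_end <- schedule$t_end
  if (t_end < WEEK_MIN)
    stop("horizon shorter than one week: last-week means undefined")
  keep <- traj$t >= t_end - WEEK_MIN & traj$t <= t_end
  tt <- traj$t[keep]
  if (length(tt) < 2) stop("too few output points in the last week")
  trap <- function(y) {
    sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) /
      (tt[length(tt)] - tt[1])
  }
  list(T_bar = trap(traj$T[keep]), TS_bar = trap(traj$T_S[keep]),
       TR_bar = trap(traj$T_R[keep]), TH_bar = trap(traj$T_H[keep]),
       V_bar = trap(traj$V[keep]), c_bar = trap(traj$c[keep]))
}

#' Relax the untreated system to its attracting steady state
#'
#' Integrates the untreated model from an arbitrary admissible initial
#' condition until the derivative sup-norm falls below `f_tol`. Which
#' steady state is reached depends on the basin the initial condition
#' lies in (the bistable regime has two).
#'
#' @param q1,q3,V0 tumour parameters.
#' @param T0,c0 initial tumour volume and oxygen concentration.
#' @param params an `rht_params`.
#' @param t_max maximum integration time (min).
#' @param f_tol convergence threshold on the derivative sup-norm.
#' @param opts an [solver_options()] list.
#' @return a list with the final `state`, the stopping time `t` and a
#'   `converged` flag.
#' @export
#' @examples
#' st <- steady_state_by_integration(q1 = 0.151, q3 = 0.210, V0 = 0.005)
#' st$state[["T"]]  # ~0.995
steady_state_by_integration <- function(q1, q3, V0, T0 = 0.01, c0 = 1,
                                        params = model_params(),
                                        t_max = 2e6, f_tol = 1e-11,
                                        opts = solver_options(rtol = 1e-10,
                                                              atol = 1e-13)) {
  p <- tumour_params(params, list(q1 = q1, q3 = q3))
  y0 <- c(T0, 0, 0, 0, V0, c0, 0)
  res <- .dp45_steady(y0, param_vec(p), t_max, f_tol, opts$rtol,
                      opts$atol)
  list(state = stats::setNames(res$y, state_names), t = res$t,
       converged = res$converged)
}
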