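#' Heaviside step function
#'
#' Unit step with the convention `H(0) = 1`, so hypoxic death switches on
#' exactly at the threshold oxygen concentration.
#'
#' @param x numeric vector, finite.
#' @return 0/1 vector of the same length.
#' @export
#' @examples
#' heaviside(c(-0.5, 0, 3))
heaviside <- function(x) {
  if (any(!is.finite(x))) stop("heaviside: non-finite argument")
  as.numeric(x >= 0)
}

#' Treatment forcing functions
#'
#' `rt_dose_rate` evaluates the dimensionless RT dose rate `D / delta_R`
#' inside any RT fraction window of a schedule (closed intervals) and 0
#' elsewhere; `ht_damage_rate` evaluates the HT damage rate `beta_tilde`
#' inside any HT window and 0 elsewhere.
#'
#' @param t time in minutes (vectorised).
#' @param schedule an `rht_schedule`.
#' @return numeric vector of rates.
#' @export
rt_dose_rate <- function(t, schedule) {
  stopifnot(inherits(schedule, "rht_schedule"))
  w <- schedule$rt_windows
  if (is.null(w) || nrow(w) == 0 || schedule$D == 0) return(numeric(length(t)))
  rate <- schedule$D / schedule$delta_R
  inside <- vapply(t, function(ti) any(ti >= w[, 1] & ti <= w[, 2]),
                   logical(1))
  ifelse(inside, rate, 0)
}

#' @rdname rt_dose_rate
#' @export
ht_damage_rate <- function(t, schedule) {
  stopifnot(inherits(schedule, "rht_schedule"))
  w <- schedule$ht_windows
  if (is.null(w) || nrow(w) == 0 || schedule$beta_tilde == 0)
    return(numeric(length(t)))
  inside <- vapply(t, function(ti) any(ti >= w[, 1] & ti <= w[, 2]),
                   logical(1))
  ifelse(inside, schedule$beta_tilde, 0)
}

#' Closed-form inactive repair-protein fraction for a single HT fraction
#'
#' Piecewise solution of the repair-protein kinetics for one heating window
#' `[t_H, t_H + delta_H]`: zero before heating, saturating rise at rate
#' `k1 + k2` during heating, exponential decay at rate `k2` afterwards.
#' Continuous at both window boundaries.
#'
#' @param t time in minutes (vectorised).
#' @param t_H heating start (min).
#' @param delta_H heating duration (min).
#' @param k1 inactivation rate (per min), `100 * beta_tilde`.
#' @param k2 reactivation rate (per min).
#' @return fraction in \[0, 1\].
#' @export
#' @examples
#' lambda_closed_form(60, t_H = 0, delta_H = 60, k1 = 0.5, k2 = 1e-3)
lambda_closed_form <- function(t, t_H, delta_H, k1, k2) {
  stopifnot(k1 > 0, k2 > 0, delta_H > 0)
  peak <- k1 / (k1 + k2) * (1 - exp(-(k1 + k2) * delta_H))
  ifelse(t < t_H, 0,
         ifelse(t < t_H + delta_H,
                k1 / (k1 + k2) * (1 - exp(-(k1 + k2) * (t - t_H))),
                peak * exp(-k2 * (t - (t_H + delta_H)))))
}

#' Heat-suppressed DNA repair rate
#'
#' `mu0 * exp(-mu_Lambda * Lambda)`: the sub-lethal damage repair rate as a
#' decreasing function of the inactive repair-protein fraction.
#'
#' @param Lambda inactive repair-protein fraction in \[0, 1\] (vectorised).
#' @param mu0 baseline repair rate.
#' @param mu_Lambda repair-inhibition weight.
#' @return repair rate, equal to `mu0` when `Lambda = 0`.
#' @export
repair_rate <- function(Lambda, mu0, mu_Lambda) {
  stopifnot(all(Lambda >= 0), all(Lambda <= 1))
  mu0 * exp(-mu_Lambda * Lambda)
}

#' Model right-hand side (reference R implementation)
#'
#' Derivatives of the seven-component state
#' `(T, T_S, T_R, T_H, V, c, Lambda)` under a schedule's forcing. This is
#' the plain-R twin of the compiled integrator kernel; it exists for
#' fixed-point residuals, oracle cross-checks and interactive inspection,
#' and is deliberately side-effect free.
#'
#' @param t time (min).
#' @param state named or positional numeric vector of length 7 in the
#'   order `T, T_S, T_R, T_H, V, c, Lambda`.
#' @param params an `rht_params` (with `k1` already set for the schedule).
#' @param schedule an `rht_schedule`, or `NULL` for the untreated system.
#' @return numeric vector of the seven derivatives.
#' @export
model_rhs <- function(t, state, params, schedule = NULL) {
  stopifnot(length(state) == 7, all(is.finite(state)))
  R <- if (is.null(schedule)) 0 else rt_dose_rate(t, schedule)
  beta <- if (is.null(schedule)) 0 else ht_damage_rate(t, schedule)
  ht_on <- as.numeric(beta > 0)
  T_ <- state[[1]]; TS <- state[[2]]; TR <- state[[3]]; TH <- state[[4]]
  V <- state[[5]]; cc <- state[[6]]; L <- state[[7]]
  Sigma <- T_ + TS + TR + TH + V
  fre <- 1 - Sigma
  hyp <- (params$c_min - cc) * heaviside(params$c_min - cc)
  mu <- repair_rate(L, params$mu0, params$mu_Lambda)
  dT <- params$q2 * cc * fre * T_ -
    (params$delta * hyp + params$lam * cc * R + params$nu * cc * R) * T_ +
    mu * TS - beta * T_
  dTS <- params$theta2 * params$q2 * cc * fre * TS -
    (params$delta_S * hyp + params$lam_S * cc * R + mu + params$xi) * TS +
    params$nu * cc * R * T_ - beta * TS
  dTR <- params$lam * cc * R * T_ +
    (params$lam_S * cc * R + params$xi) * TS - params$eta_R * TR
  dTH <- beta * (T_ + TS) - params$eta_H * TH
  dV <- params$kappa0 * TH - beta * V
  dc <- params$g * (1 - cc) * V -
    (params$q1 * cc * (T_ + params$theta1 * TS) +
       params$q3 * cc * fre * (T_ + params$theta2 * TS))
  dL <- params$k1 * ht_on * (1 - L) - params$k2 * L
  c(T = dT, T_S = dTS, T_R = dTR, T_H = dTH, V = dV, c = dc, Lambda = dL)
}

state_names <- c("T", "T_S", "T_R", "T_H", "V", "c", "Lambda")
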