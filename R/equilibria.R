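# Untreated fixed points and growth-regime classification.
#
# With treatment off and no damaged compartments, the model reduces to a
# planar system in (T, c) with V = V0 constant:
#   dT/dt = q2 c (1 - T - V0) T - delta (c_min - c) H(c_min - c) T
#   dc/dt = g (1 - c) V0 - q1 c T - q3 c (1 - T - V0) T
# The space-limited (SL) branch packs the domain (T = 1 - V0) and its
# oxygen balance has the closed form c* = g V0 / (q1 (1 - V0) + g V0).
# The nutrient-limited (NL) branch balances proliferation against hypoxic
# death below c_min, giving Sigma = 1 - (c_min - c)/c and a scalar oxygen
# residual that is solved by bracketing + uniroot.

#' Space-limited fixed point
#'
#' The fully packed steady state `T* = 1 - V0` with oxygen solving the
#' exchange/consumption balance (the proliferation-linked consumption term
#' vanishes when no free volume remains). Admissible only while the
#' resulting oxygen level is at or above the hypoxic threshold.
#'
#' @param q1,q3 per-tumour oxygen consumption rates.
#' @param V0 vascular volume fraction, in (0, 1).
#' @param params an `rht_params`.
#' @return a list with `T_star`, `c_star`, `branch = "SL"`, `stable`, or
#'   `NULL` when `c_star < c_min`.
#' @export
#' @examples
#' sl_fixed_point(q1 = 0.151, q3 = 0.210, V0 = 0.005)$T_star  # 0.995
sl_fixed_point <- function(q1, q3, V0, params = model_params()) {
  stopifnot(V0 > 0, V0 < 1)
  T_star <- 1 - V0
  c_star <- params$g * V0 / (q1 * T_star + params$g * V0)
  if (c_star < params$c_min) return(NULL)
  list(T_star = T_star, c_star = c_star, branch = "SL", stable = TRUE)
}

# oxygen residual on the NL branch as a function of c in (c_lo, c_min):
# T(c) = 1 - V0 - (c_min - c)/c from the proliferation/death balance
nl_residual <- function(cc, q1, q3, V0, p) {
  T_ <- 1 - V0 - (p$c_min - cc) / cc
  p$g * (1 - cc) * V0 - T_ * (q1 * cc + q3 * (p$c_min - cc))
}

# analytic Jacobian of the reduced (T, c) system on the NL branch
nl_jacobian <- function(T_, cc, q1, q3, V0, p) {
  fre <- 1 - T_ - V0
  j11 <- p$q2 * cc * (1 - 2 * T_ - V0) - p$delta * (p$c_min - cc)
  j12 <- p$q2 * T_ * fre + p$delta * T_
  j21 <- -q1 * cc - q3 * cc * (1 - 2 * T_ - V0)
  j22 <- -p$g * V0 - q1 * T_ - q3 * T_ * fre
  matrix(c(j11, j12, j21, j22), 2, 2, byrow = TRUE)
}

#' Nutrient-limited fixed point
#'
#' Solves the hypoxic steady state where proliferation balances hypoxic
#' death (`0 < c* < c_min`). Candidate oxygen roots are located by sign
#' change of the oxygen residual over a fine grid and polished with
#' [stats::uniroot()]; stability is certified from the eigenvalues of the
#' analytic 2x2 Jacobian of the reduced `(T, c)` system (both real parts
#' below `-1e-12`).
#'
#' @inheritParams sl_fixed_point
#' @param n_grid number of bracketing grid points.
#' @return a list with `T_star`, `c_star`, `branch = "NL"`, `stable`, or
#'   `NULL` when no admissible stable root exists.
#' @export
nl_fixed_point <- function(q1, q3, V0, params = model_params(),
                           n_grid = 400) {
  stopifnot(V0 > 0, V0 < 1)
  p <- tumour_params(params, list(q1 = q1, q3 = q3))
  # T > 0 requires (c_min - c)/c < 1 - V0
  c_lo <- p$c_min / (2 - V0)
  eps <- (p$c_min - c_lo) * 1e-9
  grid <- seq(c_lo + eps, p$c_min - eps, length.out = n_grid)
  fv <- vapply(grid, nl_residual, numeric(1), q1 = q1, q3 = q3, V0 = V0,
               p = p)
  roots <- list()
  for (i in seq_len(n_grid - 1)) {
    if (is.finite(fv[i]) && is.finite(fv[i + 1]) &&
        fv[i] == 0) {
      roots[[length(roots) + 1]] <- grid[i]
    } else if (is.finite(fv[i]) && is.finite(fv[i + 1]) &&
               fv[i] * fv[i + 1] < 0) {
      r <- tryCatch(
        stats::uniroot(nl_residual, c(grid[i], grid[i + 1]), q1 = q1,
                       q3 = q3, V0 = V0, p = p, tol = 1e-15)$root,
        error = function(e)
          stop("NL root finder failed to converge in a verified bracket: ",
               conditionMessage(e)))
      roots[[length(roots) + 1]] <- r
    }
  }
  if (length(roots) == 0) return(NULL)
  stable <- NULL
  for (cc in unlist(roots)) {
    T_ <- 1 - V0 - (p$c_min - cc) / cc
    if (T_ <= 0) next
    ev <- eigen(nl_jacobian(T_, cc, q1, q3, V0, p),
                only.values = TRUE)$values
    if (all(Re(ev) < -1e-12)) {
      cand <- list(T_star = T_, c_star = cc, branch = "NL", stable = TRUE)
      # keep the largest-T stable root if several (not expected)
      if (is.null(stable) || cand$T_star > stable$T_star) stable <- cand
    }
  }
  stable
}

#' Threshold maintenance-consumption rate for SL admissibility
#'
#' The `q1` value at which the space-limited branch's oxygen level equals
#' the hypoxic threshold; above it only nutrient-limited steady states
#' exist. Closed form from `c*_SL = c_min`:
#' `q1_bar = g V0 (1 - c_min) / (c_min (1 - V0))`.
#'
#' @inheritParams sl_fixed_point
#' @return the threshold value.
#' @export
#' @examples
#' q1_threshold(0.005)   # ~2.4874
q1_threshold <- function(V0, params = model_params()) {
  stopifnot(V0 > 0, V0 < 1)
  params$g * V0 * (1 - params$c_min) / (params$c_min * (1 - V0))
}

#' Threshold proliferation-consumption rate separating SL-only from BS
#'
#' For fixed `V0` and `q1` below [q1_threshold()], the `q3` value above
#' which a stable nutrient-limited state coexists with the space-limited
#' one (bistability). Located by bisection on the existence of a stable NL
#' root over `q3` in `[0.01, 10]`.
#'
#' @inheritParams sl_fixed_point
#' @param tol bisection tolerance on `q3`.
#' @return the threshold value.
#' @export
q3_threshold <- function(V0, q1, params = model_params(), tol = 1e-8) {
  stopifnot(V0 > 0, V0 < 1)
  if (q1 > q1_threshold(V0, params))
    stop("q3_threshold is defined only for q1 <= q1_threshold(V0)")
  has_nl <- function(q3)
    !is.null(nl_fixed_point(q1, q3, V0, params))
  lo <- 0.01; hi <- 10
  if (has_nl(lo) || !has_nl(hi))
    stop("no SL-only/BS transition in q3 bracket [0.01, 10]; ",
         "parameters outside the sampling box")
  while (hi - lo > tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (has_nl(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Classify a parameter triple into a growth regime
#'
#' `"SL"` if only the space-limited steady state is admissible, `"NL"` if
#' only the nutrient-limited one, `"BS"` if both coexist. A triple exactly
#' at `q1 = q1_bar` counts as NL and one exactly at `q3 = q3_bar` as BS,
#' matching the open/closed sides of the cohort sampling intervals.
#'
#' @inheritParams sl_fixed_point
#' @return one of `"NL"`, `"SL"`, `"BS"`.
#' @export
#' @examples
#' classify_regime(q1 = 0.151, q3 = 0.210, V0 = 0.005)  # "SL"
classify_regime <- function(q1, q3, V0, params = model_params()) {
  sl_ok <- q1 < q1_threshold(V0, params)
  nl <- nl_fixed_point(q1, q3, V0, params)
  nl_ok <- !is.null(nl)
  if (sl_ok && nl_ok) return("BS")
  if (sl_ok) return("SL")
  if (nl_ok) return("NL")
  stop("no admissible steady state for (q1, q3, V0) = (",
       q1, ", ", q3, ", ", V0, ")")
}
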