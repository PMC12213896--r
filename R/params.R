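#' Dimensionless model parameters
#'
#' Constructs the full parameter set of the tumour--vasculature--oxygen
#' model. Time is measured in minutes, volumes as fractions of the total
#' available volume, oxygen as a fraction of the vascular oxygen
#' concentration, and the RT dose rate in units of 1 Gy/min. Defaults are
#' the study's reference values; only `q1`, `q3` (per-tumour oxygen
#' consumption rates) and the vascular volume vary across virtual tumours.
#'
#' Derived quantities are never free: the proliferation rate is
#' `q2 = k * q3`, the hypoxic death rates are `delta = q2` and
#' `delta_S = theta2 * q2`, and the repair-protein inactivation rate is
#' `k1 = 100 * beta_tilde` of the active schedule (0 when no HT is given).
#'
#' @param q1 oxygen consumption rate for maintenance (per min per volume).
#' @param q3 oxygen consumption rate for proliferation.
#' @param c_min hypoxic oxygen threshold (fraction of vascular oxygen).
#' @param g oxygen exchange rate per unit vascular volume.
#' @param k conversion factor linking proliferation to oxygen consumption.
#' @param theta1 maintenance-consumption multiplier for sub-lethally
#'   damaged cells (> 1: repair costs oxygen).
#' @param theta2 proliferation multiplier for sub-lethally damaged cells
#'   (in (0,1): damaged cells proliferate slower).
#' @param nu RT sub-lethal damage rate.
#' @param lam,lam_S RT lethal damage rates for undamaged and sub-lethally
#'   damaged cells.
#' @param mu0 baseline repair rate of sub-lethal damage (per min).
#' @param xi mitotic-catastrophe rate (per min).
#' @param eta_R,eta_H clearance rates of RT- and HT-killed cells.
#' @param kappa0 HT-damage-induced angiogenesis rate.
#' @param mu_Lambda repair-inhibition weight (exponent scale).
#' @param k2 repair-protein reactivation rate (per min).
#' @return an object of class `rht_params` (a named list including the
#'   derived fields `q2`, `delta`, `delta_S` and `k1 = 0`).
#' @export
#' @examples
#' p <- model_params(q1 = 0.151, q3 = 0.210)
#' p$q2  # k * q3
model_params <- function(q1 = 1, q3 = 1, c_min = 1e-2, g = 5, k = 1e-2,
                         theta1 = 10, theta2 = 0.1, nu = 10, lam = 1,
                         lam_S = 1, mu0 = 5e-3, xi = 5e-4, eta_R = 5e-5,
                         kappa0 = 1e-7, eta_H = 5e-5, mu_Lambda = 2.5,
                         k2 = 1e-3) {
  p <- list(q1 = q1, q3 = q3, c_min = c_min, g = g, k = k, theta1 = theta1,
            theta2 = theta2, nu = nu, lam = lam, lam_S = lam_S, mu0 = mu0,
            xi = xi, eta_R = eta_R, kappa0 = kappa0, eta_H = eta_H,
            mu_Lambda = mu_Lambda, k2 = k2)
  p$q2 <- p$k * p$q3
  p$delta <- p$q2
  p$delta_S <- p$theta2 * p$q2
  p$k1 <- 0
  class(p) <- "rht_params"
  validate_params(p)
  p
}

#' @export
print.rht_params <- function(x, ...) {
  cat("dimensionless model parameters\n")
  cat(sprintf("  growth: q1=%g q3=%g (q2=%g) c_min=%g g=%g k=%g\n",
              x$q1, x$q3, x$q2, x$c_min, x$g, x$k))
  cat(sprintf("  RT: nu=%g lam=%g lam_S=%g mu0=%g xi=%g eta_R=%g\n",
              x$nu, x$lam, x$lam_S, x$mu0, x$xi, x$eta_R))
  cat(sprintf("  HT: kappa0=%g eta_H=%g mu_Lambda=%g k1=%g k2=%g\n",
              x$kappa0, x$eta_H, x$mu_Lambda, x$k1, x$k2))
  invisible(x)
}

validate_params <- function(p) {
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all parameters must be numeric")
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all parameters must be finite and non-negative")
  if (p$c_min <= 0 || p$c_min >= 1) stop("c_min must lie in (0, 1)")
  if (p$theta2 <= 0 || p$theta2 >= 1) stop("theta2 must lie in (0, 1)")
  if (p$theta1 <= 1) stop("theta1 must exceed 1")
  if (abs(p$q2 - p$k * p$q3) > 1e-15 * max(1, p$q2))
    stop("q2 must equal k * q3")
  if (p$delta != p$q2 || p$delta_S != p$theta2 * p$q2)
    stop("delta and delta_S must be derived from q2")
  invisible(p)
}

# substitute a tumour's (q1, q3) and a schedule's k1 into a parameter set
tumour_params <- function(params, tumour = NULL, beta_tilde = 0) {
  stopifnot(inherits(params, "rht_params"))
  if (!is.null(tumour)) {
    params$q1 <- tumour$q1
    params$q3 <- tumour$q3
    params$q2 <- params$k * params$q3
    params$delta <- params$q2
    params$delta_S <- params$theta2 * params$q2
  }
  params$k1 <- 100 * beta_tilde
  params
}

# flat named vector in the order the C++ side expects (by name)
param_vec <- function(p) {
  unlist(p[c("q2", "delta", "delta_S", "c_min", "lam", "nu", "lam_S",
             "mu0", "xi", "eta_R", "eta_H", "kappa0", "g", "q1", "q3",
             "theta1", "theta2", "mu_Lambda", "k1", "k2")])
}

# serialisable base fields: everything derived is recomputed on read
.param_base_fields <- c("c_min", "g", "k", "q1", "q3", "theta1", "theta2",
                        "nu", "lam", "lam_S", "mu0", "xi", "eta_R",
                        "kappa0", "eta_H", "mu_Lambda", "k2")

#' Read / write model parameters as flat JSON
#'
#' Only the free parameters are stored; derived fields (`q2`, `delta`,
#' `delta_S`, `k1`) are recomputed on read and silently ignored if present
#' in the file.
#'
#' @param params an `rht_params` object.
#' @param path file path.
#' @return `read_params_json` returns an `rht_params` object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "rht_params"))
  jsonlite::write_json(params[.param_base_fields], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- raw[names(raw) %in% .param_base_fields]
  do.call(model_params, keep)
}
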