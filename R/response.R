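# End-of-treatment response metrics, stratification and deleterious flag.

#' Percent-change response metrics
#'
#' Percent changes between baseline and the last-week means: viable
#' tumour volume (`T + T_S` vs `T*`), total occupied volume (`Sigma_bar`
#' vs `T* + V0`), vascular volume and oxygen concentration. `-100` means
#' complete eradication of the respective pool. The scalar efficacy
#' measure used for stratification and ranking is
#' `combined_score = delta_viable + delta_total`.
#'
#' @param means output of [last_week_means()].
#' @param tumour the simulated tumour (needs `T_star`, `V0`, `c_star`).
#' @param treatment label `"R"`, `"H"` or `"R_H"`.
#' @return a list of class `rht_response` with fields `delta_viable`,
#'   `delta_total`, `delta_V`, `delta_c`, `combined_score`, `treatment`.
#' @export
percent_changes <- function(means, tumour, treatment = c("R", "H", "R_H")) {
  treatment <- match.arg(treatment)
  T_star <- tumour$T_star; V0 <- tumour$V0; c_star <- tumour$c_star
  if (T_star <= 0 || V0 <= 0 || c_star <= 0)
    stop("zero baseline: metrics undefined")
  Sigma0 <- T_star + V0
  Sigma_bar <- means$T_bar + means$TS_bar + means$TR_bar + means$TH_bar +
    means$V_bar
  dv <- 100 * ((means$T_bar + means$TS_bar) - T_star) / T_star
  dt <- 100 * (Sigma_bar - Sigma0) / Sigma0
  dV <- 100 * (means$V_bar - V0) / V0
  dc <- 100 * (means$c_bar - c_star) / c_star
  # components the forcing never touches (e.g. V under RT alone) are
  # constant in exact arithmetic; snap averaging round-off to exactly 0
  # so the strict > 0 comparison rules see the analytic value
  snap <- function(x) if (abs(x) < 1e-9) 0 else x
  dv <- snap(dv); dt <- snap(dt); dV <- snap(dV); dc <- snap(dc)
  structure(list(delta_viable = dv, delta_total = dt, delta_V = dV,
                 delta_c = dc, combined_score = dv + dt,
                 treatment = treatment),
            class = "rht_response")
}

.response_classes <- c("negative", "limited", "moderate", "positive",
                       "strongly_positive")

#' Stratify combined scores into the five response classes
#'
#' Scores at or above 0 are `negative` responses. Among the negative-score
#' (i.e. responding) tumours, the 10, 37.5 and 62.5 percent percentiles of
#' the combined-score distribution split `strongly_positive` (< q10),
#' `positive` (\[q10, q37.5)), `moderate` (\[q37.5, q62.5)) and `limited`
#' (\[q62.5, 0)). Percentiles use linear interpolation between order
#' statistics ([stats::quantile()] type 7) and are cohort- and
#' schedule-specific: always compute them over one `(cohort, schedule)`
#' pair at a time.
#'
#' @param scores numeric vector of combined scores for one cohort under
#'   one schedule.
#' @param include_nonnegative if `TRUE`, percentiles are estimated over
#'   all scores rather than the responding subset (the alternative
#'   reading of the stratification table).
#' @return factor of response classes, same length as `scores`.
#' @export
stratify_cohort <- function(scores, include_nonnegative = FALSE) {
  stopifnot(is.numeric(scores))
  cls <- rep("negative", length(scores))
  neg <- scores < 0
  if (any(neg)) {
    basis <- if (include_nonnegative) scores else scores[neg]
    if (length(basis) < 10)
      warning("fewer than 10 scores: percentile estimates unstable")
    q <- stats::quantile(basis, c(0.10, 0.375, 0.625), names = FALSE,
                         type = 7)
    cls[neg] <- ifelse(scores[neg] < q[1], "strongly_positive",
                ifelse(scores[neg] < q[2], "positive",
                ifelse(scores[neg] < q[3], "moderate", "limited")))
  }
  factor(cls, levels = .response_classes)
}

#' Deleterious-treatment flag
#'
#' A treatment is deleterious when either the combined score or the
#' vascular percent change is strictly positive:
#' `max(delta_viable + delta_total, delta_V) > 0`.
#'
#' @param summary an `rht_response`.
#' @return logical.
#' @export
is_deleterious <- function(summary) {
  max(summary$combined_score, summary$delta_V) > 0
}

#' @export
print.rht_response <- function(x, ...) {
  cat(sprintf(
    "%s response: viable %+0.2f%% total %+0.2f%% V %+0.2f%% c %+0.2f%%%s\n",
    x$treatment, x$delta_viable, x$delta_total, x$delta_V, x$delta_c,
    if (is_deleterious(x)) " [deleterious]" else ""))
  invisible(x)
}

# one-call convenience: simulate + last-week means + metrics
response_summary <- function(tumour, schedule, params = model_params(),
                             opts = solver_options()) {
  treatment <- switch(schedule$modality, RT = "R", HT = "H", RT_HT = "R_H")
  traj <- simulate_tumour(tumour, schedule, params, opts)
  percent_changes(last_week_means(traj, schedule), tumour, treatment)
}
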