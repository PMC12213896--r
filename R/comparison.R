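# Rule-based treatment comparison and regimen ranking.
#
# Rule 1 drops any treatment with a strictly positive metric among
# {viable, total, vascular}. Rule 2 lets combined treatment beat a
# monotherapy only if both the viable and total reductions are at least
# 10 percentage points larger AND the vascular change is strictly
# smaller. Rule 3 orders the monotherapies by combined score (HT wins on
# strict inequality; ties go to RT).

#' Rule 1: is a treatment ineffective?
#' @param summary an `rht_response`.
#' @return `TRUE` when `max(delta_viable, delta_total, delta_V) > 0`.
#' @export
rule1_ineffective <- function(summary) {
  max(summary$delta_viable, summary$delta_total, summary$delta_V) > 0
}

#' Rule 2: does combined treatment significantly beat a monotherapy?
#' @param combo,mono `rht_response` objects.
#' @return logical.
#' @export
rule2_combined_better <- function(combo, mono) {
  max(combo$delta_viable - mono$delta_viable,
      combo$delta_total - mono$delta_total) <= -10 &&
    combo$delta_V < mono$delta_V
}

#' Rule 3: is HT more effective than RT?
#' @param ht,rt `rht_response` objects.
#' @return `TRUE` iff HT's combined score is strictly smaller.
#' @export
rule3_ht_better <- function(ht, rt) {
  ht$combined_score < rt$combined_score
}

#' Best treatment for one matched schedule pair
#'
#' Applies Rule 1 to the three summaries; if the combination survives it
#' must additionally pass Rule 2 against the better surviving monotherapy
#' (or both monotherapies with `rule2_both = TRUE`); otherwise the better
#' surviving monotherapy wins by Rule 3.
#'
#' @param rt,ht,combo `rht_response` objects for matched schedules.
#' @param rule2_both require Rule 2 against both surviving monotherapies.
#' @return one of `"R"`, `"H"`, `"R_H"`, `"none_effective"`.
#' @export
best_treatment <- function(rt, ht, combo, rule2_both = FALSE) {
  surv <- c(R = !rule1_ineffective(rt), H = !rule1_ineffective(ht),
            R_H = !rule1_ineffective(combo))
  if (!any(surv)) return("none_effective")
  best_mono <- if (surv[["R"]] && surv[["H"]]) {
    if (rule3_ht_better(ht, rt)) "H" else "R"
  } else if (surv[["R"]]) "R" else if (surv[["H"]]) "H" else NA_character_
  if (surv[["R_H"]]) {
    if (is.na(best_mono)) return("R_H")
    monos <- list(R = rt, H = ht)
    pass <- if (rule2_both) {
      all(vapply(names(surv[c("R", "H")])[surv[c("R", "H")]],
                 function(m) rule2_combined_better(combo, monos[[m]]),
                 logical(1)))
    } else {
      rule2_combined_better(combo, monos[[best_mono]])
    }
    if (pass) return("R_H")
  }
  if (is.na(best_mono)) "none_effective" else best_mono
}

#' Matched RT / HT / RT+HT comparison for one schedule pair
#'
#' Simulates the three comparable schedules derived from one
#' `(D, N_frac, beta_tilde)` triple — RT alone, HT alone over the same
#' number of weeks, and the combination — and applies the comparison
#' rules.
#'
#' @param tumour a one-row cohort slice.
#' @param D,N_frac RT fraction dose (Gy) and weekly fraction count.
#' @param beta_tilde HT damage rate per fraction.
#' @param params an `rht_params`.
#' @param opts an [solver_options()] list.
#' @param rule2_both see [best_treatment()].
#' @return a list of class `rht_matched_triple` with the three summaries,
#'   the schedule descriptors and the `winner`.
#' @export
compare_treatments <- function(tumour, D, N_frac, beta_tilde,
                               params = model_params(),
                               opts = solver_options(),
                               rule2_both = FALSE) {
  s_rt <- build_rt_schedule(D, N_frac)
  s_ht <- build_ht_schedule(beta_tilde, s_rt$N_wks)
  s_combo <- build_combined(D, N_frac, beta_tilde)
  rt <- response_summary(tumour, s_rt, params, opts)
  ht <- response_summary(tumour, s_ht, params, opts)
  combo <- response_summary(tumour, s_combo, params, opts)
  structure(list(tumour_id = tumour$id %||% NA_integer_, rt = rt, ht = ht,
                 combo = combo,
                 schedule_pair = c(rt = schedule_descriptor(s_rt),
                                   ht = schedule_descriptor(s_ht)),
                 winner = best_treatment(rt, ht, combo, rule2_both)),
            class = "rht_matched_triple")
}

#' Grid of matched schedule pairs
#'
#' Expands `(D, N_frac, beta_tilde)` combinations, resolves the week
#' count from the RT maximum-tolerated-dose rule and drops pairs whose
#' thermal total would break the HT cap.
#'
#' @param Ds RT doses (Gy).
#' @param N_fracs weekly RT fraction counts.
#' @param beta_tildes HT damage rates.
#' @return data.frame with columns `D, N_frac, beta_tilde, N_wks`.
#' @export
schedule_grid <- function(Ds = 1:5, N_fracs = c(1, 3, 5),
                          beta_tildes = c(0.001, 0.003, 0.005, 0.007,
                                          0.009, 0.01)) {
  g <- expand.grid(D = Ds, N_frac = N_fracs, beta_tilde = beta_tildes)
  g$N_wks <- mapply(mtd_weeks, g$D, g$N_frac)
  g[g$beta_tilde * g$N_wks <= BETA_MAX + 1e-12, , drop = FALSE]
}

.treat_order <- c(R = 1, H = 2, R_H = 3)

#' Rank regimens for one tumour across a schedule grid
#'
#' Step one is [compare_treatments()] per schedule pair; step two ranks
#' the per-pair winners from most to least negative combined score. Any
#' combined-treatment entry that fails the Rule 2 margin against its own
#' matched monotherapies is replaced in rank by the better monotherapy
#' (defensive: per-pair winners normally satisfy it already). Ties break
#' deterministically by treatment order R < H < R_H then by schedule
#' descriptor.
#'
#' @param tumour a one-row cohort slice.
#' @param grid output of [schedule_grid()].
#' @inheritParams compare_treatments
#' @return a list of class `rht_ranked_outcome` with `tumour_id`,
#'   `best_treatment`, `best_regimen` and the full `ranking` data.frame.
#' @export
rank_regimens <- function(tumour, grid = schedule_grid(),
                          params = model_params(),
                          opts = solver_options(), rule2_both = FALSE) {
  entries <- list()
  for (i in seq_len(nrow(grid))) {
    tri <- compare_treatments(tumour, grid$D[i], grid$N_frac[i],
                              grid$beta_tilde[i], params, opts,
                              rule2_both)
    if (tri$winner == "none_effective") next
    win <- tri$winner
    if (win == "R_H") {
      # defensive Rule-2 re-check against both matched monotherapies
      monos <- Filter(function(m) !rule1_ineffective(m),
                      list(R = tri$rt, H = tri$ht))
      bad <- any(!vapply(monos, function(m)
        rule2_combined_better(tri$combo, m), logical(1)))
      if (length(monos) > 0 && bad) {
        win <- if (length(monos) == 2) {
          if (rule3_ht_better(tri$ht, tri$rt)) "H" else "R"
        } else names(monos)[1]
      }
    }
    summ <- switch(win, R = tri$rt, H = tri$ht, R_H = tri$combo)
    desc <- switch(win, R = tri$schedule_pair[["rt"]],
                   H = tri$schedule_pair[["ht"]],
                   R_H = sprintf("%s + %s", tri$schedule_pair[["rt"]],
                                 tri$schedule_pair[["ht"]]))
    entries[[length(entries) + 1]] <-
      data.frame(treatment = win, regimen = desc,
                 combined_score = summ$combined_score,
                 D = grid$D[i], N_frac = grid$N_frac[i],
                 beta_tilde = grid$beta_tilde[i], N_wks = grid$N_wks[i])
  }
  if (length(entries) == 0) {
    return(structure(list(tumour_id = tumour$id %||% NA_integer_,
                          best_treatment = "none_effective",
                          best_regimen = NA_character_,
                          ranking = data.frame()),
                     class = "rht_ranked_outcome"))
  }
  rk <- do.call(rbind, entries)
  ord <- order(rk$combined_score, .treat_order[rk$treatment], rk$regimen)
  rk <- rk[ord, , drop = FALSE]
  rownames(rk) <- NULL
  structure(list(tumour_id = tumour$id %||% NA_integer_,
                 best_treatment = rk$treatment[1],
                 best_regimen = rk$regimen[1], ranking = rk),
            class = "rht_ranked_outcome")
}

#' @export
print.rht_ranked_outcome <- function(x, ...) {
  cat(sprintf("tumour %s: best treatment %s (%s)\n", x$tumour_id,
              x$best_treatment, x$best_regimen %||% ""))
  if (nrow(x$ranking) > 0)
    print(utils::head(x$ranking[, c("treatment", "regimen",
                                    "combined_score")], 5))
  invisible(x)
}
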