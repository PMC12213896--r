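# Treatment schedules on the minute-resolution clock.
#
# t = 0 is Monday at the daily treatment time; a week is 10080 min and a
# day 1440 min. RT fractions (duration 10 min) repeat at the same time
# each day: 5/wk on Mon-Fri, 3/wk on Mon/Wed/Fri, 1/wk on Mon. One weekly
# HT fraction (60 min) is given on Mondays: immediately after the Monday
# RT fraction plus a 1-min gap when combined, at the Monday slot itself
# for HT alone. Maximum tolerated doses: 80 Gy total radiation and a
# cumulative thermal cap beta_tilde * N_wks <= 0.08.

WEEK_MIN <- 10080
DAY_MIN <- 1440
D_MAX_GY <- 80
BETA_MAX <- 0.08

new_schedule <- function(modality, D, N_frac, beta_tilde, N_wks,
                         delta_R = 10, delta_H = 60) {
  rt_windows <- matrix(numeric(0), 0, 2)
  ht_windows <- matrix(numeric(0), 0, 2)
  if (modality %in% c("RT", "RT_HT") && D > 0) {
    offsets <- switch(as.character(N_frac),
                      "5" = (0:4) * DAY_MIN,
                      "3" = c(0, 2, 4) * DAY_MIN,
                      "1" = 0,
                      stop("N_frac must be one of 1, 3, 5"))
    starts <- as.vector(outer(offsets, (seq_len(N_wks) - 1) * WEEK_MIN,
                              "+"))
    starts <- sort(starts)
    rt_windows <- cbind(starts, starts + delta_R)
  }
  if (modality %in% c("HT", "RT_HT") && beta_tilde > 0) {
    base <- (seq_len(N_wks) - 1) * WEEK_MIN
    t_H <- if (modality == "RT_HT") base + delta_R + 1 else base
    ht_windows <- cbind(t_H, t_H + delta_H)
  }
  colnames(rt_windows) <- colnames(ht_windows) <- c("start", "end")
  structure(list(modality = modality, D = D, N_frac = N_frac,
                 delta_R = delta_R, beta_tilde = beta_tilde,
                 delta_H = delta_H, N_wks = N_wks,
                 rt_windows = rt_windows, ht_windows = ht_windows,
                 t_end = N_wks * WEEK_MIN),
            class = "rht_schedule")
}

#' @export
print.rht_schedule <- function(x, ...) {
  cat(sprintf("%s schedule: %s over %d week(s), t_end = %g min\n",
              x$modality, schedule_descriptor(x), x$N_wks, x$t_end))
  if (nrow(x$rt_windows) > 0)
    cat(sprintf("  RT: %d fractions of %g Gy (total %g Gy)\n",
                nrow(x$rt_windows), x$D, total_rt_dose(x)))
  if (nrow(x$ht_windows) > 0)
    cat(sprintf("  HT: %d weekly fractions, beta = %g (total %g)\n",
                nrow(x$ht_windows), x$beta_tilde,
                x$beta_tilde * x$N_wks))
  invisible(x)
}

# weeks minimising |D * N_frac * w - 80|, ties towards fewer weeks
mtd_weeks <- function(D, N_frac, D_max = D_MAX_GY) {
  w <- 1:400
  which.min(abs(D * N_frac * w - D_max))
}

#' Total administered radiation dose of a schedule (Gy)
#' @param schedule an `rht_schedule`.
#' @export
total_rt_dose <- function(schedule) {
  schedule$D * schedule$N_frac * schedule$N_wks
}

#' Build a radiotherapy-only schedule
#'
#' Weekly pattern of `N_frac` fractions of `D` Gy (10-min fractions,
#' Monday-anchored); the number of weeks is the positive integer that
#' brings the total dose closest to the 80 Gy maximum tolerated dose,
#' ties broken towards fewer weeks.
#'
#' @param D fraction dose in Gy, integer 1..5 (0 gives the null schedule).
#' @param N_frac weekly fractions: 1, 3 or 5.
#' @return an `rht_schedule`.
#' @export
#' @examples
#' build_rt_schedule(2, 5)$N_wks   # 8 -> 40 x 2 Gy = 80 Gy
build_rt_schedule <- function(D, N_frac) {
  if (!D %in% 0:5) stop("D must be an integer dose in 0..5 Gy")
  if (D == 0) return(null_schedule())
  if (!N_frac %in% c(1, 3, 5)) stop("N_frac must be one of 1, 3, 5")
  new_schedule("RT", D, N_frac, beta_tilde = 0,
               N_wks = mtd_weeks(D, N_frac))
}

#' Build a hyperthermia-only schedule
#'
#' One 60-min HT fraction per week at damage rate `beta_tilde`, subject to
#' the cumulative thermal cap `beta_tilde * N_wks <= 0.08`.
#'
#' @param beta_tilde HT damage rate per fraction (study grid
#'   0.001..0.01).
#' @param N_wks number of treatment weeks.
#' @return an `rht_schedule`.
#' @export
#' @examples
#' build_ht_schedule(0.001, 80)$t_end  # 80 weeks within the cap
build_ht_schedule <- function(beta_tilde, N_wks) {
  stopifnot(beta_tilde >= 0, N_wks >= 1, N_wks == round(N_wks))
  total <- beta_tilde * N_wks
  if (total > BETA_MAX + 1e-12)
    stop(sprintf("HT MTD violation: beta_tilde * N_wks = %g > %g",
                 total, BETA_MAX))
  new_schedule("HT", D = 0, N_frac = 0, beta_tilde = beta_tilde,
               N_wks = N_wks)
}

#' Build a combined RT + HT schedule
#'
#' RT windows as in [build_rt_schedule()]; each Monday's HT fraction
#' starts one minute after that Monday's RT fraction ends
#' (`t_H = t_R + delta_R + 1`). The duration is inherited from the RT
#' maximum-tolerated-dose rule and the thermal cap is enforced.
#'
#' @inheritParams build_rt_schedule
#' @inheritParams build_ht_schedule
#' @return an `rht_schedule`.
#' @export
build_combined <- function(D, N_frac, beta_tilde) {
  if (!D %in% 1:5) stop("D must be an integer dose in 1..5 Gy")
  if (!N_frac %in% c(1, 3, 5)) stop("N_frac must be one of 1, 3, 5")
  N_wks <- mtd_weeks(D, N_frac)
  total <- beta_tilde * N_wks
  if (total > BETA_MAX + 1e-12)
    stop(sprintf("HT MTD violation: beta_tilde * N_wks = %g > %g",
                 total, BETA_MAX))
  new_schedule("RT_HT", D, N_frac, beta_tilde, N_wks)
}

#' Null (no-treatment) schedule
#' @param N_wks horizon in weeks.
#' @return an `rht_schedule` with no treatment windows.
#' @export
null_schedule <- function(N_wks = 8) {
  new_schedule("RT", D = 0, N_frac = 0, beta_tilde = 0, N_wks = N_wks)
}

#' Integration breakpoints of a schedule
#'
#' Sorted, de-duplicated window starts/ends plus 0 and `t_end`; the
#' integrator restarts at each so the forcing is constant within every
#' segment.
#'
#' @param schedule an `rht_schedule`.
#' @return increasing numeric vector.
#' @export
event_times <- function(schedule) {
  stopifnot(inherits(schedule, "rht_schedule"))
  tt <- c(0, schedule$t_end, as.vector(schedule$rt_windows),
          as.vector(schedule$ht_windows))
  sort(unique(tt[tt <= schedule$t_end]))
}

# resolve the piecewise-constant forcing: one row per segment with
# columns t0, t1, R, beta, ht_on (midpoint membership; windows closed)
schedule_segments <- function(schedule) {
  et <- event_times(schedule)
  t0 <- et[-length(et)]
  t1 <- et[-1]
  mid <- (t0 + t1) / 2
  R <- rt_dose_rate(mid, schedule)
  beta <- ht_damage_rate(mid, schedule)
  cbind(t0 = t0, t1 = t1, R = R, beta = beta,
        ht_on = as.numeric(beta > 0))
}

#' Short text descriptor of a schedule
#' @param schedule an `rht_schedule`.
#' @export
schedule_descriptor <- function(schedule) {
  switch(schedule$modality,
         RT = if (schedule$D == 0)
           sprintf("null/%dwk", schedule$N_wks)
         else sprintf("RT %gGyx%d/%dwk", schedule$D, schedule$N_frac,
                      schedule$N_wks),
         HT = sprintf("HT b%.3g/%dwk", schedule$beta_tilde,
                      schedule$N_wks),
         RT_HT = sprintf("RT %gGyx%d+HT b%.3g/%dwk", schedule$D,
                         schedule$N_frac, schedule$beta_tilde,
                         schedule$N_wks))
}

#' Export a resolved schedule to JSON for audit
#' @param schedule an `rht_schedule`.
#' @param path file path.
#' @export
write_schedule_json <- function(schedule, path) {
  x <- unclass(schedule)
  x$rt_windows <- unname(x$rt_windows)   # arrays of [start, end] rows
  x$ht_windows <- unname(x$ht_windows)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
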