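# Study orchestration: configuration, end-to-end runs, fixtures, CLI.

#' The six representative tumours
#'
#' Three nutrient-limited tumours A1--C1 (vascular volume 0.0005) and
#' three space-limited tumours A2--C2 (vascular volume 0.005) spanning
#' the `(q3, q1)` sampling boxes, with regimes verified and baseline
#' steady states resolved.
#'
#' @return an `rht_cohort`-like data.frame with an extra `label` column.
#' @export
#' @examples
#' representative_tumours()[, c("label", "regime", "q3", "q1")]
representative_tumours <- function() {
  df <- data.frame(
    id = 1:6,
    label = c("A1", "B1", "C1", "A2", "B2", "C2"),
    q3 = c(0.272, 0.0401, 9.94, 0.210, 0.143, 7.61),
    q1 = c(0.503, 7.78, 7.60, 0.151, 2.14, 2.14),
    V0 = c(rep(0.0005, 3), rep(0.005, 3)))
  params <- model_params()
  df$regime <- mapply(classify_regime, df$q1, df$q3, df$V0,
                      MoreArgs = list(params = params))
  fp <- lapply(seq_len(6), function(i) {
    if (df$regime[i] == "SL")
      sl_fixed_point(df$q1[i], df$q3[i], df$V0[i], params)
    else nl_fixed_point(df$q1[i], df$q3[i], df$V0[i], params)
  })
  df$T_star <- vapply(fp, `[[`, numeric(1), "T_star")
  df$c_star <- vapply(fp, `[[`, numeric(1), "c_star")
  df
}

#' Run configuration
#'
#' @param regimes cohorts to generate.
#' @param N tumours per cohort.
#' @param seed root RNG seed (per-cohort seeds are derived by adding the
#'   regime index).
#' @param Ds,N_fracs,beta_tildes schedule grid (see [schedule_grid()]).
#' @param out_dir output directory.
#' @param rtol,atol,coarse_dt,fine_dt solver options.
#' @param include_nonnegative,rule2_both documented ambiguity switches
#'   (see [stratify_cohort()] and [best_treatment()]).
#' @param workers parallel workers across tumours (results are ordered by
#'   tumour id, so worker count never changes the output).
#' @return a list of class `rht_run_config`.
#' @export
run_config <- function(regimes = c("NL", "SL", "BS"), N = 50, seed = 1,
                       Ds = 2, N_fracs = 5, beta_tildes = 0.005,
                       out_dir = "thermorad_run", rtol = 1e-8,
                       atol = 1e-10, coarse_dt = 10, fine_dt = 1,
                       include_nonnegative = FALSE, rule2_both = FALSE,
                       workers = 1) {
  structure(list(regimes = regimes, N = N, seed = seed, Ds = Ds,
                 N_fracs = N_fracs, beta_tildes = beta_tildes,
                 out_dir = out_dir, rtol = rtol, atol = atol,
                 coarse_dt = coarse_dt, fine_dt = fine_dt,
                 include_nonnegative = include_nonnegative,
                 rule2_both = rule2_both, workers = workers),
            class = "rht_run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with any subset of the [run_config()] fields.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[names(raw) %in% names(formals(run_config))])
}

.apply_tumours <- function(cohort, fn, workers) {
  idx <- seq_len(nrow(cohort))
  res <- if (workers > 1) {
    parallel::mclapply(idx, fn, mc.cores = workers)
  } else {
    lapply(idx, fn)
  }
  res[order(cohort$id)]
}

#' Run a full virtual trial
#'
#' Samples the configured cohorts, simulates every tumour under every
#' matched schedule pair of the grid and all three treatments, computes
#' response metrics, five-class stratification (per cohort and schedule
#' pair), deleterious flags, per-pair winners and per-tumour regimen
#' rankings, and writes cohort/response/comparison CSVs, ranked-outcome
#' JSON and a manifest to `config$out_dir`. A tumour whose integration
#' fails is logged in the manifest and excluded rather than aborting the
#' study.
#'
#' @param config an [run_config()] object.
#' @return invisibly, a list with the assembled data.frames and the paths
#'   written.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "rht_run_config"))
  params <- model_params()
  opts <- solver_options(config$rtol, config$atol, config$coarse_dt,
                         config$fine_dt)
  grid <- schedule_grid(config$Ds, config$N_fracs, config$beta_tildes)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  all_resp <- list(); all_comp <- list(); ranked <- list()
  failures <- list(); cohort_paths <- character(0)
  thresholds <- list()
  for (ri in seq_along(config$regimes)) {
    regime <- config$regimes[ri]
    cohort <- sample_cohort(regime, config$N, config$seed + ri - 1,
                            params)
    cpath <- file.path(config$out_dir,
                       sprintf("cohort_%s.csv", regime))
    write_cohort_csv(cohort, cpath)
    cohort_paths <- c(cohort_paths, cpath)
    thresholds[[regime]] <- list(V0 = attr(cohort, "V0"),
                                 q1_bar = attr(cohort, "q1_bar"))
    per_tumour <- .apply_tumours(cohort, function(i) {
      tum <- cohort[i, ]
      tryCatch({
        rows <- list(); comps <- list()
        for (gi in seq_len(nrow(grid))) {
          tri <- compare_treatments(tum, grid$D[gi], grid$N_frac[gi],
                                    grid$beta_tilde[gi], params, opts,
                                    config$rule2_both)
          for (tr in c("rt", "ht", "combo")) {
            s <- tri[[tr]]
            rows[[length(rows) + 1]] <- data.frame(
              id = tum$id, regime = regime, treatment = s$treatment,
              D = grid$D[gi], N_frac = grid$N_frac[gi],
              beta_tilde = grid$beta_tilde[gi], N_wks = grid$N_wks[gi],
              delta_viable = s$delta_viable, delta_total = s$delta_total,
              delta_V = s$delta_V, delta_c = s$delta_c,
              combined_score = s$combined_score,
              deleterious = is_deleterious(s))
          }
          comps[[length(comps) + 1]] <- data.frame(
            id = tum$id, regime = regime,
            rt_schedule = tri$schedule_pair[["rt"]],
            ht_schedule = tri$schedule_pair[["ht"]],
            score_R = tri$rt$combined_score,
            score_H = tri$ht$combined_score,
            score_RH = tri$combo$combined_score, winner = tri$winner)
        }
        rk <- rank_regimens(tum, grid, params, opts, config$rule2_both)
        list(resp = do.call(rbind, rows), comp = do.call(rbind, comps),
             rank = rk, error = NULL)
      }, error = function(e)
        list(resp = NULL, comp = NULL, rank = NULL,
             error = sprintf("tumour %d (%s): %s", tum$id, regime,
                             conditionMessage(e))))
    }, config$workers)
    for (pt in per_tumour) {
      if (!is.null(pt$error)) {
        failures[[length(failures) + 1]] <- pt$error
        next
      }
      all_resp[[length(all_resp) + 1]] <- pt$resp
      all_comp[[length(all_comp) + 1]] <- pt$comp
      ranked[[length(ranked) + 1]] <- list(
        tumour_id = pt$rank$tumour_id, regime = regime,
        best_treatment = pt$rank$best_treatment,
        best_regimen = pt$rank$best_regimen)
    }
  }
  resp <- do.call(rbind, all_resp)
  comp <- do.call(rbind, all_comp)
  # five-class stratification per (cohort, schedule, treatment)
  resp$response_class <- NA_character_
  for (key in split(seq_len(nrow(resp)),
                    interaction(resp$regime, resp$treatment, resp$D,
                                resp$N_frac, resp$beta_tilde,
                                drop = TRUE))) {
    resp$response_class[key] <- as.character(
      stratify_cohort(resp$combined_score[key],
                      config$include_nonnegative))
  }
  rpath <- file.path(config$out_dir, "responses.csv")
  utils::write.csv(resp, rpath, row.names = FALSE)
  cpath2 <- file.path(config$out_dir, "comparisons.csv")
  utils::write.csv(comp, cpath2, row.names = FALSE)
  jpath <- file.path(config$out_dir, "ranked_outcomes.json")
  jsonlite::write_json(ranked, jpath, auto_unbox = TRUE, digits = NA)
  manifest <- list(config = unclass(config), thresholds = thresholds,
                   t_end_by_pair = stats::setNames(
                     as.list(grid$N_wks * WEEK_MIN),
                     sprintf("D%g_Nf%g_b%g", grid$D, grid$N_frac,
                             grid$beta_tilde)),
                   failures = unlist(failures),
                   package_version = as.character(
                     utils::packageVersion("thermorad")))
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(list(responses = resp, comparisons = comp, ranked = ranked,
                 paths = c(cohort_paths, rpath, cpath2, jpath, mpath)))
}

#' Score-distribution and parameter-map plots
#'
#' `plot_scores` draws per-cohort boxplots of a response metric;
#' `plot_qmap` draws the `(q3, q1)` scatter coloured by a discrete label
#' (response class or best treatment), on log10 axes as in the cohort
#' sampling boxes.
#'
#' @param resp a responses data.frame from [run_study()].
#' @param metric column to plot.
#' @export
plot_scores <- function(resp, metric = "combined_score") {
  graphics::boxplot(resp[[metric]] ~ resp$regime,
                    xlab = "cohort", ylab = metric, col = "grey85")
  graphics::abline(h = 0, lty = 2)
  invisible(NULL)
}

#' @rdname plot_scores
#' @param df data.frame with `q1`, `q3` and the label column.
#' @param label name of the discrete label column.
#' @export
plot_qmap <- function(df, label = "response_class") {
  lab <- factor(df[[label]])
  graphics::plot(log10(df$q3), log10(df$q1), col = as.integer(lab),
                 pch = 19, xlab = "log10 q3", ylab = "log10 q1")
  graphics::legend("topright", legend = levels(lab),
                   col = seq_along(levels(lab)), pch = 19, cex = 0.8)
  invisible(NULL)
}

#' Command-line entry point
#'
#' Subcommands: `cohort`, `simulate`, `sweep`, `compare`, `study`,
#' `thresholds`. Run `thermorad_main(c("help"))` for usage. Installed as
#' the `thermorad` executable under `exec/`.
#'
#' @param args character vector of CLI arguments.
#' @return exit status, invisibly.
#' @export
thermorad_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: thermorad <command> [options]",
    "  cohort --regime NL|SL|BS --n N --seed S --out FILE.csv",
    "  simulate --regime R --tumour I --seed S --modality RT|HT|RT_HT",
    "           --dose D --nfrac K --beta B --out FILE.csv",
    "  sweep|study --config FILE.json",
    "  compare --config FILE.json   (alias of study)",
    "  thresholds --v0 V [--q1 Q]",
    sep = "\n")
  if (length(args) == 0 || args[1] %in% c("help", "--help", "-h")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  switch(cmd,
    cohort = {
      co <- sample_cohort(opt("regime", "SL"),
                          as.integer(opt("n", "250")),
                          as.integer(opt("seed", "1")))
      write_cohort_csv(co, opt("out", "cohort.csv"))
      cat("wrote", opt("out", "cohort.csv"), "\n")
    },
    simulate = {
      co <- sample_cohort(opt("regime", "SL"),
                          as.integer(opt("n", "250")),
                          as.integer(opt("seed", "1")))
      tum <- co[as.integer(opt("tumour", "1")), ]
      mod <- opt("modality", "RT")
      sch <- switch(mod,
        RT = build_rt_schedule(as.numeric(opt("dose", "2")),
                               as.numeric(opt("nfrac", "5"))),
        HT = build_ht_schedule(as.numeric(opt("beta", "0.005")),
                               as.integer(opt("nwks", "8"))),
        RT_HT = build_combined(as.numeric(opt("dose", "2")),
                               as.numeric(opt("nfrac", "5")),
                               as.numeric(opt("beta", "0.005"))))
      tr <- simulate_tumour(tum, sch)
      utils::write.csv(as.data.frame(tr), opt("out", "trajectory.csv"),
                       row.names = FALSE)
      cat("wrote", opt("out", "trajectory.csv"), "\n")
    },
    sweep = ,
    compare = ,
    study = {
      cfgfile <- opt("config")
      cfg <- if (is.null(cfgfile)) run_config() else
        read_run_config(cfgfile)
      run_study(cfg)
      cat("study written to", cfg$out_dir, "\n")
    },
    thresholds = {
      V0 <- as.numeric(opt("v0", "0.005"))
      q1b <- q1_threshold(V0)
      cat(sprintf("q1_bar(V0=%g) = %.6f\n", V0, q1b))
      q1 <- opt("q1")
      if (!is.null(q1))
        cat(sprintf("q3_bar(V0=%g, q1=%s) = %.6f\n", V0, q1,
                    q3_threshold(V0, as.numeric(q1))))
    },
    {
      cat("unknown command: ", cmd, "\n", usage, "\n", sep = "")
      return(invisible(1L))
    })
  invisible(0L)
}
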