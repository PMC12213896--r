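# Virtual tumour cohorts: the synthetic-data generator of the pipeline.
#
# A virtual tumour is a triple (q3, q1, V0) plus its untreated steady
# state; a cohort is N such tumours sampled from the regime-specific
# uniform boxes, with the cohort-specific vascular volume fixed.

.cohort_V0 <- c(NL = 0.0005, SL = 0.005, BS = 0.00275)

# independent L'Ecuyer-CMRG sub-streams, one per tumour id, so cohorts are
# extensible without reshuffling earlier draws
.substreams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

.with_stream <- function(stream, expr) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  assign(".Random.seed", stream, envir = globalenv())
  expr
}

#' Sample a seeded virtual tumour cohort
#'
#' Draws `N` tumours from the regime-specific uniform boxes. The vascular
#' volume is fixed per regime (NL 0.0005, SL 0.005, BS 0.00275). `q1` is
#' drawn first; for SL and BS cohorts the `q3` box is then conditioned on
#' the tumour's own `q3_bar(q1)` threshold. Each draw is verified with
#' [classify_regime()] and resampled on mismatch (numeric thresholds make
#' rare boundary misclassifications possible); a rejection rate above 20%
#' aborts, as it signals a faulty threshold computation. Each tumour's
#' untreated steady state is resolved on the branch the cohort occupies
#' (NL branch for NL and BS tumours, SL branch for SL tumours).
#'
#' @param regime `"NL"`, `"SL"` or `"BS"`.
#' @param N cohort size (the study uses 250).
#' @param seed integer root seed; tumour `i` uses the `i`-th L'Ecuyer
#'   sub-stream of this seed, independent of `N`.
#' @param params an `rht_params` (cohort-level constants; `q1`, `q3`
#'   are overridden per tumour).
#' @return an object of class `rht_cohort`: a data.frame with columns
#'   `id, regime, q1, q3, V0, T_star, c_star` and attributes `regime`,
#'   `seed`, `N`, `V0`, `q1_bar`, `n_reject`.
#' @export
#' @examples
#' co <- sample_cohort("SL", N = 5, seed = 1)
#' co$T_star  # all 0.995
sample_cohort <- function(regime = c("NL", "SL", "BS"), N = 250, seed,
                          params = model_params()) {
  regime <- match.arg(regime)
  stopifnot(N >= 1, is.numeric(seed))
  V0 <- .cohort_V0[[regime]]
  q1_bar <- q1_threshold(V0, params)
  streams <- .substreams(seed, N)
  n_reject <- 0L
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    draw <- .with_stream(streams[[i]], {
      ok <- FALSE; tries <- 0L
      q1 <- q3 <- NA_real_
      while (!ok) {
        tries <- tries + 1L
        if (tries > 50L) stop("rejection sampling failed to converge")
        q1 <- switch(regime,
                     NL = stats::runif(1, q1_bar, 10),
                     stats::runif(1, 0.01, q1_bar))
        # for small q1 the bistability boundary q3_bar can exceed the
        # q3 sampling box [0.01, 10]; the SL box is then the whole range
        # and a BS draw at that q1 is impossible (pair is rejected)
        q3bar <- if (regime == "NL") NA_real_ else
          tryCatch(q3_threshold(V0, q1, params),
                   error = function(e) Inf)
        q3 <- switch(regime,
                     NL = stats::runif(1, 0.01, 10),
                     SL = stats::runif(1, 0.01, min(q3bar, 10)),
                     BS = if (q3bar >= 10) NaN
                          else stats::runif(1, q3bar, 10))
        ok <- is.finite(q3) &&
          identical(classify_regime(q1, q3, V0, params), regime)
      }
      list(q1 = q1, q3 = q3, rejects = tries - 1L)
    })
    n_reject <- n_reject + draw$rejects
    fp <- switch(regime,
                 SL = sl_fixed_point(draw$q1, draw$q3, V0, params),
                 nl_fixed_point(draw$q1, draw$q3, V0, params))
    if (is.null(fp)) stop("fixed point unresolved for sampled tumour ", i)
    rows[[i]] <- data.frame(id = i, regime = regime, q1 = draw$q1,
                            q3 = draw$q3, V0 = V0, T_star = fp$T_star,
                            c_star = fp$c_star)
  }
  if (n_reject / (N + n_reject) > 0.2)
    stop("cohort rejection rate exceeds 20%: threshold computation fault?")
  co <- do.call(rbind, rows)
  structure(co, class = c("rht_cohort", "data.frame"), regime = regime,
            seed = seed, N = N, V0 = V0, q1_bar = q1_bar,
            n_reject = n_reject)
}

#' Pre-treatment baseline state of a virtual tumour
#'
#' The augmented seven-component state at the untreated steady state:
#' `(T*, 0, 0, 0, V0, c*, 0)`. Bistable tumours sit on their
#' nutrient-limited branch at treatment start.
#'
#' @param tumour a one-row slice of an `rht_cohort` (or any list with
#'   `T_star`, `V0`, `c_star`).
#' @return named numeric state vector of length 7.
#' @export
baseline_state <- function(tumour) {
  stats::setNames(c(tumour$T_star, 0, 0, 0, tumour$V0, tumour$c_star, 0),
                  state_names)
}

#' Write / read a cohort as CSV plus a JSON manifest
#'
#' The CSV holds one row per tumour (`id, regime, q1, q3, V0, T_star,
#' c_star`); the manifest records the seed, size, vascular volume and
#' `q1_bar` threshold so a cohort file is self-describing.
#'
#' @param cohort an `rht_cohort`.
#' @param path CSV path; the manifest is written alongside with extension
#'   `.manifest.json`.
#' @return `read_cohort_csv` returns an `rht_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "rht_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  manifest <- list(regime = attr(cohort, "regime"),
                   seed = attr(cohort, "seed"), N = attr(cohort, "N"),
                   V0 = attr(cohort, "V0"),
                   q1_bar = attr(cohort, "q1_bar"),
                   n_reject = attr(cohort, "n_reject"),
                   package_version = as.character(
                     utils::packageVersion("thermorad")))
  jsonlite::write_json(manifest, sub("\\.csv$", ".manifest.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mpath <- sub("\\.csv$", ".manifest.json", path)
  m <- if (file.exists(mpath)) jsonlite::read_json(mpath,
                                                   simplifyVector = TRUE)
       else list()
  structure(df, class = c("rht_cohort", "data.frame"),
            regime = m$regime %||% df$regime[1], seed = m$seed,
            N = m$N %||% nrow(df), V0 = m$V0 %||% df$V0[1],
            q1_bar = m$q1_bar, n_reject = m$n_reject)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
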