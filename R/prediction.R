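#' Personalized relapse prediction for one patient
#'
#' Simulates `n_rep` in-silico replicates of a patient with the given
#' covariate values: each replicate draws a diagnosis volume from a
#' log-normal around the nominal volume (median = nominal, coefficient of
#' variation `vdiag_cv`) and fresh random effects on `alpha` and `mu`,
#' then computes its time to relapse. The replicate TTRs yield the
#' personalized DMFS curve, the predicted TTR (the median replicate TTR),
#' the probability of metastasis at diagnosis (fraction of replicates
#' with TTR at or below 0) and the probability of being metastasis-free
#' at 5 years (fraction with TTR above 60 months; never-relapse
#' replicates count as metastasis-free).
#'
#' @param pop a fitted [population_params()] (covariate effects included).
#' @param covariates one-row data frame of covariate values on the
#'   standardized scale the effects were fitted on.
#' @param vdiag_cells nominal primary tumor volume at diagnosis, cells.
#' @param n_rep number of replicates. Default 10000.
#' @param vdiag_cv coefficient of variation of the log-normal diagnosis
#'   volume. Default 0.2; set 0 for a fixed volume.
#' @param seed integer seed (draws are local and reproducible).
#' @param times DMFS evaluation grid, months.
#' @return an object of class `prediction_result`: list with
#'   `ttr_samples` (months), `predicted_ttr` (months), `p_met_at_diagnosis`,
#'   `p_met_free_5y` and `dmfs` (a `dmfs_curve` tibble). Supports
#'   [glance()] and [autoplot()].
#' @export
personalized_prediction <- function(pop, covariates = tibble(.rows = 1),
                                    vdiag_cells = 2e10, n_rep = 10000,
                                    vdiag_cv = 0.2, seed = 1,
                                    times = seq(0, 120, by = 1)) {
  stopifnot(inherits(pop, "population_params"), n_rep >= 1)
  covariates <- as_tibble(covariates)
  if (nrow(covariates) != 1L) abort("`covariates` must have exactly one row.")
  sdlog <- sqrt(log(1 + vdiag_cv^2))
  sim <- withr::with_seed(seed, {
    vd <- if (sdlog > 0) rlnorm(n_rep, log(vdiag_cells), sdlog)
          else rep(vdiag_cells, n_rep)
    cov_rep <- covariates[rep(1L, n_rep), , drop = FALSE]
    simulate_cohort_ttr(pop, cov_rep, vd)
  })
  ttr <- sim$ttr_months
  dmfs <- tibble(time = times,
                 survival = vapply(times, function(tt) mean(ttr > tt),
                                   numeric(1)))
  class(dmfs) <- c("dmfs_curve", class(dmfs))
  attr(dmfs, "n_sim") <- n_rep
  attr(dmfs, "conditioning") <- "all"
  structure(
    list(
      ttr_samples = ttr,
      predicted_ttr = median(ttr),
      p_met_at_diagnosis = mean(ttr <= 0),
      p_met_free_5y = mean(ttr > 60),
      dmfs = dmfs,
      n_rep = n_rep, seed = seed
    ),
    class = "prediction_result"
  )
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("<prediction_result>\n")
  cat(sprintf("  predicted TTR (median of %d replicates): %.1f months\n",
              x$n_rep, x$predicted_ttr))
  cat(sprintf("  P(metastasis at diagnosis): %.3f\n", x$p_met_at_diagnosis))
  cat(sprintf("  P(metastasis-free at 5 years): %.3f\n", x$p_met_free_5y))
  invisible(x)
}

#' @rdname personalized_prediction
#' @param x a `prediction_result`.
#' @param ... unused.
#' @export
glance.prediction_result <- function(x, ...) {
  tibble(predicted_ttr = x$predicted_ttr,
         p_met_at_diagnosis = x$p_met_at_diagnosis,
         p_met_free_5y = x$p_met_free_5y, n_rep = x$n_rep)
}

#' Predicted time to relapse for every patient of a cohort
#'
#' Vectorized cohort version of [personalized_prediction()]: for each row
#' of `data`, simulates `n_rep` replicates (fresh random effects and a
#' log-normal diagnosis volume around the patient's nominal volume) and
#' records the median replicate TTR as the patient's predicted TTR. The
#' predicted TTR is the natural mechanistic score for concordance
#' benchmarking against Cox regression: larger = later predicted relapse.
#'
#' @param pop a fitted [population_params()].
#' @param data data frame with the covariate columns named by the
#'   effects in `pop` (standardized scale) and optionally `vdiag_cells`.
#' @param vdiag_cells default nominal diagnosis volume for patients
#'   without their own, cells.
#' @param n_rep replicates per patient. Default 1000.
#' @param vdiag_cv coefficient of variation of the diagnosis volume.
#' @param seed integer seed.
#' @return `data` with a `predicted_ttr` column (months; `Inf` = predicted
#'   never to relapse).
#' @export
predict_cohort_ttr <- function(pop, data, vdiag_cells = 2e10, n_rep = 1000,
                               vdiag_cv = 0.2, seed = 1) {
  stopifnot(inherits(pop, "population_params"))
  data <- as_tibble(data)
  n <- nrow(data)
  nominal <- if ("vdiag_cells" %in% names(data)) data$vdiag_cells
             else rep(vdiag_cells, n)
  idx <- rep(seq_len(n), each = n_rep)
  sdlog <- sqrt(log(1 + vdiag_cv^2))
  cov_cols <- unique(vapply(pop$effects, function(e) e$covariate,
                            character(1)))
  sim <- withr::with_seed(seed, {
    vd <- rlnorm(length(idx), log(nominal[idx]), sdlog)
    simulate_cohort_ttr(pop, data[idx, cov_cols, drop = FALSE], vd)
  })
  med <- tapply(sim$ttr_months, idx, median)
  data$predicted_ttr <- as.numeric(med[as.character(seq_len(n))])
  data
}

#' Harrell's concordance index for right-censored data
#'
#' Fraction of comparable patient pairs in which the predicted ordering
#' matches the observed ordering. A pair is comparable iff the observed
#' times differ and the patient with the smaller observed time had an
#' event. A pair is concordant when that patient also has the smaller
#' predicted score (scores are oriented so that larger = later relapse);
#' score ties count 0.5. With no comparable pairs the index is 0.5 by
#' convention (with a warning). Infinite scores (never-relapse
#' predictions) are allowed and compare as the largest values.
#'
#' @param data data frame with the score and outcome columns.
#' @param score,time,event unquoted column names (defaults `score`,
#'   `time`, `event`): predicted score (larger = later relapse), observed
#'   follow-up time, and event indicator (1 = relapse observed).
#' @return an object of class `concordance_result`: list with `c_index`
#'   and `n_comparable_pairs` (and bootstrap bounds `ci_low`/`ci_high`
#'   when filled in by [cox_benchmark()] or a bootstrap). Supports
#'   [glance()].
#' @export
#' @examples
#' d <- tibble::tibble(score = c(3, 1, 2), time = c(30, 10, 20),
#'                     event = c(0, 1, 1))
#' harrell_c_index(d)
harrell_c_index <- function(data, score = score, time = time, event = event) {
  data <- as_tibble(data)
  s <- dplyr::pull(data, {{ score }})
  tt <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  n <- length(s)
  if (n < 2) abort("need at least 2 patients.")
  num <- 0; n_comp <- 0
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    # comparable: distinct times, event at the earlier time
    earlier_i <- tt[i] < tt[j] & ev[i] == 1
    earlier_j <- tt[j] < tt[i] & ev[j] == 1
    comp <- earlier_i | earlier_j
    if (!any(comp)) next
    si <- s[i]; sj <- s[j]
    conc <- (earlier_i & si < sj) | (earlier_j & sj < si)
    ties <- comp & si == sj
    num <- num + sum(conc[comp]) + 0.5 * sum(ties[comp])
    n_comp <- n_comp + sum(comp)
  }
  if (n_comp == 0) {
    warn("no comparable pairs; returning c_index = 0.5.")
    ci <- 0.5
  } else ci <- num / n_comp
  structure(list(c_index = ci, n_comparable_pairs = n_comp,
                 ci_low = NA_real_, ci_high = NA_real_),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> C-index = %.4f (%d comparable pairs)",
              x$c_index, x$n_comparable_pairs))
  if (!is.na(x$ci_low))
    cat(sprintf("  95%% CI [%.4f, %.4f]", x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' @rdname harrell_c_index
#' @param x a `concordance_result`.
#' @param ... unused.
#' @export
glance.concordance_result <- function(x, ...) {
  tibble(c_index = x$c_index, n_comparable_pairs = x$n_comparable_pairs,
         ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Bootstrap percentile confidence interval for a data-table statistic
#'
#' Resamples the rows of `data` with replacement `n_boot` times,
#' recomputes `statistic` on each resample and returns the empirical
#' percentile interval. Resamples on which the statistic fails are
#' skipped and counted.
#'
#' @param data a data frame.
#' @param statistic function(data) returning a single number.
#' @param n_boot number of bootstrap resamples. Default 100.
#' @param level confidence level. Default 0.95.
#' @param seed integer seed (local, reproducible).
#' @return tibble with `low`, `high`, `n_boot_used`, `n_failed`.
#' @export
bootstrap_percentile_ci <- function(data, statistic, n_boot = 100,
                                    level = 0.95, seed = 1) {
  data <- as_tibble(data)
  n <- nrow(data)
  vals <- withr::with_seed(seed, {
    purrr::map_dbl(seq_len(n_boot), function(b) {
      rows <- sample.int(n, n, replace = TRUE)
      tryCatch(statistic(data[rows, , drop = FALSE]),
               error = function(e) NA_real_)
    })
  })
  failed <- sum(is.na(vals))
  if (failed > 0)
    warn(sprintf("%d of %d bootstrap resamples failed and were skipped.",
                 failed, n_boot))
  ok <- vals[!is.na(vals)]
  a <- (1 - level) / 2
  q <- quantile(ok, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  tibble(low = q[1], high = q[2], n_boot_used = length(ok), n_failed = failed)
}

#' Cox proportional-hazards benchmark for relapse prediction
#'
#' Fits a multivariable Cox model on the listed covariates and scores
#' patients by the negated linear predictor (so larger = later relapse,
#' mirroring the mechanistic predicted-TTR score), then evaluates
#' Harrell's C-index of that score, optionally with a bootstrap
#' percentile confidence interval (the whole fit + scoring pipeline is
#' re-run on each resample).
#'
#' @param data data frame with `time` (months), `event` (0/1) and the
#'   covariate columns.
#' @param covariates character vector of covariate column names.
#' @param n_boot bootstrap resamples for the CI; 0 to skip.
#' @param seed integer seed for the bootstrap.
#' @return a `concordance_result` (with CI bounds when `n_boot > 0`).
#' @export
cox_benchmark <- function(data, covariates, n_boot = 100, seed = 1) {
  data <- as_tibble(data)
  if (length(covariates) < 1) abort("need at least one covariate.")
  if (!all(covariates %in% names(data)))
    abort("missing covariate columns in `data`.")
  if (sum(data$event) < 1) abort("no events in `data`.")
  score_fun <- function(d) {
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~", paste(covariates, collapse = " + ")))
    fit <- survival::coxph(fml, data = d)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      abort(sprintf("singular design; collinear column(s): %s",
                    paste(bad, collapse = ", ")))
    }
    -unname(stats::predict(fit, type = "lp"))
  }
  d <- dplyr::mutate(data, score = score_fun(data))
  res <- harrell_c_index(d)
  if (n_boot > 0) {
    ci <- bootstrap_percentile_ci(
      data,
      function(dd) {
        dd$score <- score_fun(dd)
        harrell_c_index(dd)$c_index
      },
      n_boot = n_boot, seed = seed
    )
    res$ci_low <- ci$low
    res$ci_high <- ci$high
  }
  res
}
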