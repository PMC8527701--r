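#' Covariate effect on a model parameter
#'
#' Describes how one clinical covariate (e.g. complement factor B (CFB),
#' serum amyloid A2 (SAA2) or Fuhrman grade) shifts the log of a model
#' parameter. The shift can act on the growth rate `alpha`
#' (`placement = "growth"`), on the dissemination rate `mu`
#' (`"dissemination"`), or on both. Three functional forms are available,
#' all on the log-parameter scale with the covariate standardized
#' (z-scored):
#' \describe{
#'   \item{linear}{`b * (value - c)`}
#'   \item{step}{`dif * 1[value < c]`}
#'   \item{linear_plus_step}{`b * max(0, value - c) + dif * 1[value < c]`}
#' }
#'
#' @param covariate name of the covariate column, e.g. `"CFB"`.
#' @param placement one of `"growth"`, `"dissemination"`, `"both"`.
#' @param form one of `"linear"`, `"step"`, `"linear_plus_step"`.
#' @param b slope per (standardized) covariate unit. Unused for `"step"`.
#' @param c threshold / centre, standardized covariate units.
#' @param dif step offset on the log-parameter scale. Unused for `"linear"`.
#' @return an object of class `covariate_effect`.
#' @export
#' @examples
#' eff <- covariate_effect("CFB", "dissemination", "linear_plus_step",
#'                         b = 1.04, c = 0.22, dif = -0.67)
#' covariate_shift(1.0, eff)
covariate_effect <- function(covariate,
                             placement = c("dissemination", "growth", "both"),
                             form = c("linear", "step", "linear_plus_step"),
                             b = 0, c = 0, dif = 0) {
  placement <- match.arg(placement)
  form <- match.arg(form)
  stopifnot(is.character(covariate), length(covariate) == 1L)
  structure(
    list(covariate = covariate, placement = placement, form = form,
         b = b, c = c, dif = dif),
    class = "covariate_effect"
  )
}

#' Evaluate a covariate effect
#'
#' Returns the shift a covariate value induces on the log-parameter
#' scale; multiply the parameter by `exp(shift)`.
#'
#' @param value covariate value(s), standardized units (vectorized).
#' @param eff a [covariate_effect()].
#' @return numeric vector of log-scale shifts.
#' @export
covariate_shift <- function(value, eff) {
  stopifnot(inherits(eff, "covariate_effect"))
  if (any(!is.finite(value))) abort("covariate values must be finite.")
  switch(eff$form,
    linear = eff$b * (value - eff$c),
    step = eff$dif * as.numeric(value < eff$c),
    linear_plus_step = eff$b * pmax(0, value - eff$c) +
      eff$dif * as.numeric(value < eff$c),
    abort(sprintf("unknown effect form '%s'", eff$form))
  )
}

#' Population-level model parameters
#'
#' Log-normal population distributions for the Gompertz growth rate
#' `alpha` and the dissemination rate `mu`:
#' `log(alpha_i) = log(alpha_pop) + growth shifts + eta_alpha`,
#' `eta_alpha ~ N(0, omega_alpha^2)`, and analogously for `mu`. `beta` is
#' tied to the shared carrying capacity `K` via `beta = alpha / log(K)`.
#'
#' @param alpha_pop population growth rate, 1/day.
#' @param mu_pop population dissemination rate, per cell per day.
#' @param omega_alpha sd of `log(alpha)` across patients (dimensionless).
#' @param omega_mu sd of `log(mu)` across patients (dimensionless).
#' @param effects list of [covariate_effect()] objects (possibly empty).
#' @param K shared carrying capacity, cells.
#' @param V0 seeded lesion size, cells.
#' @param V_vis visibility threshold, cells.
#' @return an object of class `population_params`.
#' @export
population_params <- function(alpha_pop, mu_pop, omega_alpha = 0,
                              omega_mu = 0, effects = list(), K = 1e12,
                              V0 = 1, V_vis = diameter_to_cells(5)) {
  if (alpha_pop <= 0 || mu_pop < 0)
    abort("`alpha_pop` must be positive and `mu_pop` non-negative.")
  if (omega_alpha < 0 || omega_mu < 0)
    abort("`omega_alpha` and `omega_mu` must be non-negative.")
  if (inherits(effects, "covariate_effect")) effects <- list(effects)
  if (!all(vapply(effects, inherits, logical(1), "covariate_effect")))
    abort("`effects` must be a list of covariate_effect objects.")
  structure(
    list(alpha_pop = alpha_pop, mu_pop = mu_pop,
         omega_alpha = omega_alpha, omega_mu = omega_mu,
         effects = effects, K = K, V0 = V0, V_vis = V_vis),
    class = "population_params"
  )
}

#' @export
print.population_params <- function(x, ...) {
  cat("<population_params>\n")
  cat(sprintf("  alpha_pop: %.4g /day (omega %.3g)   mu_pop: %.4g /cell/day (omega %.3g)\n",
              x$alpha_pop, x$omega_alpha, x$mu_pop, x$omega_mu))
  cat(sprintf("  K: %.3g cells   V0: %.3g   V_vis: %.4g\n", x$K, x$V0, x$V_vis))
  if (length(x$effects)) {
    for (e in x$effects)
      cat(sprintf("  effect: %s -> %s (%s; b=%.3g c=%.3g dif=%.3g)\n",
                  e$covariate, e$placement, e$form, e$b, e$c, e$dif))
  } else cat("  no covariate effects\n")
  invisible(x)
}

# Sum of covariate shifts placed on one parameter for a covariate table.
# `covariates` is a data frame whose columns are standardized values.
placed_shifts <- function(covariates, effects, where) {
  shift <- numeric(nrow(covariates))
  for (e in effects) {
    if (e$placement %in% c(where, "both")) {
      if (!e$covariate %in% names(covariates))
        abort(sprintf("covariate '%s' required by an effect is missing.",
                      e$covariate))
      shift <- shift + covariate_shift(covariates[[e$covariate]], e)
    }
  }
  shift
}

#' Draw individual patient parameters from the population model
#'
#' For each row of `covariates`, realizes
#' `log(alpha) = log(alpha_pop) + growth shifts + eta_alpha` and
#' `log(mu) = log(mu_pop) + dissemination shifts + eta_mu` with
#' independent normal random effects. Covariate columns are expected on
#' the standardized scale used when the effects were defined.
#'
#' @param pop a [population_params()] object.
#' @param covariates data frame of covariate values, one row per patient
#'   (may have zero columns when no effects are present).
#' @param seed optional integer; when given, draws are made in a local,
#'   restored RNG state so the call is reproducible and side-effect free.
#' @return a tibble with columns `alpha`, `mu`, `eta_alpha`, `eta_mu`
#'   plus the covariate columns.
#' @export
sample_patients <- function(pop, covariates, seed = NULL) {
  stopifnot(inherits(pop, "population_params"))
  covariates <- as_tibble(covariates)
  n <- nrow(covariates)
  draw <- function() {
    eta_a <- rnorm(n, 0, pop$omega_alpha)
    eta_m <- rnorm(n, 0, pop$omega_mu)
    list(eta_a = eta_a, eta_m = eta_m)
  }
  e <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  g_shift <- placed_shifts(covariates, pop$effects, "growth")
  m_shift <- placed_shifts(covariates, pop$effects, "dissemination")
  dplyr::bind_cols(
    tibble(
      alpha = exp(log(pop$alpha_pop) + g_shift + e$eta_a),
      mu = if (pop$mu_pop > 0) exp(log(pop$mu_pop) + m_shift + e$eta_m)
           else rep(0, n),
      eta_alpha = e$eta_a,
      eta_mu = e$eta_m
    ),
    covariates
  )
}

#' Simulate time to relapse for a cohort
#'
#' Draws individual parameters with [sample_patients()] and computes each
#' patient's time to relapse with the mechanistic model (seeding stopped
#' at diagnosis unless `unbounded = TRUE`).
#'
#' @inheritParams sample_patients
#' @param vdiag_cells primary tumor volume at diagnosis per patient,
#'   cells (recycled).
#' @param unbounded keep seeding after diagnosis?
#' @return the [sample_patients()] tibble with extra columns `vdiag_cells`,
#'   `ttr_days`, `ttr_months` (`Inf` = never relapses; `<= 0` = metastasis
#'   already visible at diagnosis).
#' @export
simulate_cohort_ttr <- function(pop, covariates, vdiag_cells, seed = NULL,
                                unbounded = FALSE) {
  pts <- sample_patients(pop, covariates, seed = seed)
  vdiag <- rep_len(vdiag_cells, nrow(pts))
  ttr <- ttr_vectorized(pts$alpha, pts$mu, vdiag, K = pop$K, V0 = pop$V0,
                        V_vis = pop$V_vis, unbounded = unbounded)
  pts$vdiag_cells <- vdiag
  pts$ttr_days <- ttr
  pts$ttr_months <- days_to_months(ttr)
  pts
}

#' Population distant-metastasis-free survival curve
#'
#' Monte-Carlo estimate of \eqn{DMFS(t) = P[TTR > t]} for a population
#' defined by `pop` and a covariate table. Replicates are generated by
#' resampling covariate rows (with replacement) and drawing random
#' effects and diagnosis volumes.
#'
#' @inheritParams simulate_cohort_ttr
#' @param covariates covariate table (standardized scale); rows are
#'   resampled to `n_sim` replicates. May be a zero-column/one-row frame.
#' @param vdiag_sampler function(n) returning diagnosis volumes in cells,
#'   or a fixed numeric (recycled).
#' @param n_sim number of Monte-Carlo replicates.
#' @param times evaluation grid, months.
#' @param conditioning `"M0_at_diagnosis"` (default) restricts to
#'   replicates metastasis-free at diagnosis (`TTR > 0`), matching
#'   clinical DMFS cohorts assembled at surgery; `"all"` keeps every
#'   replicate.
#' @return a tibble of class `dmfs_curve` with columns `time` (months)
#'   and `survival`.
#' @export
dmfs_curve <- function(pop, covariates = tibble(.rows = 1),
                       vdiag_sampler = 2e10, n_sim = 2000,
                       times = seq(0, 120, by = 1),
                       conditioning = c("M0_at_diagnosis", "all"),
                       seed = NULL, unbounded = FALSE) {
  conditioning <- match.arg(conditioning)
  stopifnot(n_sim >= 1)
  covariates <- as_tibble(covariates)
  run <- function() {
    rows <- sample.int(nrow(covariates), n_sim, replace = TRUE)
    vd <- if (is.function(vdiag_sampler)) vdiag_sampler(n_sim)
          else rep_len(vdiag_sampler, n_sim)
    sim <- simulate_cohort_ttr(pop, covariates[rows, , drop = FALSE], vd,
                               unbounded = unbounded)
    sim$ttr_months
  }
  ttr <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (conditioning == "M0_at_diagnosis") {
    keep <- ttr > 0
    if (!any(keep)) {
      warn("no replicate is metastasis-free at diagnosis; returning a degenerate curve.")
      ttr <- numeric(0)
    } else ttr <- ttr[keep]
  }
  surv <- if (length(ttr)) vapply(times, function(tt) mean(ttr > tt), numeric(1))
          else rep(NA_real_, length(times))
  out <- tibble(time = times, survival = surv)
  class(out) <- c("dmfs_curve", class(out))
  attr(out, "n_sim") <- n_sim
  attr(out, "conditioning") <- conditioning
  attr(out, "ttr_months") <- ttr # the (conditioned) simulated TTR sample
  out
}
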