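test_that("covariate_shift implements the three effect forms", {
  lin <- covariate_effect("CFB", "dissemination", "linear", b = 0.5, c = 1)
  expect_equal(covariate_shift(c(0, 1, 3), lin), c(-0.5, 0, 1))
  stp <- covariate_effect("SAA2", "dissemination", "step", c = 0.2, dif = -0.9)
  expect_equal(covariate_shift(c(-1, 0.19, 0.2, 2), stp), c(-0.9, -0.9, 0, 0))
  # zero parameters give a null effect for any value
  null_eff <- covariate_effect("CFB", "growth", "linear_plus_step")
  expect_equal(covariate_shift(seq(-3, 3, by = 0.5), null_eff),
               rep(0, 13))
  # combined form at published-scale parameter values, against direct
  # arithmetic: b*(max(0, v - c)) + dif*(v < c)
  eff <- covariate_effect("CFB", "dissemination", "linear_plus_step",
                          b = 1.04, c = 0.22, dif = -0.67)
  expect_equal(covariate_shift(1.0, eff), 1.04 * (1.0 - 0.22))
  expect_equal(covariate_shift(0.0, eff), -0.67)
  expect_error(covariate_shift(NA, eff), "finite")
})

test_that("sample_patients realizes the log-normal population model", {
  pop <- population_params(0.05, 1e-12, omega_alpha = 0, omega_mu = 0)
  pts <- sample_patients(pop, tibble::tibble(.rows = 4), seed = 1)
  expect_equal(pts$alpha, rep(0.05, 4))
  expect_equal(pts$mu, rep(1e-12, 4))
  # Monte-Carlo mean of log(alpha) within the CLT bound
  pop2 <- population_params(0.05, 1e-12, omega_alpha = 0.4, omega_mu = 1)
  n <- 1e5
  pts2 <- sample_patients(pop2, tibble::tibble(.rows = n), seed = 2)
  expect_lt(abs(mean(log(pts2$alpha)) - log(0.05)), 4 * 0.4 / sqrt(n))
  # a dissemination-placed shift multiplies mu by exp(shift) exactly
  eff <- covariate_effect("CFB", "dissemination", "linear", b = 1)
  pop3 <- population_params(0.05, 1e-12, 0, 0, effects = list(eff))
  pts3 <- sample_patients(pop3, tibble::tibble(CFB = c(0, 1, 2)), seed = 1)
  expect_equal(pts3$mu, 1e-12 * exp(c(0, 1, 2)))
  # missing covariate is an input error
  expect_error(sample_patients(pop3, tibble::tibble(SAA2 = 1)), "missing")
})

test_that("simulate_cohort_ttr is seed-deterministic and flags M1 correctly", {
  pop <- population_params(0.05, 3e-13, 0.3, 1.5)
  cov <- tibble::tibble(.rows = 300)
  a <- simulate_cohort_ttr(pop, cov, 2e10, seed = 7)
  b <- simulate_cohort_ttr(pop, cov, 2e10, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 300)
  # mu_pop = 0: nobody ever relapses
  pop0 <- population_params(0.05, 0)
  z <- simulate_cohort_ttr(pop0, cov, 2e10, seed = 1)
  expect_true(all(z$ttr_days == Inf))
  # TTR <= 0 exactly when >= 1 metastasis is already visible at diagnosis
  m1_sim <- is.finite(a$ttr_days) & a$ttr_days <= 0
  g_list <- lapply(seq_len(nrow(a)), function(i) {
    g <- growth_params(alpha = a$alpha[i], K = pop$K)
    t_diag <- time_to_volume(2e10, 1, g)
    n_visible(t_diag, g, a$mu[i], t_stop = t_diag) >= 1
  })
  expect_equal(m1_sim, unlist(g_list))
})

test_that("dmfs_curve is a valid survival curve matching its own KM estimate", {
  pop <- population_params(0.05, 3e-13, 0.3, 1.5)
  d <- dmfs_curve(pop, n_sim = 500, seed = 3)
  expect_true(all(d$survival >= 0 & d$survival <= 1))
  expect_true(all(diff(d$survival) <= 0))
  expect_equal(d$survival[1], 1) # conditioned on M0 at diagnosis
  # mu_pop = 0 gives the constant-1 curve
  d0 <- dmfs_curve(population_params(0.05, 0), n_sim = 50, seed = 1)
  expect_true(all(d0$survival == 1))
  # equals the Kaplan-Meier estimator on the same (uncensored) TTR sample
  ttr <- attr(d, "ttr_months")
  sf <- survival::survfit(survival::Surv(ttr[is.finite(ttr)],
                                         rep(1, sum(is.finite(ttr)))) ~ 1)
  km_at <- stats::stepfun(sf$time, c(1, sf$surv))(d$time)
  frac_inf <- mean(!is.finite(ttr))
  expect_equal(d$survival, km_at * (1 - frac_inf) + frac_inf,
               tolerance = 1e-10)
})

test_that("fit_dmfs recovers planted dissemination parameters", {
  pop_true <- population_params(0.05, 3e-13, 0.3, 1.5,
    effects = list(covariate_effect("CFB", "dissemination", "linear", b = 1)))
  cg <- generate_cohort(cohort_config(n_patients = 200, pop = pop_true,
                                      seed = 3))
  dat <- dplyr::select(cg$cohort, time, event, CFB)
  pop0 <- population_params(0.05, 1e-13, 0.3, 1.0)
  fit <- fit_dmfs(dat, "CFB", pop0, form = "linear",
                  placement = "dissemination", seed = 11)
  expect_true(fit$converged)
  expect_lt(abs(log(fit$par[["mu_pop"]]) - log(3e-13)) / abs(log(3e-13)),
            0.2)
  expect_gt(fit$par[["b"]], 0.4)
  # determinism: same data and seed reproduce the same optimum
  fit2 <- fit_dmfs(dat, "CFB", pop0, form = "linear",
                   placement = "dissemination", seed = 11)
  expect_equal(fit$par, fit2$par)
  expect_equal(fit$objective, fit2$objective)
  # a step form cannot explain linear-generated data as well
  fit_step <- fit_dmfs(dat, "CFB", pop0, form = "step",
                       placement = "dissemination", seed = 11)
  expect_gt(fit_step$objective, fit$objective)
  # broom-style accessors
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_true("mu_pop" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$objective, fit$objective)
})

test_that("select_effect_form ranks placements by objective", {
  pop_true <- population_params(0.05, 3e-13, 0.3, 1.5,
    effects = list(covariate_effect("CFB", "dissemination", "linear", b = 1)))
  cg <- generate_cohort(cohort_config(n_patients = 200, pop = pop_true,
                                      seed = 5))
  dat <- dplyr::select(cg$cohort, time, event, CFB)
  pop0 <- population_params(0.05, 1e-13, 0.3, 1.0)
  sel <- select_effect_form(dat, "CFB", pop0, form = "linear", seed = 5)
  expect_true(all(diff(sel$ranking$objective) >= 0))
  expect_equal(sel$best$placement, sel$ranking$placement[1])
  expect_equal(sel$best$placement, "dissemination")
  # single candidate is returned as-is
  sel1 <- select_effect_form(dat, "CFB", pop0, form = "linear",
                             placements = "growth", seed = 5)
  expect_equal(sel1$best$placement, "growth")
})
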