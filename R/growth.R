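#' Gompertz growth parameters for a single tumor
#'
#' Bundles the per-individual Gompertz growth constants and the size
#' conventions used by the dissemination model. Growth follows
#' \eqn{dV/dt = (\alpha - \beta \log V) V}, so the carrying capacity is
#' \eqn{K = \exp(\alpha/\beta)}. By convention only `alpha` carries
#' inter-individual variability: `beta` is tied to a fixed carrying
#' capacity through `beta = alpha / log(K)` unless given explicitly.
#'
#' @param alpha Gompertz growth rate, 1/day. Must be positive.
#' @param beta Gompertz decay rate, 1/day. Defaults to `alpha / log(K)`.
#' @param K carrying capacity in cells; used only when `beta` is missing.
#'   Default `1e12` cells (~1 litre).
#' @param V0 size of a newly seeded lesion, cells. Default 1 cell.
#' @param V_vis minimal clinically visible lesion volume, cells. Default is
#'   a 5 mm diameter sphere (`diameter_to_cells(5)`).
#' @return an object of class `growth_params`.
#' @export
#' @examples
#' g <- growth_params(alpha = 0.1)
#' primary_volume(365, g)
growth_params <- function(alpha, beta = NULL, K = 1e12, V0 = 1,
                          V_vis = diameter_to_cells(5)) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    abort("`alpha` must be a single positive number (1/day).")
  if (is.null(beta)) {
    if (K <= 1) abort("`K` must exceed 1 cell.")
    beta <- alpha / log(K)
  }
  if (beta <= 0) abort("`beta` must be positive (1/day).")
  if (V0 < 1) abort("`V0` must be at least 1 cell.")
  if (V_vis <= V0) abort("`V_vis` must exceed `V0`.")
  if (alpha / beta <= log(V_vis))
    abort("carrying capacity exp(alpha/beta) must exceed `V_vis`.")
  structure(list(alpha = alpha, beta = beta, V0 = V0, V_vis = V_vis),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  cat(sprintf("  alpha: %.4g /day   beta: %.4g /day   K: %.3g cells\n",
              x$alpha, x$beta, exp(x$alpha / x$beta)))
  cat(sprintf("  V0: %.3g cells   V_vis: %.4g cells (%.1f mm diameter)\n",
              x$V0, x$V_vis, (6 * x$V_vis / CELLS_PER_MM3 / pi)^(1 / 3)))
  invisible(x)
}

#' Primary tumor volume under Gompertz growth
#'
#' Closed-form solution of \eqn{dV/dt = (\alpha - \beta \log V) V} with
#' \eqn{V(0) = 1} cell:
#' \eqn{V_p(t) = \exp\{(\alpha/\beta)(1 - e^{-\beta t})\}}.
#'
#' @param t time since tumor inception, days (vectorized, non-negative).
#' @param g a [growth_params()] object.
#' @return volume in cells, same length as `t`.
#' @export
primary_volume <- function(t, g) {
  stopifnot(inherits(g, "growth_params"))
  if (any(t < 0)) abort("`t` must be non-negative (days).")
  exp((g$alpha / g$beta) * (1 - exp(-g$beta * t)))
}

#' Instantaneous Gompertz growth rate
#'
#' \eqn{g(v) = (\alpha - \beta \log v)\, v}, in cells/day. Zero exactly at
#' the carrying capacity \eqn{v = \exp(\alpha/\beta)}.
#'
#' @param v tumor volume, cells (vectorized, positive).
#' @inheritParams primary_volume
#' @return growth rate in cells/day.
#' @export
growth_rate <- function(v, g) {
  stopifnot(inherits(g, "growth_params"))
  if (any(v <= 0)) abort("`v` must be positive (cells).")
  (g$alpha - g$beta * log(v)) * v
}

#' Volume of a metastasis a given time after seeding
#'
#' Gompertz solution started from the seeding size `V0`:
#' \eqn{v(\tau) = \exp\{e^{-\beta\tau}\log V_0 + (\alpha/\beta)(1 - e^{-\beta\tau})\}}.
#'
#' @param tau time since seeding, days (vectorized, non-negative).
#' @inheritParams primary_volume
#' @return lesion volume in cells.
#' @export
met_volume <- function(tau, g) {
  stopifnot(inherits(g, "growth_params"))
  if (any(tau < 0)) abort("`tau` must be non-negative (days).")
  e <- exp(-g$beta * tau)
  exp(e * log(g$V0) + (g$alpha / g$beta) * (1 - e))
}

#' Time for a Gompertz tumor to grow between two volumes
#'
#' Inverse of [met_volume()]: the time for a lesion to grow from
#' `V_start` to `V_target`,
#' \eqn{\tau = -(1/\beta)\log\{(\alpha - \beta\log V_{target}) /
#'   (\alpha - \beta\log V_{start})\}}.
#'
#' @param V_target target volume, cells; must be below the carrying
#'   capacity `exp(alpha/beta)`.
#' @param V_start starting volume, cells; defaults to `g$V0`.
#' @inheritParams primary_volume
#' @return time in days.
#' @export
time_to_volume <- function(V_target, V_start = g$V0, g) {
  stopifnot(inherits(g, "growth_params"))
  cap <- g$alpha / g$beta # log carrying capacity
  if (any(V_target < V_start)) abort("`V_target` must be >= `V_start`.")
  if (any(log(V_target) >= cap))
    abort("`V_target` is at or beyond the carrying capacity: unreachable.")
  -(1 / g$beta) * log((cap - log(V_target)) / (cap - log(V_start)))
}

# Cumulative primary-tumor influx integral I(u) = int_0^u V_p(s) ds, in
# cell-days. Closed form via the exponential integral E1: with c = alpha/beta,
#   I(u) = e^c / beta * (E1(c e^{-beta u}) - E1(c)).
# The E1 difference loses precision only when alpha*u is tiny, where
# I(u) ~ u; a series guard covers that regime.
cum_primary_volume <- function(u, g) {
  cc <- g$alpha / g$beta
  out <- numeric(length(u))
  u <- pmax(u, 0)
  pos <- u > 0
  if (any(pos)) {
    small <- pos & (g$alpha * u < 1e-6)
    big <- pos & !small
    if (any(small)) out[small] <- u[small] * (1 + g$alpha * u[small] / 2)
    if (any(big)) {
      out[big] <- exp(cc) / g$beta *
        (pracma::expint(cc * exp(-g$beta * u[big])) - pracma::expint(cc))
    }
  }
  out
}

# Inverse of cum_primary_volume: smallest u with I(u) = target.
# I is increasing and convex (I' = V_p > 0 increasing), so a Newton
# iteration started from an upper bound decreases monotonically to the
# root with quadratic convergence. Vectorized over `target` / `upper`.
inv_cum_primary_volume <- function(target, g, upper) {
  u <- upper
  for (i in seq_len(60L)) {
    f <- cum_primary_volume(u, g) - target
    step <- f / primary_volume(u, g)
    u_new <- pmax(u - step, 0)
    if (all(abs(u_new - u) <= 1e-10 * (1 + u))) {
      u <- u_new
      break
    }
    u <- u_new
  }
  u
}

#' Expected number of visible metastases
#'
#' Integrates the metastatic size distribution above the visibility
#' threshold. Because every lesion grows deterministically with the same
#' Gompertz law, a lesion is visible at time `t` iff it was seeded before
#' \eqn{t - \tau_{vis}}, where \eqn{\tau_{vis}} is the time to grow from
#' `V0` to `V_vis`; hence
#' \eqn{N_{vis}(t) = \mu \int_0^{\min(t - \tau_{vis},\; t_{stop})} V_p(s)\,ds}.
#'
#' @param t time since tumor inception, days (vectorized).
#' @param g a [growth_params()] object.
#' @param mu dissemination rate, metastases per cell per day (non-negative).
#' @param t_stop time at which seeding stops (e.g. resection of the
#'   primary), days; `Inf` for unbounded seeding.
#' @return expected visible metastasis count, same length as `t`.
#' @export
n_visible <- function(t, g, mu, t_stop = Inf) {
  stopifnot(inherits(g, "growth_params"))
  if (mu < 0) abort("`mu` must be non-negative.")
  if (any(t < 0)) abort("`t` must be non-negative (days).")
  if (mu == 0) return(numeric(length(t)))
  tau_vis <- time_to_volume(g$V_vis, g$V0, g)
  u <- pmin(t - tau_vis, t_stop)
  mu * cum_primary_volume(pmax(u, 0), g)
}

#' Time to relapse for a single patient
#'
#' Computes the time from diagnosis (primary tumor at volume `V_diag`) to
#' the appearance of the first visible metastasis: the root of
#' \eqn{N_{vis}(t_{diag} + TTR) = 1}. By default seeding stops at
#' diagnosis (resection); set `seeding = "unbounded"` to let the primary
#' keep seeding. The root is found by bracketing and bisection
#' ([stats::uniroot()]) to a relative tolerance of 1e-6 days.
#'
#' A negative `ttr` means at least one metastasis was already visible at
#' diagnosis; `ttr = Inf` means the expected lifetime number of visible
#' metastases never reaches 1 (no relapse).
#'
#' @param V_diag primary tumor volume at diagnosis, cells.
#' @param g a [growth_params()] object.
#' @param mu dissemination rate, metastases per cell per day.
#' @param seeding `"stop_at_diagnosis"` (default) or `"unbounded"`.
#' @param t_max horizon beyond which the relapse time is reported as
#'   `Inf`, days. Default 40 years.
#' @return a one-row tibble with columns `t_diag` (days from inception to
#'   diagnosis), `ttr_days`, `ttr_months` and `n_vis_at_diag`.
#' @export
#' @examples
#' g <- growth_params(alpha = 0.05)
#' time_to_relapse(2e10, g, mu = 1e-12)
time_to_relapse <- function(V_diag, g, mu,
                            seeding = c("stop_at_diagnosis", "unbounded"),
                            t_max = 40 * 365.25) {
  stopifnot(inherits(g, "growth_params"))
  seeding <- match.arg(seeding)
  if (length(V_diag) != 1L || V_diag <= g$V0)
    abort("`V_diag` must be a single volume above `V0`.")
  if (log(V_diag) >= g$alpha / g$beta)
    abort("`V_diag` is at or beyond the carrying capacity.")
  t_diag <- time_to_volume(V_diag, g$V0, g)
  t_stop <- if (seeding == "stop_at_diagnosis") t_diag else Inf
  n_at_diag <- if (mu > 0) n_visible(t_diag, g, mu, t_stop) else 0

  tau_vis <- time_to_volume(g$V_vis, g$V0, g)
  lifetime <- if (mu > 0 && is.finite(t_stop)) {
    mu * cum_primary_volume(t_stop, g)
  } else if (mu > 0) Inf else 0

  if (lifetime < 1) {
    ttr <- Inf
  } else {
    f <- function(ttr) n_visible(t_diag + ttr, g, mu, t_stop) - 1
    # N_vis rises from 0 at ttr = tau_vis - t_diag; with seeding stopped it
    # saturates at the lifetime count by ttr = tau_vis. Expand the upper
    # bracket geometrically for the unbounded case.
    lo <- tau_vis - t_diag
    hi <- max(tau_vis, 1)
    while (f(hi) < 0) {
      hi <- hi * 2
      if (t_diag + hi > t_max + t_diag) break
    }
    if (f(hi) < 0) {
      ttr <- Inf
    } else {
      ttr <- uniroot(f, c(lo, hi), tol = 1e-6 * max(1, abs(hi)))$root
      if (ttr > t_max) ttr <- Inf
    }
  }
  tibble(
    t_diag = t_diag,
    ttr_days = ttr,
    ttr_months = days_to_months(ttr),
    n_vis_at_diag = n_at_diag
  )
}

# Fully vectorized influx integral for per-patient (beta_i) at shared log
# carrying capacity cc: I(u_i) = e^cc/beta_i * (E1(cc e^{-beta_i u_i}) - E1(cc)).
cum_influx_vec <- function(u, beta, cc) {
  out <- numeric(length(u))
  u <- pmax(u, 0)
  alpha <- beta * cc
  small <- u > 0 & alpha * u < 1e-6
  big <- u > 0 & !small
  if (any(small)) out[small] <- u[small] * (1 + alpha[small] * u[small] / 2)
  if (any(big)) {
    out[big] <- exp(cc) / beta[big] *
      (e1_exp(cc * exp(-beta[big] * u[big])) - e1_exp(cc))
  }
  out
}

# Vectorized closed-form TTR used by the population layer. Shares the
# size conventions (V0, V_vis) and carrying capacity K across patients;
# alpha, mu, V_diag vary per patient (beta_i = alpha_i / log K).
# Returns TTR in days (finite, possibly negative, or Inf for never-relapse).
# With seeding stopped at diagnosis,
#   TTR = tau_vis + I^{-1}(1/mu) - t_diag     (when mu * I(t_diag) >= 1)
# because N_vis(t_diag + ttr) = mu * I(t_diag + ttr - tau_vis) for
# ttr < tau_vis and saturates beyond. I is increasing and convex, so a
# vectorized Newton iteration from an upper bound converges monotonically.
ttr_vectorized <- function(alpha, mu, V_diag, K = 1e12, V0 = 1,
                           V_vis = diameter_to_cells(5), unbounded = FALSE,
                           t_max = 40 * 365.25) {
  n <- max(length(alpha), length(mu), length(V_diag))
  alpha <- rep_len(alpha, n); mu <- rep_len(mu, n)
  V_diag <- rep_len(V_diag, n)
  cc <- log(K)
  beta <- alpha / cc
  t_diag <- -(1 / beta) * log((cc - log(V_diag)) / (cc - log(V0)))
  tau_vis <- -(1 / beta) * log((cc - log(V_vis)) / (cc - log(V0)))

  ttr <- rep(Inf, n)
  ok <- mu > 0
  if (!any(ok)) return(ttr)
  target <- 1 / mu
  upper <- t_diag
  if (unbounded) {
    # expand the Newton starting point until I(upper) >= 1/mu
    need <- ok & cum_influx_vec(upper, beta, cc) < target
    while (any(need)) {
      upper[need] <- upper[need] * 2 + 1
      need <- ok & cum_influx_vec(upper, beta, cc) < target
    }
    idx <- which(ok)
  } else {
    idx <- which(ok & cum_influx_vec(t_diag, beta, cc) >= target)
  }
  if (length(idx)) {
    u <- upper[idx]
    b <- beta[idx]; tg <- target[idx]
    for (iter in seq_len(80L)) {
      f <- cum_influx_vec(u, b, cc) - tg
      vp <- exp(cc * (1 - exp(-b * u)))
      u_new <- pmax(u - f / vp, 0)
      if (all(abs(u_new - u) <= 1e-10 * (1 + u))) { u <- u_new; break }
      u <- u_new
    }
    ttr[idx] <- tau_vis[idx] + u - t_diag[idx]
  }
  ttr[ttr > t_max] <- Inf
  ttr
}
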