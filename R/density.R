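#' Metastatic size distribution by the method of characteristics
#'
#' Solves the size-structured transport equation for the metastatic
#' density \eqn{\rho(t, v)},
#' \deqn{\partial_t \rho + \partial_v(g(v)\rho) = 0, \quad
#'       g(V_0)\rho(t, V_0) = \mu V_p(t), \quad \rho(0, v) = 0,}
#' exactly along characteristics: a lesion of size `v` at time `t` was
#' seeded at \eqn{s^*(t,v) = t - \tau(v)} where \eqn{\tau(v)} is the
#' Gompertz travel time from `V0` to `v`, giving
#' \eqn{\rho(t,v) = \mu V_p(s^*) / g(v)} wherever a characteristic lands
#' (\eqn{0 \le s^* \le \min(t, t_{stop})}) and 0 elsewhere.
#'
#' @param t evaluation time, days.
#' @param size_grid strictly increasing lesion volumes, cells; must start
#'   at or below `V0` + tolerance and extend to at least `V_vis`.
#' @inheritParams n_visible
#' @return a tibble of class `met_density` with columns `size` (cells)
#'   and `density` (lesions per unit volume), carrying `t`, `mu` and the
#'   growth parameters as attributes.
#' @seealso [solve_density_fv()] for the independent finite-volume
#'   integrator used as a numerical cross-check.
#' @export
solve_density <- function(t, size_grid, g, mu, t_stop = Inf) {
  stopifnot(inherits(g, "growth_params"))
  if (length(t) != 1L || t < 0) abort("`t` must be a single non-negative time.")
  if (is.unsorted(size_grid, strictly = TRUE))
    abort("`size_grid` must be strictly increasing.")
  if (size_grid[1] > g$V0 * (1 + 1e-12))
    abort("`size_grid` must start at `V0`.")
  if (utils::tail(size_grid, 1) < g$V_vis)
    abort("`size_grid` must extend to at least `V_vis`.")
  dens <- numeric(length(size_grid))
  if (t > 0 && mu > 0) {
    cap <- exp(g$alpha / g$beta)
    valid <- size_grid < cap & size_grid >= g$V0
    tau <- rep(NA_real_, length(size_grid))
    tau[valid] <- time_to_volume(size_grid[valid], g$V0, g)
    s_star <- t - tau
    landed <- valid & !is.na(s_star) & s_star >= 0 & s_star <= min(t, t_stop)
    if (any(landed)) {
      dens[landed] <- mu * primary_volume(s_star[landed], g) /
        growth_rate(size_grid[landed], g)
    }
  }
  out <- tibble(size = size_grid, density = dens)
  class(out) <- c("met_density", class(out))
  attr(out, "t") <- t
  attr(out, "mu") <- mu
  attr(out, "t_stop") <- t_stop
  attr(out, "growth") <- g
  out
}

#' Total metastatic number carried by a density
#'
#' Trapezoidal integral of the density over sizes at or above `from`.
#' With `from = V0` this is the cumulative number of seeded metastases;
#' with `from = V_vis` it is the expected visible count.
#'
#' @param dens a `met_density` tibble from [solve_density()] or
#'   [solve_density_fv()].
#' @param from lower integration bound, cells. Default: smallest grid size.
#' @return a number (expected metastasis count).
#' @export
density_mass <- function(dens, from = NULL) {
  stopifnot(inherits(dens, "met_density"))
  edges <- attr(dens, "edges")
  if (!is.null(edges)) {
    # cell-average representation: exact cell sums, partial cell at `from`
    lo <- edges[-length(edges)]; hi <- edges[-1]
    frac <- if (is.null(from)) 1 else pmin(pmax((hi - from) / (hi - lo), 0), 1)
    return(sum(dens$density * (hi - lo) * frac))
  }
  v <- dens$size; rho <- dens$density
  if (!is.null(from)) {
    keep <- v >= from
    # add an interpolated point at the bound so the integral is exact-ish
    if (any(!keep) && any(keep)) {
      i <- which(keep)[1]
      if (i > 1) {
        w <- (from - v[i - 1]) / (v[i] - v[i - 1])
        v <- c(from, v[keep])
        rho <- c(rho[i - 1] + w * (rho[i] - rho[i - 1]), rho[keep])
      } else {
        v <- v[keep]; rho <- rho[keep]
      }
    } else {
      v <- v[keep]; rho <- rho[keep]
    }
  }
  if (length(v) < 2L) return(0)
  sum(diff(v) * (utils::head(rho, -1) + utils::tail(rho, -1)) / 2)
}

#' Finite-volume solution of the metastatic transport equation
#'
#' First-order upwind conservative scheme on a log-spaced size grid with
#' the seeding boundary flux \eqn{g(V_0)\rho(t,V_0) = \mu V_p(t)} and a
#' CFL number of 0.9. This integrator is deliberately independent of the
#' characteristic solution in [solve_density()]; it exists as a numerical
#' cross-check (and is exercised as such in the test suite), not as the
#' production path.
#'
#' @inheritParams solve_density
#' @param n_cells number of finite-volume cells. Default 400.
#' @param v_max upper end of the size domain, cells. Default: slightly
#'   above the size of the oldest possible lesion at time `t` (the
#'   characteristic from s = 0), so no mass leaves the domain.
#' @param cfl CFL number in (0, 1]. Default 0.9.
#' @return a `met_density` tibble (cell centres and cell-average density).
#' @export
solve_density_fv <- function(t, g, mu, t_stop = Inf, n_cells = 400,
                             v_max = NULL, cfl = 0.9) {
  stopifnot(inherits(g, "growth_params"))
  if (t < 0) abort("`t` must be non-negative.")
  if (is.null(v_max)) v_max <- met_volume(t, g) * 1.05 + 10
  v_max <- min(v_max, exp(g$alpha / g$beta) * 0.999)
  if (v_max <= g$V_vis) v_max <- g$V_vis * 1.5
  edges <- exp(seq(log(g$V0), log(v_max), length.out = n_cells + 1L))
  centres <- sqrt(edges[-1] * edges[-(n_cells + 1L)])
  dv <- diff(edges)
  g_edge <- growth_rate(edges, g) # g > 0 on the whole grid (below capacity)
  rho <- numeric(n_cells)
  dt_max <- cfl * min(dv / g_edge[-1])
  time <- 0
  while (time < t) {
    dt <- min(dt_max, t - time)
    influx <- if (time < t_stop) mu * primary_volume(time, g) else 0
    flux <- c(influx, g_edge[-1] * rho) # upwind: g > 0, take left state
    rho <- rho - dt / dv * (flux[-1] - flux[-(n_cells + 1L)])
    time <- time + dt
  }
  out <- tibble(size = centres, density = rho)
  class(out) <- c("met_density", class(out))
  attr(out, "t") <- t
  attr(out, "mu") <- mu
  attr(out, "t_stop") <- t_stop
  attr(out, "growth") <- g
  attr(out, "edges") <- edges
  out
}

# Visible count from a finite-volume density: exact cell sums with a
# partial cell at the threshold.
n_visible_fv <- function(dens, V_vis = attr(dens, "growth")$V_vis) {
  edges <- attr(dens, "edges")
  if (is.null(edges)) return(density_mass(dens, from = V_vis))
  rho <- dens$density
  lo <- edges[-length(edges)]; hi <- edges[-1]
  frac <- pmin(pmax((hi - V_vis) / (hi - lo), 0), 1)
  sum(rho * (hi - lo) * frac)
}
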