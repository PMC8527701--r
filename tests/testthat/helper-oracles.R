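# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Runge-Kutta integration of the Gompertz ODE dV/dt = (alpha - beta log V) V.
ode_gompertz <- function(t_end, alpha, beta, v0 = 1, rtol = 1e-10) {
  # integrate y = log V (dy/dt = alpha - beta y): stable over the full
  # 12-decade volume range, unlike integrating V directly
  out <- deSolve::ode(
    y = c(y = log(v0)), times = c(0, t_end),
    func = function(t, y, p) list(alpha - beta * y),
    parms = NULL, method = "ode45", rtol = rtol, atol = rtol
  )
  exp(unname(out[2, "y"]))
}

# Exhaustive pair enumeration for Harrell's C-index under right censoring.
# Comparable: distinct observed times and an event at the earlier time.
# Concordant: the earlier patient has the smaller score; score ties 0.5.
brute_force_cindex <- function(score, time, event) {
  n <- length(score)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      a <- if (time[i] < time[j]) i else j
      b <- if (time[i] < time[j]) j else i
      if (event[a] != 1) next
      den <- den + 1
      if (score[a] < score[b]) num <- num + 1
      else if (score[a] == score[b]) num <- num + 0.5
    }
  }
  if (den == 0) 0.5 else num / den
}

# Upper-tail hypergeometric probability by explicit combinatorics:
# P(overlap >= k) with term size K, universe N, draw size n.
enum_hyper_upper <- function(k, K, N, n) {
  j <- max(k, 0):min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# A tiny deterministic mouse -> human ortholog table for pipeline tests:
# mouse GeneXXXX maps to human HGENEXXXX; every 10th gene additionally
# maps to a second human symbol to exercise one-to-many expansion.
toy_ortholog_table <- function(n_genes) {
  mouse <- sprintf("Gene%04d", seq_len(n_genes))
  human <- sprintf("HGENE%04d", seq_len(n_genes))
  tab <- tibble::tibble(mouse = mouse, human = human)
  extra <- tibble::tibble(
    mouse = mouse[seq(10, n_genes, by = 10)],
    human = paste0(human[seq(10, n_genes, by = 10)], "B")
  )
  dplyr::bind_rows(tab, extra)
}
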