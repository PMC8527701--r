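---
title: "Methods: mechanistic relapse modelling and signature discovery in ccRCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mechanistic relapse modelling and signature discovery in ccRCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rccmet)
```

`rccmet` couples a mechanistic model of metastatic relapse in clear cell
renal cell carcinoma with a prognostic gene-signature discovery
pipeline. This vignette is the package's account of the science: the
models and their assumptions, the parameters that matter, the numerical
choices, what the synthetic-data generators do and do not emulate, and
the design decisions taken where more than one reasonable reading
existed.

## The mechanistic model

### Growth

Primary tumor and metastases follow Gompertz kinetics,
$dV/dt = (\alpha - \beta \log V)V$, with the same $(\alpha, \beta)$ —
no metastasis-specific growth law is introduced. Volumes are counted in
cells (1 mm³ ≡ 10⁶ cells); a tumor starts from one cell, giving the
closed form $V_p(t) = \exp[(\alpha/\beta)(1-e^{-\beta t})]$ and the
carrying capacity $K = e^{\alpha/\beta}$.

Only $\alpha$ carries inter-individual variability: $\beta$ is tied to
a fixed carrying capacity through $\beta = \alpha / \log K$, with
$K = 10^{12}$ cells (~1 L) by default. This keeps the population model
two-dimensional (random effects on $\alpha$ and $\mu$ only) and is the
conventional reduction when growth data cannot identify $\beta$
separately.

### Dissemination and visibility

The primary seeds metastases at rate $\mu V_p(t)$; each new lesion
starts at $V_0$ (default 1 cell) and grows with the same Gompertz law.
The lesion-size density $\rho(t,v)$ obeys the transport equation
$\partial_t\rho + \partial_v(g\rho) = 0$ with boundary influx
$g(V_0)\rho(t,V_0) = \mu V_p(t)$. Because all lesions follow the same
deterministic characteristics, `solve_density()` evaluates the solution
exactly: $\rho(t,v) = \mu V_p(s^*)/g(v)$, where $s^*$ is the seeding
time of a lesion of size $v$ at time $t$. A first-order upwind
finite-volume integrator (`solve_density_fv()`, log-spaced grid,
CFL 0.9) ships as an *independent numerical cross-check*, not a
production path.

A metastasis is clinically visible above $V_{vis}$, a 5 mm-diameter
sphere (≈ 6.5×10⁷ cells). The expected visible count reduces to
$N_{vis}(t) = \mu \int_0^{\min(t-\tau_{vis},\,t_{stop})} V_p(s)\,ds$
with $\tau_{vis}$ the growth time from $V_0$ to $V_{vis}$. The integral
has a closed form in the exponential integral $E_1$; the scalar path
uses `pracma::expint`, while batched cohort simulation uses an internal
vectorized $E_1$ (power series below 1.5, continued fraction above)
that the unit tests pin against `pracma::expint` to 10⁻¹⁰.

### Time to relapse

TTR is the time from diagnosis (primary at $V_{diag}$) until
$N_{vis} = 1$. Two conventions were genuinely open:

* **Seeding stop.** Whether seeding continues after diagnosis is not
  determined by the clinical DMFS presentation alone. The default stops
  seeding at diagnosis (nephrectomy removes the primary), which yields
  a finite never-relapse fraction and the DMFS plateaus seen in M0
  cohorts; an `unbounded` switch exists for sensitivity analyses.
* **$V_0$.** The seeded-lesion size is not identifiable from relapse
  data; the default is 1 cell, configurable.

`time_to_relapse()` brackets and bisects $N_{vis}=1$
(`stats::uniroot`, relative tolerance 10⁻⁶ days, 40-year horizon with
an `Inf` sentinel). TTR ≤ 0 means a metastasis was already visible at
diagnosis (M1); TTR = Inf means the expected lifetime visible count
never reaches one. The cohort path (`ttr_vectorized`) inverts the
influx integral with a monotone Newton iteration started from an upper
bound (the integral is increasing and convex, so convergence is
monotone and quadratic); unit tests verify scalar and vectorized paths
agree to 10⁻⁵.

TTR is strictly decreasing in $\mu$ and — less obviously — in
$\alpha$ wherever finite: a faster-growing tumor is younger at
diagnosis and has seeded less, but its metastases also surface sooner,
and the net effect (verified numerically across the working parameter
range) is earlier relapse, with a finite→never flip at large $\alpha$.

### Numerical regime of the finite-volume cross-check

A first-order upwind scheme smears the advancing size front. Early
after inception the visible tail holds a vanishing fraction of the
total metastatic mass (≈10⁻⁶), and the smearing error dwarfs it — no
practical resolution reaches percent-level agreement there. The
cross-check is therefore run in the late-stage regime (t about 5–7
times the visibility lag, expected visible counts of order 10–10³)
where the density is smooth near $V_{vis}$; with 2000 cells the two
solvers agree on $N_{vis}$ to well under 1%, and mass conservation
against the influx integral holds to 10⁻⁴ (2×10⁻³ across the
stopped-seeding discontinuity). First-order convergence of the scheme
was verified by grid refinement.

## The population layer

Individual parameters are log-normal:
$\log\alpha_i = \log\alpha_{pop} + (\text{growth shifts}) + \eta_{\alpha,i}$,
$\eta_\alpha \sim N(0, \omega_\alpha^2)$, and likewise for $\mu$. A
covariate effect declares a *placement* (growth, dissemination, or
both) and a *form* on the log-parameter scale:

| form | shift |
|---|---|
| linear | $b(x - c)$ |
| step | $d\cdot 1[x < c]$ |
| linear_plus_step | $b\max(0, x-c) + d\cdot 1[x < c]$ |

Covariates are standardized (z-scored) before effects apply, so $b$,
$c$, $d$ live on the SD scale; Fuhrman grade is treated as ordinal
1–4 and standardized like the continuous markers. The exact functional
form used in companion estimation software is not fully specified
anywhere accessible to this package, so the three forms above are
explicit, selectable approximations — no claim is made that any of
them reproduces externally printed effect values.

### Fitting

`fit_dmfs()` calibrates $(\mu_{pop}, \omega_\mu)$ and the active
effect's free parameters by weighted least squares between simulated
DMFS curves and Kaplan-Meier estimates of the observed cohort
dichotomized at several covariate thresholds (default terciles and the
median; weights = at-risk counts). This mirrors how goodness-of-fit is
actually displayed for such models; a full nonlinear mixed-effects
(SAEM-style) likelihood machinery is deliberately out of scope, as are
standard errors from the Fisher information.

Numerics: common random numbers (random effects and diagnosis volumes
drawn once per fit, ~4000 replicates, reused at every objective
evaluation) make the objective smooth; optimization is Nelder-Mead
(≤400 iterations) restarted once from a perturbed optimum; DMFS curves
condition on being metastasis-free at diagnosis, matching M0 surgical
cohorts (an unconditional mode exists). `select_effect_form()` fits
each candidate placement and returns the full ranking by objective.

On synthetic cohorts of n = 200 generated by the model itself
(dissemination-placed linear effect b = 1), the fit recovers
$\log\mu_{pop}$ within a few percent and picks the correct placement;
the acceptance suite runs 20 seeds of this recovery study.

## Prediction and benchmarking

`personalized_prediction()` simulates 10,000 replicates of one patient:
each draws fresh $\eta_\alpha, \eta_\mu$ and a log-normal diagnosis
volume around the nominal value (median-preserving, CV 20% by default —
the distribution of volumetry error is not otherwise specified).
Outputs: the personalized DMFS curve, predicted TTR (median replicate),
P(metastasis at diagnosis) = fraction of replicates with TTR ≤ 0, and
P(metastasis-free at 5 y), with never-relapse replicates counted as
metastasis-free.

`harrell_c_index()` implements the standard right-censored concordance
estimator: pairs are comparable when the observed times differ and the
earlier time carries an event; score ties count ½; no comparable pairs
returns ½ by convention. Never-relapse predictions enter as `Inf`
scores, which compare as the largest values and tie among themselves —
equivalent to the largest-finite-rank convention. The implementation is
pinned against exhaustive pair enumeration (all seeded instances with
n ≤ 8, with censoring and ties) and against `survival::concordance` on
tie-free data. `cox_benchmark()` fits `survival::coxph` on the listed
covariates, scores patients by the negated linear predictor (so both
predictors share the larger-is-later orientation) and reports the same
concordance record; `bootstrap_percentile_ci()` (100 row resamples,
percentile method) supplies intervals for either path.

## The signature-discovery pipeline

The pipeline screens serial-passage expression panels (parental P0 and
passages P2–P6; P1 is absent from the emulated design) for genes that
change progressively with passaging, then tests them for prognostic
value in a clinical expression cohort:

1. `differential_expression()` — limma moderated t-tests on log2
   values, BH adjustment, DEG at adjusted p ≤ 0.01. limma is the
   field-standard engine for such panels; exact DEG counts from any
   specific physical panel are not a target.
2. `zscore_select()` — logFC standardized against the mean and SD of
   all logFC; keep |z| ≥ 2.58 (the two-sided normal critical value at
   p = 0.01) and |logFC| ≥ 2.
3. `progressive_genes()` — DEG in P0–P6 with every step comparison
   (P0–P2, P2–P3, P3–P4, P4–P5, P5–P6) either non-significant (stable
   states allowed) or significant in the same direction. The
   late-passage refinement ("progressive and DEG in P4–P5 / P5–P6") has
   two defensible readings — a literal intersection of all three sets is
   vacuous — so all three labelled subsets are returned and the default
   `selected` set is the union of the two late-passage-restricted
   subsets (genes still actively changing late in the series).
4. `pca_contribution_filter()` — centered PCA over samples; per-gene
   contribution = squared loading normalized to sum to one per
   component; keep genes above the mean contribution (1/n_genes) on PC1
   *or* PC2 (the conjunctive reading is available by flag).
5. `map_orthologs()` — two-column mouse→human table; one-to-many
   mappings expand, unmapped genes are dropped and counted.
6. `prognostic_gene_filter()` — per gene, expression terciles
   (remainder to the lower groups, ties broken by stable rank);
   high-vs-low Cox HR and log-rank test; the *direction-consistent* HR
   (reciprocal for mouse-down genes) must be ≥ 2 with BH-adjusted
   log-rank p ≤ 0.01. High-vs-low (rather than the 3-group statistic)
   is used for the per-gene log-rank p; genes with an event-free
   tercile are skipped with a warning.
7. `score_signature()` / `empirical_signature_pvalue()` — sample score
   = mean expression over signature genes; tercile split; high-vs-low
   HR with CI, 2- and 3-arm log-rank tests, optional M0-only DFS. The
   empirical null draws 1000 same-size random gene sets; the
   performance metric compared is the 2-arm log-rank p (the natural
   scalar summary of stratification strength), and the add-one
   estimator $(1 + \#\{p_{rand} \le p_{obs}\})/(n+1)$ avoids zero
   p-values. Note the mean-expression score assumes direction-consistent
   genes: up- and down-regulated genes cancel in a plain mean, so mixed
   signatures should be scored per direction arm.
8. `hypergeometric_enrichment()` / `go_zscore()` — upper-tail
   hypergeometric test per term (BH across terms, enriched at adjusted
   p ≤ 0.05) and the directional z-score (up − down)/√count.

## Synthetic data: what it emulates, and what it does not

`generate_panel()` plants progressive genes that drift by a fixed
log2 increment per passage *number* (so the expected P0→P6 difference
is 6 increments; the missing P1 is skipped, not interpolated) over
i.i.d. Gaussian replicate noise. Defaults — 3000 genes, 30 planted,
increment 1 log2/passage, noise SD 0.25, replicate counts
2/2/2/3/5/5 (P0, P2–P6) as in a kidney-primary serial-passage arm —
describe strongly selected genes in clonal lines. Not emulated: probe
effects, batch structure, correlated co-expression modules,
heavy-tailed noise. Passing recovery tests therefore demonstrates the
pipeline's logic and calibration, not robustness to microarray
artefacts.

`generate_cohort()` draws CFB/SAA2 log-normal and Fuhrman-grade ordinal
covariates, then produces TTRs *from the mechanistic model itself*
under administrative censoring. Defaults (α_pop = 0.05/day,
ω_α = 0.3, μ_pop = 3×10⁻¹³, ω_μ = 1.5, V_diag log-normal around
2×10¹⁰ cells ≈ 3.4 cm, dissemination-placed linear CFB effect b = 1,
120-month horizon) give ≈40% ten-year relapse and a DMFS plateau near
0.6 — the order seen in M0 ccRCC cohorts. Because seeding stops at
surgery, no simulated relapse occurs later than one visibility lag
after diagnosis; very late clinical relapses (dormancy) are outside
this model class.

`generate_survival_expression()` links expression to survival through a
single latent frailty: planted genes read out the frailty
(± direction, noise SD 0.5) and event times are exponential with rate
$\lambda_0 e^{1.2 \cdot \text{frailty}}$ ($\lambda_0 = \log 2 / 60$
months). One shared frailty is the simplest structure that makes a
signature's mean score prognostic; it does not emulate multiple
independent risk axes.

All generators are pure functions of their configuration (fixed seed ⇒
byte-identical output), and `run_pipeline()` writes each stage's
outputs with an MD5 manifest so reruns are verifiable.

## Problem sizes and test design

The test suite runs the recovery studies at desk scale, chosen as the
smallest sizes at which the statistical claims are comfortably
separated from Monte-Carlo noise: 20 seeds × n = 200 cohorts for
parameter recovery and placement selection; 10 seeds × 3000-gene panels
with 30 planted genes for the discovery chain; 1000 random signatures
for the planted-signature null and 99 per draw for the null-uniformity
check; C-index equivalence exhaustively for n ≤ 8. Dual-route checks
pin every nontrivial numeric path to an independent oracle: closed
forms vs `deSolve` integration, characteristics vs upwind finite
volume, closed-form influx vs `stats::integrate`, internal E1 vs
`pracma::expint`, concordance vs brute-force enumeration and
`survival::concordance`, hypergeometric p vs explicit combinatorics.

## Known limitations

* Metastases do not seed metastases; no dormancy, no treatment effects,
  no spatial structure.
* $\beta$ is not independently identifiable (fixed carrying capacity);
  fitted $\mu_{pop}$ is conditional on the assumed growth layer.
* The least-squares KM fit returns no standard errors; RSE-style
  uncertainty would require the likelihood machinery that is out of
  scope.
* The three covariate-effect forms are approximations; printed effect
  values from external cohort analyses are not reproduction targets,
  and clinical headline numbers (hazard ratios, C-indices on real
  cohorts) require external patient data that this package does not
  ship.
* The empirical signature p-value inherits the discreteness of its
  add-one estimator; with n_random = 1000 its floor is ≈ 0.001.
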