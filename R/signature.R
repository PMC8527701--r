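#' Gene signature
#'
#' A named list of human gene symbols with per-gene directions (+1 for
#' genes up-regulated along the mouse passages, -1 for down-regulated).
#'
#' @param name signature label, e.g. `"KPT"`.
#' @param genes character vector of unique gene symbols.
#' @param directions numeric vector of +1/-1, recycled to `length(genes)`.
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, directions = 1) {
  if (length(genes) == 0) abort("a signature must contain genes.")
  if (anyDuplicated(genes)) abort("signature genes must be unique.")
  directions <- rep_len(directions, length(genes))
  if (!all(directions %in% c(-1, 1)))
    abort("`directions` must be +1 or -1.")
  structure(list(name = name, genes = genes,
                 directions = setNames(directions, genes)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes (%d up, %d down)\n", x$name,
              length(x$genes), sum(x$directions > 0), sum(x$directions < 0)))
  invisible(x)
}

# Column-checking helper for survival datasets: returns (time, event)
# vectors for the requested endpoint, optionally restricted to M0.
endpoint_columns <- function(surv, endpoint = c("OS", "DFS"), m0_only = FALSE) {
  endpoint <- match.arg(endpoint)
  cols <- if (endpoint == "OS") c("os_time", "os_event")
          else c("dfs_time", "dfs_event")
  if (!all(cols %in% names(surv)))
    abort(sprintf("survival table lacks columns %s.", paste(cols, collapse = ", ")))
  keep <- rep(TRUE, nrow(surv))
  if (m0_only) {
    if (!"m_stage" %in% names(surv))
      abort("`m0_only = TRUE` requires an `m_stage` column.")
    keep <- surv$m_stage %in% "M0"
  }
  list(time = surv[[cols[1]]][keep], event = surv[[cols[2]]][keep], keep = keep)
}

# Split n samples into 3 ordered groups by score rank; remainder goes to
# the lower groups so sizes differ by at most 1. Ties broken by stable
# rank order. Returns integer 1 (low) .. 3 (high).
tertile_groups <- function(score) {
  n <- length(score)
  sizes <- rep(n %/% 3, 3) + (seq_len(3) <= n %% 3)
  ord <- order(score) # stable for ties
  grp <- integer(n)
  grp[ord] <- rep(1:3, times = sizes)
  grp
}

#' Filter genes by prognostic value in a clinical expression cohort
#'
#' For each candidate gene, splits the cohort into expression tertiles,
#' estimates the hazard ratio of the high vs low tertile (Cox
#' proportional hazards on the group indicator) and the high-vs-low
#' log-rank p-value. The direction-consistent HR is the fitted HR for
#' genes up-regulated in the mouse model and its reciprocal for
#' down-regulated genes (a protective "up" gene is thereby rejected).
#' Log-rank p-values are BH-adjusted across the tested genes; a gene is
#' kept when its direction-consistent HR is at least `hr_cut` and its
#' adjusted p at most `p_cut`.
#'
#' @param expr numeric matrix, genes x samples (human symbols).
#' @param surv survival table with `sample_id`, `os_time`, `os_event`,
#'   `dfs_time`, `dfs_event` and optionally `m_stage`; rows must match
#'   `colnames(expr)`.
#' @param genes candidate gene symbols.
#' @param directions named (+1/-1) vector or single value, recycled.
#' @param endpoint `"OS"` or `"DFS"`.
#' @param hr_cut,p_cut selection thresholds (defaults 2 and 0.01).
#' @return tibble with per-gene `hr` (high vs low), `hr_dc`
#'   (direction-consistent), `logrank_p`, `adj_p`, `selected`; genes
#'   skipped for lack of events in a tertile are reported with NA and a
#'   warning.
#' @export
prognostic_gene_filter <- function(expr, surv, genes, directions = 1,
                                   endpoint = c("OS", "DFS"),
                                   hr_cut = 2, p_cut = 0.01) {
  endpoint <- match.arg(endpoint)
  surv <- as_tibble(surv)
  if (!identical(surv$sample_id, colnames(expr)))
    abort("`surv$sample_id` must match `colnames(expr)` in order.")
  genes <- unique(genes)
  present <- genes %in% rownames(expr)
  if (!any(present)) abort("none of the candidate genes are in `expr`.")
  if (any(!present))
    warn(sprintf("%d candidate gene(s) absent from `expr` were dropped.",
                 sum(!present)))
  genes <- genes[present]
  dirs <- rep_len(directions, length(genes))
  if (!is.null(names(directions))) dirs <- directions[genes]
  ep <- endpoint_columns(surv, endpoint)
  skipped <- character(0)
  rows <- purrr::map_dfr(seq_along(genes), function(i) {
    gexp <- expr[genes[i], ]
    grp <- tertile_groups(gexp)
    hl <- grp != 2
    d <- tibble(time = ep$time[hl], event = ep$event[hl],
                high = as.integer(grp[hl] == 3))
    if (sum(d$event[d$high == 1]) == 0 || sum(d$event[d$high == 0]) == 0) {
      skipped <<- c(skipped, genes[i])
      return(tibble(gene = genes[i], direction = dirs[i], hr = NA_real_,
                    hr_dc = NA_real_, logrank_p = NA_real_))
    }
    cox <- survival::coxph(survival::Surv(time, event) ~ high, data = d)
    hr <- unname(exp(stats::coef(cox)))
    lr <- survival::survdiff(survival::Surv(time, event) ~ high, data = d)
    p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
    tibble(gene = genes[i], direction = dirs[i], hr = hr,
           hr_dc = ifelse(dirs[i] > 0, hr, 1 / hr), logrank_p = p)
  })
  if (length(skipped))
    warn(sprintf("skipped %d gene(s) with no events in a tertile: %s",
                 length(skipped), paste(utils::head(skipped, 5), collapse = ", ")))
  rows$adj_p <- p.adjust(rows$logrank_p, method = "BH")
  rows$selected <- !is.na(rows$hr_dc) & rows$hr_dc >= hr_cut &
    rows$adj_p <= p_cut
  rows
}

# 2-arm (high vs low tertile) log-rank p for a signature score --
# the performance metric used for the empirical random-signature null.
signature_logrank_p <- function(score, time, event) {
  grp <- tertile_groups(score)
  hl <- grp != 2
  lr <- survival::survdiff(
    survival::Surv(time[hl], event[hl]) ~ I(grp[hl] == 3))
  stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
}

#' Score a signature on a clinical expression cohort
#'
#' Each sample's score is the mean expression over the signature genes.
#' Samples are ranked by score and split into three equal-size groups
#' (low / medium / high; the remainder goes to the lower groups). Returns
#' the high-vs-low hazard ratio with its 95% CI (Cox on the group
#' indicator), the high-vs-low (2-arm) log-rank p and the 3-group log-rank
#' p. The DFS endpoint can be restricted to M0 (non-metastatic at
#' diagnosis) patients.
#'
#' @param sig a [gene_signature()].
#' @inheritParams prognostic_gene_filter
#' @param m0_only evaluate only M0 patients (requires `m_stage` column)?
#' @return a one-row tibble of class `survival_test_result`: `signature`,
#'   `n_genes_used`, `hr`, `hr_ci_low`, `hr_ci_high`, `logrank_p_2arm`,
#'   `logrank_p_3arm`.
#' @export
score_signature <- function(sig, expr, surv, endpoint = c("OS", "DFS"),
                            m0_only = FALSE) {
  stopifnot(inherits(sig, "gene_signature"))
  endpoint <- match.arg(endpoint)
  surv <- as_tibble(surv)
  if (!identical(surv$sample_id, colnames(expr)))
    abort("`surv$sample_id` must match `colnames(expr)` in order.")
  used <- intersect(sig$genes, rownames(expr))
  if (length(used) == 0)
    abort(sprintf("no gene of signature '%s' is present in `expr`.", sig$name))
  ep <- endpoint_columns(surv, endpoint, m0_only)
  score <- colMeans(expr[used, ep$keep, drop = FALSE])
  grp <- tertile_groups(score)
  hl <- grp != 2
  d <- tibble(time = ep$time[hl], event = ep$event[hl],
              high = as.integer(grp[hl] == 3))
  cox <- survival::coxph(survival::Surv(time, event) ~ high, data = d)
  ci <- exp(stats::confint(cox))
  lr2 <- survival::survdiff(survival::Surv(time, event) ~ high, data = d)
  lr3 <- survival::survdiff(
    survival::Surv(ep$time, ep$event) ~ factor(grp))
  out <- tibble(
    signature = sig$name,
    n_genes_used = length(used),
    hr = unname(exp(stats::coef(cox))),
    hr_ci_low = ci[1], hr_ci_high = ci[2],
    logrank_p_2arm = stats::pchisq(lr2$chisq, 1, lower.tail = FALSE),
    logrank_p_3arm = stats::pchisq(lr3$chisq, 2, lower.tail = FALSE)
  )
  class(out) <- c("survival_test_result", class(out))
  attr(out, "groups") <- grp
  out
}

#' Empirical p-value of a signature against random same-size signatures
#'
#' Compares the signature's survival-stratification performance (the
#' high-vs-low tertile log-rank p of the mean-expression score) with
#' `n_random` signatures of the same size drawn uniformly without
#' replacement from the dataset's gene universe. The empirical p-value
#' uses the add-one estimator
#' `(1 + #random performing at least as well) / (n_random + 1)`.
#'
#' @inheritParams score_signature
#' @param n_random number of random signatures. Default 1000.
#' @param seed integer seed (local, reproducible).
#' @return one-row tibble: `signature`, `observed_p` (the signature's own
#'   log-rank p), `empirical_p`, `n_random`.
#' @export
empirical_signature_pvalue <- function(sig, expr, surv,
                                       endpoint = c("OS", "DFS"),
                                       m0_only = FALSE, n_random = 1000,
                                       seed = 1) {
  stopifnot(inherits(sig, "gene_signature"))
  endpoint <- match.arg(endpoint)
  used <- intersect(sig$genes, rownames(expr))
  if (length(used) == 0) abort("no signature gene present in `expr`.")
  universe <- rownames(expr)
  if (length(universe) < length(used))
    abort("gene universe smaller than the signature.")
  ep <- endpoint_columns(as_tibble(surv), endpoint, m0_only)
  sub <- expr[, ep$keep, drop = FALSE]
  obs <- signature_logrank_p(colMeans(sub[used, , drop = FALSE]),
                             ep$time, ep$event)
  rand_p <- withr::with_seed(seed, {
    purrr::map_dbl(seq_len(n_random), function(b) {
      gs <- sample(universe, length(used))
      signature_logrank_p(colMeans(sub[gs, , drop = FALSE]),
                          ep$time, ep$event)
    })
  })
  tibble(
    signature = sig$name,
    observed_p = obs,
    empirical_p = (1 + sum(rand_p <= obs)) / (n_random + 1),
    n_random = n_random
  )
}
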