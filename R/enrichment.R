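#' Directional z-score for an enriched term
#'
#' `z = (up - down) / sqrt(count)`, where `up` / `down` are the numbers
#' of up- and down-regulated differentially expressed genes assigned to
#' the term and `count` is the term's DE gene count. Positive values mean
#' the term is dominated by up-regulated genes.
#'
#' @param up,down counts of up-/down-regulated DE genes in the term.
#' @param count total DE genes in the term (at least 1; `up + down <= count`).
#' @return the z-score (vectorized).
#' @export
#' @examples
#' go_zscore(4, 0, 4) # 2
go_zscore <- function(up, down, count) {
  if (any(count < 1)) abort("`count` must be at least 1.")
  if (any(up + down > count)) abort("`up + down` cannot exceed `count`.")
  if (any(up < 0 | down < 0)) abort("counts must be non-negative.")
  (up - down) / sqrt(count)
}

#' Hypergeometric gene-set enrichment with directional z-scores
#'
#' Upper-tail hypergeometric test of the overlap between a set of
#' differentially expressed genes and each term's gene set, given a gene
#' universe; BH adjustment across terms; per-term directional
#' [go_zscore()] from the up/down split of the overlapping genes.
#'
#' @param de_genes character vector of DE gene symbols (must lie in
#'   `universe`).
#' @param directions named +1/-1 vector for `de_genes` (or a single
#'   value, recycled) used for the up/down split.
#' @param terms named list of character vectors (term -> gene set), e.g.
#'   from [read_gmt()]. Genes outside the universe are trimmed with a
#'   warning.
#' @param universe character vector of all assayed genes.
#' @param alpha adjusted-p threshold for the `enriched` flag. Default 0.05.
#' @return tibble of class `enrichment_result`: `term`, `term_size`,
#'   `count` (overlap), `up`, `down`, `p`, `adj_p`, `zscore`, `enriched`.
#' @export
hypergeometric_enrichment <- function(de_genes, terms, universe,
                                      directions = 1, alpha = 0.05) {
  if (!all(de_genes %in% universe))
    abort("`universe` must contain all `de_genes`.")
  if (anyDuplicated(de_genes)) de_genes <- unique(de_genes)
  universe <- unique(universe)
  dirs <- rep_len(directions, length(de_genes))
  if (!is.null(names(directions))) dirs <- unname(directions[de_genes])
  names(dirs) <- de_genes
  n_univ <- length(universe)
  n_de <- length(de_genes)
  trimmed <- FALSE
  rows <- purrr::map_dfr(names(terms), function(tm) {
    tg <- unique(terms[[tm]])
    out_univ <- setdiff(tg, universe)
    if (length(out_univ)) trimmed <<- TRUE
    tg <- intersect(tg, universe)
    ov <- intersect(tg, de_genes)
    k <- length(ov)
    p <- phyper(k - 1, length(tg), n_univ - length(tg), n_de,
                lower.tail = FALSE)
    up <- sum(dirs[ov] > 0)
    down <- sum(dirs[ov] < 0)
    tibble(term = tm, term_size = length(tg), count = k, up = up,
           down = down, p = p,
           zscore = if (k >= 1) go_zscore(up, down, k) else NA_real_)
  })
  if (trimmed)
    warn("some term genes were outside the universe and were trimmed.")
  rows$adj_p <- p.adjust(rows$p, method = "BH")
  rows$enriched <- rows$adj_p <= alpha
  rows <- rows[, c("term", "term_size", "count", "up", "down", "p",
                   "adj_p", "zscore", "enriched")]
  class(rows) <- c("enrichment_result", class(rows))
  rows
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper around `fgsea::gmtPathways()`.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    abort("reading GMT files requires the fgsea package.")
  fgsea::gmtPathways(path)
}
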