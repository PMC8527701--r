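#' Passage-labelled expression panel
#'
#' Container for a log2-scale genes-by-samples expression matrix with
#' per-sample passage (P0, P2..P6; P1 is absent from the serial-passage
#' design) and group labels (e.g. KPT, T-LM, K-LM, or "parental" for P0).
#'
#' @param expr numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns.
#' @param meta data frame with columns `sample_id` (matching `colnames(expr)`),
#'   `passage` and `group`.
#' @return an object of class `expression_panel`.
#' @export
expression_panel <- function(expr, meta) {
  if (!is.matrix(expr) || !is.numeric(expr))
    abort("`expr` must be a numeric matrix (genes x samples).")
  if (any(!is.finite(expr))) abort("`expr` must be finite.")
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr)))
    abort("`expr` needs unique gene rownames.")
  meta <- as_tibble(meta)
  if (!all(c("sample_id", "passage", "group") %in% names(meta)))
    abort("`meta` needs columns sample_id, passage, group.")
  if (!identical(sort(colnames(expr)), sort(meta$sample_id)))
    abort("`meta$sample_id` must match `colnames(expr)`.")
  known <- paste0("P", 0:6)
  if (!all(meta$passage %in% known))
    abort("passage labels must be among P0..P6.")
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  structure(list(expr = expr, meta = meta), class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("<expression_panel> %d genes x %d samples\n",
              nrow(x$expr), ncol(x$expr)))
  print(dplyr::count(x$meta, .data$group, .data$passage))
  invisible(x)
}

# Subset the panel's samples for a two-passage comparison. P0 (parental)
# samples are shared across groups, so a group filter keeps them.
panel_samples <- function(panel, passages, group = NULL) {
  keep <- panel$meta$passage %in% passages
  if (!is.null(group))
    keep <- keep & (panel$meta$group %in% group | panel$meta$passage == "P0")
  keep
}

#' Differential expression between two passages
#'
#' Moderated per-gene linear-model test (limma) on log2 values between
#' two passages, with Benjamini-Hochberg adjustment across genes. The
#' log fold change is mean(`pass_b`) - mean(`pass_a`). A gene is flagged
#' `deg` when its adjusted p-value is at or below `alpha` (default 0.01).
#' The `z` column standardizes the logFC against the mean and sd of all
#' logFC values (used by [zscore_select()]).
#'
#' @param panel an [expression_panel()].
#' @param pass_a,pass_b passage labels, e.g. `"P0"`, `"P6"`.
#' @param group optional group label to restrict samples to (P0 parental
#'   samples are always retained).
#' @param alpha adjusted-p threshold for the DEG flag.
#' @return a tibble with columns `gene`, `logFC`, `p`, `adj_p`, `z`,
#'   `direction` (+1/-1 where `deg`, else 0) and `deg`.
#' @export
differential_expression <- function(panel, pass_a, pass_b, group = NULL,
                                    alpha = 0.01) {
  stopifnot(inherits(panel, "expression_panel"))
  keep <- panel_samples(panel, c(pass_a, pass_b), group)
  meta <- panel$meta[keep, ]
  if (sum(meta$passage == pass_a) < 2 || sum(meta$passage == pass_b) < 2)
    abort(sprintf("need >= 2 samples in each of %s and %s.", pass_a, pass_b))
  f <- factor(meta$passage, levels = c(pass_a, pass_b))
  design <- stats::model.matrix(~f)
  fit <- limma::eBayes(limma::lmFit(panel$expr[, keep, drop = FALSE], design))
  tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  lfc <- tt$logFC
  zz <- if (sd(lfc) > 0) (lfc - mean(lfc)) / sd(lfc) else rep(0, length(lfc))
  adj <- tt$adj.P.Val
  deg <- adj <= alpha
  tibble(
    gene = rownames(tt), logFC = lfc, p = tt$P.Value, adj_p = adj, z = zz,
    direction = ifelse(deg, sign(lfc), 0), deg = deg
  )
}

#' Select highly differentially expressed genes by logFC z-score
#'
#' Standardizes each gene's logFC against the mean and sd of all logFC
#' values and keeps genes with |z| at or above `z_cut` (default 2.58, the
#' two-sided standard-normal critical value at p = 0.01) and |logFC| at
#' or above `lfc_cut` (default 2, i.e. a 4-fold change).
#'
#' @param de a [differential_expression()] result.
#' @param z_cut absolute z-score threshold.
#' @param lfc_cut absolute log2 fold-change threshold.
#' @return tibble of selected genes with `gene`, `logFC`, `z`, `direction`
#'   (sign of logFC).
#' @export
zscore_select <- function(de, z_cut = 2.58, lfc_cut = 2) {
  if (nrow(de) < 2) abort("need at least 2 genes.")
  s <- sd(de$logFC)
  if (!is.finite(s) || s == 0) {
    warn("zero sd of logFC; no gene selected.")
    return(de[0, c("gene", "logFC", "z")])
  }
  out <- de[abs(de$z) >= z_cut & abs(de$logFC) >= lfc_cut,
            c("gene", "logFC", "z")]
  out$direction <- sign(out$logFC)
  out
}

#' Genes with a progressive expression pattern across passages
#'
#' Runs [differential_expression()] for the comparisons (P0,P6), (P0,P2),
#' (P2,P3), (P3,P4), (P4,P5) and (P5,P6). A gene is progressive iff it is
#' a DEG for P0-P6 and every step comparison is either non-significant
#' (stable states are allowed) or significant in the same direction.
#' Three labelled subsets are returned: all progressive genes, and the
#' progressive genes additionally DEG in the late steps P4-P5 or P5-P6;
#' `selected` is the union of the two late-passage-restricted subsets,
#' which targets genes still actively changing in late passages.
#'
#' @inheritParams differential_expression
#' @return list of class `progressive_result`: character vectors
#'   `progressive_all`, `progressive_p4p5`, `progressive_p5p6`,
#'   `selected`, plus `directions` (named +1/-1 for progressive genes)
#'   and `table` (per-gene per-comparison significance codes).
#' @export
progressive_genes <- function(panel, group = NULL, alpha = 0.01) {
  stopifnot(inherits(panel, "expression_panel"))
  steps <- list(c("P0", "P6"), c("P0", "P2"), c("P2", "P3"),
                c("P3", "P4"), c("P4", "P5"), c("P5", "P6"))
  have <- unique(panel$meta$passage[panel_samples(panel, paste0("P", 0:6), group)])
  needed <- unique(unlist(steps))
  miss <- setdiff(needed, have)
  if (length(miss))
    abort(sprintf("missing passage(s): %s", paste(miss, collapse = ", ")))
  de <- purrr::map(steps, function(s)
    differential_expression(panel, s[1], s[2], group = group, alpha = alpha))
  names(de) <- purrr::map_chr(steps, paste, collapse = "_")
  genes <- de[[1]]$gene
  dir_mat <- vapply(de, function(d) d$direction[match(genes, d$gene)],
                    numeric(length(genes)))
  anchor <- dir_mat[, "P0_P6"]
  # same-direction rule: every step is 0 (stable) or equals the P0-P6 sign
  consistent <- anchor != 0
  for (k in 2:ncol(dir_mat)) {
    consistent <- consistent & (dir_mat[, k] == 0 | dir_mat[, k] == anchor)
  }
  prog <- genes[consistent]
  p45 <- genes[consistent & dir_mat[, "P4_P5"] != 0]
  p56 <- genes[consistent & dir_mat[, "P5_P6"] != 0]
  structure(
    list(
      progressive_all = prog,
      progressive_p4p5 = p45,
      progressive_p5p6 = p56,
      selected = union(p45, p56),
      directions = setNames(anchor[consistent], prog),
      table = tibble(gene = genes) |>
        dplyr::bind_cols(as_tibble(dir_mat))
    ),
    class = "progressive_result"
  )
}

#' @export
print.progressive_result <- function(x, ...) {
  cat(sprintf(
    "<progressive_result> %d progressive (%d also DEG P4-P5, %d also DEG P5-P6; %d selected)\n",
    length(x$progressive_all), length(x$progressive_p4p5),
    length(x$progressive_p5p6), length(x$selected)))
  invisible(x)
}

#' PCA contribution filter
#'
#' Centered PCA over samples; a gene's contribution to a component is its
#' squared loading normalized so contributions sum to 1 over genes. Keeps
#' genes whose contribution exceeds the mean contribution (1 / n_genes)
#' on PC1 or PC2 (`combine = "union"`, default) or on both
#' (`combine = "intersection"`).
#'
#' @inheritParams differential_expression
#' @param combine `"union"` or `"intersection"` of the PC1/PC2 selections.
#' @return character vector of selected gene symbols.
#' @export
pca_contribution_filter <- function(panel, combine = c("union", "intersection")) {
  stopifnot(inherits(panel, "expression_panel"))
  combine <- match.arg(combine)
  if (ncol(panel$expr) < 3) abort("need at least 3 samples for PCA.")
  keep_var <- apply(panel$expr, 1, sd) > 0
  if (!any(keep_var)) abort("constant expression matrix: PCA undefined.")
  pc <- prcomp(t(panel$expr), center = TRUE, scale. = FALSE)
  load2 <- pc$rotation[, 1:2, drop = FALSE]^2
  contrib <- sweep(load2, 2, colSums(load2), "/")
  thr <- 1 / nrow(panel$expr) # mean contribution
  # genes absent from the rotation (zero variance never happens here since
  # prcomp keeps all rows) -- contributions of flat genes are exactly 0
  on1 <- contrib[, 1] > thr
  on2 <- contrib[, 2] > thr
  sel <- if (combine == "union") on1 | on2 else on1 & on2
  rownames(contrib)[sel]
}

#' Map mouse gene symbols to human symbols
#'
#' Expands one-to-many mappings, drops unmapped genes, deduplicates while
#' preserving the original order, and reports the counts.
#'
#' @param genes character vector of mouse gene symbols.
#' @param mapping data frame with columns `mouse` and `human`.
#' @return list with `human` (character vector), `n_unmapped`, and
#'   `report` (tibble mouse -> human for the mapped genes).
#' @export
map_orthologs <- function(genes, mapping) {
  mapping <- as_tibble(mapping)
  if (!all(c("mouse", "human") %in% names(mapping)) || nrow(mapping) == 0)
    abort("`mapping` must be a non-empty table with columns mouse, human.")
  hits <- dplyr::inner_join(tibble(mouse = genes), mapping, by = "mouse",
                            relationship = "many-to-many")
  human <- unique(hits$human)
  list(
    human = human,
    n_unmapped = sum(!genes %in% mapping$mouse),
    report = hits
  )
}
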