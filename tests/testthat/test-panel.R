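test_that("differential_expression is calibrated under the null and powered", {
  # null: both passages from the same distribution -> uniform raw p
  set.seed(1)
  n_genes <- 2000
  expr <- matrix(rnorm(n_genes * 10, 8, 0.5), nrow = n_genes,
                 dimnames = list(sprintf("G%04d", 1:n_genes), NULL))
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:10),
    passage = rep(c("P0", "P6"), each = 5),
    group = rep(c("parental", "KPT"), each = 5)
  )
  colnames(expr) <- meta$sample_id
  pan <- expression_panel(expr, meta)
  de <- differential_expression(pan, "P0", "P6")
  ks <- stats::ks.test(de$p, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_true(all(de$adj_p >= de$p))
  # power: a 4-within-group-SD shift is flagged as a DEG
  expr2 <- expr
  expr2["G0001", meta$passage == "P6"] <- expr2["G0001", meta$passage == "P6"] + 2
  pan2 <- expression_panel(expr2, meta)
  de2 <- differential_expression(pan2, "P0", "P6")
  expect_true(de2$deg[de2$gene == "G0001"])
  expect_equal(de2$direction[de2$gene == "G0001"], 1)
  expect_equal(de2$logFC[de2$gene == "G0001"],
               mean(expr2["G0001", 6:10]) - mean(expr2["G0001", 1:5]))
  # too few replicates is an error
  expect_error(
    differential_expression(pan, "P0", "P6",
                            group = "nonexistent"), ">= 2 samples")
})

test_that("zscore_select applies the |z| and |logFC| rules", {
  # one outlying gene among tight null logFCs
  set.seed(2)
  de <- tibble::tibble(gene = sprintf("g%d", 1:1000),
                       logFC = c(rnorm(999, 0, 0.1), 5))
  de$z <- (de$logFC - mean(de$logFC)) / sd(de$logFC)
  sel <- zscore_select(de)
  expect_equal(sel$gene, "g1000")
  expect_equal(sel$direction, 1)
  # all-identical logFC: nothing selectable
  de2 <- tibble::tibble(gene = c("a", "b", "c"), logFC = c(1, 1, 1),
                        z = c(0, 0, 0))
  expect_warning(sel2 <- zscore_select(de2), "zero sd")
  expect_equal(nrow(sel2), 0)
  # large z but small fold change fails the logFC arm
  de3 <- tibble::tibble(gene = sprintf("g%d", 1:1000),
                        logFC = c(rnorm(999, 0, 0.01), 1))
  de3$z <- (de3$logFC - mean(de3$logFC)) / sd(de3$logFC)
  expect_equal(nrow(zscore_select(de3)), 0)
})

test_that("the default z threshold is the two-sided normal critical value at 0.01", {
  expect_equal(round(qnorm(1 - 0.01 / 2), 2), 2.58)
  expect_equal(formals(zscore_select)$z_cut, 2.58)
})

test_that("progressive_genes keeps monotone genes and drops reversals", {
  cfg <- panel_config(n_genes = 300, n_progressive = 5, increment = 1,
                      noise_sd = 0.2, seed = 4)
  gp <- generate_panel(cfg)
  res <- progressive_genes(gp$panel)
  expect_true(all(gp$truth$gene %in% res$progressive_all))
  expect_equal(res$directions[gp$truth$gene],
               setNames(gp$truth$direction, gp$truth$gene))
  expect_true(all(res$selected %in% res$progressive_all))
  expect_setequal(res$selected,
                  union(res$progressive_p4p5, res$progressive_p5p6))
  # a gene significantly up overall but reversing mid-way is excluded
  pan <- gp$panel
  rev_gene <- gp$truth$gene[gp$truth$direction == 1][1]
  p23 <- pan$meta$passage %in% c("P2", "P3")
  pan$expr[rev_gene, pan$meta$passage == "P3"] <-
    pan$expr[rev_gene, pan$meta$passage == "P3"] - 4
  res2 <- progressive_genes(pan)
  expect_false(rev_gene %in% res2$progressive_all)
  # flat genes fail the P0-P6 anchor
  flat <- setdiff(rownames(pan$expr), gp$truth$gene)
  expect_lt(mean(flat %in% res$progressive_all), 0.02)
})

test_that("pca_contribution_filter normalizes contributions and finds structure", {
  # toy matrix: 2 informative genes, 2 flat genes, 6 samples
  expr <- rbind(
    g1 = c(0, 0, 0, 4, 4, 4),
    g2 = c(4, 4, 4, 0, 0, 0),
    g3 = rep(1, 6),
    g4 = rep(2, 6)
  ) + 0 # numeric
  colnames(expr) <- paste0("s", 1:6)
  meta <- tibble::tibble(sample_id = paste0("s", 1:6),
                         passage = rep(c("P0", "P6"), each = 3),
                         group = "KPT")
  pan <- expression_panel(expr, meta)
  sel <- pca_contribution_filter(pan)
  # hand-computed eigendecomposition: all variance is on g1/g2; their PC1
  # contributions are 1/2 each, above the mean 1/4; flat genes contribute 0
  expect_setequal(sel, c("g1", "g2"))
  pc <- prcomp(t(expr), center = TRUE)
  contrib1 <- pc$rotation[, 1]^2 / sum(pc$rotation[, 1]^2)
  expect_equal(sum(contrib1), 1)
  expect_equal(unname(contrib1[c("g3", "g4")]), c(0, 0))
  # intersection mode is at least as strict as union
  sel_int <- pca_contribution_filter(pan, combine = "intersection")
  expect_true(all(sel_int %in% sel))
  expect_error(
    pca_contribution_filter(
      expression_panel(matrix(5, 3, 3,
                              dimnames = list(letters[1:3], paste0("s", 1:3))),
                       tibble::tibble(sample_id = paste0("s", 1:3),
                                      passage = "P0", group = "parental"))),
    "constant")
})

test_that("map_orthologs expands, deduplicates and reports drops", {
  tab <- tibble::tibble(mouse = c("Aa", "Bb", "Bb"),
                        human = c("AA", "BB1", "BB2"))
  res <- map_orthologs(c("Aa", "Bb", "Cc", "Aa"), tab)
  expect_equal(res$human, c("AA", "BB1", "BB2"))
  expect_equal(res$n_unmapped, 1) # Cc
  # identity table maps identically
  idt <- tibble::tibble(mouse = c("x", "y"), human = c("x", "y"))
  expect_equal(map_orthologs(c("y", "x"), idt)$human, c("y", "x"))
  expect_error(map_orthologs("x", tibble::tibble()), "non-empty")
})
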