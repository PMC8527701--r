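test_that("tertile_groups splits by rank with remainder to lower groups", {
  expect_equal(as.vector(table(rccmet:::tertile_groups(rnorm(9)))),
               c(3L, 3L, 3L))
  expect_equal(as.vector(table(rccmet:::tertile_groups(rnorm(10)))),
               c(4L, 3L, 3L))
  expect_equal(as.vector(table(rccmet:::tertile_groups(rnorm(11)))),
               c(4L, 4L, 3L))
  # highest scores land in group 3
  s <- c(5, 1, 3, 2, 4, 0)
  grp <- rccmet:::tertile_groups(s)
  expect_equal(grp[s >= 4], c(3L, 3L))
  # ties broken by stable order, sizes preserved
  grp_t <- rccmet:::tertile_groups(rep(1, 7))
  expect_equal(as.vector(table(grp_t)), c(3L, 2L, 2L))
})

test_that("prognostic_gene_filter keeps hazard-linked genes with the right direction", {
  ds <- generate_survival_expression(n_patients = 300, n_genes = 400,
                                     planted_genes = 6,
                                     directions = c(1, 1, 1, -1, -1, -1),
                                     effect = 1.2, seed = 2)
  genes <- c(ds$truth$genes, sprintf("HGENE%04d", 390:399))
  dirs <- setNames(c(ds$truth$directions, rep(1, 10)), genes)
  res <- prognostic_gene_filter(ds$expr, ds$surv, genes, dirs,
                                endpoint = "OS")
  # planted genes pass; null genes fail
  expect_true(all(res$selected[res$gene %in% ds$truth$genes]))
  expect_false(any(res$selected[!res$gene %in% ds$truth$genes]))
  # a protective gene carried with an "up" direction must be excluded:
  # re-test a planted down-gene claiming it is up-regulated
  res_bad <- prognostic_gene_filter(ds$expr, ds$surv, ds$truth$genes[4],
                                    directions = 1, endpoint = "OS")
  expect_false(res_bad$selected)
  expect_lt(res_bad$hr_dc, 1)
})

test_that("score_signature scores by mean expression and stratifies", {
  ds <- generate_survival_expression(n_patients = 300, n_genes = 400,
                                     planted_genes = 8, effect = 1.2,
                                     seed = 3)
  sig <- gene_signature("planted", ds$truth$genes)
  res <- score_signature(sig, ds$expr, ds$surv, endpoint = "OS")
  expect_gt(res$hr, 2)
  expect_lt(res$logrank_p_2arm, 0.01)
  expect_lt(res$logrank_p_3arm, 0.01)
  expect_true(res$hr_ci_low <= res$hr && res$hr <= res$hr_ci_high)
  # single-gene signature scores with the gene's own expression
  sg <- gene_signature("one", ds$truth$genes[1])
  res1 <- score_signature(sg, ds$expr, ds$surv, endpoint = "OS")
  expect_equal(res1$n_genes_used, 1)
  # M0 restriction filters the evaluated samples
  surv_m1 <- ds$surv
  surv_m1$m_stage[1:50] <- "M1"
  res_m0 <- score_signature(sig, ds$expr, surv_m1, endpoint = "DFS",
                            m0_only = TRUE)
  expect_equal(length(attr(res_m0, "groups")), 250)
  expect_error(score_signature(gene_signature("none", "NOPE"),
                               ds$expr, ds$surv), "present")
})

test_that("empirical signature p-value separates signal from noise", {
  ds <- generate_survival_expression(n_patients = 250, n_genes = 500,
                                     planted_genes = 8, effect = 1.2,
                                     seed = 4)
  sig <- gene_signature("planted", ds$truth$genes)
  res <- empirical_signature_pvalue(sig, ds$expr, ds$surv, endpoint = "OS",
                                    n_random = 200, seed = 1)
  expect_lte(res$empirical_p, 0.05)
  # determinism
  res2 <- empirical_signature_pvalue(sig, ds$expr, ds$surv, endpoint = "OS",
                                     n_random = 200, seed = 1)
  expect_identical(res, res2)
  # null dataset: random signatures score uniformly (mean ~ 0.5)
  ds0 <- generate_survival_expression(n_patients = 150, n_genes = 300,
                                      planted_genes = 5, effect = 0,
                                      seed = 5)
  set.seed(6)
  emp <- vapply(1:25, function(b) {
    gs <- sample(rownames(ds0$expr), 8)
    empirical_signature_pvalue(gene_signature("rand", gs), ds0$expr,
                               ds0$surv, endpoint = "OS", n_random = 60,
                               seed = b)$empirical_p
  }, numeric(1))
  expect_gt(mean(emp), 0.3)
  expect_lt(mean(emp), 0.7)
})

test_that("the discovery chain recovers planted progressive prognostic genes", {
  # one seed end-to-end: panel -> DE z-score + progressive -> orthologs ->
  # prognostic filter (the multi-seed version runs in the acceptance suite)
  gp <- generate_panel(panel_config(n_genes = 800, n_progressive = 12,
                                    seed = 7))
  de <- differential_expression(gp$panel, "P0", "P6")
  zsel <- zscore_select(de)
  prog <- progressive_genes(gp$panel)
  mouse_candidates <- union(zsel$gene, prog$selected)
  recovered_mouse <- mean(gp$truth$gene %in% mouse_candidates)
  expect_gte(recovered_mouse, 0.8)
  tab <- toy_ortholog_table(800)
  mapped <- map_orthologs(mouse_candidates, tab)
  dirs_mouse <- setNames(sign(de$logFC[match(mouse_candidates, de$gene)]),
                         mouse_candidates)
  human_dirs <- setNames(unname(dirs_mouse[mapped$report$mouse]),
                         mapped$report$human)[mapped$human]
  planted_human <- sprintf("HGENE%04d",
                           as.integer(sub("Gene", "", gp$truth$gene)))
  ds <- generate_survival_expression(
    n_patients = 300, n_genes = 800, planted_genes = planted_human,
    directions = unname(human_dirs[planted_human]), effect = 1.2, seed = 8)
  res <- suppressWarnings(
    prognostic_gene_filter(ds$expr, ds$surv, mapped$human,
                           human_dirs, endpoint = "OS"))
  final <- res$gene[res$selected]
  expect_gte(mean(planted_human %in% final), 0.8)
  false_disc <- mean(!final %in% planted_human)
  expect_lte(false_disc, 0.1)
})
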