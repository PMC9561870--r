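test_that("rank test matches exact enumeration and handles degenerate input", {
  expect_equal(rank_test(c(1, 2, 3), c(10, 11, 12)), enum_rank_p(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(enum_rank_p(c(1, 2, 3), c(10, 11, 12)), 2 * 1 / 20) # C(6,3)=20 splits
  expect_equal(rank_test(c(5, 5, 5), c(5, 5, 5, 5)), 1)
  expect_equal(rank_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(rank_test(numeric(0), 1), "non-empty")
  # symmetry
  set.seed(61)
  for (i in 1:10) {
    a <- rnorm(7)
    b <- rnorm(5)
    expect_equal(rank_test(a, b), rank_test(b, a))
  }
})

test_that("significance needs both >20% change and adjusted p < 0.05", {
  # 15% change with a vanishing p-value: never significant
  n <- 300
  counts <- rbind(
    g = c(rep(100, n), rep(115, n)),
    rest = c(rep(9900, n), rep(9885, n)),
    other = 5
  )
  colnames(counts) <- paste0("c", seq_len(2 * n))
  m <- count_matrix(counts)
  de <- differential_expression(
    m, paste0("c", 1:n), paste0("c", (n + 1):(2 * n))
  )
  row <- de[de$gene == "g", ]
  expect_lt(row$p_adj, 1e-10)
  expect_equal(row$fold_change, 1.15, tolerance = 1e-3)
  expect_false(row$significant)

  # small fold with small p, large fold with large p: also not significant
  expect_true(all(!de$significant[de$gene != "g"] | de$pct_change[de$gene != "g"] > 20))
})

test_that("self-contrast yields folds of 1 and no significant genes", {
  m <- simulate_cells(ob_spec(62, n = 120))
  units <- unit_ids(m)
  de <- differential_expression(m, units, units,
    genes = c("Hspa9", "Atf5", "Bg001")
  )
  expect_true(all(de$fold_change == 1))
  expect_true(all(!de$significant))
  expect_true(all(de$p_raw == 1))
})

test_that("a simulated 2-fold effect is detected with an accurate fold estimate", {
  wt <- simulate_cells(ob_spec(63, n = 400))
  het <- simulate_cells(ob_spec(64, genotype = "Het", n = 400),
    dose_responses = list(flat_effect("Hspa9", 2))
  )
  m <- merge_matrices(list(wt, het))
  de <- differential_expression(
    m, unit_ids(wt), paste0(unit_ids(het), "-2"),
    genes = gene_names(m)
  )
  row <- de[de$gene == "Hspa9", ]
  expect_true(row$significant)
  expect_equal(row$fold_change, 2, tolerance = 0.2)
})

test_that("Bonferroni uses the per-call denominator and folds invert on swap", {
  m <- simulate_cells(ob_spec(65, n = 100))
  a <- unit_ids(m)[1:50]
  b <- unit_ids(m)[51:100]
  genes <- c("Hspa9", "Atf5", "Hspa5", "Bg001", "Bg002")
  de <- differential_expression(m, a, b, genes = genes)
  expect_equal(de$p_adj, pmin(1, de$p_raw * length(genes)))
  de_swap <- differential_expression(m, b, a, genes = genes)
  ok <- de$flag == "ok"
  expect_equal(de$fold_change[ok], 1 / de_swap$fold_change[ok], tolerance = 1e-12)
  expect_equal(de$p_raw, de_swap$p_raw)
})

test_that("all-zero genes are flagged with p = 1, never dropped", {
  counts <- rbind(dead = 0, g1 = rand_counts(1, 12, seed = 66), g2 = 5)
  rownames(counts) <- c("dead", "g1", "g2")
  m <- count_matrix(counts)
  de <- differential_expression(m, paste0("u", 1:6), paste0("u", 7:12))
  row <- de[de$gene == "dead", ]
  expect_equal(row$p_raw, 1)
  expect_true(is.na(row$fold_change))
  expect_equal(row$flag, "zero_both")
  expect_false(row$significant)
})

test_that("group-size floor guards degenerate inputs", {
  m <- count_matrix(rand_counts(4, 6, seed = 67))
  expect_error(
    differential_expression(m, "u1", paste0("u", 2:6)), ">= 3 units"
  )
})

test_that("the cross-tissue filter applies its four criteria with a trace", {
  mk <- function(genes, fold, p_adj, sig = NULL) {
    if (is.null(sig)) sig <- p_adj < 0.05 & abs(fold - 1) * 100 > 20
    data.frame(
      gene = genes, mean_A = 1, mean_B = fold, fold_change = fold,
      pct_change = abs(fold - 1) * 100, p_raw = p_adj, p_adj = p_adj,
      significant = sig, flag = "ok", stringsAsFactors = FALSE
    )
  }
  genes <- c("pass", "weakfold", "unreplicated", "unannotated")
  tables <- list(
    hom_e18 = mk(genes, fold = c(2.5, 1.8, 2.4, 3.0), p_adj = 0.001),
    het_p5 = mk(genes, fold = c(1.6, 1.7, 1.5, 1.8), p_adj = 0.002),
    p5_exp1 = mk(genes, fold = c(1.4, 1.5, 1.3, 1.4), p_adj = 0.01),
    p5_exp2 = mk(genes, fold = c(1.3, 1.4, 0.8, 1.5), p_adj = 0.01)
  )
  annotation <- data.frame(
    gene = c("pass", "pass", "weakfold", "weakfold", "unreplicated", "unreplicated"),
    category = c("stress", "metab", "stress", "mito", "stress", "ECM")
  )
  res <- cross_tissue_filter(
    tables,
    required_significant_contrasts = c("hom_e18", "het_p5"),
    min_fold_contrast = "hom_e18", min_fold = 2,
    replication_contrasts = c("p5_exp1", "p5_exp2"),
    annotation = annotation, min_categories = 2
  )
  expect_identical(res$genes, "pass")
  tr <- res$trace
  expect_false(tr$fold_floor[tr$gene == "weakfold"]) # 1.8-fold < 2
  expect_false(tr$replicated[tr$gene == "unreplicated"]) # direction flips
  expect_equal(tr$n_categories[tr$gene == "unannotated"], 0L)

  # empty annotation removes everything when categories are required
  res0 <- cross_tissue_filter(
    tables,
    required_significant_contrasts = "hom_e18",
    min_fold_contrast = "hom_e18",
    annotation = NULL, min_categories = 1
  )
  expect_length(res0$genes, 0)
  expect_error(
    cross_tissue_filter(tables, "nope", "hom_e18"), "missing"
  )
})

test_that("downregulated genes can pass the fold floor in either direction", {
  tab <- data.frame(
    gene = c("up", "down"), mean_A = c(1, 1), mean_B = c(2.2, 0.4),
    fold_change = c(2.2, 0.4), pct_change = c(120, 60),
    p_raw = 0.001, p_adj = 0.001, significant = TRUE, flag = "ok"
  )
  res <- cross_tissue_filter(
    list(only = tab),
    required_significant_contrasts = "only",
    min_fold_contrast = "only", min_fold = 2,
    min_categories = 0
  )
  expect_setequal(res$genes, c("up", "down"))
})
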