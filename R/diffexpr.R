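#' Two-sided Wilcoxon rank-sum test between two expression groups
#'
#' Thin, guarded wrapper around the standard rank-sum test. With no ties
#' and both groups of 50 or fewer values the exact permutation
#' distribution is used; otherwise the normal approximation with midrank
#' tie correction and continuity correction. Degenerate inputs where
#' every value is identical across both groups return p = 1.
#'
#' @param a,b numeric vectors of per-unit %UMI values (both non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact distribution;
#'   `NULL` (default) decides as above.
#' @return The two-sided p-value.
#' @export
rank_test <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Group-vs-group differential expression with UMI-weighted means
#'
#' For each gene: UMI-weighted (pooled-fraction) mean %UMI in each group,
#' fold change B/A, percent change |fold - 1| x 100, a per-cell rank-sum
#' test on %UMI values, Bonferroni correction over the genes tested in
#' this call, and the significance rule: more than `min_pct_change`%
#' change with adjusted p below `alpha` (defaults 20% and 0.05). A gene
#' with zero counts in both groups gets p = 1 and an undefined fold; a
#' gene expressed only in B gets an undefined fold and can become
#' significant only in `pseudocount` mode, which adds a small constant to
#' both means before forming the ratio.
#'
#' @param m a `CountMatrix`.
#' @param units_A,units_B unit-id vectors for the two groups (group A is
#'   the reference, e.g. WT).
#' @param genes genes to test (default: all genes in `m`); the Bonferroni
#'   denominator is `length(genes)`.
#' @param alpha significance level applied to the adjusted p-value.
#' @param min_pct_change percent-change floor of the significance rule.
#' @param min_group_size floor on both group sizes (default 3).
#' @param pseudocount optional %UMI pseudocount for fold changes with a
#'   zero denominator (`NULL`, the default, leaves them undefined).
#' @return A `DETable` data.frame: `gene`, `mean_A`, `mean_B`,
#'   `fold_change`, `pct_change`, `p_raw`, `p_adj`, `significant`,
#'   `flag` (`"ok"`, `"zero_both"`, `"zero_reference"`).
#' @export
differential_expression <- function(m, units_A, units_B, genes = NULL,
                                    alpha = 0.05, min_pct_change = 20,
                                    min_group_size = 3,
                                    pseudocount = NULL) {
  m <- assert_count_matrix(m)
  if (length(units_A) < min_group_size || length(units_B) < min_group_size) {
    stop(sprintf(
      "both groups need >= %d units (got %d and %d)",
      min_group_size, length(units_A), length(units_B)
    ), call. = FALSE)
  }
  if (is.null(genes)) genes <- gene_names(m)
  require_genes(m, genes)
  p <- to_percent_umi(subset_units(m, units = unique(c(units_A, units_B))))
  mean_A <- pooled_fraction(m, units_A, genes)
  mean_B <- pooled_fraction(m, units_B, genes)
  n_tested <- length(genes)
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    a <- p$values[g, units_A]
    b <- p$values[g, units_B]
    if (mean_A[i] == 0 && mean_B[i] == 0) {
      return(data.frame(
        gene = g, mean_A = 0, mean_B = 0, fold_change = NA_real_,
        pct_change = NA_real_, p_raw = 1, flag = "zero_both",
        stringsAsFactors = FALSE
      ))
    }
    p_raw <- rank_test(a, b)
    if (mean_A[i] == 0) {
      fold <- if (is.null(pseudocount)) NA_real_ else
        (mean_B[i] + pseudocount) / (mean_A[i] + pseudocount)
      flag <- "zero_reference"
    } else {
      fold <- mean_B[i] / mean_A[i]
      flag <- "ok"
    }
    data.frame(
      gene = g, mean_A = mean_A[i], mean_B = mean_B[i], fold_change = fold,
      pct_change = if (is.na(fold)) NA_real_ else abs(fold - 1) * 100,
      p_raw = p_raw, flag = flag, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- pmin(1, tab$p_raw * n_tested)
  tab$significant <- !is.na(tab$pct_change) &
    tab$pct_change > min_pct_change & tab$p_adj < alpha
  tab[, c(
    "gene", "mean_A", "mean_B", "fold_change", "pct_change",
    "p_raw", "p_adj", "significant", "flag"
  )]
}

#' Cross-tissue four-criterion gene filter
#'
#' Reduces a set of differential-expression tables to the genes robustly
#' affected by the mutation across tissues and experiments:
#' (i) significant in every contrast named in
#' `required_significant_contrasts`; (ii) at least `min_fold` change
#' (in either direction) in the `min_fold_contrast`; (iii) same-direction
#' fold change in every contrast named in `replication_contrasts`
#' (reproducibility across independent experiments); (iv) membership in
#' at least `min_categories` functional categories of the annotation
#' table. A gene absent from the annotation table has zero categories and
#' fails (iv) whenever `min_categories` >= 1.
#'
#' @param tables named list of `DETable`s from
#'   [differential_expression()].
#' @param required_significant_contrasts names into `tables` that must
#'   call the gene significant.
#' @param min_fold_contrast name of the contrast carrying the fold floor.
#' @param min_fold fold-change floor (default 2; a fold of f passes when
#'   `f >= min_fold` or `f <= 1/min_fold`).
#' @param replication_contrasts names into `tables` whose fold changes
#'   must agree in direction.
#' @param annotation two-column data.frame (`gene`, `category`),
#'   GO-style membership without any database dependency.
#' @param min_categories minimum number of distinct categories.
#' @return A list with `genes` (character vector passing all criteria)
#'   and `trace` (per-gene logical data.frame of the four criteria).
#' @export
cross_tissue_filter <- function(tables,
                                required_significant_contrasts,
                                min_fold_contrast,
                                min_fold = 2,
                                replication_contrasts = character(),
                                annotation = NULL,
                                min_categories = 2) {
  stopifnot(min_fold >= 1, min_categories >= 0)
  needed <- unique(c(
    required_significant_contrasts, min_fold_contrast, replication_contrasts
  ))
  miss <- setdiff(needed, names(tables))
  if (length(miss)) {
    stop("contrast(s) missing from tables: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene"))))
  get_col <- function(contrast, col) {
    t <- tables[[contrast]]
    stats::setNames(t[[col]], t$gene)[genes]
  }
  crit_i <- Reduce(`&`, lapply(required_significant_contrasts, function(ct) {
    s <- get_col(ct, "significant")
    !is.na(s) & s
  }))
  f <- get_col(min_fold_contrast, "fold_change")
  crit_ii <- !is.na(f) & (f >= min_fold | f <= 1 / min_fold)
  if (length(replication_contrasts)) {
    dirs <- vapply(replication_contrasts, function(ct) {
      sign(get_col(ct, "fold_change") - 1)
    }, numeric(length(genes)))
    dirs <- matrix(dirs, nrow = length(genes))
    crit_iii <- apply(dirs, 1, function(d) {
      !anyNA(d) && all(d != 0) && length(unique(d)) == 1
    })
  } else {
    crit_iii <- rep(TRUE, length(genes))
  }
  n_cat <- rep(0L, length(genes))
  if (!is.null(annotation) && nrow(annotation)) {
    counts <- tapply(
      annotation$category, annotation$gene,
      function(x) length(unique(x))
    )
    hit <- genes %in% names(counts)
    n_cat[hit] <- as.integer(counts[genes[hit]])
  }
  crit_iv <- n_cat >= min_categories
  trace <- data.frame(
    gene = genes,
    significant_everywhere = crit_i,
    fold_floor = crit_ii,
    replicated = crit_iii,
    n_categories = n_cat,
    annotated = crit_iv,
    row.names = NULL, stringsAsFactors = FALSE
  )
  pass <- crit_i & crit_ii & crit_iii & crit_iv
  list(genes = genes[pass], trace = trace)
}
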