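#' Housekeeping-gene relative quantity (RQ) normalization
#'
#' Bulk libraries without UMIs cannot be expressed as %UMI, so each
#' gene's count is divided by the geometric mean of the housekeeping-gene
#' counts in the same replicate — the count-space analogue of the
#' delta-delta-Ct method in qPCR, where averaging Ct values corresponds
#' to a geometric mean of quantities. RQ is exactly invariant to scaling
#' every count in a replicate by a constant (sequencing depth).
#'
#' @param bulk genes x replicates matrix of non-negative counts with row
#'   (gene) and column (replicate) names, e.g. from [simulate_bulk()] or
#'   [read_bulk_counts()].
#' @param housekeeping housekeeping gene names (default Actg1, Actb,
#'   Mrfap1, Sdha); every one must have count > 0 in every replicate.
#' @return An `RQTable` data.frame in long form: `gene`, `replicate`,
#'   `rq`, plus `genotype` when the matrix carries a `"genotype"`
#'   attribute.
#' @export
compute_rq <- function(bulk, housekeeping = c("Actg1", "Actb", "Mrfap1", "Sdha")) {
  bulk <- as.matrix(bulk)
  miss <- setdiff(housekeeping, rownames(bulk))
  if (length(miss)) {
    stop("housekeeping gene(s) absent: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  hk <- bulk[housekeeping, , drop = FALSE]
  zero <- which(hk == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    stop(sprintf(
      "housekeeping gene %s has zero count in replicate %s",
      rownames(hk)[zero[1, 1]], colnames(bulk)[zero[1, 2]]
    ), call. = FALSE)
  }
  denom <- apply(hk, 2, geometric_mean)
  rq <- sweep(bulk, 2, denom, "/")
  out <- data.frame(
    gene = rep(rownames(bulk), times = ncol(bulk)),
    replicate = rep(colnames(bulk), each = nrow(bulk)),
    rq = as.vector(rq),
    stringsAsFactors = FALSE
  )
  if (!is.null(attr(bulk, "genotype"))) out$genotype <- attr(bulk, "genotype")
  out
}

#' Read / write bulk count tables
#'
#' Plain TSV, genes in rows (first column `gene`), one column per
#' replicate.
#'
#' @param path TSV file.
#' @return For `read_bulk_counts()`, a genes x replicates integer matrix.
#' @export
read_bulk_counts <- function(path) {
  tab <- utils::read.table(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_bulk_counts
#' @param bulk genes x replicates count matrix.
#' @export
write_bulk_counts <- function(bulk, path) {
  tab <- data.frame(gene = rownames(bulk), bulk, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate housekeeping candidates against single-cell data
#'
#' A usable housekeeping gene must be (a) stable across cells — low
#' coefficient of variation of %UMI pooled over genotypes — and (b)
#' genotype-neutral — no detectable expression difference between the
#' genotype groups by the rank-sum test. Candidates absent from the gene
#' universe fail with an explicit reason.
#'
#' @param sc a single-cell `CountMatrix`.
#' @param candidates candidate gene names.
#' @param groups named list of two unit-id vectors (the genotype
#'   partition).
#' @param stability_ceiling maximum CV of %UMI (default 1.0).
#' @param alpha genotype-neutrality level: the candidate fails when the
#'   rank-sum p-value falls below it.
#' @return Data.frame: `gene`, `stability_score` (CV), `genotype_effect_p`,
#'   `passes`, `reason`.
#' @export
validate_housekeeping <- function(sc, candidates, groups,
                                  stability_ceiling = 1.0, alpha = 0.05) {
  sc <- assert_count_matrix(sc)
  stopifnot(length(groups) == 2)
  if (!length(candidates)) {
    return(data.frame(
      gene = character(), stability_score = numeric(),
      genotype_effect_p = numeric(), passes = logical(),
      reason = character(), stringsAsFactors = FALSE
    ))
  }
  all_units <- unlist(groups, use.names = FALSE)
  p <- to_percent_umi(subset_units(sc, units = all_units))
  rows <- lapply(candidates, function(g) {
    if (!g %in% gene_names(sc)) {
      return(data.frame(
        gene = g, stability_score = NA_real_, genotype_effect_p = NA_real_,
        passes = FALSE, reason = "absent from gene universe",
        stringsAsFactors = FALSE
      ))
    }
    v <- gene_percent_umi(p, g)
    cv <- if (mean(v) > 0) stats::sd(v) / mean(v) else Inf
    pg <- rank_test(
      gene_percent_umi(p, g, groups[[1]]),
      gene_percent_umi(p, g, groups[[2]])
    )
    stable <- cv <= stability_ceiling
    neutral <- pg > alpha
    data.frame(
      gene = g, stability_score = cv, genotype_effect_p = pg,
      passes = stable && neutral,
      reason = if (stable && neutral) {
        "ok"
      } else if (!stable) {
        "unstable across cells"
      } else {
        "genotype effect detected"
      },
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Dual parametric / non-parametric significance test on RQ values
#'
#' Runs both a two-tailed heteroscedastic (Welch) t-test and a
#' Mann-Whitney U-test between two groups of RQ values, since bulk RQ
#' data does not reliably pass normality checks. The significance call
#' follows the pipeline rule — more than `min_pct_change`% change in the
#' group means with t-test p below `alpha` — and a `discordant` flag
#' records when the two tests disagree at `alpha` (the "#" annotation
#' case). A Shapiro-Wilk p-value per group is reported as a diagnostic
#' only. Zero variance in both groups with equal means yields p_t = 1
#' with a flag.
#'
#' @param rq_A,rq_B numeric RQ values (A = reference group; >= 2 values
#'   per group for the t-test).
#' @param alpha significance level (default 0.05).
#' @param min_pct_change percent-change floor (default 20).
#' @return One-row data.frame: `mean_A`, `mean_B`, `pct_change`, `p_t`,
#'   `p_u`, `significant`, `discordant`, `shapiro_A`, `shapiro_B`,
#'   `flag`.
#' @export
dual_test <- function(rq_A, rq_B, alpha = 0.05, min_pct_change = 20) {
  if (length(rq_A) < 2 || length(rq_B) < 1) {
    stop("need >= 2 reference values and >= 1 test value", call. = FALSE)
  }
  degenerate <- stats::sd(rq_A) == 0 &&
    (length(rq_B) < 2 || stats::sd(rq_B) == 0) &&
    mean(rq_A) == mean(rq_B)
  p_t <- if (degenerate) {
    1
  } else {
    tryCatch(
      stats::t.test(rq_A, rq_B, var.equal = FALSE)$p.value,
      error = function(e) NA_real_
    )
  }
  p_u <- rank_test(rq_A, rq_B)
  shapiro <- function(x) {
    if (length(x) >= 3 && stats::sd(x) > 0) {
      stats::shapiro.test(x)$p.value
    } else {
      NA_real_
    }
  }
  mean_A <- mean(rq_A)
  mean_B <- mean(rq_B)
  pct <- if (mean_A > 0) abs(mean_B / mean_A - 1) * 100 else NA_real_
  data.frame(
    mean_A = mean_A, mean_B = mean_B, pct_change = pct,
    p_t = p_t, p_u = p_u,
    significant = !is.na(pct) && !is.na(p_t) &&
      pct > min_pct_change && p_t < alpha,
    discordant = !is.na(p_t) && !is.na(p_u) &&
      ((p_t < alpha) != (p_u < alpha)),
    shapiro_A = shapiro(rq_A), shapiro_B = shapiro(rq_B),
    flag = if (degenerate) "zero_variance" else "ok",
    stringsAsFactors = FALSE
  )
}
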