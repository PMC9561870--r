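#' Running-average expression profile along a covariate gradient
#'
#' Sorts cells by a covariate gene's %UMI (Col1a1 by default; ties broken
#' by unit id for determinism) and slides a window of `window_size` cells
#' advancing by `stride`. Each window's value is the UMI-weighted
#' (pooled-fraction) mean of the target gene over its member cells; the
#' trailing partial window is dropped. With `window_size = 1` the profile
#' is just the per-cell %UMI sequence.
#'
#' @param m a `CountMatrix`.
#' @param units unit ids to profile (at least `window_size` of them).
#' @param gene target gene.
#' @param covariate covariate gene (default `"Col1a1"`).
#' @param window_size cells per window (default 20).
#' @param stride window advance in cells (default 1).
#' @return A `TrajectoryProfile`: list with `gene`, `covariate`,
#'   `window_size`, `stride`, `windows` (data.frame: `index`,
#'   `covariate_mean`, `value`, `sd`, `start`), and `cells` (the sorted
#'   per-cell table: `unit`, `covariate`, `value`, `gene_count`,
#'   `total`).
#' @export
build_profile <- function(m, units, gene, covariate = "Col1a1",
                          window_size = 20, stride = 1) {
  m <- assert_count_matrix(m)
  require_genes(m, c(gene, covariate))
  stopifnot(window_size >= 1, stride >= 1)
  if (length(units) < window_size) {
    stop(sprintf(
      "window_size %d exceeds the %d units supplied",
      window_size, length(units)
    ), call. = FALSE)
  }
  sub <- subset_units(m, units = units)
  totals <- unit_totals(sub)
  cov_pct <- 100 * as.numeric(sub$counts[covariate, ]) / totals
  ord <- order(cov_pct, unit_ids(sub))
  ids <- unit_ids(sub)[ord]
  gcount <- as.numeric(sub$counts[gene, ids])
  total <- totals[ids]
  cells <- data.frame(
    unit = ids, covariate = cov_pct[ord], value = 100 * gcount / total,
    gene_count = gcount, total = total,
    row.names = NULL, stringsAsFactors = FALSE
  )
  starts <- seq.int(1L, length(ids) - window_size + 1L, by = stride)
  cg <- c(0, cumsum(gcount))
  ct <- c(0, cumsum(total))
  cc <- c(0, cumsum(cells$covariate))
  ends <- starts + window_size - 1L
  value <- 100 * (cg[ends + 1L] - cg[starts]) / (ct[ends + 1L] - ct[starts])
  cov_mean <- (cc[ends + 1L] - cc[starts]) / window_size
  sds <- vapply(
    seq_along(starts),
    function(i) stats::sd(cells$value[starts[i]:ends[i]]),
    numeric(1)
  )
  if (window_size == 1L) sds[] <- 0
  structure(
    list(
      gene = gene, covariate = covariate, window_size = window_size,
      stride = stride,
      windows = data.frame(
        index = seq_along(starts), covariate_mean = cov_mean,
        value = value, sd = sds, start = starts
      ),
      cells = cells
    ),
    class = "TrajectoryProfile"
  )
}

#' @export
print.TrajectoryProfile <- function(x, ...) {
  cat(sprintf(
    "TrajectoryProfile: %s vs %s, %d windows of %d cells (stride %d)\n",
    x$gene, x$covariate, nrow(x$windows), x$window_size, x$stride
  ))
  invisible(x)
}

# Greedy nearest-covariate pairing of two ascending window grids; each
# B-window is used at most once, scanning both in covariate order.
pair_windows <- function(cov_A, cov_B) {
  pairs_a <- integer(0)
  pairs_b <- integer(0)
  j <- 1L
  nB <- length(cov_B)
  for (i in seq_along(cov_A)) {
    if (j > nB) break
    while (j < nB && abs(cov_B[j + 1L] - cov_A[i]) < abs(cov_B[j] - cov_A[i])) {
      j <- j + 1L
    }
    pairs_a <- c(pairs_a, i)
    pairs_b <- c(pairs_b, j)
    j <- j + 1L
  }
  cbind(a = pairs_a, b = pairs_b)
}

#' Compare running-average profiles of two cohorts window by window
#'
#' Builds a trajectory profile per cohort, aligns windows on the
#' covariate axis (greedy nearest-covariate pairing, each window of the
#' second cohort used at most once), and runs a two-sided rank-sum test
#' between the per-cell %UMI values of every aligned window pair. In
#' place of a Bonferroni correction over the heavily overlapping windows,
#' windows are simply *marked* at `alpha_mark` (default p < 0.01) and the
#' expected number of false-positive marks, `n_windows * alpha_mark`, is
#' reported alongside.
#'
#' @param m a `CountMatrix` holding both cohorts.
#' @param units_A,units_B unit ids of the two cohorts (each at least
#'   `window_size`).
#' @param gene,covariate,window_size,stride as in [build_profile()].
#' @param alpha_mark mark threshold on the per-window p-value.
#' @param exact passed to [rank_test()]; the default `FALSE` uses the
#'   tie-corrected normal approximation, appropriate for the heavily
#'   tied 20-vs-20 window comparisons.
#' @return A list with `pairs` (data.frame: window indices, covariate
#'   means, running-average values, `p_raw`, `marked`), `n_windows`,
#'   `n_marked`, `alpha_mark`, `expected_fp`, and the two profiles
#'   (`profile_A`, `profile_B`).
#' @export
compare_profiles <- function(m, units_A, units_B, gene,
                             covariate = "Col1a1", window_size = 20,
                             stride = 1, alpha_mark = 0.01, exact = FALSE) {
  prof_A <- build_profile(m, units_A, gene, covariate, window_size, stride)
  prof_B <- build_profile(m, units_B, gene, covariate, window_size, stride)
  idx <- pair_windows(
    prof_A$windows$covariate_mean, prof_B$windows$covariate_mean
  )
  if (nrow(idx) < 2) {
    stop("fewer than 2 aligned windows; supply larger cohorts", call. = FALSE)
  }
  w <- window_size
  p_raw <- vapply(seq_len(nrow(idx)), function(k) {
    sa <- prof_A$windows$start[idx[k, "a"]]
    sb <- prof_B$windows$start[idx[k, "b"]]
    rank_test(
      prof_A$cells$value[sa:(sa + w - 1L)],
      prof_B$cells$value[sb:(sb + w - 1L)],
      exact = exact
    )
  }, numeric(1))
  pairs <- data.frame(
    window_A = idx[, "a"], window_B = idx[, "b"],
    covariate_A = prof_A$windows$covariate_mean[idx[, "a"]],
    covariate_B = prof_B$windows$covariate_mean[idx[, "b"]],
    value_A = prof_A$windows$value[idx[, "a"]],
    value_B = prof_B$windows$value[idx[, "b"]],
    p_raw = p_raw, marked = p_raw < alpha_mark
  )
  list(
    pairs = pairs,
    n_windows = nrow(pairs),
    n_marked = sum(pairs$marked),
    alpha_mark = alpha_mark,
    expected_fp = nrow(pairs) * alpha_mark,
    profile_A = prof_A, profile_B = prof_B
  )
}

#' Bin-level summary of a trajectory profile
#'
#' The circles-with-error-bars summary: the UMI-weighted mean of the gene
#' over the profile cells falling in one covariate subpopulation bin,
#' paired with the mean per-window standard deviation of the running
#' average across the profile's full covariate range.
#'
#' @param profile a [build_profile()] result.
#' @param label bin label to summarize (e.g. `"mOB"`).
#' @param bins a [subpop_bins()] on the profile's covariate.
#' @return A one-row data.frame: `label`, `n_cells`, `weighted_mean`
#'   (%UMI), `dispersion` (mean per-window SD).
#' @export
summarize_profile_mean <- function(profile, label, bins = subpop_bins()) {
  stopifnot(inherits(profile, "TrajectoryProfile"))
  stopifnot(label %in% bins$labels)
  edges <- bins$edges
  k <- length(edges)
  v <- profile$cells$covariate
  idx <- ifelse(v < edges[1], 1L,
    ifelse(v > edges[k], k + 1L, findInterval(v, edges) + 1L)
  )
  idx[v == edges[k]] <- k
  in_bin <- bins$labels[idx] == label
  if (!any(in_bin)) stop("no profile cells fall in bin ", label, call. = FALSE)
  data.frame(
    label = label,
    n_cells = sum(in_bin),
    weighted_mean = 100 * sum(profile$cells$gene_count[in_bin]) /
      sum(profile$cells$total[in_bin]),
    dispersion = mean(profile$windows$sd)
  )
}
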