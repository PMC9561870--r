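#' Marker-threshold gating configuration
#'
#' Osteoblasts (or osteoblast-enriched spots) are selected operationally:
#' a unit passes when it meets *every* inclusion threshold and sits below
#' *every* exclusion ceiling. Inclusion thresholds carry an explicit
#' scale — raw UMI counts (the usual choice for cells) or %UMI (used for
#' spots) — to remove any ambiguity about the axis they are read on.
#' Exclusion ceilings are always %UMI and strict (`value < max`), e.g.
#' Col2a1 < 0.15 %UMI and Col10a1 < 0.03 %UMI for spots.
#'
#' @param inclusion data.frame with columns `gene`, `min` and optionally
#'   `scale` (`"count"` or `"percent"`, default `"count"`); must be
#'   non-empty.
#' @param exclusion optional data.frame with columns `gene`, `max`
#'   (%UMI ceilings).
#' @param mode `"cell"` or `"spot"` (bookkeeping only; both gate the same
#'   way).
#' @param leakage_cutoff %UMI above which a selected unit counts as
#'   "leaking" an exclusion marker in the gating report (default 0: any
#'   expression).
#' @return A `GatingConfig` list.
#' @export
gating_config <- function(inclusion, exclusion = NULL, mode = c("cell", "spot"),
                          leakage_cutoff = 0) {
  mode <- match.arg(mode)
  inclusion <- as.data.frame(inclusion)
  if (!nrow(inclusion)) stop("inclusion list must be non-empty", call. = FALSE)
  if (is.null(inclusion$scale)) inclusion$scale <- "count"
  stopifnot(
    all(c("gene", "min") %in% colnames(inclusion)),
    all(inclusion$min >= 0),
    all(inclusion$scale %in% c("count", "percent"))
  )
  if (!is.null(exclusion)) {
    exclusion <- as.data.frame(exclusion)
    stopifnot(
      all(c("gene", "max") %in% colnames(exclusion)),
      all(exclusion$max >= 0)
    )
  }
  structure(
    list(
      inclusion = inclusion, exclusion = exclusion, mode = mode,
      leakage_cutoff = leakage_cutoff
    ),
    class = "GatingConfig"
  )
}

#' Default osteoblast gates
#'
#' `ob_cell_gate()` selects cells on raw UMI counts of the four
#' osteoblast markers; `ob_spot_gate()` selects spots on %UMI of the same
#' markers plus the chondrocyte exclusion ceilings (Col2a1 < 0.15,
#' Col10a1 < 0.03 %UMI). Threshold values are configuration entries meant
#' to be tuned per dataset (see [tune_thresholds()]), not fixed truths.
#'
#' @param col1a1,runx2,sp7,ibsp inclusion thresholds for the four markers.
#' @return A [gating_config()].
#' @export
ob_cell_gate <- function(col1a1 = 1, runx2 = 1, sp7 = 1, ibsp = 1) {
  gating_config(
    inclusion = data.frame(
      gene = c("Col1a1", "Runx2", "Sp7", "Ibsp"),
      min = c(col1a1, runx2, sp7, ibsp), scale = "count"
    ),
    mode = "cell"
  )
}

#' @rdname ob_cell_gate
#' @param col2a1,col10a1 %UMI exclusion ceilings for the spot gate.
#' @export
ob_spot_gate <- function(col1a1 = 0.75, runx2 = 0.005, sp7 = 0.005,
                         ibsp = 0.01, col2a1 = 0.15, col10a1 = 0.03) {
  gating_config(
    inclusion = data.frame(
      gene = c("Col1a1", "Runx2", "Sp7", "Ibsp"),
      min = c(col1a1, runx2, sp7, ibsp), scale = "percent"
    ),
    exclusion = data.frame(
      gene = c("Col2a1", "Col10a1"), max = c(col2a1, col10a1)
    ),
    mode = "spot"
  )
}

#' Apply a marker gate to a %UMI matrix
#'
#' A unit is selected iff it meets all inclusion thresholds
#' (`value >= min`, on each threshold's own scale) and all exclusion
#' ceilings (`%UMI < max`, strict). Count-scale thresholds are evaluated
#' on raw counts recovered from the %UMI values and stored totals.
#'
#' @param p a `PercentUMIMatrix` (see [to_percent_umi()]).
#' @param cfg a [gating_config()].
#' @return A list with `selected` (unit ids, in input order) and `report`
#'   (`n_in`, `n_selected`, and per-exclusion-marker leakage: the
#'   fraction of selected units expressing that marker above
#'   `leakage_cutoff`).
#' @export
gate <- function(p, cfg) {
  p <- assert_percent_umi(p)
  stopifnot(inherits(cfg, "GatingConfig"))
  genes_needed <- unique(c(cfg$inclusion$gene, cfg$exclusion$gene))
  miss <- setdiff(genes_needed, rownames(p$values))
  if (length(miss)) {
    stop("gating gene(s) missing from matrix: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- rep(TRUE, ncol(p$values))
  for (i in seq_len(nrow(cfg$inclusion))) {
    g <- cfg$inclusion$gene[i]
    v <- p$values[g, ]
    if (cfg$inclusion$scale[i] == "count") v <- v * p$totals / 100
    # small slack absorbs float error when reconstructing integer counts
    keep <- keep & (v - cfg$inclusion$min[i] > -1e-9)
  }
  if (!is.null(cfg$exclusion)) {
    for (i in seq_len(nrow(cfg$exclusion))) {
      keep <- keep & p$values[cfg$exclusion$gene[i], ] < cfg$exclusion$max[i]
    }
  }
  selected <- colnames(p$values)[keep]
  leakage <- NULL
  if (!is.null(cfg$exclusion) && length(selected)) {
    leakage <- vapply(cfg$exclusion$gene, function(g) {
      mean(p$values[g, selected] > cfg$leakage_cutoff)
    }, numeric(1))
  } else if (!is.null(cfg$exclusion)) {
    leakage <- stats::setNames(
      rep(NA_real_, nrow(cfg$exclusion)), cfg$exclusion$gene
    )
  }
  list(
    selected = selected,
    report = list(
      n_in = ncol(p$values), n_selected = length(selected), leakage = leakage
    )
  )
}

#' Tune inclusion thresholds against exclusion-marker leakage
#'
#' Grid-searches inclusion thresholds for the gate that best excludes
#' contaminating cell types while keeping the osteoblast population. The
#' objective: among candidate threshold sets whose gate retains at least
#' `min_retention` of the units co-expressing every inclusion marker at
#' any positive level, pick the one minimizing total exclusion-marker
#' leakage (sum over markers of the fraction of selected units expressing
#' that marker above `leakage_cutoff`). Ties go to the larger selected
#' set, then to the lexicographically smallest threshold vector.
#'
#' @param p a `PercentUMIMatrix`.
#' @param grid named list: for each inclusion gene, a vector of candidate
#'   thresholds. All combinations are evaluated.
#' @param exclusion_genes markers that selected units should not express
#'   (e.g. Clec3b, Pecam1, Acan, Acta2, Cd68, Cd33).
#' @param min_retention retention floor in (0, 1].
#' @param scale scale of the candidate thresholds (`"count"` or
#'   `"percent"`).
#' @param leakage_cutoff %UMI above which expression counts as leakage.
#' @return A list with `config` (the winning [gating_config()], including
#'   the exclusion markers as reporting entries only), and `diagnostics`
#'   (a data.frame over the grid: thresholds, retention, leakage,
#'   n_selected).
#' @export
tune_thresholds <- function(p, grid, exclusion_genes,
                            min_retention = 0.9, scale = "count",
                            leakage_cutoff = 0) {
  p <- assert_percent_umi(p)
  if (!length(grid)) stop("empty threshold grid", call. = FALSE)
  stopifnot(min_retention > 0, min_retention <= 1)
  inclusion_genes <- names(grid)
  miss <- setdiff(c(inclusion_genes, exclusion_genes), rownames(p$values))
  if (length(miss)) {
    stop("gene(s) missing from matrix: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  # reference population: co-expresses every inclusion marker at all
  ref <- rep(TRUE, ncol(p$values))
  for (g in inclusion_genes) ref <- ref & p$values[g, ] > 0
  n_ref <- sum(ref)
  if (!n_ref) stop("no unit co-expresses all inclusion markers", call. = FALSE)

  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  vals <- lapply(inclusion_genes, function(g) {
    v <- p$values[g, ]
    if (scale == "count") v * p$totals / 100 else v
  })
  names(vals) <- inclusion_genes
  excl_pos <- lapply(exclusion_genes, function(g) {
    p$values[g, ] > leakage_cutoff
  })
  diag_rows <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    keep <- rep(TRUE, ncol(p$values))
    for (g in inclusion_genes) keep <- keep & (vals[[g]] - combos[k, g] > -1e-9)
    retention <- sum(keep & ref) / n_ref
    leak <- if (any(keep)) {
      sum(vapply(excl_pos, function(e) mean(e[keep]), numeric(1)))
    } else {
      NA_real_
    }
    diag_rows[[k]] <- data.frame(
      combos[k, , drop = FALSE],
      retention = retention, leakage = leak, n_selected = sum(keep)
    )
  }
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  ok <- which(diagnostics$retention >= min_retention &
    !is.na(diagnostics$leakage))
  if (!length(ok)) {
    stop(sprintf(
      "no grid point retains >= %.2f of marker-co-expressing units (best: %.3f)",
      min_retention, max(diagnostics$retention)
    ), call. = FALSE)
  }
  # order: leakage asc, n_selected desc, thresholds lexicographic asc
  lex <- do.call(
    order,
    c(
      list(diagnostics$leakage[ok], -diagnostics$n_selected[ok]),
      lapply(inclusion_genes, function(g) diagnostics[ok, g])
    )
  )
  best <- ok[lex[1]]
  cfg <- gating_config(
    inclusion = data.frame(
      gene = inclusion_genes,
      min = as.numeric(diagnostics[best, inclusion_genes]),
      scale = scale
    ),
    exclusion = NULL,
    mode = if (scale == "percent") "spot" else "cell",
    leakage_cutoff = leakage_cutoff
  )
  list(config = cfg, best = diagnostics[best, , drop = FALSE],
    diagnostics = diagnostics)
}

#' Col1a1 subpopulation bins
#'
#' The osteoblast lineage splits on Col1a1 %UMI into early (eOB),
#' differentiating (dOB) and mature (mOB) subpopulations at the printed
#' edges: eOB strictly below 0.75, dOB in the closed interval
#' [0.75, 3.5], mOB strictly above 3.5 — values landing exactly on an
#' edge belong to the middle bin.
#'
#' @param gene covariate gene (default `"Col1a1"`).
#' @param edges strictly increasing %UMI cut points.
#' @param labels bin labels, one more than `edges`.
#' @return A `SubpopulationBins` list.
#' @export
subpop_bins <- function(gene = "Col1a1", edges = c(0.75, 3.5),
                        labels = c("eOB", "dOB", "mOB")) {
  stopifnot(
    length(labels) == length(edges) + 1,
    !is.unsorted(edges, strictly = TRUE)
  )
  structure(
    list(gene = gene, edges = edges, labels = labels),
    class = "SubpopulationBins"
  )
}

#' Assign gated units to Col1a1 subpopulations
#'
#' @param p a `PercentUMIMatrix`.
#' @param selected unit ids to label (typically the output of [gate()]).
#' @param bins a [subpop_bins()].
#' @return Named factor of bin labels, one per selected unit; every unit
#'   receives exactly one label.
#' @export
bin_subpopulations <- function(p, selected, bins = subpop_bins()) {
  p <- assert_percent_umi(p)
  stopifnot(inherits(bins, "SubpopulationBins"))
  v <- gene_percent_umi(p, bins$gene, selected)
  edges <- bins$edges
  k <- length(edges)
  # outer bins are strict; interior values at an edge fall to the middle
  idx <- ifelse(v < edges[1], 1L,
    ifelse(v > edges[k], k + 1L, findInterval(v, edges) + 1L)
  )
  # values exactly at an interior edge: findInterval puts them rightward;
  # the last edge must map into bin k (closed upper bound of the middle)
  idx[v == edges[k]] <- k
  stats::setNames(factor(bins$labels[idx], levels = bins$labels), selected)
}
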