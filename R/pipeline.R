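#' Pipeline configuration
#'
#' One plain, YAML-serializable list holding every tunable threshold of
#' the three analyses: QC filters, the cell and spot gates, the Col1a1
#' subpopulation bins, the differential-expression significance rule, the
#' trajectory settings and the bulk housekeeping panel. Field values
#' default to the study conditions; all are meant to be overridden per
#' dataset through the YAML file.
#'
#' @return Nested named list (class `"PipelineConfig"`).
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    qc = list(
      min_features = 500L, max_features = NULL, max_mito_fraction = 0.10,
      mito_prefix = "mt-", death_markers = c("Apaf1", "Trp53inp1"),
      death_screen_alpha = 0.05
    ),
    cell_gate = list(
      genes = c("Col1a1", "Runx2", "Sp7", "Ibsp"),
      min = c(1, 1, 1, 1), scale = "count"
    ),
    spot_gate = list(
      genes = c("Col1a1", "Runx2", "Sp7", "Ibsp"),
      min = c(0.75, 0.005, 0.005, 0.01), scale = "percent",
      exclusion_genes = c("Col2a1", "Col10a1"),
      exclusion_max = c(0.15, 0.03)
    ),
    bins = list(
      gene = "Col1a1", edges = c(0.75, 3.5),
      labels = c("eOB", "dOB", "mOB")
    ),
    de = list(alpha = 0.05, min_pct_change = 20, min_group_size = 3L,
      bin = "mOB"),
    trajectory = list(window_size = 20L, stride = 1L, alpha_mark = 0.01,
      genes = c("Hspa9", "Atf5", "Hspa5", "Atf4")),
    bulk = list(
      housekeeping = c("Actg1", "Actb", "Mrfap1", "Sdha"),
      exclude_replicates = character(), alpha = 0.05, min_pct_change = 20
    )
  ), class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' Serialization is round-trippable: write, read, write again produces
#' identical YAML.
#'
#' @param path YAML file.
#' @return `read_pipeline_config()` returns a `PipelineConfig`; defaults
#'   fill any field the file omits.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_pipeline_config())
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (sub in names(user[[nm]])) {
        # list-assignment keeps explicit NULLs (e.g. "no feature ceiling")
        cfg[[nm]][sub] <- list(user[[nm]][[sub]])
      }
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  structure(cfg, class = "PipelineConfig")
}

#' @rdname read_pipeline_config
#' @param config a `PipelineConfig`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

as_qc_config <- function(cfg) {
  do.call(qc_config, cfg$qc)
}

as_gating_config <- function(g, mode) {
  gating_config(
    inclusion = data.frame(gene = g$genes, min = g$min, scale = g$scale),
    exclusion = if (!is.null(g$exclusion_genes)) {
      data.frame(gene = g$exclusion_genes, max = g$exclusion_max)
    },
    mode = mode
  )
}

as_bins <- function(cfg) {
  subpop_bins(cfg$bins$gene, cfg$bins$edges, cfg$bins$labels)
}

resolve_input <- function(x) {
  if (inherits(x, "CountMatrix")) x else read_matrix(x)
}

write_artifact <- function(tab, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(tab, file.path(out_dir, name),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
}

finish_run <- function(out_dir, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    seed = config$seed
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  manifest
}

#' Run the single-cell analysis end to end
#'
#' QC-filters each input dataset, merges them without transformation,
#' gates osteoblasts on the marker thresholds, bins them into
#' eOB/dOB/mOB subpopulations, then contrasts every non-WT genotype
#' against WT: differential expression with the weighted-mean /
#' rank-test / Bonferroni rule inside the configured bin, and
#' running-average trajectory comparisons for the configured stress
#' genes. All stages are deterministic given the config.
#'
#' @param inputs list of `CountMatrix` objects or triplet directories;
#'   each must carry a `genotype` column in its unit metadata.
#' @param config a `PipelineConfig`.
#' @param out_dir optional run directory; when given, every intermediate
#'   (QC report, gated barcodes, bin labels, DE tables, trajectory
#'   comparisons) is written as TSV plus a `manifest.tsv` of content
#'   hashes and the seed.
#' @param de_genes genes to test for differential expression (default:
#'   all).
#' @return List: `qc_reports`, `gate` (report + selected ids), `bins`
#'   (per-unit labels), `de` (named DETable list, one per non-WT
#'   genotype), `trajectories` (nested: genotype -> gene ->
#'   [compare_profiles()] result), `manifest`.
#' @export
run_single_cell <- function(inputs, config = default_pipeline_config(),
                            out_dir = NULL, de_genes = NULL) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(inputs, "CountMatrix")) inputs <- list(inputs)
  qc <- as_qc_config(config)
  filtered <- lapply(inputs, function(x) filter_cells(resolve_input(x), qc))
  qc_reports <- do.call(rbind, lapply(filtered, attr, "qc_report"))
  qc_reports <- data.frame(dataset = seq_len(nrow(qc_reports)), qc_reports)
  write_artifact(qc_reports, out_dir, "qc_report.tsv")
  m <- merge_matrices(filtered)
  if (!"genotype" %in% colnames(m$unit_meta)) {
    stop("single-cell stage failed: unit metadata lacks 'genotype'",
      call. = FALSE
    )
  }
  p <- to_percent_umi(m)
  g <- gate(p, as_gating_config(config$cell_gate, "cell"))
  message(sprintf(
    "gate: %d of %d cells selected", g$report$n_selected, g$report$n_in
  ))
  if (!is.null(out_dir)) {
    writeLines(g$selected, file.path(out_dir, "gated_barcodes.txt"))
  }
  bins <- bin_subpopulations(p, g$selected, as_bins(config))
  write_artifact(
    data.frame(barcode = names(bins), bin = as.character(bins)),
    out_dir, "bin_labels.tsv"
  )
  genotype <- m$unit_meta[g$selected, "genotype"]
  others <- setdiff(unique(genotype), "WT")
  de_bin <- config$de$bin
  de <- list()
  trajectories <- list()
  for (gt in others) {
    a <- g$selected[genotype == "WT" & bins == de_bin]
    b <- g$selected[genotype == gt & bins == de_bin]
    de[[gt]] <- differential_expression(
      m, a, b,
      genes = de_genes,
      alpha = config$de$alpha, min_pct_change = config$de$min_pct_change,
      min_group_size = config$de$min_group_size
    )
    write_artifact(de[[gt]], out_dir, sprintf("de_%s_vs_WT_%s.tsv", gt, de_bin))
    message(sprintf(
      "de %s vs WT in %s: %d WT, %d %s cells, %d significant",
      gt, de_bin, length(a), length(b), gt, sum(de[[gt]]$significant)
    ))
    tr_genes <- intersect(config$trajectory$genes, gene_names(m))
    wt_units <- g$selected[genotype == "WT"]
    gt_units <- g$selected[genotype == gt]
    trajectories[[gt]] <- lapply(stats::setNames(tr_genes, tr_genes), function(gene) {
      cmp <- compare_profiles(
        m, wt_units, gt_units, gene,
        covariate = config$bins$gene,
        window_size = config$trajectory$window_size,
        stride = config$trajectory$stride,
        alpha_mark = config$trajectory$alpha_mark
      )
      write_artifact(
        cmp$pairs, out_dir, sprintf("trajectory_%s_%s_vs_WT.tsv", gene, gt)
      )
      cmp
    })
  }
  manifest <- finish_run(out_dir, config)
  list(
    qc_reports = qc_reports, gate = g, bins = bins, de = de,
    trajectories = trajectories, manifest = manifest
  )
}

#' Run the spatial-spot analysis
#'
#' QC-filters spots, gates osteoblast-enriched spots on %UMI inclusion
#' thresholds plus the chondrocyte exclusion ceilings, and contrasts
#' non-WT against WT spots by differential expression. Per-genotype
#' group summaries of the selected spots (the violin-plot statistics)
#' are returned alongside.
#'
#' @param input a spot `CountMatrix` (or triplet directory) whose
#'   metadata carries `genotype` and `x`/`y` coordinates.
#' @param config,out_dir,de_genes as in [run_single_cell()].
#' @return List: `gate`, `de` (possibly empty, with a warning, when too
#'   few spots pass), `summaries` (per genotype x gene: n, weighted
#'   mean), `manifest`.
#' @export
run_spatial <- function(input, config = default_pipeline_config(),
                        out_dir = NULL, de_genes = NULL) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- resolve_input(input)
  if (!all(c("x", "y") %in% colnames(m$unit_meta))) {
    stop("spatial stage failed: spot coordinates (x, y) missing", call. = FALSE)
  }
  m <- filter_cells(m, as_qc_config(config))
  p <- to_percent_umi(m)
  g <- gate(p, as_gating_config(config$spot_gate, "spot"))
  message(sprintf(
    "spot gate: %d of %d spots selected", g$report$n_selected, g$report$n_in
  ))
  if (!is.null(out_dir)) {
    writeLines(g$selected, file.path(out_dir, "gated_spots.txt"))
  }
  if (!g$report$n_selected) {
    warning("no spot passed the gate; nothing to analyze", call. = FALSE)
    manifest <- finish_run(out_dir, config)
    return(list(gate = g, de = list(), summaries = NULL, manifest = manifest))
  }
  genotype <- m$unit_meta[g$selected, "genotype"]
  gene_set <- if (is.null(de_genes)) gene_names(m) else de_genes
  summaries <- do.call(rbind, lapply(unique(genotype), function(gt) {
    units <- g$selected[genotype == gt]
    data.frame(
      genotype = gt, gene = gene_set, n_spots = length(units),
      weighted_mean = pooled_fraction(m, units, gene_set),
      row.names = NULL
    )
  }))
  write_artifact(summaries, out_dir, "spot_group_summaries.tsv")
  de <- list()
  for (gt in setdiff(unique(genotype), "WT")) {
    a <- g$selected[genotype == "WT"]
    b <- g$selected[genotype == gt]
    if (length(a) < config$de$min_group_size ||
      length(b) < config$de$min_group_size) {
      warning(sprintf(
        "too few gated spots for DE (%d WT vs %d %s); skipped",
        length(a), length(b), gt
      ), call. = FALSE)
      next
    }
    de[[gt]] <- differential_expression(
      m, a, b,
      genes = de_genes,
      alpha = config$de$alpha, min_pct_change = config$de$min_pct_change,
      min_group_size = config$de$min_group_size
    )
    write_artifact(de[[gt]], out_dir, sprintf("de_spots_%s_vs_WT.tsv", gt))
  }
  manifest <- finish_run(out_dir, config)
  list(gate = g, de = de, summaries = summaries, manifest = manifest)
}

#' Run the bulk RQ analysis
#'
#' Normalizes each genotype's count table to housekeeping relative
#' quantities and runs the dual t / Mann-Whitney test per gene against
#' the WT group. Replicates named in `config$bulk$exclude_replicates`
#' (e.g. early, pre-steady-state time points) are dropped before
#' normalization.
#'
#' @param counts named list of genes x replicates matrices or TSV paths,
#'   one entry per genotype; must include `"WT"`.
#' @param config,out_dir as in [run_single_cell()].
#' @param genes genes to test (default: all shared genes).
#' @return List: `rq` (long RQTable over genotypes), `tests` (per
#'   genotype: data.frame of [dual_test()] rows per gene), `manifest`.
#' @export
run_bulk <- function(counts, config = default_pipeline_config(),
                     out_dir = NULL, genes = NULL) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!"WT" %in% names(counts)) {
    stop("bulk stage failed: no WT group supplied", call. = FALSE)
  }
  counts <- lapply(counts, function(x) {
    m <- if (is.character(x)) read_bulk_counts(x) else as.matrix(x)
    m[, setdiff(colnames(m), config$bulk$exclude_replicates), drop = FALSE]
  })
  hk <- config$bulk$housekeeping
  rq <- do.call(rbind, lapply(names(counts), function(gt) {
    tab <- compute_rq(counts[[gt]], hk)
    tab$genotype <- gt
    tab
  }))
  write_artifact(rq, out_dir, "rq_table.tsv")
  if (is.null(genes)) {
    genes <- Reduce(intersect, lapply(counts, rownames))
  }
  wt <- rq[rq$genotype == "WT", ]
  tests <- list()
  for (gt in setdiff(names(counts), "WT")) {
    sub <- rq[rq$genotype == gt, ]
    rows <- lapply(genes, function(g) {
      cbind(
        gene = g,
        dual_test(
          wt$rq[wt$gene == g], sub$rq[sub$gene == g],
          alpha = config$bulk$alpha,
          min_pct_change = config$bulk$min_pct_change
        )
      )
    })
    tests[[gt]] <- do.call(rbind, rows)
    write_artifact(tests[[gt]], out_dir, sprintf("bulk_tests_%s_vs_WT.tsv", gt))
  }
  manifest <- finish_run(out_dir, config)
  list(rq = rq, tests = tests, manifest = manifest)
}
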