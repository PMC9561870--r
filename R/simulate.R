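#' Default gene universe for the synthetic bone transcriptome
#'
#' Builds the named gene set the simulator draws from: osteoblast
#' inclusion markers (Col1a1, Runx2, Sp7, Ibsp), contaminating-cell-type
#' exclusion markers (fibroblast Clec3b, endothelial Pecam1, chondrocyte
#' Acan/Col2a1, hypertrophic-chondrocyte Col10a1, smooth-muscle Acta2,
#' macrophage Cd68/Cd33), mitochondrial genes ("mt-" prefix),
#' housekeeping genes (Actg1, Actb, Mrfap1, Sdha), integrated-stress-
#' response genes plus Hspa9/Atf5, ER-UPR genes used as negative controls,
#' cell-death markers (Apaf1, Trp53inp1) and anonymous background genes.
#'
#' @param n_background number of background genes (`Bg001`, ...). The
#'   default 600 makes a typical simulated cell express around 600
#'   features, so the 500-feature QC floor separates intact cells from
#'   shallow libraries; small universes are handy for fast statistical
#'   simulations that skip QC.
#' @return Named list of character vectors by class (`marker`, `exclusion`,
#'   `mito`, `housekeeping`, `stress`, `upr`, `death`, `background`) with
#'   attribute `all` flattening them in a fixed order.
#' @export
gene_universe <- function(n_background = 600) {
  u <- list(
    marker = c("Col1a1", "Runx2", "Sp7", "Ibsp"),
    exclusion = c(
      "Clec3b", "Pecam1", "Acan", "Col2a1", "Col10a1",
      "Acta2", "Cd68", "Cd33"
    ),
    mito = paste0("mt-", c("Co1", "Co2", "Nd1", "Nd2", "Cyb", "Atp6")),
    housekeeping = c("Actg1", "Actb", "Mrfap1", "Sdha"),
    stress = c("Ddit3", "Eif4ebp1", "Trib3", "Nupr1", "Eif3c", "Hspa9", "Atf5"),
    upr = c("Hspa5", "Hsp90b1", "Xbp1", "Atf6", "Atf4"),
    death = c("Apaf1", "Trp53inp1"),
    background = sprintf("Bg%03d", seq_len(n_background))
  )
  attr(u, "all") <- unlist(u, use.names = FALSE)
  u
}

# Baseline expected %UMI shared by all simulated cell types. Background
# genes absorb whatever budget the named genes leave unclaimed.
base_rates <- function(universe) {
  genes <- attr(universe, "all")
  r <- stats::setNames(numeric(length(genes)), genes)
  r[universe$mito] <- 4.0 / length(universe$mito)
  r[c("Actg1", "Actb", "Mrfap1", "Sdha")] <- c(1.5, 2.5, 0.10, 0.15)
  r[c("Ddit3", "Eif4ebp1", "Trib3", "Nupr1", "Eif3c", "Hspa9", "Atf5")] <-
    c(0.05, 0.08, 0.03, 0.20, 0.15, 0.25, 0.05)
  r[c("Hspa5", "Hsp90b1", "Xbp1", "Atf6", "Atf4")] <-
    c(0.40, 0.30, 0.10, 0.03, 0.30)
  r[c("Apaf1", "Trp53inp1")] <- c(0.02, 0.03)
  bg <- universe$background
  r[bg] <- max(100 - sum(r), 0) / length(bg)
  r
}

#' Cell-type expression profiles for the simulator
#'
#' One profile per simulated cell type: expected %UMI per gene
#' (`mean_expression`), the type's marker genes, and per-gene
#' negative-binomial dispersions. The osteoblast profile leaves Col1a1 at
#' zero — each osteoblast draws its own Col1a1 level from the trimodal
#' differentiation gradient in [simulate_cells()]. Contaminant marker
#' expression is disjoint from the osteoblast inclusion markers except for
#' weak fibroblast Col1a1, mimicking periosteal fibroblasts.
#'
#' @param universe a gene universe from [gene_universe()].
#' @param dispersion baseline NB dispersion (1/size) applied to every gene.
#' @return Named list of profiles (lists with `name`, `mean_expression`,
#'   `marker_genes`, `dispersion`).
#' @export
cell_type_profiles <- function(universe = gene_universe(), dispersion = 0.1) {
  base <- base_rates(universe)
  disp <- stats::setNames(
    rep(dispersion, length(base)), names(base)
  )
  make <- function(name, markers, levels) {
    r <- base
    r[names(levels)] <- levels
    list(
      name = name, mean_expression = r,
      marker_genes = markers, dispersion = disp
    )
  }
  list(
    osteoblast = make(
      "osteoblast", c("Col1a1", "Runx2", "Sp7", "Ibsp"),
      c(Runx2 = 0.30, Sp7 = 0.40, Ibsp = 0.50)
    ),
    fibroblast = make("fibroblast", "Clec3b", c(Clec3b = 1.0, Col1a1 = 0.30)),
    endothelial = make("endothelial", "Pecam1", c(Pecam1 = 1.5)),
    chondrocyte = make(
      "chondrocyte", c("Acan", "Col2a1"), c(Acan = 1.2, Col2a1 = 4.0)
    ),
    hypertrophic_chondrocyte = make(
      "hypertrophic_chondrocyte", "Col10a1",
      c(Col10a1 = 3.0, Col2a1 = 1.0, Acan = 0.5)
    ),
    smooth_muscle = make("smooth_muscle", "Acta2", c(Acta2 = 2.5)),
    macrophage = make("macrophage", c("Cd68", "Cd33"), c(Cd68 = 1.0, Cd33 = 0.5))
  )
}

#' Threshold dose-response specification for a stress gene
#'
#' Describes how a gene's expected expression scales with the cell's
#' Col1a1 level: flat (fold 1) below `threshold` %UMI, then log-linear in
#' the covariate up to `max_fold` at `covariate_max`, where it saturates.
#' `genotype_scaling` maps genotype to a response multiplier m applied to
#' the excess fold, `fold = 1 + (m - 1) * (f - 1)`: m = 1 (wild type)
#' forces fold 1 everywhere, m = 2 reproduces the nominal curve, m = 3
#' doubles the excess — making the homozygote response more pronounced
#' than the heterozygote, as observed for Hspa9/Atf5.
#'
#' @param gene responding gene name.
#' @param threshold covariate %UMI at which the response begins (>= 0).
#' @param max_fold fold change reached at `covariate_max` (>= 1).
#' @param covariate_gene covariate gene (default `"Col1a1"`).
#' @param genotype_scaling named multipliers; the WT entry must be 1.
#' @param covariate_max covariate %UMI at which the response saturates.
#' @return A `DoseResponse` list.
#' @export
dose_response <- function(gene, threshold, max_fold,
                          covariate_gene = "Col1a1",
                          genotype_scaling = c(WT = 1, Het = 2, Hom = 3),
                          covariate_max = 8) {
  stopifnot(threshold >= 0, max_fold >= 1, covariate_max > threshold)
  if (is.na(genotype_scaling["WT"]) || genotype_scaling[["WT"]] != 1) {
    stop("genotype_scaling must map WT to 1", call. = FALSE)
  }
  structure(
    list(
      gene = gene, covariate_gene = covariate_gene, threshold = threshold,
      max_fold = max_fold, genotype_scaling = genotype_scaling,
      covariate_max = covariate_max
    ),
    class = "DoseResponse"
  )
}

#' Ground-truth fold change of a dose-response gene
#'
#' @param dr a [dose_response()] object.
#' @param covariate covariate level(s) in %UMI.
#' @param genotype genotype label present in `dr$genotype_scaling`.
#' @return Numeric fold change(s), 1 below threshold.
#' @export
dose_response_fold <- function(dr, covariate, genotype) {
  m <- dr$genotype_scaling[[genotype]]
  f <- rep(1, length(covariate))
  up <- which(covariate > dr$threshold)
  if (length(up)) {
    frac <- if (dr$threshold > 0) {
      log(covariate[up] / dr$threshold) / log(dr$covariate_max / dr$threshold)
    } else {
      covariate[up] / dr$covariate_max
    }
    f[up] <- 1 + (dr$max_fold - 1) * pmin(1, pmax(0, frac))
  }
  1 + (m - 1) * (f - 1)
}

#' Simulation specification (study conditions)
#'
#' Bundles the generative settings every simulator shares. Defaults are
#' the package's fixed study conditions: a bone-tissue mix dominated by
#' osteoblasts with six contaminating cell types, lognormal library sizes
#' around 8000 UMI, a trimodal Col1a1 differentiation gradient whose
#' density modes straddle the 0.75 and 3.5 %UMI subpopulation edges, and a
#' small fraction of high-mitochondrial cells to exercise QC.
#'
#' @param genotype `"WT"`, `"Het"` or `"Hom"`.
#' @param n_cells number of cells (> 0).
#' @param seed integer seed; identical spec + seed gives identical data.
#' @param cell_type_mix named proportions over the profiles (sum to 1).
#' @param library_size lognormal parameters (`meanlog`, `sdlog`).
#' @param col1a1_mixture 3-component lognormal mixture (weights, meanlog,
#'   sdlog) for the osteoblast Col1a1 %UMI gradient.
#' @param mito_elevated_fraction fraction of cells with 4x mitochondrial
#'   load (expected mito fraction around 15%), used to exercise the QC
#'   filter.
#' @param profiles cell-type profiles, see [cell_type_profiles()].
#' @param universe gene universe, see [gene_universe()].
#' @return A `SimulationSpec` list.
#' @export
simulation_spec <- function(genotype = "WT", n_cells = 2000, seed = 1,
                            cell_type_mix = c(
                              osteoblast = 0.70, fibroblast = 0.06,
                              endothelial = 0.06, chondrocyte = 0.06,
                              hypertrophic_chondrocyte = 0.04,
                              smooth_muscle = 0.04, macrophage = 0.04
                            ),
                            library_size = list(
                              meanlog = log(8000), sdlog = 0.35
                            ),
                            col1a1_mixture = list(
                              weights = c(0.30, 0.40, 0.30),
                              meanlog = log(c(0.35, 1.7, 5.5)),
                              sdlog = c(0.45, 0.35, 0.25)
                            ),
                            mito_elevated_fraction = 0.05,
                            profiles = NULL,
                            universe = gene_universe()) {
  if (is.null(profiles)) profiles <- cell_type_profiles(universe)
  stopifnot(
    n_cells > 0,
    genotype %in% c("WT", "Het", "Hom"),
    abs(sum(cell_type_mix) - 1) < 1e-8,
    all(names(cell_type_mix) %in% names(profiles)),
    mito_elevated_fraction >= 0, mito_elevated_fraction <= 1
  )
  structure(
    list(
      genotype = genotype, n_cells = as.integer(n_cells), seed = seed,
      cell_type_mix = cell_type_mix, library_size = library_size,
      col1a1_mixture = col1a1_mixture,
      mito_elevated_fraction = mito_elevated_fraction,
      profiles = profiles, universe = universe
    ),
    class = "SimulationSpec"
  )
}

#' Simulate a single-cell UMI count matrix with known ground truth
#'
#' Draws cell types from the spec's mixture, assigns each osteoblast a
#' latent Col1a1 level from the trimodal lognormal gradient, applies any
#' dose responses to the cell's latent Col1a1, renormalizes expected
#' fractions, and samples negative-binomial UMI counts at the cell's
#' lognormal library size. Ground truth (cell type, latent Col1a1, per-
#' gene true fold, mitochondrial-load flag) is kept in `unit_meta`.
#'
#' @param spec a [simulation_spec()].
#' @param dose_responses list of [dose_response()] objects; each gene and
#'   covariate must exist in the spec's universe.
#' @return A `CountMatrix` (genes x cells).
#' @export
simulate_cells <- function(spec, dose_responses = list()) {
  stopifnot(inherits(spec, "SimulationSpec"))
  genes <- attr(spec$universe, "all")
  for (dr in dose_responses) {
    bad <- setdiff(c(dr$gene, dr$covariate_gene), genes)
    if (length(bad)) {
      stop("dose-response gene(s) not in universe: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  with_local_seed(spec$seed, {
    n <- spec$n_cells
    types <- sample(names(spec$cell_type_mix), n,
      replace = TRUE, prob = spec$cell_type_mix
    )
    libs <- stats::rlnorm(n, spec$library_size$meanlog, spec$library_size$sdlog)
    mito_hi <- stats::runif(n) < spec$mito_elevated_fraction

    rates <- vapply(
      types, function(tp) spec$profiles[[tp]]$mean_expression,
      numeric(length(genes))
    )
    rownames(rates) <- genes

    is_ob <- types == "osteoblast"
    mix <- spec$col1a1_mixture
    col_level <- rep(NA_real_, n)
    if (any(is_ob)) {
      comp <- sample(seq_along(mix$weights), sum(is_ob),
        replace = TRUE, prob = mix$weights
      )
      col_level[is_ob] <- pmin(
        stats::rlnorm(sum(is_ob), mix$meanlog[comp], mix$sdlog[comp]), 15
      )
      rates["Col1a1", is_ob] <- col_level[is_ob]
    }
    if (any(mito_hi)) {
      mt <- spec$universe$mito
      rates[mt, mito_hi] <- rates[mt, mito_hi] * 4
    }
    for (dr in dose_responses) {
      fold <- rep(1, n)
      fold[is_ob] <- dose_response_fold(dr, col_level[is_ob], spec$genotype)
      rates[dr$gene, ] <- rates[dr$gene, ] * fold
    }
    rates <- sweep(rates, 2, colSums(rates), "/")
    mu <- sweep(rates, 2, libs, "*")
    size <- 1 / spec$profiles[[1]]$dispersion[genes]
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = rep(size, ncol(mu))),
      nrow = length(genes),
      dimnames = list(genes, sprintf("cell%05d", seq_len(n)))
    )
    meta <- data.frame(
      genotype = spec$genotype, cell_type = types,
      col1a1_latent = col_level, mito_elevated = mito_hi,
      row.names = colnames(counts), stringsAsFactors = FALSE
    )
    count_matrix(counts, meta)
  })
}

#' Simulate spatial capture spots as mixtures of cells
#'
#' Simulates `cells_per_spot * n_spots` cells with [simulate_cells()] and
#' sums consecutive groups of `cells_per_spot` cells into spots laid out
#' on a rectangular grid — emulating 55-um capture areas that pool the
#' mRNA of up to roughly 10 cells. Spot counts conserve constituent cell
#' counts exactly; the ground-truth composition of each spot (cell-type
#' counts, osteoblast fraction) is retained in `unit_meta`, and the
#' underlying cell-level matrix is attached as attribute `"cells"`.
#'
#' @param spec a [simulation_spec()]; `spec$n_cells` is the cell budget,
#'   giving `floor(n_cells / cells_per_spot)` spots.
#' @param cells_per_spot cells pooled per spot (>= 1, default 10).
#' @param grid integer `c(rows, cols)`; must hold all spots.
#' @param dose_responses as in [simulate_cells()].
#' @return A `CountMatrix` of spots with `row`, `col`, `x`, `y`
#'   coordinates (microns, 100-um pitch) in `unit_meta`.
#' @export
simulate_spots <- function(spec, cells_per_spot = 10, grid = NULL,
                           dose_responses = list()) {
  stopifnot(cells_per_spot >= 1)
  n_spots <- spec$n_cells %/% cells_per_spot
  if (n_spots < 1) stop("n_cells smaller than cells_per_spot", call. = FALSE)
  if (is.null(grid)) grid <- c(ceiling(n_spots / 50), min(n_spots, 50))
  if (prod(grid) < n_spots) {
    stop(sprintf(
      "grid %dx%d cannot hold %d spots", grid[1], grid[2], n_spots
    ), call. = FALSE)
  }
  cells <- simulate_cells(spec, dose_responses)
  use <- seq_len(n_spots * cells_per_spot)
  assignment <- rep(seq_len(n_spots), each = cells_per_spot)
  counts <- cells$counts[, use, drop = FALSE] %*%
    Matrix::sparseMatrix(
      i = seq_along(use), j = assignment, x = 1,
      dims = c(length(use), n_spots)
    )
  spot_ids <- sprintf("spot%04d", seq_len(n_spots))
  dimnames(counts) <- list(gene_names(cells), spot_ids)
  rows <- (seq_len(n_spots) - 1L) %/% grid[2] + 1L
  cols <- (seq_len(n_spots) - 1L) %% grid[2] + 1L
  ob_frac <- as.numeric(tapply(
    cells$unit_meta$cell_type[use] == "osteoblast", assignment, mean
  ))
  meta <- data.frame(
    genotype = spec$genotype, row = rows, col = cols,
    x = cols * 100, y = rows * 100, n_cells = cells_per_spot,
    ob_fraction = ob_frac,
    row.names = spot_ids, stringsAsFactors = FALSE
  )
  m <- count_matrix(counts, meta)
  attr(m, "cells") <- cells
  attr(m, "spot_assignment") <- assignment
  m
}

#' Simulate bulk RNA-seq count replicates from cultured osteoblasts
#'
#' Generates a genes x replicates count table: a fixed osteoblast-culture
#' expression profile (Col1a1 set to a mature level), lognormal library
#' sizes across replicates, and negative-binomial counts. Housekeeping
#' genes keep a genotype-independent expected fraction by construction;
#' genotype effects are injected only through `effects` and only when the
#' spec's genotype is not WT.
#'
#' @param spec a [simulation_spec()]; `library_size` and `seed` are used,
#'   and `genotype` determines whether `effects` apply.
#' @param n_replicates number of replicate libraries (>= 2).
#' @param effects named fold changes (e.g. `c(Hspa9 = 2)`) applied to the
#'   non-WT genotype.
#' @return A plain genes x replicates integer matrix with attribute
#'   `"genotype"`; column names `rep1`, `rep2`, ...
#' @export
simulate_bulk <- function(spec, n_replicates, effects = NULL) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (n_replicates < 2) {
    stop("need at least 2 replicates for downstream tests", call. = FALSE)
  }
  genes <- attr(spec$universe, "all")
  if (!is.null(effects)) {
    bad <- setdiff(names(effects), genes)
    if (length(bad)) {
      stop("effect gene(s) not in universe: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  rates <- spec$profiles$osteoblast$mean_expression
  rates["Col1a1"] <- 4.0
  if (!is.null(effects) && spec$genotype != "WT") {
    rates[names(effects)] <- rates[names(effects)] * effects
  }
  rates <- rates / sum(rates)
  with_local_seed(spec$seed, {
    libs <- stats::rlnorm(
      n_replicates, spec$library_size$meanlog + log(100),
      spec$library_size$sdlog
    )
    size <- 1 / spec$profiles$osteoblast$dispersion[genes]
    mu <- outer(rates[genes], libs)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = as.vector(mu), size = rep(size, n_replicates)),
      nrow = length(genes),
      dimnames = list(genes, paste0("rep", seq_len(n_replicates)))
    )
    attr(counts, "genotype") <- spec$genotype
    counts
  })
}
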