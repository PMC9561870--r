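# Shared fixtures: small simulation specs, random matrices, and the
# brute-force rank-sum oracle used against rank_test().

small_universe <- gene_universe(n_background = 40)
small_profiles <- cell_type_profiles(small_universe)

# Pure-osteoblast spec on the small universe: fast, no QC interference.
ob_spec <- function(seed, genotype = "WT", n = 500,
                    mix = c(osteoblast = 1), mito = 0, ...) {
  simulation_spec(
    genotype = genotype, n_cells = n, seed = seed,
    universe = small_universe, profiles = small_profiles,
    cell_type_mix = mix, mito_elevated_fraction = mito, ...
  )
}

# Dense random Poisson count matrix with names g1..., u1...
rand_counts <- function(n_genes, n_units, seed, lambda = 5) {
  set.seed(seed)
  matrix(
    rpois(n_genes * n_units, lambda) + rep(c(1, 0), length.out = n_genes),
    n_genes, n_units,
    dimnames = list(paste0("g", seq_len(n_genes)), paste0("u", seq_len(n_units)))
  )
}

# Two WT cohorts from the identical generative model, merged; returns the
# merged matrix plus the two unit-id sets.
null_cohorts <- function(seed, n) {
  a <- simulate_cells(ob_spec(seed, n = n))
  b <- simulate_cells(ob_spec(seed + 100000L, n = n))
  m <- merge_matrices(list(a, b))
  list(m = m, a = unit_ids(a), b = paste0(unit_ids(b), "-2"))
}

# Exact two-sided rank-sum p-value by enumeration of all group
# assignments (the independent oracle for rank_test).
enum_rank_p <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nA)])
  splits <- utils::combn(length(pooled), nA)
  w_all <- apply(splits, 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Saturated (threshold ~ 0) dose response: a uniform fold change for
# every osteoblast, useful for simulating plain group effects.
flat_effect <- function(gene, fold) {
  dose_response(gene,
    threshold = 1e-4, max_fold = fold, covariate_max = 2e-4
  )
}
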