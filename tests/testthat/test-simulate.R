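test_that("simulation is deterministic under a fixed seed and leaves global RNG alone", {
  set.seed(999)
  before <- .Random.seed
  m1 <- simulate_cells(ob_spec(5, n = 200))
  expect_identical(.Random.seed, before)
  m2 <- simulate_cells(ob_spec(5, n = 200))
  expect_identical(as.matrix(m1$counts), as.matrix(m2$counts))
  expect_identical(m1$unit_meta, m2$unit_meta)
  m3 <- simulate_cells(ob_spec(6, n = 200))
  expect_false(identical(as.matrix(m1$counts), as.matrix(m3$counts)))
})

test_that("unknown dose-response genes are a configuration error", {
  expect_error(
    simulate_cells(ob_spec(1, n = 10),
      dose_responses = list(dose_response("NotAGene", 1, 2))
    ),
    "not in universe"
  )
  expect_error(dose_response("Hspa9", -1, 2), "threshold")
  expect_error(dose_response("Hspa9", 1, 0.5), "max_fold")
  expect_error(
    dose_response("Hspa9", 1, 2, genotype_scaling = c(WT = 2, Het = 3)),
    "WT"
  )
})

test_that("the Col1a1 gradient is trimodal around the printed bin edges", {
  m <- simulate_cells(ob_spec(7, n = 5000))
  lat <- m$unit_meta$col1a1_latent
  bins <- cut(lat, c(-Inf, 0.75, 3.5, Inf))
  props <- as.numeric(table(bins)) / length(lat)
  # all three subpopulations are well represented
  expect_true(all(props > 0.15))
})

test_that("WT dose-response genes are independent of Col1a1", {
  dr <- dose_response("Hspa9", threshold = 1.5, max_fold = 3)
  m <- simulate_cells(ob_spec(8, n = 5000), dose_responses = list(dr))
  counts <- m$counts
  col <- as.numeric(counts["Col1a1", ])
  tot <- Matrix::colSums(counts)
  # compositional coupling removed: gene fraction of the non-Col1a1 budget
  frac <- as.numeric(counts["Hspa9", ]) / (tot - col)
  r <- cor(frac, 100 * col / tot)
  expect_lt(abs(r), 2.5 / sqrt(length(col)))
  expect_equal(dose_response_fold(dr, c(0.5, 1.5), "WT"), c(1, 1))
})

test_that("dose response is flat below threshold, log-linear above, capped", {
  dr <- dose_response("Hspa9",
    threshold = 1.5, max_fold = 2, covariate_max = 6,
    genotype_scaling = c(WT = 1, Het = 2, Hom = 3)
  )
  expect_equal(dose_response_fold(dr, c(0.1, 1.5), "Hom"), c(1, 1))
  mid <- dose_response_fold(dr, 3, "Het")
  expect_equal(mid, 1 + 1 * log(3 / 1.5) / log(6 / 1.5))
  expect_equal(dose_response_fold(dr, c(6, 10), "Het"), c(2, 2))
  # homozygote excess fold is twice the heterozygote excess
  expect_equal(dose_response_fold(dr, 3, "Hom") - 1, 2 * (mid - 1))

  # below-threshold cells keep the baseline rate: compare realized means
  hom <- simulate_cells(ob_spec(9, genotype = "Hom", n = 4000),
    dose_responses = list(dr)
  )
  wt <- simulate_cells(ob_spec(9, genotype = "WT", n = 4000),
    dose_responses = list(dr)
  )
  below_h <- unit_ids(hom)[hom$unit_meta$col1a1_latent < 1.5]
  below_w <- unit_ids(wt)[wt$unit_meta$col1a1_latent < 1.5]
  mh <- weighted_group_mean(hom, below_h, "Hspa9")$weighted_mean
  mw <- weighted_group_mean(wt, below_w, "Hspa9")$weighted_mean
  expect_equal(mh, mw, tolerance = 0.1)
})

test_that("NB counts reproduce the requested mean and dispersion", {
  # fibroblast-only mix with fixed library size: iid NB per gene
  spec <- ob_spec(10, n = 5000, mix = c(fibroblast = 1),
    library_size = list(meanlog = log(8000), sdlog = 0)
  )
  m <- simulate_cells(spec)
  rates <- small_profiles$fibroblast$mean_expression
  rates <- rates / sum(rates)
  for (g in c("Clec3b", "Actb", "Bg001")) {
    x <- as.numeric(m$counts[g, ])
    mu <- 8000 * rates[[g]]
    expect_equal(mean(x), mu, tolerance = 0.05)
    disp_hat <- (var(x) - mean(x)) / mean(x)^2
    expect_equal(disp_hat, 0.1, tolerance = 0.35)
  }
})

test_that("spot counts conserve their constituent cells exactly", {
  s <- simulate_spots(ob_spec(12, n = 200,
    mix = c(osteoblast = 0.6, hypertrophic_chondrocyte = 0.4)
  ), cells_per_spot = 10, grid = c(4, 5))
  cells <- attr(s, "cells")
  assignment <- attr(s, "spot_assignment")
  for (k in c(1, 7, 20)) {
    members <- unit_ids(cells)[assignment == k]
    expect_equal(
      as.numeric(s$counts[, k]),
      as.numeric(Matrix::rowSums(cells$counts[, members, drop = FALSE]))
    )
  }
  # singleton spots reproduce the cell matrix
  s1 <- simulate_spots(ob_spec(13, n = 30), cells_per_spot = 1, grid = c(5, 6))
  c1 <- attr(s1, "cells")
  expect_equal(unname(as.matrix(s1$counts)), unname(as.matrix(c1$counts)))
})

test_that("spots mixing in hypertrophic chondrocytes show above-threshold Col10a1", {
  s <- simulate_spots(ob_spec(14, n = 500,
    mix = c(osteoblast = 0.5, hypertrophic_chondrocyte = 0.5)
  ), cells_per_spot = 10, grid = c(5, 10))
  cells <- attr(s, "cells")
  assignment <- attr(s, "spot_assignment")
  p <- to_percent_umi(s)
  # ground-truth recomputation: %UMI of each spot from its member cells
  for (k in seq_len(ncol(s$counts))) {
    members <- unit_ids(cells)[assignment == k]
    truth <- 100 * sum(cells$counts["Col10a1", members]) /
      sum(cells$counts[, members])
    expect_equal(p$values["Col10a1", k], truth, tolerance = 1e-12)
  }
  mixed <- s$unit_meta$ob_fraction < 1
  expect_true(mean(p$values["Col10a1", mixed] > 0.03) > 0.95)
})

test_that("grid too small for the spot count is an error", {
  expect_error(
    simulate_spots(ob_spec(15, n = 100), cells_per_spot = 10, grid = c(2, 2)),
    "grid"
  )
})

test_that("bulk libraries vary in depth but keep housekeeping fractions stable", {
  expect_error(simulate_bulk(ob_spec(16), 1), "replicates")
  b1 <- simulate_bulk(ob_spec(16), 6)
  b2 <- simulate_bulk(ob_spec(16), 6)
  expect_identical(b1, b2)
  expect_gt(max(colSums(b1)) / min(colSums(b1)), 1.05)
  # housekeeping expected fraction is genotype-independent (per-replicate
  # NB dispersion gives the fraction a ~16% CV, hence the replicate count)
  het <- simulate_bulk(ob_spec(17, genotype = "Het"), 500,
    effects = c(Hspa9 = 2)
  )
  wt <- simulate_bulk(ob_spec(18, genotype = "WT"), 500)
  hk_frac <- function(b) mean(colSums(b[c("Actg1", "Actb", "Mrfap1", "Sdha"), ]) /
    colSums(b))
  expect_equal(hk_frac(het), hk_frac(wt), tolerance = 0.03)
  # the injected effect is absent for WT genotype
  wt_eff <- simulate_bulk(ob_spec(18, genotype = "WT"), 500, effects = c(Hspa9 = 2))
  expect_identical(wt_eff, wt)
})
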