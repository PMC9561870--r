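test_that("window size 1 reproduces the per-cell %UMI sequence", {
  m <- simulate_cells(ob_spec(71, n = 50))
  prof <- build_profile(m, unit_ids(m), "Hspa9", window_size = 1)
  p <- to_percent_umi(m)
  ord <- order(gene_percent_umi(p, "Col1a1"), unit_ids(m))
  expect_equal(prof$windows$value, unname(gene_percent_umi(p, "Hspa9")[ord]))
  expect_equal(nrow(prof$windows), 50)
})

test_that("a constant gene yields constant windows", {
  counts <- rbind(
    Col1a1 = 1:30, g = 50, rest = 1000 - 50 - (1:30)
  )
  colnames(counts) <- sprintf("c%02d", 1:30)
  m <- count_matrix(counts)
  prof <- build_profile(m, colnames(counts), "g", window_size = 10)
  expect_true(all(abs(prof$windows$value - 5) < 1e-12))
})

test_that("running averages match a dense brute-force sliding oracle", {
  m <- simulate_cells(ob_spec(72, n = 60))
  prof <- build_profile(m, unit_ids(m), "Hspa9", window_size = 20)
  dense <- as.matrix(m$counts)
  tot <- colSums(dense)
  cov <- 100 * dense["Col1a1", ] / tot
  ord <- order(cov, colnames(dense))
  for (s in seq_len(41)) {
    ids <- colnames(dense)[ord][s:(s + 19)]
    oracle <- 100 * sum(dense["Hspa9", ids]) / sum(tot[ids])
    expect_equal(prof$windows$value[s], oracle, tolerance = 1e-12)
  }
  expect_equal(nrow(prof$windows), 41) # trailing partial window dropped
})

test_that("profiles are invariant to the order units are supplied in", {
  m <- simulate_cells(ob_spec(73, n = 80))
  set.seed(1)
  shuffled <- sample(unit_ids(m))
  p1 <- build_profile(m, unit_ids(m), "Atf5")
  p2 <- build_profile(m, shuffled, "Atf5")
  expect_identical(p1$windows, p2$windows)
  expect_identical(p1$cells, p2$cells)
})

test_that("window size beyond the cohort is an error", {
  m <- simulate_cells(ob_spec(74, n = 10))
  expect_error(build_profile(m, unit_ids(m), "Hspa9", window_size = 20), "exceeds")
})

test_that("identical cohorts produce zero marked windows and exact fp arithmetic", {
  m <- simulate_cells(ob_spec(75, n = 80))
  cmp <- compare_profiles(m, unit_ids(m), unit_ids(m), "Hspa9")
  expect_equal(cmp$n_marked, 0)
  expect_true(all(cmp$pairs$p_raw == 1))
  expect_equal(cmp$expected_fp, cmp$n_windows * 0.01)
  cmp2 <- compare_profiles(m, unit_ids(m), unit_ids(m), "Hspa9",
    alpha_mark = 0.05
  )
  expect_equal(cmp2$expected_fp, cmp2$n_windows * 0.05)
})

test_that("null cohorts mark no more windows than the false-positive budget", {
  # modest replicate count here; the full calibration lives in the
  # acceptance suite
  marked <- vapply(1:15, function(i) {
    nc <- null_cohorts(700 + i, n = 150)
    cmp <- compare_profiles(nc$m, nc$a, nc$b, "Bg001")
    c(cmp$n_marked, cmp$n_windows)
  }, numeric(2))
  rate <- sum(marked[1, ]) / sum(marked[2, ])
  expect_lt(rate, 0.01 + 2 * sqrt(0.01 * 0.99 / sum(marked[2, ])) + 0.005)
})

test_that("a heterozygote threshold response marks only above-threshold windows", {
  dr <- dose_response("Hspa9", threshold = 1.5, max_fold = 3)
  wt <- simulate_cells(ob_spec(76, n = 600))
  het <- simulate_cells(ob_spec(77, genotype = "Het", n = 600),
    dose_responses = list(dr)
  )
  m <- merge_matrices(list(wt, het))
  cmp <- compare_profiles(m, unit_ids(wt), paste0(unit_ids(het), "-2"), "Hspa9")
  above <- cmp$pairs$covariate_B > 2.2 # clearly past the 1.5 threshold
  below <- cmp$pairs$covariate_B < 1.2 # clearly before it
  expect_gt(sum(cmp$pairs$marked[above]), 5 * sum(above) * 0.01)
  expect_lte(
    sum(cmp$pairs$marked[below]),
    sum(below) * 0.01 + 2 * sqrt(sum(below) * 0.01) + 1
  )
})

test_that("profile summaries match a dense two-pass oracle", {
  m <- simulate_cells(ob_spec(78, n = 100))
  prof <- build_profile(m, unit_ids(m), "Hspa9", window_size = 20)
  s <- summarize_profile_mean(prof, "dOB")
  in_bin <- prof$cells$covariate >= 0.75 & prof$cells$covariate <= 3.5
  oracle_mean <- 100 * sum(prof$cells$gene_count[in_bin]) /
    sum(prof$cells$total[in_bin])
  oracle_disp <- mean(vapply(seq_len(nrow(prof$windows)), function(i) {
    s <- prof$windows$start[i]
    sd(prof$cells$value[s:(s + 19)])
  }, numeric(1)))
  expect_equal(s$weighted_mean, oracle_mean, tolerance = 1e-12)
  expect_equal(s$dispersion, oracle_disp, tolerance = 1e-12)

  # single-window profile: dispersion is that window's standard deviation
  m2 <- subset_units(m, units = unit_ids(m)[1:20])
  prof2 <- build_profile(m2, unit_ids(m2), "Hspa9", window_size = 20)
  s2 <- summarize_profile_mean(prof2, "dOB")
  expect_equal(s2$dispersion, sd(prof2$cells$value))

  # constant gene: zero dispersion
  counts <- rbind(Col1a1 = 1:25, g = 40, rest = 960 - (1:25))
  colnames(counts) <- sprintf("k%02d", 1:25)
  mc <- count_matrix(counts)
  pc <- build_profile(mc, colnames(counts), "g", window_size = 5)
  expect_error(summarize_profile_mean(pc, "mOB"), "no profile cells")
  expect_equal(summarize_profile_mean(pc, "eOB")$dispersion, 0)
})
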