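# Synthetic cohort generators: seeded determinism, planted-effect fidelity,
# dropout behavior, censoring calibration, and the IHC conditionals.

test_that("bulk generator is a pure function of its spec", {
  spec <- bulk_cohort_spec(n_msi = 10, n_mss = 15, seed = 42)
  a <- generate_bulk_cohort(spec)
  b <- generate_bulk_cohort(spec)
  expect_identical(a, b)
  c <- generate_bulk_cohort(bulk_cohort_spec(n_msi = 10, n_mss = 15,
                                             seed = 43))
  expect_false(identical(a$values, c$values))
})

test_that("bulk generator leaves the calling RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_bulk_cohort(bulk_cohort_spec(n_msi = 3, n_mss = 3)))
  expect_identical(.Random.seed, before)
})

test_that("zero planted effect gives zero expected fold change everywhere", {
  spec <- bulk_cohort_spec(n_msi = 300, n_mss = 300, effect_log2fc = 0,
                           noise_sd = 0.5, seed = 7)
  fc <- log2_fold_change(generate_bulk_cohort(spec))
  # SE of each fc is 0.5*sqrt(2/300) ~ 0.041
  expect_lt(max(abs(fc)), 0.2)
  expect_lt(abs(mean(fc)), 0.02)
})

test_that("planted log2 fold changes are recovered near +/- effect", {
  # Monte-Carlo against the generating mean shift (effect 0.8, sd 0.5,
  # 200/200). The fold-change SE is 0.5 * sqrt(2/200) = 0.05, so +/-0.1 is
  # a 2-SE band: the hit fraction must sit near pnorm bounds (95.45%),
  # checked with Monte-Carlo slack over 50 x 5 planted genes.
  hits <- 0L
  checks <- 0L
  for (s in 1:50) {
    spec <- bulk_cohort_spec(n_msi = 200, n_mss = 200, effect_log2fc = 0.8,
                             noise_sd = 0.5, seed = s)
    fc <- log2_fold_change(generate_bulk_cohort(spec))
    dev <- c(abs(fc[spec$planted_up] - 0.8), abs(fc[spec$planted_down] + 0.8))
    hits <- hits + sum(dev <= 0.1)
    checks <- checks + length(dev)
  }
  expect_gte(hits / checks, 0.91)
  expect_lte(hits / checks, 0.995)
})

test_that("group-mean differences converge to the planted effect at n = 1000", {
  spec <- bulk_cohort_spec(n_msi = 1000, n_mss = 1000, effect_log2fc = 0.8,
                           noise_sd = 0.5, seed = 11)
  fc <- log2_fold_change(generate_bulk_cohort(spec))
  expect_true(all(abs(fc[spec$planted_up] - 0.8) < 0.05))
  expect_true(all(abs(fc[spec$planted_down] + 0.8) < 0.05))
  nulls <- setdiff(names(fc), c(spec$planted_up, spec$planted_down))
  expect_true(all(abs(fc[nulls]) < 0.15))
})

test_that("bulk spec validation rejects bad planted sets", {
  expect_error(bulk_cohort_spec(planted_up = c("GALNT7"),
                                planted_down = c("GALNT7")), "overlap")
  expect_error(bulk_cohort_spec(gene_universe = c("A", "B"),
                                planted_up = "C", planted_down = "B"),
               "not in universe")
  expect_error(bulk_cohort_spec(n_msi = 1), "at least 2")
})

test_that("single-cell generator is seeded and respects dropout", {
  spec <- single_cell_spec(n_cells_tumor_epithelial = 200,
                           n_cells_other = 50, seed = 5)
  a <- generate_single_cell(spec)
  b <- generate_single_cell(spec)
  expect_identical(a, b)
  expect_true(all(a$counts >= 0))
  expect_setequal(unique(a$cells$cell_type), sc_cell_types())

  # extreme dropout drives every detection fraction to ~0
  hi <- generate_single_cell(single_cell_spec(
    n_cells_tumor_epithelial = 300, n_cells_other = 0,
    dropout_rate = 0.999, effect_log2fc = 0, seed = 5))
  expect_lt(max(fraction_expressing(hi)), 0.02)
})

test_that("observed detection fraction matches the binomial expectation", {
  # gene detected in essentially every cell pre-dropout; dropout 0.5 on
  # 10,000 cells leaves an observed fraction within +/-0.02 of 0.5
  spec <- single_cell_spec(n_cells_tumor_epithelial = 10000,
                           n_cells_other = 0, dropout_rate = 0.5,
                           detection_rate = 1 - 1e-9, effect_log2fc = 0,
                           seed = 3)
  frac <- fraction_expressing(generate_single_cell(spec))
  expect_lt(max(abs(frac - 0.5)), 0.02)
})

test_that("single-cell planted effect lands on the log2(count+1) scale", {
  spec <- single_cell_spec(n_cells_tumor_epithelial = 8000,
                           n_cells_other = 0, effect_log2fc = 0.8, seed = 2)
  fc <- sc_log2_fold_change(generate_single_cell(spec))
  expect_true(all(abs(fc[spec$planted_up] - 0.8) < 0.07))
  expect_true(all(abs(fc[spec$planted_down] + 0.8) < 0.07))
  nulls <- setdiff(names(fc), c(spec$planted_up, spec$planted_down))
  expect_lt(max(abs(fc[nulls])), 0.15)
})

test_that("survival generator honors its null, censoring and seed contracts", {
  spec0 <- survival_sim_spec(n = 200, log_hr = 0, censoring_rate = 0,
                             seed = 8)
  g <- rep(0:1, each = 100)
  rec <- generate_survival(g, spec0)
  expect_identical(rec, generate_survival(g, spec0))
  expect_true(all(rec$event == 1))  # no censoring requested

  rec30 <- generate_survival(g, survival_sim_spec(
    n = 200, log_hr = log(2), censoring_rate = 0.3, seed = 8))
  expect_gt(mean(rec30$event == 0), 0.15)
  expect_lt(mean(rec30$event == 0), 0.45)

  expect_error(generate_survival(rep(2, 200), spec0), "binary")
  expect_error(generate_survival(g[1:10], spec0), "length")
})

test_that("administrative horizon censors every later observation", {
  rec <- generate_survival(rep(0:1, 50), survival_sim_spec(
    n = 100, baseline_hazard = 0.01, censoring_rate = 0,
    admin_horizon = 20, seed = 4))
  expect_lte(max(rec$time), 20)
  expect_true(all(rec$event[rec$time == 20] == 0))
})

test_that("cox recovers the generating log hazard ratio", {
  ests <- vapply(1:50, function(s) {
    g <- rep(0:1, each = 150)
    rec <- generate_survival(g, survival_sim_spec(
      n = 300, log_hr = log(4), censoring_rate = 0.2, seed = s))
    cox_fit(rec, "group")$coefficients$beta
  }, 0)
  expect_lt(abs(mean(ests) - log(4)), 0.15)
})

test_that("IHC generator honors degenerate and stochastic conditionals", {
  all_high <- generate_ihc_cohort(ihc_sim_spec(
    n = 400, p_dmmr = 0.5, p_high_given_dmmr = 1, seed = 6))
  dmmr <- all_high[all_high$mmr_status == "dMMR_MSI", ]
  expect_true(all(dmmr$h_score >= 8 & dmmr$h_score <= 12))

  no_pdl1 <- generate_ihc_cohort(ihc_sim_spec(
    n = 400, p_dmmr = 0.5, p_pdl1_given_high_dmmr = 0, seed = 6))
  hi_dmmr <- no_pdl1$mmr_status == "dMMR_MSI" & no_pdl1$galnt7_class == "High"
  expect_true(all(no_pdl1$pdl1_tumor[hi_dmmr] == 0))

  big <- generate_ihc_cohort(ihc_sim_spec(n = 5000, p_dmmr = 0.5,
                                          p_high_given_dmmr = 0.65,
                                          seed = 10))
  obs <- mean(big$galnt7_class[big$mmr_status == "dMMR_MSI"] == "High")
  expect_lt(abs(obs - 0.65), 0.03)
  # intensity x positivity always reproduces the stored H-score and class
  expect_identical(big$h_score, big$intensity * big$positivity_category)
  expect_identical(big$galnt7_class, unname(classify_galnt7(big$h_score)))
})
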