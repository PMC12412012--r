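# Glyco-MSI score, signature averages, rank-based AUC and Pearson
# correlation, each against an independent brute-force computation.

test_that("score is mean(up) minus mean(down) with shift invariance", {
  m <- matrix(c(4, 2, 1, 3, 5, 3, 2, 4), ncol = 2,
              dimnames = list(c("u1", "u2", "d1", "d2"), c("s1", "s2")))
  co <- expression_cohort(m, c("MSI", "MSS"))
  sig <- gene_signature(c("u1", "u2"), c("d1", "d2"))
  sv <- glyco_msi_score(co, sig)
  expect_equal(unname(sv$score), c(1, 1))  # (3 - 2); shift leaves it at 1

  const <- expression_cohort(matrix(5, 4, 3, dimnames = list(
    rownames(m), paste0("s", 1:3))), c("MSI", "MSS", "MSS"))
  expect_equal(unname(glyco_msi_score(const, sig)$score), rep(0, 3))
})

test_that("score matches an independent mean-minus-mean loop", {
  set.seed(5)
  rc <- random_cohort(12, 5, 5)
  sig <- gene_signature(c("g1", "g4", "g7"), c("g2", "g9"))
  sv <- glyco_msi_score(rc, sig)
  manual <- vapply(seq_len(ncol(rc$values)), function(j) {
    v <- rc$values[, j]
    mean(v[sig$up]) - mean(v[sig$down])
  }, 0)
  expect_equal(unname(sv$score), manual)
  expect_equal(sv$n_up_used, 3)
  expect_equal(sv$n_down_used, 2)
})

test_that("missing signature genes are dropped and counted; empty arm errors", {
  set.seed(6)
  rc <- random_cohort(6, 3, 3)
  sig <- gene_signature(c("g1", "NOT_PRESENT"), c("g2"))
  sv <- glyco_msi_score(rc, sig)
  expect_equal(sv$n_up_used, 1)
  expect_equal(unname(sv$score),
               unname(rc$values["g1", ] - rc$values["g2", ]))
  expect_error(glyco_msi_score(rc, gene_signature("ABSENT", "g2")),
               "up-arm")
})

test_that("swapping signature arms negates scores and flips the AUC", {
  st <- simulate_study(seed = 12)
  sig <- glyco_msi_signature()
  sv <- glyco_msi_score(st$bulk, sig)
  swapped <- glyco_msi_score(st$bulk, gene_signature(sig$down, sig$up))
  expect_equal(swapped$score, -sv$score)
  a1 <- roc_auc(sv$score, st$bulk$labels)$auc
  a2 <- roc_auc(swapped$score, st$bulk$labels)$auc
  expect_equal(a1 + a2, 1)
})

test_that("signature average reduces to the per-gene mean", {
  m <- matrix(c(2, 4, 7, 2, 4, 7), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  co <- expression_cohort(m, c("MSI", "MSS"))
  expect_equal(unname(signature_average(co, c("g1", "g2"))), c(3, 3))
  expect_equal(unname(signature_average(co, "g3")), c(7, 7))
  set.seed(7)
  rc <- random_cohort(20, 3, 3)
  gs <- c("g3", "g11", "g17", "ABSENT")
  expect_equal(signature_average(rc, gs),
               colMeans(rc$values[c("g3", "g11", "g17"), ]))
  expect_error(signature_average(rc, "NOPE"), "no gene")
})

test_that("AUC agrees with explicit pair enumeration, including ties", {
  r <- roc_auc(c(3, 1, 2, 0), c("MSI", "MSI", "MSS", "MSS"))
  expect_equal(r$auc, 0.75)  # 3 of 4 concordant pairs
  expect_equal(r$u_statistic, 3)

  expect_equal(roc_auc(c(5, 4, 3, 2), c("MSI", "MSI", "MSS", "MSS"))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("MSI", "MSS"), 3))$auc, 0.5)

  set.seed(8)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    lab <- sample(c("MSI", "MSS"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("MSI", "MSS")
    sc <- sample(round(rnorm(n), 1))  # rounding forces ties
    r <- roc_auc(sc, lab)
    expect_equal(r$auc, brute_force_auc(sc, lab), tolerance = 1e-12)
    expect_equal(r$auc, r$u_statistic / (r$n_pos * r$n_neg))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(9)
  sc <- rnorm(80)
  lab <- rep(c("MSI", "MSS"), 40)
  a <- roc_auc(sc, lab)$auc
  expect_equal(roc_auc(exp(sc), lab)$auc, a)
  expect_equal(roc_auc(5 * sc - 3, lab)$auc, a)
  expect_equal(roc_auc(rank(sc), lab)$auc, a)
})

test_that("AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  sc <- round(rnorm(60), 1)
  lab <- rep(c("MSI", "MSS"), 30)
  ours <- roc_auc(sc, lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lab, predictor = sc, levels = c("MSS", "MSI"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Pearson correlation matches hand computation and errors sanely", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_correlation(1:10, -(1:10)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
})

test_that("cohort evaluation reports per-cohort AUC and isolates failures", {
  st <- simulate_study(seed = 13)
  tab <- evaluate_cohorts(st$eval_cohorts)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$auc > 0.9))
  expect_equal(tab$n_msi, c(76, 40, 30))

  # shuffled labels -> chance-level AUC
  shuf <- st$bulk
  set.seed(14)
  shuf <- expression_cohort(shuf$values,
                            setNames(sample(shuf$labels),
                                     names(shuf$labels)))
  null_auc <- evaluate_cohorts(list(null = shuf))$auc
  expect_lt(abs(null_auc - 0.5), 0.1)

  # a cohort missing the whole down arm fails its row, others proceed
  broken <- expression_cohort(
    st$bulk$values[setdiff(rownames(st$bulk$values),
                           c("GALNT6", "ST6GAL1")), ],
    st$bulk$labels)
  tab2 <- evaluate_cohorts(list(ok = st$bulk, broken = broken))
  expect_equal(tab2$status[1], "ok")
  expect_match(tab2$status[2], "down-arm")
  expect_true(is.na(tab2$auc[2]))

  # one missing down gene only reduces n_down_used
  partial <- expression_cohort(
    st$bulk$values[setdiff(rownames(st$bulk$values), "ST6GAL1"), ],
    st$bulk$labels)
  tab3 <- evaluate_cohorts(list(partial = partial))
  expect_equal(tab3$n_down_used, 1)
  expect_equal(tab3$status, "ok")
})

test_that("gaussian separation gives the closed-form AUC", {
  # score difference delta with per-class score sd sigma gives
  # AUC = pnorm(delta / (sigma * sqrt(2)))
  for (ratio in c(1, 2)) {
    sigma_score <- sqrt(5 / 6)  # var(mean of 3) + var(mean of 2), sd = 1
    spec <- bulk_cohort_spec(n_msi = 500, n_mss = 500,
                             effect_log2fc = ratio * sigma_score / 2,
                             noise_sd = 1, seed = 100 + ratio)
    co <- generate_bulk_cohort(spec)
    auc <- roc_auc(glyco_msi_score(co)$score, co$labels)$auc
    expect_lt(abs(auc - pnorm(ratio / sqrt(2))), 0.03)
  }
})
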