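# Seeded synthetic cohort generators. These emulate the data structures the
# analysis consumes -- MSI/MSS-labeled bulk and cell-line log2 expression
# matrices with planted fold-change effects, a zero-inflated single-cell
# count matrix, score-linked exponential survival with calibrated censoring,
# and MMR-stratified IHC records -- so every downstream stage can be tested
# against planted truth without any external dataset.

#' Default synthetic gene universe
#'
#' A 188-symbol glycosyltransferase-like gene universe: the five Glyco-MSI
#' signature genes plus synthetic filler symbols. It mirrors the size of the
#' curated 188-gene glycosyltransferase list used for screening; the filler
#' symbols are synthetic placeholders, not real gene names.
#'
#' @param n Universe size (default 188).
#' @return Character vector of `n` unique gene symbols.
#' @export
default_gene_universe <- function(n = 188) {
  sig <- c("GALNT7", "GALNT1", "HPSE", "GALNT6", "ST6GAL1")
  if (n < length(sig)) stop("universe must hold the 5 signature genes")
  c(sig, sprintf("GTSYN%03d", seq_len(n - length(sig))))
}

#' Specification of a synthetic bulk (or cell-line) cohort
#'
#' Expression is simulated directly on the log2 scale as Gaussian noise
#' around group means; MSI samples receive `+effect_log2fc` on the planted
#' up genes and `-effect_log2fc` on the planted down genes. The default
#' sample sizes mirror a large bulk tumor cohort (76 MSI / 450 MSS).
#'
#' @param n_msi,n_mss Samples per class (each >= 2).
#' @param gene_universe Gene symbols to simulate.
#' @param planted_up,planted_down Genes carrying the planted effect; must be
#'   disjoint subsets of `gene_universe`.
#' @param effect_log2fc Planted mean shift on the log2 scale.
#' @param noise_sd Within-group standard deviation of log2 expression.
#' @param baseline_mean Grand mean of log2 expression.
#' @param seed Integer seed; identical specs give bit-identical cohorts.
#' @return A list of class `"bulk_cohort_spec"`.
#' @export
bulk_cohort_spec <- function(n_msi = 76, n_mss = 450,
                             gene_universe = default_gene_universe(),
                             planted_up = c("GALNT7", "GALNT1", "HPSE"),
                             planted_down = c("GALNT6", "ST6GAL1"),
                             effect_log2fc = 0.8, noise_sd = 0.5,
                             baseline_mean = 6, seed = 1L) {
  if (n_msi < 2 || n_mss < 2) stop("need at least 2 samples per class")
  if (length(intersect(planted_up, planted_down)))
    stop("planted up and down sets overlap")
  outside <- setdiff(c(planted_up, planted_down), gene_universe)
  if (length(outside))
    stop("planted genes not in universe: ", paste(outside, collapse = ", "))
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_msi = n_msi, n_mss = n_mss,
                 gene_universe = gene_universe,
                 planted_up = planted_up, planted_down = planted_down,
                 effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, seed = as.integer(seed)),
            class = "bulk_cohort_spec")
}

#' Generate a synthetic bulk or cell-line cohort
#'
#' @param spec A [bulk_cohort_spec()].
#' @return An [expression_cohort()] with `n_msi + n_mss` samples; MSI
#'   samples come first. Group means of planted up (down) genes differ by
#'   `+effect_log2fc` (`-effect_log2fc`) in expectation; non-planted genes
#'   are identically distributed in both classes.
#' @export
generate_bulk_cohort <- function(spec) {
  stopifnot(inherits(spec, "bulk_cohort_spec"))
  seeds <- substream_seeds(spec$seed, "noise")
  n <- spec$n_msi + spec$n_mss
  g <- length(spec$gene_universe)
  labels <- c(rep("MSI", spec$n_msi), rep("MSS", spec$n_mss))
  sample_ids <- sprintf("%s_%04d", labels, seq_len(n))
  mu <- matrix(spec$baseline_mean, g, n,
               dimnames = list(spec$gene_universe, sample_ids))
  is_msi <- labels == "MSI"
  mu[spec$planted_up,   is_msi] <- mu[spec$planted_up,   is_msi] + spec$effect_log2fc
  mu[spec$planted_down, is_msi] <- mu[spec$planted_down, is_msi] - spec$effect_log2fc
  vals <- with_preserved_rng(seeds[["noise"]],
                             mu + matrix(stats::rnorm(g * n, 0, spec$noise_sd), g, n))
  expression_cohort(vals, labels)
}

# ---- single cell ----------------------------------------------------------

# E[log2(1 + X)] for X ~ Poisson(lambda), by truncated summation over a
# +/- 10 sd window around the mean (the full 0..qpois range for small
# lambda).
elog2p1_poisson <- function(lambda) {
  if (lambda <= 0) return(0)
  if (lambda <= 50) {
    k <- 0:max(30, stats::qpois(1 - 1e-13, lambda))
  } else {
    half <- ceiling(10 * sqrt(lambda))
    k <- max(0, floor(lambda - half)):ceiling(lambda + half)
  }
  sum(stats::dpois(k, lambda) * log2(1 + k))
}

# Poisson rate whose post-dropout mean log2(count+1) equals `target`.
# Monotone in lambda, solved by uniroot; used to plant single-cell effects
# on the same scale the screen measures them. Targets requiring a
# pre-dropout mean above 25 (rate ~ 2^25) are unattainable for any
# realistic count scale and are truncated with a warning.
lambda_for_log2_mean <- function(target, dropout_rate) {
  if (target <= 0) return(0)
  pre <- target / (1 - dropout_rate)
  if (pre > 25) {
    warning("planted single-cell effect truncated: target mean ",
            signif(target, 3), " is unattainable at dropout rate ",
            dropout_rate)
    pre <- 25
  }
  f <- function(l) elog2p1_poisson(l) - pre
  stats::uniroot(f, lower = 1e-10, upper = 2^(pre + 4), tol = 1e-10)$root
}

#' Specification of a synthetic single-cell dataset
#'
#' Counts are Poisson with per-gene rates, then zeroed by independent
#' Bernoulli dropout, reproducing the zero inflation that motivates the
#' 5%-of-cells prevalence rule. Rates are calibrated (by root finding) so
#' that the observed mean log2(count + 1) of planted genes differs between
#' MSI- and MSS-patient tumor-epithelial cells by exactly `effect_log2fc`
#' in expectation; down genes are planted by raising the MSS group, since a
#' mean of non-negative values cannot be shifted below zero.
#'
#' @param n_cells_tumor_epithelial Number of tumor-epithelial cells.
#' @param n_cells_other Cells of the other types (normal epithelial,
#'   stromal, immune), split evenly.
#' @param frac_patients_msi Fraction of patients labeled MSI.
#' @param n_patients Number of patients cells are assigned to.
#' @param dropout_rate Probability a true count is zeroed, in `[0, 1)`.
#' @param detection_rate Pre-dropout probability of a non-zero count for a
#'   baseline gene; the observed fraction expressing is approximately
#'   `(1 - dropout_rate) * detection_rate`. The default pairs with the
#'   default dropout to give an observed prevalence of 0.5.
#' @param effect_log2fc Planted mean log2(count+1) shift (tumor-epithelial
#'   cells only).
#' @param gene_universe,planted_up,planted_down As in [bulk_cohort_spec()].
#' @param seed Integer seed.
#' @return A list of class `"single_cell_spec"`.
#' @export
single_cell_spec <- function(n_cells_tumor_epithelial = 2000,
                             n_cells_other = 500,
                             frac_patients_msi = 0.5, n_patients = 10,
                             dropout_rate = 0.3, detection_rate = 5 / 7,
                             effect_log2fc = 0.8,
                             gene_universe = default_gene_universe(),
                             planted_up = c("GALNT7", "GALNT1", "HPSE"),
                             planted_down = c("GALNT6", "ST6GAL1"),
                             seed = 1L) {
  if (n_cells_tumor_epithelial + n_cells_other < 1)
    stop("at least one cell required")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (detection_rate <= 0 || detection_rate >= 1)
    stop("detection_rate must be in (0, 1)")
  if (frac_patients_msi <= 0 || frac_patients_msi >= 1)
    stop("both MSI and MSS patients are required")
  if (length(intersect(planted_up, planted_down)))
    stop("planted up and down sets overlap")
  outside <- setdiff(c(planted_up, planted_down), gene_universe)
  if (length(outside))
    stop("planted genes not in universe: ", paste(outside, collapse = ", "))
  structure(list(n_cells_tumor_epithelial = n_cells_tumor_epithelial,
                 n_cells_other = n_cells_other,
                 frac_patients_msi = frac_patients_msi,
                 n_patients = n_patients,
                 dropout_rate = dropout_rate,
                 detection_rate = detection_rate,
                 effect_log2fc = effect_log2fc,
                 gene_universe = gene_universe,
                 planted_up = planted_up, planted_down = planted_down,
                 seed = as.integer(seed)),
            class = "single_cell_spec")
}

#' Generate a synthetic single-cell dataset
#'
#' @param spec A [single_cell_spec()].
#' @return An [sc_dataset()] with cell-type, tissue and patient annotations
#'   and a per-patient MSI label.
#' @export
generate_single_cell <- function(spec) {
  stopifnot(inherits(spec, "single_cell_spec"))
  seeds <- substream_seeds(spec$seed, c("assign", "counts", "dropout"))
  n_cells <- spec$n_cells_tumor_epithelial + spec$n_cells_other
  genes <- spec$gene_universe

  n_msi_pat <- min(spec$n_patients - 1L,
                   max(1L, round(spec$frac_patients_msi * spec$n_patients)))
  patients <- sprintf("P%02d", seq_len(spec$n_patients))
  patient_msi <- stats::setNames(
    c(rep("MSI", n_msi_pat), rep("MSS", spec$n_patients - n_msi_pat)),
    patients)

  other_types <- rep(c("normal_epithelial", "stromal", "immune"),
                     length.out = spec$n_cells_other)
  cell_type <- c(rep("tumor_epithelial", spec$n_cells_tumor_epithelial),
                 other_types)
  tissue <- ifelse(cell_type == "normal_epithelial", "normal", "tumor")
  patient_id <- with_preserved_rng(
    seeds[["assign"]], sample(patients, n_cells, replace = TRUE))
  barcodes <- sprintf("cell_%05d", seq_len(n_cells))

  d <- spec$dropout_rate
  lambda0 <- -log(1 - spec$detection_rate)
  t0 <- (1 - d) * elog2p1_poisson(lambda0)
  lambda_hi <- lambda_for_log2_mean(t0 + spec$effect_log2fc, d)

  # rate matrix: baseline everywhere; planted shifts only in tumor
  # epithelial cells (up genes raised in MSI patients, down genes raised in
  # MSS patients so the MSI-minus-MSS difference is -effect)
  lam <- matrix(lambda0, length(genes), n_cells,
                dimnames = list(genes, barcodes))
  is_epi <- cell_type == "tumor_epithelial"
  cell_msi <- patient_msi[patient_id] == "MSI"
  if (spec$effect_log2fc != 0) {
    lam[spec$planted_up,   is_epi & cell_msi]  <- lambda_hi
    lam[spec$planted_down, is_epi & !cell_msi] <- lambda_hi
  }
  counts <- with_preserved_rng(
    seeds[["counts"]],
    matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam),
           dimnames = dimnames(lam)))
  if (d > 0) {
    keep <- with_preserved_rng(
      seeds[["dropout"]],
      matrix(stats::rbinom(length(counts), 1L, 1 - d),
             nrow(counts), ncol(counts)))
    counts <- counts * keep
  }
  cells <- data.frame(barcode = barcodes, cell_type = cell_type,
                      tissue = tissue, patient_id = patient_id,
                      stringsAsFactors = FALSE)
  sc_dataset(counts, cells, patient_msi)
}

# ---- survival -------------------------------------------------------------

#' Specification of a two-group exponential survival simulation
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hr * group)`. Independent exponential
#' censoring is calibrated by root finding so the expected censored fraction
#' matches `censoring_rate`; an administrative horizon (if finite)
#' additionally censors at `admin_horizon`.
#'
#' @param n Number of subjects.
#' @param log_hr Log hazard ratio of group 1 versus group 0.
#' @param baseline_hazard Hazard of group 0 (> 0).
#' @param censoring_rate Target censored proportion, in `[0, 1)`.
#' @param admin_horizon Administrative censoring time (default `Inf`).
#' @param seed Integer seed.
#' @return A list of class `"survival_sim_spec"`.
#' @export
survival_sim_spec <- function(n, log_hr = 0, baseline_hazard = 0.1,
                              censoring_rate = 0, admin_horizon = Inf,
                              seed = 1L) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  structure(list(n = as.integer(n), log_hr = log_hr,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 admin_horizon = admin_horizon, seed = as.integer(seed)),
            class = "survival_sim_spec")
}

# Expected censored fraction for one subject with event hazard h, censoring
# hazard hc, and administrative horizon H.
censored_prob <- function(h, hc, H) {
  if (!is.finite(H)) {
    if (hc == 0) return(0)
    return(hc / (h + hc))
  }
  tot <- h + hc
  if (tot == 0) return(1)
  hc / tot * (1 - exp(-tot * H)) + exp(-tot * H)
}

# Censoring hazard achieving the target mean censored fraction across the
# subjects' event hazards; 0 if administrative censoring alone exceeds it.
calibrate_censoring_hazard <- function(hazards, target, H) {
  mean_cens <- function(hc) mean(vapply(hazards, censored_prob, 0,
                                        hc = hc, H = H))
  if (target <= mean_cens(0)) return(0)
  upper <- max(hazards)
  while (mean_cens(upper) < target) upper <- upper * 2
  stats::uniroot(function(hc) mean_cens(hc) - target,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

#' Generate two-group exponential survival records
#'
#' @param groups Binary vector (0/1, logical, or two-level factor) of length
#'   `spec$n`; group 1 carries the `log_hr` effect.
#' @param spec A [survival_sim_spec()].
#' @return `data.frame` with columns `sample_id`, `time`, `event`
#'   (1 = event, 0 = censored), `group`.
#' @export
generate_survival <- function(groups, spec) {
  stopifnot(inherits(spec, "survival_sim_spec"))
  if (is.factor(groups)) groups <- as.integer(groups) - 1L
  groups <- as.numeric(groups)
  if (length(groups) != spec$n)
    stop("length(groups) must equal spec$n")
  if (!all(groups %in% c(0, 1)))
    stop("groups must be binary (0/1)")
  seeds <- substream_seeds(spec$seed, c("event", "censor"))
  hazards <- spec$baseline_hazard * exp(spec$log_hr * groups)
  t_event <- with_preserved_rng(seeds[["event"]],
                                stats::rexp(spec$n, rate = hazards))
  hc <- calibrate_censoring_hazard(hazards, spec$censoring_rate,
                                   spec$admin_horizon)
  t_cens <- if (hc > 0)
    with_preserved_rng(seeds[["censor"]], stats::rexp(spec$n, rate = hc))
  else rep(Inf, spec$n)
  t_cens <- pmin(t_cens, spec$admin_horizon)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  data.frame(sample_id = sprintf("S%04d", seq_len(spec$n)),
             time = time, event = event, group = groups,
             stringsAsFactors = FALSE)
}

# ---- IHC ------------------------------------------------------------------

#' Specification of a synthetic IHC cohort
#'
#' Records are drawn hierarchically: MMR status (dMMR/MSI with probability
#' `p_dmmr`), then the GALNT7-High class conditional on MMR status, then an
#' (intensity, positivity) pair uniform over the pairs whose H-score product
#' falls in the class's bin (High: 8-12; Low: 0-7), then tumor-cell PD-L1
#' from the stated conditionals. Tn-antigen H-scores and TIL counts are
#' drawn with a class-linked shift so the downstream comparisons have signal.
#' Defaults follow the observed IHC cohort proportions (High in 65.4% of
#' dMMR and 21.3% of pMMR tumors; PD-L1 positivity 23.8% / 58.8% in
#' High / Low dMMR tumors).
#'
#' @param n Number of records.
#' @param p_dmmr Probability of dMMR/MSI status.
#' @param p_high_given_dmmr,p_high_given_pmmr P(GALNT7-High | MMR status).
#' @param p_pdl1_given_high_dmmr,p_pdl1_given_low_dmmr,p_pdl1_given_mss
#'   Conditional tumor-cell PD-L1 positivity probabilities.
#' @param seed Integer seed.
#' @return A list of class `"ihc_sim_spec"`.
#' @export
ihc_sim_spec <- function(n = 619, p_dmmr = 52 / 619,
                         p_high_given_dmmr = 0.654,
                         p_high_given_pmmr = 0.213,
                         p_pdl1_given_high_dmmr = 0.238,
                         p_pdl1_given_low_dmmr = 0.588,
                         p_pdl1_given_mss = 0.10, seed = 1L) {
  p <- c(p_dmmr, p_high_given_dmmr, p_high_given_pmmr,
         p_pdl1_given_high_dmmr, p_pdl1_given_low_dmmr, p_pdl1_given_mss)
  if (any(p < 0 | p > 1)) stop("all probabilities must be in [0, 1]")
  structure(list(n = as.integer(n), p_dmmr = p_dmmr,
                 p_high_given_dmmr = p_high_given_dmmr,
                 p_high_given_pmmr = p_high_given_pmmr,
                 p_pdl1_given_high_dmmr = p_pdl1_given_high_dmmr,
                 p_pdl1_given_low_dmmr = p_pdl1_given_low_dmmr,
                 p_pdl1_given_mss = p_pdl1_given_mss,
                 seed = as.integer(seed)),
            class = "ihc_sim_spec")
}

# All 16 (intensity, positivity) pairs split by the H-score >= 8 cut.
ihc_score_pairs <- function(high) {
  pairs <- expand.grid(intensity = 0:3, positivity = 1:4)
  pairs[(pairs$intensity * pairs$positivity >= 8) == high, , drop = FALSE]
}

#' Generate a synthetic IHC cohort
#'
#' @param spec An [ihc_sim_spec()].
#' @return `data.frame` with one row per tumor: `sample_id`, `mmr_status`
#'   (`"dMMR_MSI"`/`"pMMR_MSS"`), `intensity` (0-3), `positivity_category`
#'   (1-4), `h_score`, `galnt7_class`, `pdl1_tumor` (0/1), `tn_h_score`,
#'   and TIL counts `cd8`, `cd4`, `foxp3`, `cd163`.
#' @export
generate_ihc_cohort <- function(spec) {
  stopifnot(inherits(spec, "ihc_sim_spec"))
  seeds <- substream_seeds(spec$seed, c("mmr", "class", "pairs", "pdl1",
                                        "tn", "til"))
  n <- spec$n
  dmmr <- with_preserved_rng(seeds[["mmr"]],
                             stats::rbinom(n, 1L, spec$p_dmmr)) == 1L
  p_high <- ifelse(dmmr, spec$p_high_given_dmmr, spec$p_high_given_pmmr)
  high <- with_preserved_rng(seeds[["class"]],
                             stats::rbinom(n, 1L, p_high)) == 1L
  hi_pairs <- ihc_score_pairs(TRUE)
  lo_pairs <- ihc_score_pairs(FALSE)
  idx <- with_preserved_rng(seeds[["pairs"]], {
    i <- integer(n)
    i[high]  <- sample.int(nrow(hi_pairs), sum(high), replace = TRUE)
    i[!high] <- sample.int(nrow(lo_pairs), sum(!high), replace = TRUE)
    i
  })
  intensity <- positivity <- integer(n)
  intensity[high]  <- hi_pairs$intensity[idx[high]]
  positivity[high] <- hi_pairs$positivity[idx[high]]
  intensity[!high]  <- lo_pairs$intensity[idx[!high]]
  positivity[!high] <- lo_pairs$positivity[idx[!high]]
  p_pdl1 <- ifelse(dmmr,
                   ifelse(high, spec$p_pdl1_given_high_dmmr,
                          spec$p_pdl1_given_low_dmmr),
                   spec$p_pdl1_given_mss)
  pdl1 <- with_preserved_rng(seeds[["pdl1"]], stats::rbinom(n, 1L, p_pdl1))
  # Tn antigen tracks GALNT7 class (higher in High tumors); TILs track MMR
  # status (CD8 enriched in dMMR) -- both give the stratified comparisons
  # real signal without extra spec parameters.
  tn <- with_preserved_rng(seeds[["tn"]], {
    vals <- c(0, 1, 2, 3, 4, 6, 8, 9, 12)
    w_hi <- vals + 1; w_lo <- rev(vals + 1)
    ifelse(high,
           sample(vals, n, replace = TRUE, prob = w_hi),
           sample(vals, n, replace = TRUE, prob = w_lo))
  })
  til <- with_preserved_rng(seeds[["til"]], {
    base <- ifelse(dmmr, 120, 60)
    data.frame(cd8 = stats::rpois(n, base),
               cd4 = stats::rpois(n, 80),
               foxp3 = stats::rpois(n, 40),
               cd163 = stats::rpois(n, 70))
  })
  data.frame(sample_id = sprintf("T%04d", seq_len(n)),
             mmr_status = ifelse(dmmr, "dMMR_MSI", "pMMR_MSS"),
             intensity = intensity, positivity_category = positivity,
             h_score = intensity * positivity,
             galnt7_class = ifelse(high, "High", "Low"),
             pdl1_tumor = pdl1, tn_h_score = tn, til,
             stringsAsFactors = FALSE)
}
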