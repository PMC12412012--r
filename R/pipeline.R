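# End-to-end orchestration: simulate a full synthetic study, run
# screen -> score -> evaluate -> survival, and record a run manifest
# sufficient to re-execute the deterministic stages byte-identically.

#' Simulate a complete synthetic study
#'
#' Generates the full set of datasets the pipeline consumes under one
#' master seed: an MSI/MSS bulk tumor cohort (76/450 samples), a cell-line
#' panel (20/34), a single-cell dataset (2,000 tumor-epithelial plus 500
#' other cells), two additional bulk validation cohorts, survival records
#' in which the hazard is linked to the bulk cohort's median-split GALNT7
#' expression, and an IHC cohort (619 tumors). All planted effects use the
#' default 0.8 log2 fold change on the five signature genes.
#'
#' @param seed Master integer seed; each dataset draws its own substream.
#' @param effect_log2fc Planted log2 fold change (0 gives a null study).
#' @return Named list: `bulk`, `cellline`, `sc`, `eval_cohorts` (named list
#'   of expression cohorts including `bulk`), `survival` (records aligned
#'   with the bulk cohort, `group` = high GALNT7), `ihc`.
#' @export
simulate_study <- function(seed = 1L, effect_log2fc = 0.8) {
  seeds <- substream_seeds(seed, c("bulk", "cellline", "sc", "val1", "val2",
                                   "surv", "ihc"))
  bulk <- generate_bulk_cohort(bulk_cohort_spec(
    n_msi = 76, n_mss = 450, effect_log2fc = effect_log2fc,
    seed = seeds[["bulk"]]))
  cellline <- generate_bulk_cohort(bulk_cohort_spec(
    n_msi = 20, n_mss = 34, effect_log2fc = effect_log2fc,
    seed = seeds[["cellline"]]))
  sc <- generate_single_cell(single_cell_spec(
    effect_log2fc = effect_log2fc, seed = seeds[["sc"]]))
  val1 <- generate_bulk_cohort(bulk_cohort_spec(
    n_msi = 40, n_mss = 160, effect_log2fc = effect_log2fc,
    seed = seeds[["val1"]]))
  val2 <- generate_bulk_cohort(bulk_cohort_spec(
    n_msi = 30, n_mss = 220, effect_log2fc = effect_log2fc,
    seed = seeds[["val2"]]))
  galnt7_high <- dichotomize_at_median(bulk$values["GALNT7", ]) == "high"
  surv <- generate_survival(as.integer(galnt7_high), survival_sim_spec(
    n = ncol(bulk$values), log_hr = log(0.5), baseline_hazard = 0.05,
    censoring_rate = 0.3, seed = seeds[["surv"]]))
  surv$sample_id <- colnames(bulk$values)
  ihc <- generate_ihc_cohort(ihc_sim_spec(seed = seeds[["ihc"]]))
  list(bulk = bulk, cellline = cellline, sc = sc,
       eval_cohorts = list(bulk = bulk, validation1 = val1,
                           validation2 = val2),
       survival = surv, ihc = ihc)
}

#' Run the full analysis pipeline
#'
#' Chains the stages: concordant tri-modal screen, Glyco-MSI scoring and
#' per-cohort AUC evaluation, median-split survival stratification of a
#' marker gene (falling back to the signature score if the gene is absent),
#' and the stratified IHC summary. Per-cohort failures are isolated in the
#' outputs; a run manifest (JSON) records the configuration, seed, package
#' version and output paths.
#'
#' @param study A study list as returned by [simulate_study()], or an
#'   equivalently shaped list of user data (`bulk`, `cellline`, `sc`
#'   required; `eval_cohorts`, `survival`, `ihc` optional).
#' @param out_dir Output directory; created if missing.
#' @param thresholds A [screen_thresholds()].
#' @param signature Optional [gene_signature()] overriding the screened
#'   signature for scoring/evaluation.
#' @param survival_gene Marker gene for the survival split (default
#'   `"GALNT7"`).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given the study data).
#' @return Invisibly, a list with `screen`, `signature`, `auc_table`,
#'   `survival`, `ihc_summary`, `manifest`.
#' @export
run_pipeline <- function(study, out_dir,
                         thresholds = screen_thresholds(),
                         signature = NULL, survival_gene = "GALNT7",
                         seed = NA_integer_) {
  for (req in c("bulk", "cellline", "sc"))
    if (is.null(study[[req]]))
      stop("study is missing the '", req, "' dataset")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    outputs[[name]] <<- p
    p
  }

  screen <- screen_cohorts(study$bulk, study$cellline, study$sc,
                           thresholds = thresholds)
  utils::write.csv(screen$result, emit("screen_result.csv"),
                   row.names = FALSE)
  sig <- if (!is.null(signature)) signature else screen$signature
  if (is.null(sig))
    stop("screen selected no genes and no signature override was given")
  write_signature(sig, emit("signature.json"))

  eval_cohorts <- study$eval_cohorts
  if (is.null(eval_cohorts)) eval_cohorts <- list(bulk = study$bulk)
  auc_table <- evaluate_cohorts(eval_cohorts, sig)
  utils::write.csv(auc_table, emit("auc_table.csv"), row.names = FALSE)

  surv_out <- NULL
  if (!is.null(study$survival)) {
    surv_out <- tryCatch({
      rec <- study$survival
      marker <- if (survival_gene %in% rownames(study$bulk$values))
        study$bulk$values[survival_gene, rec$sample_id]
      else glyco_msi_score(study$bulk, sig)$score[rec$sample_id]
      ms <- median_split_survival(rec$time, rec$event, marker)
      list(marker = if (survival_gene %in% rownames(study$bulk$values))
             survival_gene else sig$name,
           logrank_p = ms$logrank$p_value,
           hr = ms$cox$coefficients$hr[1],
           ci_low = ms$cox$coefficients$ci_low[1],
           ci_high = ms$cox$coefficients$ci_high[1],
           n = ms$cox$n, n_events = ms$cox$n_events)
    }, error = function(e) list(status = conditionMessage(e)))
    jsonlite::write_json(surv_out, emit("survival_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ihc_summary <- NULL
  if (!is.null(study$ihc)) {
    ihc_summary <- summarize_ihc_cohort(study$ihc)
    flat <- lapply(ihc_summary, function(s)
      list(n = s$n, n_high = s$n_high, prop_high = s$prop_high,
           pdl1_prop_pos_high = if (!is.null(s$pdl1)) s$pdl1$prop_pos_high,
           pdl1_prop_pos_low = if (!is.null(s$pdl1)) s$pdl1$prop_pos_low,
           pdl1_fisher_p = if (!is.null(s$pdl1) &&
                               inherits(s$pdl1$fisher, "fisher_result"))
             s$pdl1$fisher$p_value))
    jsonlite::write_json(flat, emit("ihc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "glycoMSI",
    version = as.character(utils::packageVersion("glycoMSI")),
    seed = seed,
    thresholds = unclass(thresholds),
    signature = list(name = sig$name, up = sig$up, down = sig$down),
    survival_gene = survival_gene,
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(screen = screen$result, signature = sig,
                 auc_table = auc_table, survival = surv_out,
                 ihc_summary = ihc_summary, manifest = manifest))
}
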