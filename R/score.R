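# The Glyco-MSI score and its evaluation: mean-difference signature
# scoring, signature-average (immune) scores, rank-based ROC/AUC, Pearson
# correlation, and the multi-cohort AUC table.

#' Glyco-MSI signature score
#'
#' Per sample: the average expression of the signature's up-regulated genes
#' minus the average expression of its down-regulated genes, on the
#' log2-scale values as provided (no re-normalization). Signature genes
#' missing from the matrix are dropped and counted.
#'
#' @param cohort An [expression_cohort()] (labels are not used here).
#' @param signature A [gene_signature()]; default [glyco_msi_signature()].
#' @return A list of class `"score_vector"` with elements `sample_ids`,
#'   `score` (named numeric), `signature_name`, `n_up_used`, `n_down_used`.
#' @examples
#' co <- generate_bulk_cohort(bulk_cohort_spec(n_msi = 5, n_mss = 5))
#' sv <- glyco_msi_score(co)
#' head(sv$score)
#' @export
glyco_msi_score <- function(cohort, signature = glyco_msi_signature()) {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(signature, "gene_signature"))
  genes <- rownames(cohort$values)
  up <- intersect(signature$up, genes)
  down <- intersect(signature$down, genes)
  if (length(signature$up) > 0 && length(up) == 0)
    stop("no up-arm signature gene present in the matrix")
  if (length(signature$down) > 0 && length(down) == 0)
    stop("no down-arm signature gene present in the matrix")
  arm_mean <- function(g) {
    if (length(g) == 0) return(rep(0, ncol(cohort$values)))
    colMeans(cohort$values[g, , drop = FALSE])
  }
  score <- arm_mean(up) - arm_mean(down)
  structure(list(sample_ids = colnames(cohort$values),
                 score = score,
                 signature_name = signature$name,
                 n_up_used = length(up), n_down_used = length(down)),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector '%s': %d samples (%d up / %d down genes used)\n",
              x$signature_name, length(x$score), x$n_up_used, x$n_down_used))
  print(utils::head(x$score))
  invisible(x)
}

#' Signature-average score
#'
#' Per-sample mean of the (present) genes of an arbitrary gene set; used
#' here as a plain-average immune-infiltration score over an immune gene
#' signature. Genes absent from the matrix are dropped.
#'
#' @param cohort An [expression_cohort()].
#' @param gene_set Character vector of gene symbols.
#' @return Named numeric vector, one value per sample.
#' @export
signature_average <- function(cohort, gene_set) {
  stopifnot(inherits(cohort, "expression_cohort"))
  present <- intersect(unique(as.character(gene_set)),
                       rownames(cohort$values))
  if (length(present) == 0)
    stop("no gene of the set is present in the matrix")
  colMeans(cohort$values[present, , drop = FALSE])
}

#' Rank-based ROC AUC
#'
#' The tie-corrected concordance probability that an MSI sample's score
#' exceeds an MSS sample's (ties counted half), computed through the
#' Mann-Whitney U statistic with midranks: `AUC = U / (n_pos * n_neg)`.
#' Exact and deterministic; no curve interpolation.
#'
#' @param scores Numeric vector of per-sample scores (finite).
#' @param labels Per-sample class labels.
#' @param positive The positive-class label (default `"MSI"`).
#' @return A list of class `"roc_result"` with `auc`, `n_pos`, `n_neg`,
#'   `u_statistic`.
#' @export
roc_auc <- function(scores, labels, positive = "MSI") {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  u <- sum(r[pos]) - n_pos * (n_pos + 1) / 2
  structure(list(auc = u / (n_pos * n_neg),
                 n_pos = n_pos, n_neg = n_neg, u_statistic = u),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (n_pos = %d, n_neg = %d, U = %.1f)\n",
              x$auc, x$n_pos, x$n_neg, x$u_statistic))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Paired numeric vectors, `n >= 3`, each with non-zero variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  stats::cor(x, y, method = "pearson")
}

#' Evaluate the signature score across cohorts
#'
#' Computes the Glyco-MSI score and its MSI-vs-MSS AUC for each cohort.
#' Per-cohort failures (e.g. a missing signature arm or a single-class
#' cohort) are reported in the `status` column without aborting the
#' remaining cohorts.
#'
#' @param cohorts Named list of [expression_cohort()] objects.
#' @param signature A [gene_signature()].
#' @return `data.frame` with one row per cohort: `cohort`, `auc`, `n_msi`,
#'   `n_mss`, `n_up_used`, `n_down_used`, `status` (`"ok"` or the error
#'   message).
#' @export
evaluate_cohorts <- function(cohorts, signature = glyco_msi_signature()) {
  if (length(cohorts) == 0) stop("at least one cohort required")
  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  rows <- lapply(names(cohorts), function(nm) {
    co <- cohorts[[nm]]
    out <- data.frame(cohort = nm, auc = NA_real_,
                      n_msi = NA_integer_, n_mss = NA_integer_,
                      n_up_used = NA_integer_, n_down_used = NA_integer_,
                      status = "ok", stringsAsFactors = FALSE)
    tryCatch({
      sv <- glyco_msi_score(co, signature)
      roc <- roc_auc(sv$score, co$labels, positive = "MSI")
      out$auc <- roc$auc
      out$n_msi <- roc$n_pos
      out$n_mss <- roc$n_neg
      out$n_up_used <- sv$n_up_used
      out$n_down_used <- sv$n_down_used
      out
    }, error = function(e) {
      out$status <- conditionMessage(e)
      out
    })
  })
  do.call(rbind, rows)
}
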