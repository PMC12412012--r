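# The tri-modal concordant screen: per-modality MSI-vs-MSS log2 fold
# changes (bulk tissue, cell lines, single tumor-epithelial cells), the
# single-cell prevalence filter, and the selection rule that assembles the
# signature.

#' Per-gene log2 fold change between two classes
#'
#' Difference of group means of log2-scale values (not the log2 of a ratio
#' of linear means): `mean(class_a) - mean(class_b)` per gene. By the
#' package convention class_a is MSI and class_b is MSS, so positive values
#' mean up-regulation in MSI.
#'
#' @param cohort An [expression_cohort()] of log2-scale values.
#' @param class_a,class_b Class labels (defaults `"MSI"`, `"MSS"`).
#' @return Named numeric vector, one value per gene.
#' @export
log2_fold_change <- function(cohort, class_a = "MSI", class_b = "MSS") {
  stopifnot(inherits(cohort, "expression_cohort"))
  in_a <- cohort$labels == class_a
  in_b <- cohort$labels == class_b
  if (sum(in_a) < 2 || sum(in_b) < 2)
    stop("each class needs at least 2 samples (",
         class_a, ": ", sum(in_a), ", ", class_b, ": ", sum(in_b), ")")
  rowMeans(cohort$values[, in_a, drop = FALSE]) -
    rowMeans(cohort$values[, in_b, drop = FALSE])
}

#' Fraction of cells expressing each gene
#'
#' Proportion of the masked cells with a non-zero count, per gene. Used for
#' the prevalence rule that a gene must be expressed by at least 5% of
#' tumor epithelial cells to enter the screen.
#'
#' @param sc An [sc_dataset()].
#' @param cell_mask Logical vector over cells (default: tumor-epithelial
#'   cells).
#' @return Named numeric vector of proportions in `[0, 1]`.
#' @export
fraction_expressing <- function(sc, cell_mask = sc$cells$cell_type == "tumor_epithelial") {
  stopifnot(inherits(sc, "sc_dataset"))
  if (!any(cell_mask)) stop("cell mask selects no cells")
  sub <- sc$counts[, cell_mask, drop = FALSE]
  frac <- Matrix::rowSums(sub > 0) / ncol(sub)
  stats::setNames(as.numeric(frac), rownames(sc$counts))
}

#' Single-cell log2 fold change between MSI and MSS tumor-epithelial cells
#'
#' Mean `log2(count + 1)` over tumor-epithelial cells of MSI patients minus
#' the same over tumor-epithelial cells of MSS patients, per gene. Cells
#' are pooled across patients.
#'
#' @param sc An [sc_dataset()].
#' @return Named numeric vector, one value per gene.
#' @export
sc_log2_fold_change <- function(sc) {
  stopifnot(inherits(sc, "sc_dataset"))
  epi <- sc$cells$cell_type == "tumor_epithelial"
  msi <- sc$patient_msi[as.character(sc$cells$patient_id)] == "MSI"
  a <- epi & msi
  b <- epi & !msi
  if (!any(a) || !any(b))
    stop("tumor-epithelial cells required for both MSI and MSS patients")
  lc <- function(m) {
    m <- as.matrix(m)
    rowMeans(log2(m + 1))
  }
  lc(sc$counts[, a, drop = FALSE]) - lc(sc$counts[, b, drop = FALSE])
}

#' Screen thresholds
#'
#' @param fc_threshold Absolute log2 fold-change threshold; selection uses
#'   the strict inequality `|fc| > fc_threshold` in every modality
#'   (default 0.4).
#' @param prevalence_threshold Minimum fraction of tumor-epithelial cells
#'   expressing the gene, compared with `>=` (default 0.05, "at least 5%").
#' @param require_sign_concordance Require all three fold changes to share
#'   one sign (default `TRUE`), implementing "consistently up- or
#'   down-regulated".
#' @return A list of class `"screen_thresholds"`.
#' @export
screen_thresholds <- function(fc_threshold = 0.4,
                              prevalence_threshold = 0.05,
                              require_sign_concordance = TRUE) {
  if (fc_threshold <= 0) stop("fc_threshold must be positive")
  if (prevalence_threshold <= 0 || prevalence_threshold >= 1)
    stop("prevalence_threshold must be in (0, 1)")
  structure(list(fc_threshold = fc_threshold,
                 prevalence_threshold = prevalence_threshold,
                 require_sign_concordance = require_sign_concordance),
            class = "screen_thresholds")
}

#' Concordant tri-modal signature screen
#'
#' Selects the genes whose MSI-vs-MSS log2 fold change exceeds the
#' threshold in absolute value in all three modalities (bulk tissue, cell
#' line, single cell), that are expressed by at least the prevalence
#' threshold of tumor epithelial cells, and (by default) whose fold changes
#' agree in sign. Genes missing from any modality (NA fold change or
#' prevalence) cannot satisfy "all three datasets" and are reported as
#' unevaluable.
#'
#' @param bulk_fc,cellline_fc,sc_fc Named per-gene log2 fold-change vectors
#'   over the same gene universe (see [log2_fold_change()],
#'   [sc_log2_fold_change()]).
#' @param frac_sc Named per-gene fraction of tumor-epithelial cells
#'   expressing the gene (see [fraction_expressing()]).
#' @param thresholds A [screen_thresholds()].
#' @param signature_name Name given to the assembled signature.
#' @return A list with `result` (a `data.frame` with columns `gene`,
#'   `log2fc_bulk`, `log2fc_cellline`, `log2fc_sc`, `frac_expressing_sc`,
#'   `evaluable`, `selected`, `direction`) and `signature`
#'   (a [gene_signature()] of the selected genes; `NULL` if none selected).
#' @export
screen_signature <- function(bulk_fc, cellline_fc, sc_fc, frac_sc,
                             thresholds = screen_thresholds(),
                             signature_name = "screened") {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  genes <- names(bulk_fc)
  if (is.null(genes))
    stop("fold-change vectors must be named by gene")
  for (v in list(cellline_fc, sc_fc, frac_sc))
    if (!setequal(names(v), genes))
      stop("all per-gene vectors must cover the same gene universe")
  cellline_fc <- cellline_fc[genes]
  sc_fc <- sc_fc[genes]
  frac_sc <- frac_sc[genes]

  fc <- cbind(bulk = bulk_fc, cellline = cellline_fc, sc = sc_fc)
  evaluable <- stats::complete.cases(fc) & !is.na(frac_sc)
  pass_fc <- rowSums(abs(fc) > thresholds$fc_threshold) == 3
  pass_prev <- frac_sc >= thresholds$prevalence_threshold
  same_sign <- apply(sign(fc), 1, function(s) all(s == s[1]) && s[1] != 0)
  selected <- evaluable & pass_fc & pass_prev &
    (!thresholds$require_sign_concordance | same_sign)
  selected[is.na(selected)] <- FALSE
  direction <- rep("none", length(genes))
  direction[selected] <- ifelse(bulk_fc[selected] > 0, "up", "down")

  result <- data.frame(gene = genes,
                       log2fc_bulk = as.numeric(bulk_fc),
                       log2fc_cellline = as.numeric(cellline_fc),
                       log2fc_sc = as.numeric(sc_fc),
                       frac_expressing_sc = as.numeric(frac_sc),
                       evaluable = evaluable,
                       selected = as.logical(selected),
                       direction = direction,
                       stringsAsFactors = FALSE,
                       row.names = NULL)
  up <- result$gene[result$selected & result$direction == "up"]
  down <- result$gene[result$selected & result$direction == "down"]
  signature <- if (length(up) + length(down) > 0)
    gene_signature(up, down, name = signature_name) else NULL
  list(result = result, signature = signature)
}

#' Run the full screen from cohort objects
#'
#' Convenience wrapper computing the three fold-change vectors and the
#' prevalence vector from an MSI/MSS bulk cohort, a cell-line cohort, and a
#' single-cell dataset, then applying [screen_signature()] over the genes
#' common to all three.
#'
#' @param bulk,cellline [expression_cohort()] objects.
#' @param sc An [sc_dataset()].
#' @inheritParams screen_signature
#' @return As [screen_signature()].
#' @export
screen_cohorts <- function(bulk, cellline, sc,
                           thresholds = screen_thresholds(),
                           signature_name = "screened") {
  genes <- rownames(bulk$values)
  pad <- function(v) {
    out <- stats::setNames(rep(NA_real_, length(genes)), genes)
    common <- intersect(genes, names(v))
    out[common] <- v[common]
    out
  }
  screen_signature(bulk_fc = log2_fold_change(bulk),
                   cellline_fc = pad(log2_fold_change(cellline)),
                   sc_fc = pad(sc_log2_fold_change(sc)),
                   frac_sc = pad(fraction_expressing(sc)),
                   thresholds = thresholds,
                   signature_name = signature_name)
}
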