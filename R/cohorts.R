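#' Expression cohort container
#'
#' Bundles a genes-by-samples matrix of log2-scale expression values with a
#' per-sample MSI/MSS class label. This is the substrate of the concordant
#' screen, the Glyco-MSI score, and the cohort-level AUC evaluation.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene symbols),
#'   samples in columns (colnames are sample ids). Values are assumed to be
#'   on a log2 scale already; no transformation is applied.
#' @param labels Character vector of per-sample class labels, `"MSI"` or
#'   `"MSS"`, one per column of `values`. May be a named vector keyed by
#'   sample id, in which case it is reordered to match the columns.
#' @return An object of class `"expression_cohort"`: a list with elements
#'   `values` and `labels`.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' co <- expression_cohort(m, c("MSI", "MSI", "MSS", "MSS", "MSS"))
#' @export
expression_cohort <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in 'values'")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in 'values'")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  labels <- as.character(labels)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), colnames(values)))
      stop("label names do not match sample ids")
    labels <- labels[colnames(values)]
  }
  if (length(labels) != ncol(values))
    stop("one label per sample required")
  bad <- setdiff(unique(labels), c("MSI", "MSS"))
  if (length(bad))
    stop("labels must be 'MSI' or 'MSS'; found: ",
         paste(bad, collapse = ", "),
         " (use harmonize_msi_labels() first)")
  names(labels) <- colnames(values)
  structure(list(values = values, labels = labels),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("expression_cohort: %d genes x %d samples (%d MSI, %d MSS)\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "MSI"), sum(x$labels == "MSS")))
  invisible(x)
}

#' Single-cell dataset container
#'
#' Holds a genes-by-cells count matrix together with per-cell annotations
#' (cell type, tissue, patient) and the per-patient MSI label. Counts are
#' assumed to be non-negative (raw or normalized); the screen applies
#' log2(count + 1) internally.
#'
#' @param counts Matrix (dense or `Matrix::sparseMatrix`) of non-negative
#'   values, genes in rows, cells in columns; dimnames required.
#' @param cells `data.frame` with one row per cell and columns `barcode`,
#'   `cell_type` (one of `"tumor_epithelial"`, `"normal_epithelial"`,
#'   `"stromal"`, `"immune"`), `tissue` (`"tumor"`/`"normal"`), `patient_id`.
#' @param patient_msi Named character vector mapping every `patient_id` to
#'   `"MSI"` or `"MSS"`.
#' @return An object of class `"sc_dataset"`.
#' @export
sc_dataset <- function(counts, cells, patient_msi) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene rownames and cell colnames")
  if (min(counts) < 0) stop("counts must be non-negative")
  required <- c("barcode", "cell_type", "tissue", "patient_id")
  if (!all(required %in% names(cells)))
    stop("'cells' must have columns: ", paste(required, collapse = ", "))
  if (nrow(cells) != ncol(counts))
    stop("one annotation row per cell required")
  if (!identical(as.character(cells$barcode), colnames(counts)))
    stop("cell barcodes must match count matrix columns in order")
  bad <- setdiff(unique(as.character(cells$cell_type)), sc_cell_types())
  if (length(bad))
    stop("unknown cell types: ", paste(bad, collapse = ", "))
  missing_pat <- setdiff(unique(as.character(cells$patient_id)),
                         names(patient_msi))
  if (length(missing_pat))
    stop("patients without an MSI label: ",
         paste(missing_pat, collapse = ", "))
  bad_lab <- setdiff(unique(patient_msi), c("MSI", "MSS"))
  if (length(bad_lab))
    stop("patient_msi values must be 'MSI' or 'MSS'")
  structure(list(counts = counts, cells = cells, patient_msi = patient_msi),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("sc_dataset: %d genes x %d cells, %d patients\n",
              nrow(x$counts), ncol(x$counts), length(x$patient_msi)))
  print(table(x$cells$cell_type))
  invisible(x)
}

#' Fixed vocabulary of single-cell cell-type labels
#' @return Character vector of the four admissible cell-type labels.
#' @export
sc_cell_types <- function() {
  c("tumor_epithelial", "normal_epithelial", "stromal", "immune")
}

#' Gene signature (up/down arm lists)
#'
#' An ordered pair of disjoint gene lists: genes up-regulated in MSI tumors
#' and genes down-regulated in MSI tumors. The Glyco-MSI score is the mean
#' expression over the up arm minus the mean over the down arm.
#'
#' @param up Character vector of up-regulated gene symbols.
#' @param down Character vector of down-regulated gene symbols.
#' @param name Signature name.
#' @return An object of class `"gene_signature"`.
#' @seealso [glyco_msi_signature()] for the packaged default.
#' @export
gene_signature <- function(up, down, name = "custom") {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stop("up and down arms must be disjoint")
  if (length(up) + length(down) < 1)
    stop("signature must contain at least one gene")
  structure(list(name = name, up = up, down = down),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': up = {%s}; down = {%s}\n", x$name,
              paste(x$up, collapse = ", "), paste(x$down, collapse = ", ")))
  invisible(x)
}

#' The default Glyco-MSI signature
#'
#' The five glycosyltransferase genes that separate MSI from MSS colorectal
#' cancers concordantly across bulk tissue, cell lines, and single tumor
#' epithelial cells: GALNT7, GALNT1 and HPSE up-regulated in MSI; GALNT6
#' and ST6GAL1 down-regulated.
#'
#' @return A [gene_signature()] named `"glyco_msi_v1"`.
#' @examples
#' glyco_msi_signature()
#' @export
glyco_msi_signature <- function() {
  gene_signature(up = c("GALNT7", "GALNT1", "HPSE"),
                 down = c("GALNT6", "ST6GAL1"),
                 name = "glyco_msi_v1")
}
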