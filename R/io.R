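# Readers and writers for the plain-text interchange formats (expression
# TSV, annotation CSV, MatrixMarket single-cell triplets, signature JSON)
# and the two cohort-preprocessing rules applied before analysis: probe
# collapse and MSI label harmonization.

#' Write / read an expression matrix as TSV
#'
#' Tab-separated, header row of sample ids, first column `gene` holding the
#' gene (or probe) id, UTF-8, `.` decimal — the layout of GEO
#' series-matrix-derived exports.
#'
#' @param values Numeric matrix with gene rownames and sample colnames, or
#'   an [expression_cohort()] (its `values` are written).
#' @param path File path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns the numeric matrix.
#' @export
write_expression_tsv <- function(values, path) {
  if (inherits(values, "expression_cohort")) values <- values$values
  df <- data.frame(gene = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write / read per-sample MSI labels as CSV
#'
#' Two columns: `sample_id`, `label`.
#'
#' @param labels Named character vector (names = sample ids).
#' @param path File path.
#' @return The path (write) or a named character vector (read).
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(data.frame(sample_id = names(labels),
                              label = as.character(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$label, df$sample_id)
}

#' Read an expression cohort (matrix TSV + label CSV)
#'
#' Raw labels are passed through [harmonize_msi_labels()]; samples whose
#' label is unknown are dropped with a message.
#'
#' @param matrix_path Expression TSV (see [read_expression_tsv()]).
#' @param label_path Label CSV (see [read_labels_csv()]).
#' @param synonyms Synonym table for [harmonize_msi_labels()].
#' @return An [expression_cohort()].
#' @export
read_expression_cohort <- function(matrix_path, label_path,
                                   synonyms = msi_label_synonyms()) {
  m <- read_expression_tsv(matrix_path)
  raw <- read_labels_csv(label_path)
  lab <- harmonize_msi_labels(raw, synonyms)
  keep <- names(lab)[lab != "unknown"]
  dropped <- sum(lab == "unknown")
  if (dropped > 0)
    message(dropped, " sample(s) with unknown MSI label dropped")
  keep <- intersect(colnames(m), keep)
  expression_cohort(m[, keep, drop = FALSE], lab[keep])
}

#' Write a cohort to a directory (matrix TSV + labels CSV + spec JSON)
#'
#' @param cohort An [expression_cohort()].
#' @param dir Output directory (created if absent).
#' @param name Base name for the files.
#' @param spec Optional generator spec recorded as a JSON sidecar.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, name = "cohort", spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(cohort, file.path(dir, paste0(name, "_matrix.tsv")))
  write_labels_csv(cohort$labels, file.path(dir, paste0(name, "_labels.csv")))
  if (!is.null(spec))
    jsonlite::write_json(unclass(spec),
                         file.path(dir, paste0(name, "_spec.json")),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write / read a single-cell dataset (MTX triplet + annotation CSV)
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `cells.csv`
#' (columns `barcode`, `cell_type`, `tissue`, `patient_id`, `patient_msi`).
#'
#' @param sc An [sc_dataset()].
#' @param dir Directory.
#' @return The directory (write) or an [sc_dataset()] (read).
#' @export
write_sc_dataset <- function(sc, dir) {
  stopifnot(inherits(sc, "sc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(Matrix::Matrix(sc$counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(sc$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(sc$counts), file.path(dir, "barcodes.tsv"))
  ann <- sc$cells
  ann$patient_msi <- unname(sc$patient_msi[as.character(ann$patient_id)])
  utils::write.csv(ann, file.path(dir, "cells.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' @rdname write_sc_dataset
#' @export
read_sc_dataset <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  ann <- utils::read.csv(file.path(dir, "cells.csv"),
                         stringsAsFactors = FALSE)
  patient_msi <- stats::setNames(
    ann$patient_msi[!duplicated(ann$patient_id)],
    ann$patient_id[!duplicated(ann$patient_id)])
  sc_dataset(m, ann[c("barcode", "cell_type", "tissue", "patient_id")],
             patient_msi)
}

#' Write / read a gene signature as JSON
#'
#' JSON object `{name, up, down}`.
#'
#' @param signature A [gene_signature()].
#' @param path File path.
#' @return The path (write) or a [gene_signature()] (read).
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "gene_signature"))
  jsonlite::write_json(list(name = signature$name, up = signature$up,
                            down = signature$down),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_signature(x$up, x$down, name = x$name)
}

#' Collapse probe-level rows to gene level
#'
#' If a gene is represented by multiple probes, only the probe with the
#' highest across-sample mean expression is kept. Ties are broken toward
#' the lexicographically smallest probe id; probes without a gene mapping
#' are dropped (with a message giving the count).
#'
#' @param values Numeric matrix, probes in rows.
#' @param probe_to_gene Named character vector mapping probe id to gene
#'   symbol (or a two-column `data.frame` `probe`, `gene`).
#' @return Numeric matrix with one row per distinct mapped gene.
#' @export
collapse_probes <- function(values, probe_to_gene) {
  if (nrow(values) == 0) stop("empty matrix")
  if (is.data.frame(probe_to_gene))
    probe_to_gene <- stats::setNames(as.character(probe_to_gene$gene),
                                     probe_to_gene$probe)
  probes <- rownames(values)
  mapped <- probes[probes %in% names(probe_to_gene)]
  n_dropped <- length(probes) - length(mapped)
  if (n_dropped > 0)
    message(n_dropped, " unmapped probe(s) dropped")
  if (length(mapped) == 0) stop("no probe maps to a gene")
  genes <- probe_to_gene[mapped]
  means <- rowMeans(values[mapped, , drop = FALSE])
  ord <- order(genes, -means, mapped, method = "radix")
  best <- mapped[ord][!duplicated(genes[ord])]
  out <- values[best, , drop = FALSE]
  rownames(out) <- unname(genes[best])
  out
}

#' Default MSI label synonym table
#'
#' Maps recognized raw labels (lower-cased) to the harmonized MSI/MSS
#' vocabulary: MSI-high and dMMR become MSI; MSI-low, MSS and pMMR become
#' MSS.
#'
#' @return Named character vector keyed by lower-case raw label.
#' @export
msi_label_synonyms <- function() {
  c("msi" = "MSI", "msi-h" = "MSI", "msi-high" = "MSI", "msi_high" = "MSI",
    "dmmr" = "MSI",
    "msi-l" = "MSS", "msi-low" = "MSS", "msi_low" = "MSS",
    "mss" = "MSS", "pmmr" = "MSS")
}

#' Harmonize raw MSI status labels
#'
#' MSI-high (and dMMR) map to `"MSI"`; MSI-low is combined with MSS (and
#' pMMR) into `"MSS"`. Matching is case-insensitive through a configurable
#' synonym table; unrecognized labels become `"unknown"` (data, not an
#' error) and a message reports their count.
#'
#' @param raw_labels Character vector of raw status labels (names kept).
#' @param synonyms Synonym table, as [msi_label_synonyms()].
#' @return Character vector over `{"MSI", "MSS", "unknown"}`.
#' @export
harmonize_msi_labels <- function(raw_labels, synonyms = msi_label_synonyms()) {
  key <- tolower(trimws(as.character(raw_labels)))
  out <- unname(synonyms[key])
  out[is.na(out)] <- "unknown"
  n_unk <- sum(out == "unknown")
  if (n_unk > 0)
    message(n_unk, " unrecognized MSI label(s) set to 'unknown'")
  stats::setNames(out, names(raw_labels))
}

#' Write / read IHC records as CSV
#'
#' @param records IHC record `data.frame` (see [generate_ihc_cohort()]).
#' @param path File path.
#' @return The path (write) or the `data.frame` (read).
#' @export
write_ihc_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ihc_csv
#' @export
read_ihc_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
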