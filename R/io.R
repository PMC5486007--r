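# All tabular I/O uses one dialect: tab-separated, UTF-8, '.' decimal,
# header row, no quoting. Gene identifiers are opaque strings at this
# boundary.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (ncol(d) < 2) stop("expected at least 2 tab-separated columns in ", path)
  d
}

as_numeric_checked <- function(d, path) {
  m <- as.matrix(d[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) & !(is.na(m) | m %in% c("", "NA")), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell(s) in ", path, " at line(s) ",
         paste(unique(bad[, 1] + 1L), collapse = ", "))
  dimnames(num) <- list(d[[1]], colnames(d)[-1])
  num
}

#' Read a gene-by-sample expression table
#'
#' @param path TSV file: first column gene ids, header row of sample ids.
#' @param scale scale of the stored values (`"linear"` or `"log2"`).
#' @param orientation `"genes_by_samples"` (default) or `"samples_by_genes"`
#'   (transposed on read).
#' @return An [expression_matrix()]. Missing cells are rejected (the
#'   container does not allow them); use [read_ct_table()]-style raw matrices
#'   for data with dropouts.
#' @export
read_expression_table <- function(path, scale = c("linear", "log2"),
                                  orientation = c("genes_by_samples",
                                                  "samples_by_genes")) {
  scale <- match.arg(scale)
  orientation <- match.arg(orientation)
  d <- read_tsv_checked(path)
  if (anyDuplicated(d[[1]]))
    stop("duplicated gene id(s) in ", path, ": ",
         paste(unique(d[[1]][duplicated(d[[1]])]), collapse = ", "))
  num <- as_numeric_checked(d, path)
  if (orientation == "samples_by_genes") num <- t(num)
  expression_matrix(num, scale = scale, provenance = path)
}

#' Write an expression matrix as TSV
#' @param x an [expression_matrix()].
#' @param path output file.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  write_tsv_matrix(x$values, path, id_col = "gene")
}

write_tsv_matrix <- function(m, path, id_col = "gene") {
  d <- data.frame(rownames(m), signif(m, 6), check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d) <- c(id_col, colnames(m))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Ct table and efficiency table into a qPCR dataset
#'
#' @param ct_path TSV of Ct values (genes x samples; first column gene id).
#' @param efficiency_path optional two-column TSV (`gene`, `efficiency`);
#'   assays without an entry default to efficiency 2.0 with a warning.
#' @param reference_genes character vector of reference gene ids.
#' @return A [qpcr_dataset()].
#' @export
read_ct_table <- function(ct_path, efficiency_path = NULL, reference_genes) {
  d <- read_tsv_checked(ct_path)
  if (anyDuplicated(d[[1]]))
    stop("duplicated assay id(s) in ", ct_path, ": ",
         paste(unique(d[[1]][duplicated(d[[1]])]), collapse = ", "))
  ct <- as_numeric_checked(d, ct_path)
  if (anyNA(ct)) {
    bad <- which(is.na(ct), arr.ind = TRUE)
    stop("missing Ct value(s) in ", ct_path, ": ",
         paste(sprintf("%s/%s", rownames(ct)[bad[, 1]],
                       colnames(ct)[bad[, 2]]), collapse = ", "))
  }
  eff <- NULL
  if (!is.null(efficiency_path)) {
    e <- read_tsv_checked(efficiency_path)
    eff <- stats::setNames(as.numeric(e[[2]]), e[[1]])
  }
  qpcr_dataset(ct, efficiency = eff, reference_genes = reference_genes)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id`, `diagnosis` and optionally
#'   `oncocytic` (true/false), `tier`, and further covariates.
#' @return A [sample_annotation()].
#' @export
read_sample_sheet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "diagnosis") %in% names(d)))
    stop("sample sheet needs columns 'sample_id' and 'diagnosis': ", path)
  onco <- if ("oncocytic" %in% names(d))
    tolower(as.character(d$oncocytic)) %in% c("true", "1", "yes")
  else rep(FALSE, nrow(d))
  tier <- if ("tier" %in% names(d)) d$tier else "validation"
  extra <- d[setdiff(names(d), c("sample_id", "diagnosis", "oncocytic",
                                 "tier"))]
  do.call(sample_annotation,
          c(list(sample_id = d$sample_id, diagnosis = d$diagnosis,
                 oncocytic = onco, tier = tier), as.list(extra)))
}

#' Write a sample sheet
#' @param annot a [sample_annotation()].
#' @param path output TSV.
#' @export
write_sample_sheet <- function(annot, path) {
  utils::write.table(as.data.frame(annot), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-study gene lists
#'
#' @param path TSV with columns `study_id`, `raw_id`, `namespace`,
#'   `direction`.
#' @return A [raw_study_collection()].
#' @export
read_study_lists <- function(path) {
  raw_study_collection(utils::read.delim(path, stringsAsFactors = FALSE,
                                         colClasses = "character"))
}

#' Read an identifier-mapping table
#' @param path TSV with columns `raw_id`, `namespace`, `gene_id`, `symbol`.
#' @return An [id_map()].
#' @export
read_id_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$gene_id <- as.integer(d$gene_id)
  id_map(d)
}

#' Write an analysis result table as TSV
#'
#' Dispatches on the result type (differential-expression table, vote table,
#' cross-validation result or metric table); numeric columns are written at 6
#' significant digits with a stable column order, so repeated runs on the
#' same input are byte-identical.
#'
#' @param x a `de_result`, `vote_table`, `cv_result` or `metric_table`.
#' @param path output TSV.
#' @export
write_results <- function(x, path) {
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], signif, 6)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a simulated qPCR cohort to TSV files
#'
#' Emits the same formats the analysis readers consume: `<prefix>_ct.tsv`,
#' `<prefix>_efficiency.tsv` and `<prefix>_samples.tsv`.
#'
#' @param sim a [simulate_qpcr_dataset()] result.
#' @param prefix output path prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_qpcr_dataset <- function(sim, prefix) {
  ct_path <- paste0(prefix, "_ct.tsv")
  eff_path <- paste0(prefix, "_efficiency.tsv")
  ss_path <- paste0(prefix, "_samples.tsv")
  write_tsv_matrix(sim$data$ct, ct_path, id_col = "gene")
  utils::write.table(
    data.frame(gene = names(sim$data$efficiency),
               efficiency = sim$data$efficiency),
    eff_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sample_sheet(sim$annotation, ss_path)
  invisible(c(ct = ct_path, efficiency = eff_path, samples = ss_path))
}
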