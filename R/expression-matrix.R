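#' Expression matrix container
#'
#' A light container for a gene-by-sample value table together with the scale
#' the values live on. Linear relative quantities (e.g. Pfaffl-normalized qPCR
#' quantities) must be strictly positive; `log2` values are unrestricted.
#'
#' @param values numeric matrix, genes in rows, samples in columns; dimnames
#'   required on both margins.
#' @param scale `"linear"` for linear relative quantities, `"log2"` for
#'   log2-transformed values.
#' @param provenance optional character note on how the matrix was produced.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `scale` and `provenance`. Normalization attaches the per-sample
#'   normalization factor as element `nf`, and the retained (unnormalized)
#'   reference rows as `reference_genes`.
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))), scale = "linear")
#' @export
expression_matrix <- function(values, scale = c("linear", "log2"),
                              provenance = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyNA(values))
    stop("missing values are not allowed in an expression matrix")
  if (scale == "linear" && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)
    stop("linear-scale values must be strictly positive; offending cells: ",
         paste(sprintf("%s/%s", rownames(values)[bad[, 1]],
                       colnames(values)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
               collapse = ", "))
  }
  structure(list(values = values, scale = scale, provenance = provenance),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Log-transform a linear-relative expression matrix
#'
#' Elementwise logarithm of a strictly positive linear-scale matrix; the scale
#' flag is flipped so downstream tests know they operate on log values.
#' Non-positive cells raise an error naming the offending entries rather than
#' being silently floored.
#'
#' @param matrix an [expression_matrix()] on the linear scale.
#' @param base logarithm base, default 2.
#' @return An `expr_matrix` on the `log2` scale (any attached normalization
#'   factor is carried over).
#' @export
log_transform <- function(matrix, base = 2) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$scale != "linear")
    stop("log_transform expects a linear-scale matrix")
  v <- matrix$values
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)
    stop("non-positive values cannot be log-transformed: ",
         paste(sprintf("%s/%s", rownames(v)[bad[, 1]], colnames(v)[bad[, 2]]),
               collapse = ", "))
  }
  out <- matrix
  out$values <- log(v, base = base)
  out$scale <- "log2"
  out
}
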