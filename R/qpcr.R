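#' qPCR dataset container
#'
#' Bundles a cycle-threshold (Ct) table with per-assay amplification
#' efficiencies and the designated reference-gene set. An efficiency E is the
#' fold amplification per PCR cycle (2.0 = perfect doubling); assays without a
#' measured efficiency default to 2.0 with a warning. Technical replicates, if
#' supplied as a 3-dimensional array (gene x sample x replicate), are collapsed
#' by the arithmetic mean of Ct before any ratio is formed.
#'
#' @param ct numeric gene-by-sample matrix of Ct values (or a 3-d array with
#'   replicates in the third dimension), finite and positive; dimnames required.
#' @param efficiency named numeric vector of per-assay efficiencies in (1, 2];
#'   missing assays default to 2.0.
#' @param reference_genes character vector of reference (normalization) gene
#'   identifiers, all present in `ct`.
#' @return An object of class `qpcr_dataset` with elements `ct`, `efficiency`
#'   and `reference_genes`.
#' @export
qpcr_dataset <- function(ct, efficiency = NULL, reference_genes) {
  if (length(dim(ct)) == 3) ct <- apply(ct, c(1, 2), mean)
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("'ct' must be a numeric gene x sample matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("'ct' must have gene rownames and sample colnames")
  if (anyNA(ct) || any(!is.finite(ct)) || any(ct <= 0)) {
    bad <- which(!is.finite(ct) | ct <= 0, arr.ind = TRUE)
    stop("Ct values must be finite and positive; offending cells: ",
         paste(sprintf("%s/%s", rownames(ct)[bad[, 1]], colnames(ct)[bad[, 2]]),
               collapse = ", "))
  }
  genes <- rownames(ct)
  eff <- rep_len(2.0, length(genes))
  names(eff) <- genes
  if (!is.null(efficiency)) {
    if (is.null(names(efficiency)))
      stop("'efficiency' must be named by assay (gene)")
    unknown <- setdiff(names(efficiency), genes)
    if (length(unknown))
      stop("efficiencies given for unknown assays: ",
           paste(unknown, collapse = ", "))
    eff[names(efficiency)] <- efficiency
    missing_eff <- setdiff(genes, names(efficiency))
    if (length(missing_eff))
      warning("no measured efficiency for ", length(missing_eff),
              " assay(s); defaulting to 2.0: ",
              paste(missing_eff, collapse = ", "))
  }
  if (any(eff <= 1 | eff > 2))
    stop("amplification efficiencies must lie in (1, 2]; offending assays: ",
         paste(genes[eff <= 1 | eff > 2], collapse = ", "))
  if (length(reference_genes) == 0)
    stop("reference gene set is empty")
  if (!all(reference_genes %in% genes))
    stop("reference genes absent from Ct table: ",
         paste(setdiff(reference_genes, genes), collapse = ", "))
  structure(list(ct = ct, efficiency = eff,
                 reference_genes = as.character(reference_genes)),
            class = "qpcr_dataset")
}

#' @export
print.qpcr_dataset <- function(x, ...) {
  cat(sprintf("qpcr_dataset: %d assays x %d samples, %d reference gene(s)\n",
              nrow(x$ct), ncol(x$ct), length(x$reference_genes)))
  invisible(x)
}

#' Efficiency-corrected relative quantification (Pfaffl method)
#'
#' For each gene g and sample s the relative quantity is
#' \eqn{Q(g,s) = E_g^{Ct_{cal}(g) - Ct(g,s)}}, where the calibrator Ct is the
#' per-gene arithmetic mean over all samples (default) or the Ct of a named
#' calibrator sample. Target quantities are then divided by the per-sample
#' normalization factor \eqn{NF(s)}, the geometric mean of the reference-gene
#' quantities in that sample (the geNorm multi-reference convention). With a
#' single reference this reduces to the classical Pfaffl ratio
#' \eqn{E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}}.
#'
#' @param data a [qpcr_dataset()].
#' @param calibrator `"mean"` (per-gene mean Ct over all samples) or the name
#'   of a calibrator sample.
#' @return A linear-scale [expression_matrix()] of the normalized target
#'   genes, with the per-sample normalization factor in `$nf` and the
#'   unnormalized reference-gene quantities retained in `$reference_quantities`.
#' @examples
#' ct <- rbind(tgt = c(25, 23), ref = c(24, 23))
#' colnames(ct) <- c("cal", "s")
#' d <- qpcr_dataset(ct, c(tgt = 2, ref = 2), reference_genes = "ref")
#' pfaffl_relative_quantity(d, calibrator = "cal")$values  # tgt ratio = 2
#' @export
pfaffl_relative_quantity <- function(data, calibrator = "mean") {
  stopifnot(inherits(data, "qpcr_dataset"))
  ct <- data$ct
  if (identical(calibrator, "mean")) {
    ct_cal <- rowMeans(ct)
  } else {
    if (!calibrator %in% colnames(ct))
      stop("calibrator sample not found: ", calibrator)
    ct_cal <- ct[, calibrator]
  }
  e <- data$efficiency[rownames(ct)]
  q <- e ^ (ct_cal - ct)          # E and ct_cal recycle down columns
  refs <- data$reference_genes
  nf <- exp(colMeans(log(q[refs, , drop = FALSE])))
  targets <- setdiff(rownames(ct), refs)
  if (length(targets) == 0)
    stop("dataset contains no target genes beyond the reference set")
  norm <- sweep(q[targets, , drop = FALSE], 2, nf, "/")
  out <- expression_matrix(norm, scale = "linear",
                           provenance = "Pfaffl efficiency-corrected, multi-reference NF")
  out$nf <- nf
  out$reference_quantities <- q[refs, , drop = FALSE]
  out
}

#' geNorm reference-gene stability ranking
#'
#' The geNorm stability measure of a candidate gene g is
#' \eqn{M(g) = \mathrm{mean}_{h \ne g}\, \mathrm{sd}_s\, \log_2 (Q(g,s)/Q(h,s))},
#' the average standard deviation of its pairwise log-ratios with all other
#' candidates; lower M means more stable. Candidates are excluded stepwise
#' (largest M first, M recomputed after every removal) until two remain. The
#' pairwise variation \eqn{V_{n/n+1}}, the sd across samples of the log2 ratio
#' of normalization factors built from the n and n+1 most stable genes, is
#' reported as an advisory diagnostic (0.15 is the conventional cutoff below
#' which adding a reference gene is not needed).
#'
#' @param matrix a linear-scale [expression_matrix()] whose rows are the
#'   candidate reference genes (relative quantities, strictly positive).
#' @return An object of class `genorm_report`: list with `m_values` (M of each
#'   candidate in the full set), `exclusion_order` (genes removed stepwise,
#'   length n - 2), `stability_order` (least to most stable), `final_pair`,
#'   and `pairwise_variation` (named vector of V statistics).
#' @export
genorm_rank <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$scale != "linear")
    stop("genorm_rank expects linear-scale relative quantities")
  q <- matrix$values
  if (nrow(q) < 3) stop("geNorm needs at least 3 candidate genes")
  if (ncol(q) < 2) stop("geNorm needs at least 2 samples")
  if (any(q <= 0)) stop("zero or negative quantities in candidate matrix")
  lg <- log2(q)

  m_of <- function(l) {
    n <- nrow(l)
    m <- numeric(n)
    for (i in seq_len(n)) {
      sds <- vapply(setdiff(seq_len(n), i),
                    function(j) stats::sd(l[i, ] - l[j, ]), numeric(1))
      m[i] <- mean(sds)
    }
    names(m) <- rownames(l)
    m
  }

  m_full <- m_of(lg)
  cur <- lg
  excluded <- character(0)
  while (nrow(cur) > 2) {
    m <- m_of(cur)
    worst <- names(m)[which.max(m)]
    excluded <- c(excluded, worst)
    cur <- cur[setdiff(rownames(cur), worst), , drop = FALSE]
  }
  final_pair <- rownames(cur)
  # most stable last; final pair ordered by full-set M (larger first)
  stability_order <- c(excluded,
                       final_pair[order(m_full[final_pair], decreasing = TRUE)])

  ranked <- rev(stability_order)  # most stable first
  v <- numeric(0)
  if (length(ranked) >= 3) {
    nf_top <- function(k) colMeans(lg[ranked[seq_len(k)], , drop = FALSE])
    v <- vapply(2:(length(ranked) - 1),
                function(k) stats::sd(nf_top(k) - nf_top(k + 1)), numeric(1))
    names(v) <- paste0("V", 2:(length(ranked) - 1), "/", 3:length(ranked))
  }

  structure(list(m_values = m_full, exclusion_order = excluded,
                 stability_order = stability_order, final_pair = final_pair,
                 pairwise_variation = v),
            class = "genorm_report")
}

#' @export
print.genorm_report <- function(x, ...) {
  cat("geNorm stability report\n  M (full candidate set):\n")
  print(round(x$m_values, 4))
  cat("  exclusion order (least stable first):",
      paste(x$exclusion_order, collapse = " > "), "\n")
  cat("  retained pair:", paste(x$final_pair, collapse = ", "), "\n")
  if (length(x$pairwise_variation)) {
    cat("  pairwise variation:\n")
    print(round(x$pairwise_variation, 4))
  }
  invisible(x)
}
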