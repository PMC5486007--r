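#' Simulation parameters for a synthetic qPCR validation cohort
#'
#' Defaults emulate the FFPE validation design of the study this package
#' reimplements: 31 FTC vs 40 FTA samples, 15 target genes with FTC/FTA fold
#' changes between 0.48 and 1.49, three near-constant reference genes, an
#' oncocytic-subtype flag drawn per class (61.3% of FTC, 15% of FTA),
#' Gaussian noise of 0.25 cycles on the Ct scale (log-normal on quantities),
#' and optional planted extreme-outlier Ct shifts.
#'
#' @param n_ftc,n_fta samples per class (each >= 2).
#' @param fold_changes named numeric vector of per-target-gene linear FTC/FTA
#'   ratios, all > 0. The default reproduces the fold changes observed for the
#'   15 genes that amplified in the FFPE cohort.
#' @param reference_genes names of the reference assays (fold change fixed at 1).
#' @param oncocytic_fraction length-2 numeric, oncocytic proportion within FTC
#'   and FTA respectively.
#' @param oncocytic_effect per-target-gene log2 shift applied to oncocytic
#'   samples (scalar recycled); default 0, so the marginal FTC/FTA contrast
#'   equals `fold_changes` exactly.
#' @param ct_noise_sd Gaussian noise sd on the Ct scale, in cycles (>= 0).
#' @param efficiencies named per-assay amplification efficiency in (1, 2];
#'   default 2.0 (perfect doubling) for every assay.
#' @param outlier_spec list of `list(sample=, gene=, shift=)` Ct shifts applied
#'   after noise (a negative shift fakes an over-expression spike).
#' @param seed master integer seed; sub-streams (baselines, oncocytic flags,
#'   noise) use fixed offsets from it so adding a stream never perturbs the
#'   earlier ones.
#' @return A validated list of class `qpcr_sim_params`.
#' @export
qpcr_sim_params <- function(n_ftc = 31, n_fta = 40,
                            fold_changes = c(
                              ACVRL1 = 0.58, ZFYVE21 = 0.69, CLEC3B = 0.75,
                              ZMYND11 = 0.81, LIMK2 = 0.79, DIP2B = 0.86,
                              MAFB = 0.89, CPQ = 0.49, PLVAP = 0.51,
                              TFF3 = 0.48, FAM189A2 = 0.68, GDF15 = 1.49,
                              CKS2 = 1.07, ASNS = 1.02, EGR2 = 0.97),
                            reference_genes = c("EIF3A", "EIF5", "HADHA"),
                            oncocytic_fraction = c(0.613, 0.15),
                            oncocytic_effect = 0,
                            ct_noise_sd = 0.25,
                            efficiencies = NULL,
                            outlier_spec = NULL,
                            seed = 1L) {
  if (n_ftc < 2 || n_fta < 2)
    stop("invalid 'n_ftc'/'n_fta': need at least 2 samples per group")
  if (is.null(names(fold_changes)))
    names(fold_changes) <- sprintf("target%02d", seq_along(fold_changes))
  if (any(fold_changes <= 0))
    stop("invalid 'fold_changes': all ratios must be > 0")
  if (length(reference_genes) < 1 || anyDuplicated(reference_genes))
    stop("invalid 'reference_genes': need at least one unique name")
  if (any(reference_genes %in% names(fold_changes)))
    stop("invalid 'reference_genes': overlap with target gene names")
  oncocytic_fraction <- rep_len(oncocytic_fraction, 2)
  if (any(oncocytic_fraction < 0 | oncocytic_fraction > 1))
    stop("invalid 'oncocytic_fraction': proportions must lie in [0, 1]")
  if (ct_noise_sd < 0) stop("invalid 'ct_noise_sd': must be >= 0")
  genes <- c(names(fold_changes), reference_genes)
  eff <- rep_len(2.0, length(genes)); names(eff) <- genes
  if (!is.null(efficiencies)) {
    if (is.null(names(efficiencies)) ||
        !all(names(efficiencies) %in% genes))
      stop("invalid 'efficiencies': must be named by simulated assay")
    eff[names(efficiencies)] <- efficiencies
  }
  if (any(eff <= 1 | eff > 2))
    stop("invalid 'efficiencies': values must lie in (1, 2]")
  oncocytic_effect <- rep_len(oncocytic_effect, length(fold_changes))
  names(oncocytic_effect) <- names(fold_changes)
  structure(list(n_ftc = as.integer(n_ftc), n_fta = as.integer(n_fta),
                 fold_changes = fold_changes,
                 reference_genes = as.character(reference_genes),
                 oncocytic_fraction = oncocytic_fraction,
                 oncocytic_effect = oncocytic_effect,
                 ct_noise_sd = ct_noise_sd, efficiencies = eff,
                 outlier_spec = outlier_spec, seed = as.integer(seed)),
            class = "qpcr_sim_params")
}

#' Simulate a qPCR validation cohort with known ground truth
#'
#' Ct values are generated as
#' `baseline(g) - log_E(true relative quantity) + N(0, ct_noise_sd)`, with
#' per-gene baseline Ct drawn uniformly in \[20, 30\] (the baseline cancels in
#' Pfaffl ratios). Target genes carry the programmed FTC/FTA fold change (and
#' an optional oncocytic log2 shift); reference genes have fold change 1.
#' Planted outlier Ct shifts are applied last. The output is fully
#' reproducible from the master seed.
#'
#' @param params a [qpcr_sim_params()] object.
#' @return A list with elements `data` ([qpcr_dataset()]),
#'   `annotation` ([sample_annotation()]) and `truth` (list with
#'   `fold_change`, `de_flag`, `outliers`).
#' @export
simulate_qpcr_dataset <- function(params = qpcr_sim_params()) {
  stopifnot(inherits(params, "qpcr_sim_params"))
  p <- params
  targets <- names(p$fold_changes)
  genes <- c(targets, p$reference_genes)
  n <- p$n_ftc + p$n_fta
  ids <- c(sprintf("FTC_%02d", seq_len(p$n_ftc)),
           sprintf("FTA_%02d", seq_len(p$n_fta)))
  diagnosis <- rep(c("FTC", "FTA"), c(p$n_ftc, p$n_fta))

  set.seed(p$seed + 1L)
  baseline <- stats::runif(length(genes), 20, 30)
  names(baseline) <- genes

  set.seed(p$seed + 2L)
  onco <- c(stats::rbinom(p$n_ftc, 1, p$oncocytic_fraction[1]),
            stats::rbinom(p$n_fta, 1, p$oncocytic_fraction[2])) == 1

  # true linear relative quantity per gene/sample
  log2q <- matrix(0, length(genes), n, dimnames = list(genes, ids))
  is_ftc <- diagnosis == "FTC"
  log2q[targets, is_ftc] <- log2(p$fold_changes)
  log2q[targets, onco] <- log2q[targets, onco] + p$oncocytic_effect

  set.seed(p$seed + 3L)
  noise <- matrix(stats::rnorm(length(genes) * n, 0, p$ct_noise_sd),
                  length(genes), n)

  e <- p$efficiencies[genes]
  ct <- baseline - log2q / log2(e) + noise   # log_E(q) = log2(q)/log2(E)

  outliers <- NULL
  for (o in p$outlier_spec) {
    if (!o$sample %in% ids || !o$gene %in% genes)
      stop("outlier_spec references unknown sample/gene: ",
           o$sample, "/", o$gene)
    ct[o$gene, o$sample] <- ct[o$gene, o$sample] + o$shift
    outliers <- rbind(outliers,
                      data.frame(sample = o$sample, gene = o$gene,
                                 shift = o$shift))
  }

  truth <- list(
    fold_change = c(p$fold_changes,
                    stats::setNames(rep(1, length(p$reference_genes)),
                                    p$reference_genes)),
    de_flag = stats::setNames(c(p$fold_changes != 1,
                                rep(FALSE, length(p$reference_genes))), genes),
    outliers = outliers)

  list(data = qpcr_dataset(ct, efficiency = p$efficiencies,
                           reference_genes = p$reference_genes),
       annotation = sample_annotation(ids, diagnosis, oncocytic = onco),
       truth = truth)
}

#' Simulate a microarray-style log2 expression matrix
#'
#' Gaussian log2-scale matrix with a planted class contrast: `n_informative`
#' genes are shifted by `effect_log2` in FTC relative to FTA, the remaining
#' genes are null. Per-gene baselines are drawn uniformly in \[4, 12\]
#' (typical normalized microarray intensities).
#'
#' @param n_per_group length-2 integer (FTC, FTA) or scalar used for both.
#' @param n_genes total number of genes.
#' @param n_informative number of genes carrying the effect (<= `n_genes`).
#' @param effect_log2 log2 shift added to FTC samples of informative genes.
#' @param noise_sd residual sd on the log2 scale.
#' @param seed integer seed.
#' @return List with `matrix` (log2 [expression_matrix()]), `annotation` and
#'   `truth` (`de_flag` per gene).
#' @export
simulate_expression_matrix <- function(n_per_group = c(27, 25),
                                       n_genes = 1000, n_informative = 50,
                                       effect_log2 = 1, noise_sd = 1,
                                       seed = 1L) {
  n_per_group <- rep_len(as.integer(n_per_group), 2)
  if (n_informative > n_genes)
    stop("'n_informative' cannot exceed 'n_genes'")
  if (any(n_per_group < 2)) stop("need at least 2 samples per group")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  ids <- c(sprintf("FTC_%02d", seq_len(n_per_group[1])),
           sprintf("FTA_%02d", seq_len(n_per_group[2])))
  diagnosis <- rep(c("FTC", "FTA"), n_per_group)
  set.seed(seed + 1L)
  baseline <- stats::runif(n_genes, 4, 12)
  set.seed(seed + 2L)
  v <- baseline +
    matrix(stats::rnorm(n_genes * length(ids), 0, noise_sd),
           n_genes, length(ids))
  informative <- genes[seq_len(n_informative)]
  v[seq_len(n_informative), diagnosis == "FTC"] <-
    v[seq_len(n_informative), diagnosis == "FTC"] + effect_log2
  dimnames(v) <- list(genes, ids)
  truth <- list(de_flag = stats::setNames(
    genes %in% informative & effect_log2 != 0, genes))
  list(matrix = expression_matrix(v, scale = "log2",
                                  provenance = "simulated log2 matrix"),
       annotation = sample_annotation(ids, diagnosis),
       truth = truth)
}

#' Simulate a multi-study differential gene-list collection
#'
#' Builds per-study gene lists realizing exactly the planted cross-study vote
#' counts and direction patterns; all remaining genes of the universe are
#' reported by exactly one randomly chosen study with a random direction.
#' Used to exercise the vote-counting meta-analysis with known truth.
#'
#' @param n_studies number of studies.
#' @param universe_size number of distinct genes in the universe (>= number of
#'   planted genes).
#' @param overlap_spec named list: planted gene name -> character vector of
#'   directions (`"up"`/`"down"`), one per study that reports it; its length
#'   is the planted vote count and must be <= `n_studies`.
#' @param seed integer seed.
#' @return List with `collection` (a canonical `study_collection` data frame
#'   with columns `study_id`, `gene_id`, `symbol`, `direction`) and `truth`
#'   (planted counts and directions).
#' @export
simulate_study_collection <- function(n_studies = 14, universe_size = 600,
                                      overlap_spec = list(), seed = 1L) {
  if (length(overlap_spec)) {
    lens <- lengths(overlap_spec)
    if (any(lens > n_studies))
      stop("planted count exceeds 'n_studies' for: ",
           paste(names(overlap_spec)[lens > n_studies], collapse = ", "))
    if (!all(unlist(overlap_spec) %in% c("up", "down")))
      stop("directions must be 'up' or 'down'")
  }
  planted <- names(overlap_spec)
  if (length(planted) > universe_size)
    stop("'universe_size' smaller than the number of planted genes")
  others <- setdiff(sprintf("g%04d", seq_len(universe_size)), planted)
  others <- others[seq_len(universe_size - length(planted))]
  studies <- sprintf("study%02d", seq_len(n_studies))
  set.seed(seed)
  recs <- list()
  for (g in planted) {
    dirs <- overlap_spec[[g]]
    in_studies <- sample(studies, length(dirs))
    recs[[g]] <- data.frame(study_id = in_studies, symbol = g,
                            direction = dirs, stringsAsFactors = FALSE)
  }
  if (length(others)) {
    recs[["__singletons__"]] <- data.frame(
      study_id = sample(studies, length(others), replace = TRUE),
      symbol = others,
      direction = sample(c("up", "down"), length(others), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  coll <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  gene_ids <- stats::setNames(seq_len(universe_size) + 1000L,
                              c(planted, others))
  coll <- data.frame(study_id = coll$study_id,
                     gene_id = gene_ids[coll$symbol],
                     symbol = coll$symbol, direction = coll$direction,
                     stringsAsFactors = FALSE)
  coll <- coll[order(coll$study_id, coll$gene_id), , drop = FALSE]
  rownames(coll) <- NULL
  class(coll) <- c("study_collection", "data.frame")
  truth <- list(
    counts = stats::setNames(
      c(lengths(overlap_spec), rep(1L, length(others))), c(planted, others)),
    directions = overlap_spec)
  list(collection = coll, truth = truth)
}
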