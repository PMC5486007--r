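#' Doubly nested leave-one-out cross-validation of the DLDA classifier
#'
#' The outer leave-one-out loop estimates classifier performance; the inner
#' loop tunes the t-test gene-selection significance threshold. For every
#' held-out sample, an inner LOOCV over the remaining n - 1 samples evaluates
#' each threshold of `alpha_grid`, with gene selection recomputed inside
#' every inner training fold so that no inner validation sample influences
#' its own feature set. The threshold maximizing inner accuracy is chosen
#' (ties broken toward the smallest, most parsimonious threshold), genes are
#' reselected on all n - 1 training samples at that threshold, a DLDA model
#' is trained, and the FTC posterior probability of the held-out sample is
#' recorded. The held-out sample therefore never influences gene selection,
#' tuning or training.
#'
#' @param matrix log2 gene-by-sample matrix or [expression_matrix()].
#' @param labels class labels (`"FTC"`/`"FTA"`) per column, or a
#'   [sample_annotation()] from which `diagnosis` is taken.
#' @param alpha_grid significance thresholds to tune over; the default grid
#'   spans 1e-4 to 0.05.
#' @param priors passed to [dlda_train()].
#' @param cutoff posterior probability cutoff for the class call, default 0.5.
#' @return An object of class `cv_result`: a data frame with one row per
#'   sample (`sample`, `truth`, `prob_ftc`, `predicted`, `alpha`), carrying
#'   the confusion counts as attribute `confusion`.
#' @export
nested_loocv <- function(matrix, labels,
                         alpha_grid = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 5e-2),
                         priors = "empirical", cutoff = 0.5) {
  v <- if (inherits(matrix, "expr_matrix")) matrix$values else matrix
  if (inherits(labels, "sample_annotation")) {
    labels <- as.character(labels$diagnosis[match(colnames(v),
                                                  labels$sample_id)])
  }
  labels <- as.character(labels)
  if (length(alpha_grid) == 0) stop("'alpha_grid' must be non-empty")
  alpha_grid <- sort(alpha_grid)
  n <- ncol(v)
  if (n < 6) stop("need at least 6 samples for nested LOOCV")
  if (sum(labels == "FTC") < 3 || sum(labels == "FTA") < 3)
    stop("need at least 3 samples per class")

  prob <- numeric(n)
  chosen_alpha <- numeric(n)

  predict_fold <- function(train_idx, test_idx, alpha) {
    p <- row_ttest(v[, train_idx, drop = FALSE],
                   which(labels[train_idx] == "FTC"),
                   which(labels[train_idx] == "FTA"))$p
    sel <- rownames(v)[p < alpha]
    if (length(sel) == 0) sel <- rownames(v)[which.min(p)]
    fit <- dlda_train(v[sel, train_idx, drop = FALSE], labels[train_idx],
                      priors = priors, alpha_used = alpha)
    dlda_posterior(fit, v[sel, test_idx, drop = FALSE])
  }

  for (i in seq_len(n)) {
    outer_train <- setdiff(seq_len(n), i)
    # Inner LOOCV. The t-test p-values depend only on the inner training set,
    # so they are computed once per inner fold and thresholded at every
    # alpha. Both classes share the diagonal variance, so the per-gene
    # log-density difference for the held-out inner sample is computed once
    # and subset-summed per alpha; this is algebraically identical to
    # dlda_train() + dlda_posterior() on the selected genes.
    inner_correct <- matrix(NA, length(outer_train), length(alpha_grid))
    # class-wise sufficient statistics over the outer training set; each
    # inner fold removes one sample by downdating (sums of squares are
    # clamped at zero against cancellation error on near-constant genes)
    ot_ftc <- outer_train[labels[outer_train] == "FTC"]
    ot_fta <- outer_train[labels[outer_train] == "FTA"]
    S1 <- rowSums(v[, ot_ftc, drop = FALSE])
    Q1 <- rowSums(v[, ot_ftc, drop = FALSE]^2)
    S2 <- rowSums(v[, ot_fta, drop = FALSE])
    Q2 <- rowSums(v[, ot_fta, drop = FALSE]^2)
    N1 <- length(ot_ftc); N2 <- length(ot_fta)
    for (jj in seq_along(outer_train)) {
      j <- outer_train[jj]
      xj_rm <- v[, j]
      if (labels[j] == "FTC") {
        n1 <- N1 - 1L; n2 <- N2
        s1 <- S1 - xj_rm; q1 <- Q1 - xj_rm^2; s1b <- S2; q1b <- Q2
        m1 <- s1 / n1; m2 <- s1b / n2
        ss1 <- pmax(q1 - s1^2 / n1, 0); ss2 <- pmax(q1b - s1b^2 / n2, 0)
      } else {
        n1 <- N1; n2 <- N2 - 1L
        s1 <- S1; q1 <- Q1; s1b <- S2 - xj_rm; q1b <- Q2 - xj_rm^2
        m1 <- s1 / n1; m2 <- s1b / n2
        ss1 <- pmax(q1 - s1^2 / n1, 0); ss2 <- pmax(q1b - s1b^2 / n2, 0)
      }
      if (n1 < 1 || n2 < 1 || n1 + n2 < 3) next
      s2 <- (ss1 + ss2) / (n1 + n2 - 2)
      se <- sqrt(s2 * (1 / n1 + 1 / n2))
      tt <- (m1 - m2) / se
      tt[se == 0 & m1 == m2] <- 0
      p <- 2 * stats::pt(abs(tt), n1 + n2 - 2, lower.tail = FALSE)
      p[se == 0 & m1 == m2] <- 1
      ord_min <- which.min(p)
      xj <- v[, j]
      d_prior <- if (priors == "empirical") log(n2 / n1) else 0
      truth_ftc <- labels[j] == "FTC"
      for (a in seq_along(alpha_grid)) {
        sel <- which(p < alpha_grid[a])
        if (length(sel) == 0) sel <- ord_min
        s2f <- pmax(s2[sel], 1e-8 * stats::median(s2[sel]))
        if (any(s2f <= 0)) s2f <- pmax(s2f, 1e-12)
        d <- sum(((xj[sel] - m1[sel])^2 - (xj[sel] - m2[sel])^2) /
                   (2 * s2f)) + d_prior
        pr <- 1 / (1 + exp(d))
        inner_correct[jj, a] <- (pr > cutoff) == truth_ftc
      }
    }
    acc <- colMeans(inner_correct, na.rm = TRUE)
    best <- which(acc == max(acc))[1]        # grid sorted: tie -> smallest
    chosen_alpha[i] <- alpha_grid[best]
    prob[i] <- predict_fold(outer_train, i, alpha_grid[best])
  }

  out <- data.frame(sample = colnames(v), truth = labels, prob_ftc = prob,
                    predicted = ifelse(prob > cutoff, "FTC", "FTA"),
                    alpha = chosen_alpha, stringsAsFactors = FALSE)
  class(out) <- c("cv_result", "data.frame")
  attr(out, "confusion") <- with(out, c(
    tp = sum(truth == "FTC" & predicted == "FTC"),
    fn = sum(truth == "FTC" & predicted == "FTA"),
    tn = sum(truth == "FTA" & predicted == "FTA"),
    fp = sum(truth == "FTA" & predicted == "FTC")))
  attr(out, "cutoff") <- cutoff
  out
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from beta-distribution quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)`, upper =
#' `qbeta(1 - alpha/2, x + 1, n - x)`, with the conventional closures at
#' x = 0 and x = n.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf_level confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(x >= 0, n >= 1, x <= n)
  a <- 1 - conf_level
  c(lower = if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1),
    upper = if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x))
}

#' Confusion-matrix metrics with exact binomial confidence intervals
#'
#' Accuracy, sensitivity (recall of FTC, the positive class) and specificity
#' from leave-one-out predictions at the probability cutoff, each with a 95%
#' Clopper-Pearson interval. Percentages are additionally reported rounded
#' half-away-from-zero to the whole percent; the unrounded proportions are
#' retained. A metric whose denominator is zero is reported as missing.
#' With `strata`, metrics are additionally computed within each stratum
#' (e.g. oncocytic vs non-oncocytic tumors).
#'
#' @param cv a [nested_loocv()] result, or a named list/vector with elements
#'   `tp`, `fn`, `tn`, `fp` (confusion counts, FTC positive).
#' @param conf_level confidence level, default 0.95.
#' @param strata optional factor (named by sample or aligned with `cv` rows)
#'   defining subgroups for stratified accuracy.
#' @return A data frame of class `metric_table`: one row per metric with
#'   `x`, `n`, `estimate`, `lower`, `upper` (proportions) and `pct`,
#'   `pct_lower`, `pct_upper` (rounded whole percents).
#' @export
confusion_metrics <- function(cv, conf_level = 0.95, strata = NULL) {
  if (inherits(cv, "cv_result")) {
    counts <- attr(cv, "confusion")
  } else {
    counts <- unlist(cv)
    if (!all(c("tp", "fn", "tn", "fp") %in% names(counts)))
      stop("need confusion counts tp, fn, tn, fp")
  }
  one <- function(metric, x, n) {
    if (n == 0)
      return(data.frame(metric = metric, x = NA_integer_, n = 0L,
                        estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, pct = NA_real_,
                        pct_lower = NA_real_, pct_upper = NA_real_))
    ci <- clopper_pearson(x, n, conf_level)
    data.frame(metric = metric, x = as.integer(x), n = as.integer(n),
               estimate = x / n, lower = ci[["lower"]], upper = ci[["upper"]],
               pct = round_half_up(100 * x / n),
               pct_lower = round_half_up(100 * ci[["lower"]]),
               pct_upper = round_half_up(100 * ci[["upper"]]))
  }
  tp <- counts[["tp"]]; fn <- counts[["fn"]]
  tn <- counts[["tn"]]; fp <- counts[["fp"]]
  out <- rbind(one("accuracy", tp + tn, tp + fn + tn + fp),
               one("sensitivity", tp, tp + fn),
               one("specificity", tn, tn + fp))
  if (!is.null(strata)) {
    if (!inherits(cv, "cv_result"))
      stop("stratified metrics need per-sample predictions")
    s <- if (!is.null(names(strata))) strata[cv$sample] else strata
    for (lev in unique(as.character(s))) {
      sub <- cv[as.character(s) == lev, , drop = FALSE]
      out <- rbind(out, one(paste0("accuracy[", lev, "]"),
                            sum(sub$truth == sub$predicted), nrow(sub)))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("metric_table", "data.frame")
  out
}

#' ROC curve and AUC from leave-one-out probabilities
#'
#' The curve sweeps the class-call threshold over the distinct observed FTC
#' probabilities (plus sentinels), giving the false-positive/true-positive
#' rate at each. The area under the curve is computed by trapezoidal
#' integration and equals the Mann-Whitney statistic
#' \eqn{P(\mathrm{score}_{FTC} > \mathrm{score}_{FTA}) + \tfrac12
#' P(\mathrm{tie})}.
#'
#' @param cv a [nested_loocv()] result, or a numeric vector of scores with
#'   `labels` supplied.
#' @param labels class labels when `cv` is a plain score vector.
#' @return An object of class `roc_curve`: list with `points` (data frame of
#'   `threshold`, `fpr`, `tpr`, ordered from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(cv, labels = NULL) {
  if (inherits(cv, "cv_result")) {
    scores <- cv$prob_ftc
    labels <- cv$truth
  } else scores <- as.numeric(cv)
  labels <- as.character(labels)
  pos <- labels == "FTC"
  if (all(pos) || !any(pos))
    stop("both classes must be present to build a ROC curve")
  np <- sum(pos); nn <- sum(!pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / nn, numeric(1))
  points <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "False positive rate (1 - specificity)",
       ylab = "True positive rate (sensitivity)",
       main = sprintf("ROC curve (AUC = %.2f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
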