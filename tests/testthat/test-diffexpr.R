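make_log2_matrix <- function(v) {
  expression_matrix(v, scale = "log2")
}

test_that("Q3 + k*IQR rule flags a gross spike and nothing else", {
  v <- rbind(g1 = c(1:8, 1000), g2 = rep(5, 9))
  colnames(v) <- paste0("s", 1:9)
  rep <- flag_extreme_outliers(make_log2_matrix(v), k = 6)
  # quartiles of 1..8,1000 are 3 and 7, so threshold = 7 + 6*4 = 31
  expect_equal(rep$per_gene$threshold[rep$per_gene$gene == "g1"], 31)
  expect_equal(rep$flags$sample, "s9")
  expect_equal(rep$flags$gene, "g1")
  expect_equal(rep$excluded_samples, "s9")
  # constant gene: IQR 0, threshold Q3, nothing strictly greater
  expect_false("g2" %in% rep$flags$gene)

  v2 <- v; v2["g1", 9] <- 8
  expect_equal(nrow(flag_extreme_outliers(make_log2_matrix(v2), k = 6)$flags),
               0L)
  expect_error(flag_extreme_outliers(make_log2_matrix(v), k = -1),
               "non-negative")
})

test_that("planted spikes are flagged exactly, with no false flags at k=6", {
  spec <- list(list(sample = "FTC_02", gene = "CPQ", shift = -12),
               list(sample = "FTC_05", gene = "TFF3", shift = -12))
  sim <- simulate_qpcr_dataset(qpcr_sim_params(outlier_spec = spec, seed = 21))
  lg <- log_transform(pfaffl_relative_quantity(sim$data))
  rep <- flag_extreme_outliers(lg, k = 6)
  expect_equal(sort(rep$excluded_samples), c("FTC_02", "FTC_05"))
  expect_equal(sort(paste(rep$flags$sample, rep$flags$gene)),
               sort(c("FTC_02 CPQ", "FTC_05 TFF3")))

  clean <- simulate_qpcr_dataset(qpcr_sim_params(seed = 21))
  lg0 <- log_transform(pfaffl_relative_quantity(clean$data))
  expect_equal(nrow(flag_extreme_outliers(lg0, k = 6)$flags), 0L)
})

test_that("t-test handles the symmetric null and respects invariances", {
  v <- rbind(g = c(1, 2, 3, 1, 2, 3))
  colnames(v) <- paste0("s", 1:6)
  annot <- sample_annotation(paste0("s", 1:6),
                             rep(c("FTC", "FTA"), each = 3))
  de <- ttest_fdr(make_log2_matrix(v), annot)
  expect_equal(de$t_stat, 0)
  expect_equal(de$t_p, 1)
  expect_equal(de$fold_change, 1)

  set.seed(7)
  v2 <- matrix(stats::rnorm(60), 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  de2 <- ttest_fdr(make_log2_matrix(v2), annot)
  # adding a constant to a gene leaves its t untouched
  v3 <- v2; v3[4, ] <- v3[4, ] + 100
  de3 <- ttest_fdr(make_log2_matrix(v3), annot)
  expect_equal(de2$t_stat, de3$t_stat, tolerance = 1e-9)
  # relabeling classes inverts the fold change
  annot_swap <- sample_annotation(paste0("s", 1:6),
                                  rep(c("FTA", "FTC"), each = 3))
  de_swap <- ttest_fdr(make_log2_matrix(v2), annot_swap)
  expect_equal(de_swap$fold_change, 1 / de2$fold_change, tolerance = 1e-12)
  # results agree with stats::t.test gene by gene
  ref_p <- apply(v2, 1, function(y)
    stats::t.test(y[1:3], y[4:6], var.equal = TRUE)$p.value)
  expect_equal(de2$t_p, unname(ref_p), tolerance = 1e-12)

  expect_error(ttest_fdr(make_log2_matrix(v2),
                         sample_annotation(paste0("s", 1:6),
                                           c("FTC", rep("FTA", 5)))),
               "at least 2")
})

test_that("BH adjustment follows the step-up rule and preserves order", {
  # construct genes whose raw p's are known, then check the adjusted column
  q <- stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH")
  expect_equal(q, rep(0.04, 4))  # hand application of the step-up rule

  set.seed(3)
  for (r in 1:20) {
    v <- matrix(stats::rnorm(40 * 12), 40, 12,
                dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:12)))
    annot <- sample_annotation(paste0("s", 1:12),
                               rep(c("FTC", "FTA"), each = 6))
    de <- ttest_fdr(make_log2_matrix(v), annot)
    expect_true(all(de$t_q >= de$t_p & de$t_q <= 1))
    expect_equal(order(de$t_q[order(de$t_p)]),
                 seq_len(nrow(de)))  # monotone in raw p
  }
})

test_that("genes that failed amplification are dropped and reported", {
  v <- matrix(stats::rnorm(24), 4, 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  v[2, ] <- NA
  annot <- sample_annotation(paste0("s", 1:6),
                             rep(c("FTC", "FTA"), each = 3))
  de <- ttest_fdr(v, annot)
  expect_equal(attr(de, "dropped_genes"), "g2")
  expect_false("g2" %in% de$gene)
})

test_that("two-way ANOVA malignancy p matches a normal-equations oracle", {
  # balanced 2x2 with a pure malignancy effect
  annot <- sample_annotation(
    paste0("s", 1:12), rep(c("FTC", "FTA"), each = 6),
    oncocytic = rep(c(TRUE, FALSE), 6))
  set.seed(11)
  v <- matrix(stats::rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  v[1, 1:6] <- v[1, 1:6] + 2
  av <- anova_adjusted(make_log2_matrix(v), annot)
  diagnosis <- factor(annot$diagnosis)
  oncocytic <- factor(annot$oncocytic)
  oracle <- apply(v, 1, oracle_additive_anova_p,
                  oncocytic = oncocytic, diagnosis = diagnosis)
  expect_equal(av$anova_p, unname(oracle), tolerance = 1e-10)

  # unbalanced design, cross-checked against car's Type II table
  set.seed(12)
  onco <- c(rep(TRUE, 4), rep(FALSE, 2), rep(TRUE, 1), rep(FALSE, 5))
  annot2 <- sample_annotation(paste0("s", 1:12),
                              rep(c("FTC", "FTA"), each = 6),
                              oncocytic = onco)
  av2 <- anova_adjusted(make_log2_matrix(v), annot2)
  car_p <- apply(v, 1, function(y) {
    fit <- stats::lm(y ~ factor(onco) + factor(annot2$diagnosis))
    car::Anova(fit, type = 2)["factor(annot2$diagnosis)", "Pr(>F)"]
  })
  expect_equal(av2$anova_p, unname(car_p), tolerance = 1e-10)
})

test_that("degenerate or confounded ANOVA designs are rejected", {
  v <- matrix(stats::rnorm(12), 2, 6,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  annot_const <- sample_annotation(paste0("s", 1:6),
                                   rep(c("FTC", "FTA"), each = 3),
                                   oncocytic = rep(FALSE, 6))
  expect_error(anova_adjusted(make_log2_matrix(v), annot_const), "constant")
  annot_alias <- sample_annotation(paste0("s", 1:6),
                                   rep(c("FTC", "FTA"), each = 3),
                                   oncocytic = rep(c(TRUE, FALSE), each = 3))
  expect_error(anova_adjusted(make_log2_matrix(v), annot_alias), "aliased")
})

test_that("oncocytic-only effects do not inflate the malignancy test", {
  # planted oncocytic effect, no malignancy effect: nominal size ~5%
  reject <- vapply(1:200, function(s) {
    set.seed(s + 5000)
    onco <- stats::rbinom(40, 1, 0.4) == 1
    y <- stats::rnorm(40) + 1.5 * onco
    annot <- sample_annotation(paste0("s", 1:40),
                               rep(c("FTC", "FTA"), each = 20),
                               oncocytic = onco)
    v <- matrix(y, 1, 40, dimnames = list("g", paste0("s", 1:40)))
    anova_adjusted(v, annot)$anova_p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.01)
  expect_lt(mean(reject), 0.10)
})

test_that("two-set marker filter applies the published conjunction", {
  primary <- data.frame(
    gene = c("keep", "lowp2", "lowfc", "dim"),
    overall_mean = c(6.0, 6.0, 6.0, 3.0),
    overall_var = c(2.0, 2.0, 2.0, 2.0),
    t_p = c(0.0005, 0.0005, 0.0005, 0.0005),
    fold_change = c(0.4, 0.4, 1.2, 0.4))
  # pad the universe so the variance percentile is meaningful
  pad <- data.frame(gene = sprintf("pad%02d", 1:16), overall_mean = 5,
                    overall_var = seq(0.01, 0.16, by = 0.01), t_p = 0.5,
                    fold_change = 1)
  primary <- rbind(primary, pad)
  secondary <- data.frame(gene = primary$gene,
                          t_p = ifelse(primary$gene == "lowp2", 0.2, 0.01))
  got <- two_set_marker_filter(primary, secondary)
  expect_equal(got, "keep")

  expect_error(two_set_marker_filter(primary, secondary[-1, , drop = FALSE]),
               "universes differ")
})

test_that("PCA projection matches an eigendecomposition oracle", {
  set.seed(20)
  v <- matrix(stats::rnorm(8 * 10), 8, 10,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  m <- make_log2_matrix(v)
  pr <- pca_project(m, rownames(v))
  x <- scale(t(v), center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(x) / (nrow(x) - 1))
  for (j in 1:2) {
    sc_oracle <- x %*% eig$vectors[, j]
    agree <- max(abs(pr$scores[, j] - sc_oracle),
                 abs(pr$scores[, j] + sc_oracle))
    expect_equal(min(max(abs(pr$scores[, j] - sc_oracle)),
                     max(abs(pr$scores[, j] + sc_oracle))), 0,
                 tolerance = 1e-8)
  }
  expect_equal(pr$explained,
               (eig$values / sum(eig$values))[1:2], tolerance = 1e-10)
  expect_true(all(diff(pr$explained) <= 0) && sum(pr$explained) <= 1)

  # one separating gene: PC1 splits the classes, sign convention fixed
  v2 <- matrix(stats::rnorm(2 * 10, sd = 0.01), 2, 10,
               dimnames = list(c("sep", "flat"), paste0("s", 1:10)))
  v2["sep", 1:5] <- v2["sep", 1:5] + 10
  pr2 <- pca_project(make_log2_matrix(v2), c("sep", "flat"))
  expect_gt(pr2$loadings["sep", 1], 0)
  expect_true(all(pr2$scores[1:5, 1] > 0) && all(pr2$scores[6:10, 1] < 0))

  expect_error(pca_project(m, "g1"), "at least 2")
  expect_error(pca_project(m, c("g1", "nope")), "nope")
})
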