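# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Diagonal-Gaussian Bayes posterior, direct density products (no log space).
oracle_dlda_posterior <- function(mu_fta, mu_ftc, s2, priors, x) {
  lik <- function(mu) prod(stats::dnorm(x, mean = mu, sd = sqrt(s2)))
  num <- priors[["FTC"]] * lik(mu_ftc)
  den <- num + priors[["FTA"]] * lik(mu_fta)
  num / den
}

# Mann-Whitney AUC by exhaustive pairwise comparison.
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == "FTC"]
  neg <- scores[labels != "FTC"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# geNorm stability measure M by a double loop over gene pairs.
oracle_genorm_m <- function(q) {
  n <- nrow(q)
  m <- numeric(n)
  for (i in seq_len(n)) {
    acc <- c()
    for (j in seq_len(n)) {
      if (i == j) next
      acc <- c(acc, stats::sd(log2(q[i, ] / q[j, ])))
    }
    m[i] <- mean(acc)
  }
  stats::setNames(m, rownames(q))
}

# Malignancy-factor partial F-test in the additive two-factor model, from
# explicit normal equations (residual sums of squares of nested fits).
oracle_additive_anova_p <- function(y, oncocytic, diagnosis) {
  X0 <- cbind(1, as.numeric(oncocytic == levels(oncocytic)[2]))
  X1 <- cbind(X0, as.numeric(diagnosis == levels(diagnosis)[2]))
  rss <- function(X) {
    beta <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  r0 <- rss(X0); r1 <- rss(X1)
  df2 <- length(y) - ncol(X1)
  f <- (r0 - r1) / (r1 / df2)
  stats::pf(f, 1, df2, lower.tail = FALSE)
}

# small deterministic qPCR toy: one target, one reference, two samples
toy_pfaffl <- function(ct_target, ct_ref, e_target = 2, e_ref = 2) {
  ct <- rbind(tgt = ct_target, ref = ct_ref)
  colnames(ct) <- c("cal", "s")
  qpcr_dataset(ct, efficiency = c(tgt = e_target, ref = e_ref),
               reference_genes = "ref")
}
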