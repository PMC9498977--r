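make_group_table <- function(n = 12, k = 3, p = 3, shift = 0, seed = 61) {
  set.seed(seed)
  g <- rep(LETTERS[1:k], each = n)
  X <- matrix(rnorm(n * k * p), n * k, p)
  X[g == "A", 1] <- X[g == "A", 1] + shift
  tab <- as.data.frame(X)
  names(tab) <- paste0("v", 1:p)
  tab$group <- g
  tab
}

test_that("Roy's root agrees with a whitened symmetric eigenproblem and stats::manova", {
  for (seed in 61:65) {
    tab <- make_group_table(seed = seed, shift = 1)
    vars <- c("v1", "v2", "v3")
    res <- manova_roy(tab, vars, "group")
    # independent route: Cholesky-whitened between-group matrix
    X <- as.matrix(tab[, vars]); g <- factor(tab$group)
    W <- matrix(0, 3, 3); B <- matrix(0, 3, 3)
    grand <- colMeans(X)
    for (lev in levels(g)) {
      Xg <- X[g == lev, ]; mg <- colMeans(Xg)
      W <- W + crossprod(sweep(Xg, 2, mg))
      B <- B + nrow(Xg) * tcrossprod(mg - grand)
    }
    L <- chol(W)
    M <- t(solve(t(L), t(solve(t(L), B))))
    oracle <- max(eigen((M + t(M)) / 2, symmetric = TRUE)$values)
    expect_equal(res$statistic, oracle, tolerance = 1e-10)
    fit <- summary(stats::manova(X ~ g), test = "Roy")
    expect_equal(res$statistic, fit$stats[1, "Roy"], tolerance = 1e-8)
    expect_equal(res$p, fit$stats[1, "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("identical group means give Roy = 0, p = 1", {
  tab <- make_group_table(shift = 0)
  tab_const <- tab
  for (v in c("v1", "v2", "v3")) {
    for (g in unique(tab$group)) {
      idx <- tab$group == g
      tab_const[idx, v] <- tab[idx, v] - mean(tab[idx, v])
    }
  }
  res <- manova_roy(tab_const, c("v1", "v2", "v3"), "group")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-10)
})

test_that("MANOVA p sits inside the permutation null band", {
  set.seed(66)
  tab <- make_group_table(shift = 0)
  obs <- manova_roy(tab, c("v1", "v2", "v3"), "group")$statistic
  perm <- replicate(400, {
    tab$group <- sample(tab$group)
    manova_roy(tab, c("v1", "v2", "v3"), "group")$statistic
  })
  p_perm <- mean(perm >= obs)
  p_f <- manova_roy(tab, c("v1", "v2", "v3"), "group")$p
  # Roy's F approximation is an upper bound on significance; the permutation
  # p must not be dramatically smaller than the parametric one
  expect_gt(p_perm, 0.01)
  expect_lt(abs(p_perm - p_f), 0.35)
})

test_that("singular within-group structure is reported with the offending column", {
  tab <- make_group_table()
  tab$v3 <- tab$v1 + tab$v2
  expect_error(manova_roy(tab, c("v1", "v2", "v3"), "group"), "singular")
})

test_that("LDA agrees with the MANOVA eigenproblem and MASS::lda", {
  tab <- make_group_table(shift = 2, seed = 67)
  vars <- c("v1", "v2", "v3")
  res <- lda_fit(tab, vars, "group")
  roy <- manova_roy(tab, vars, "group")
  expect_equal(res$eigenvalues[1], roy$statistic, tolerance = 1e-10)
  expect_equal(sum(res$proportion), 100, tolerance = 1e-6)
  ref <- MASS::lda(tab[, vars], grouping = tab$group)
  expect_equal(res$proportion / 100, ref$svd^2 / sum(ref$svd^2),
               tolerance = 1e-6)
  for (j in 1:2) {
    ratio <- res$coefficients[, j] / ref$scaling[, j]
    expect_equal(unname(abs(ratio / ratio[1])), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("LDA geometry: one informative direction, collinear means", {
  # two well-separated groups in 2D: a single discriminant carries 100%
  tab2 <- make_group_table(n = 30, k = 2, p = 2, shift = 4, seed = 68)
  res2 <- lda_fit(tab2, c("v1", "v2"), "group")
  expect_equal(ncol(res2$coefficients), 1)
  expect_equal(unname(res2$proportion), 100)
  # three groups with collinear means: second eigenvalue ~ 0
  set.seed(69)
  g <- rep(c("A", "B", "C"), each = 40)
  mu <- c(A = -3, B = 0, C = 3)
  tab3 <- data.frame(v1 = rnorm(120) + mu[g], v2 = rnorm(120) + 2 * mu[g],
                     group = g)
  res3 <- lda_fit(tab3, c("v1", "v2"), "group")
  expect_lt(res3$eigenvalues[2] / res3$eigenvalues[1], 0.05)
})

test_that("the accuracy Bayes factor favors the truth and is Box-Cox stable", {
  set.seed(70)
  # identical distributions: BF01 > 1 (evidence for the null)
  acc_null <- pmin(pmax(rnorm(100, 0.75, 0.1), 0.05), 1)
  g2 <- rep(c("A", "B"), each = 50)
  expect_gt(accuracy_bayes_factor(acc_null, g2)$bf01, 1)
  # 3 SD separation: BF01 << 1
  acc_sep <- c(rnorm(50, 0.55, 0.05), rnorm(50, 0.85, 0.05))
  expect_lt(accuracy_bayes_factor(acc_sep, g2)$bf01, 0.01)
  # already-normal data: transform close to affine, conclusion stable
  acc_norm <- rnorm(100, 10, 1)
  raw_bf <- exp((BIC(lm(acc_norm ~ factor(g2))) - BIC(lm(acc_norm ~ 1))) / 2)
  bf <- accuracy_bayes_factor(acc_norm, g2)$bf01
  expect_lt(abs(bf - raw_bf) / raw_bf, 0.05)
  # constant accuracy: undefined, reported as NA
  expect_message(res <- accuracy_bayes_factor(rep(0.8, 20), rep(c("A", "B"), 10)),
                 "constant")
  expect_true(is.na(res$bf01))
})

test_that("univariate follow-up reduces to documented closed forms", {
  set.seed(71)
  tab <- data.frame(y = rnorm(40, sd = 1), group = rep(c("A", "B"), each = 20))
  tab$y[tab$group == "A"] <- tab$y[tab$group == "A"] + 1
  fu <- univariate_followup(tab, "y", "group")
  tt <- t.test(y ~ group, tab, var.equal = FALSE)
  expect_equal(fu$posthoc$t[1], unname(tt$statistic))
  expect_equal(fu$posthoc$df[1], unname(tt$parameter))
  # with two groups, Welch t^2 approximates the ANOVA F
  expect_equal(fu$posthoc$t[1]^2, fu$anova$f, tolerance = 0.15)
  expect_error(univariate_followup(data.frame(y = 1:3, group = c("A", "A", "B")),
                                   "y", "group"), "at least 2")
})

test_that("BH adjustment matches the hand-computed oracle and preserves ranks", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), rep(0.04, 4))
  p2 <- c(0.001, 0.01, 0.02, 0.8)
  hand <- rev(cummin(rev(pmin(1, sort(p2) * 4 / seq_len(4)))))
  expect_equal(p.adjust(sort(p2), "BH"), hand)
  set.seed(72)
  for (i in 1:20) {
    pr <- runif(sample(3:10, 1))
    adj <- p.adjust(pr, "BH")
    expect_true(all(diff(adj[order(pr)]) >= -1e-15))  # monotone in raw p
    expect_true(all(adj >= pr - 1e-15))
  }
})

test_that("one-tailed correlations report direction-consistent p-values", {
  x <- 1:20
  res <- one_tailed_pearson(x, -2 * x + 3, "negative")
  expect_equal(res$r, -1)
  expect_lt(res$p, 1e-10)
  set.seed(73)
  exceed <- 0
  for (i in 1:500) {
    a <- rnorm(32); b <- rnorm(32)
    if (abs(one_tailed_pearson(a, b, "negative")$r) >= 0.35) exceed <- exceed + 1
  }
  expect_lt(exceed / 500, 0.06)  # |r| < 0.35 in ~95% of null draws
  expect_error(one_tailed_pearson(rep(1, 5), rnorm(5), "negative"), "variance")
})
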