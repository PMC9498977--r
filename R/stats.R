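# Group-level statistics: Bayes factor for recognition accuracy, MANOVA with
# Roy's largest root, Fisher linear discriminant analysis, univariate ANOVA
# follow-ups with Welch post hocs and Benjamini-Hochberg correction, and
# one-tailed Pearson correlations. Roy's root and the discriminants are
# computed here from the within/between SSCP eigenproblem; ordinary model
# fits, t-tests and the BH adjustment go through base R.

sscp_decomposition <- function(X, group) {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  grand <- colMeans(X)
  W <- matrix(0, ncol(X), ncol(X))
  B <- matrix(0, ncol(X), ncol(X))
  for (g in levels(group)) {
    Xg <- X[group == g, , drop = FALSE]
    mg <- colMeans(Xg)
    C <- sweep(Xg, 2, mg)
    W <- W + crossprod(C)
    d <- mg - grand
    B <- B + nrow(Xg) * tcrossprod(d)
  }
  if (rcond(W) < 1e-12) {
    # name the offending columns: those whose removal restores conditioning
    sds <- sqrt(diag(W))
    Rw <- W / tcrossprod(pmax(sds, .Machine$double.eps))
    bad <- colnames(X)[sds < 1e-10 | apply(abs(Rw - diag(ncol(W))) > 1 - 1e-8, 2, any)]
    stop("within-group SSCP matrix is singular; collinear or constant columns: ",
         paste(unique(c(bad, if (!length(bad)) colnames(X))), collapse = ", "),
         call. = FALSE)
  }
  list(W = W, B = B, group = group, k = k, n = nrow(X), grand = grand)
}

#' MANOVA with Roy's largest root
#'
#' Roy's statistic is the largest eigenvalue of `W^{-1} B`, where `W` and `B`
#' are the within- and between-group sums-of-squares-and-cross-products
#' matrices. The F approximation uses `df1 = max(p, k - 1)` and
#' `df2 = N - k - df1 + (k - 1)` (an upper bound on significance, the standard
#' convention).
#'
#' @param table Data frame holding the variables and the grouping column.
#' @param variables Character vector of dependent-variable column names.
#' @param group Name of the grouping column, or a vector of group labels.
#' @return List with `statistic` (Roy's largest root), `f`, `df1`, `df2`, `p`
#'   and the full eigenvalue vector.
#' @export
manova_roy <- function(table, variables, group) {
  X <- as.matrix(table[, variables, drop = FALSE])
  g <- if (length(group) == 1 && is.character(group)) table[[group]] else group
  dec <- sscp_decomposition(X, g)
  eig <- eigen(solve(dec$W, dec$B), only.values = TRUE)$values
  eig <- sort(pmax(Re(eig), 0), decreasing = TRUE)
  p <- ncol(X); q <- dec$k - 1; rdf <- dec$n - dec$k
  df1 <- max(p, q)
  df2 <- rdf - df1 + q
  statistic <- eig[1]
  f <- statistic * df2 / df1
  list(statistic = statistic, f = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE),
       eigenvalues = eig)
}

#' Fisher linear discriminant analysis
#'
#' Discriminant directions are the leading eigenvectors of `W^{-1} B`, scaled
#' so the pooled within-group variance of each discriminant score is 1 (the
#' conventional normalized coefficients). The proportion of separation of each
#' discriminant is its eigenvalue's share. Signs are canonicalized so the
#' largest-magnitude coefficient of each discriminant is positive.
#'
#' @inheritParams manova_roy
#' @return List of class `lda_result` with `coefficients` (variables x
#'   discriminants), `standardized` (coefficients times pooled within-group
#'   SDs), `proportion` (percent separation per discriminant, summing to 100),
#'   `scores` (rows on each discriminant, computed from grand-mean-centered
#'   data), `centroids` (group means of the scores) and `eigenvalues`.
#' @export
lda_fit <- function(table, variables, group) {
  X <- as.matrix(table[, variables, drop = FALSE])
  g <- if (length(group) == 1 && is.character(group)) table[[group]] else group
  dec <- sscp_decomposition(X, g)
  es <- eigen(solve(dec$W, dec$B))
  ord <- order(Re(es$values), decreasing = TRUE)
  m <- min(dec$k - 1, ncol(X))
  eig <- pmax(Re(es$values[ord][seq_len(m)]), 0)
  V <- Re(es$vectors[, ord[seq_len(m)], drop = FALSE])
  Sw <- dec$W / (dec$n - dec$k)
  for (j in seq_len(m)) {
    v <- V[, j]
    v <- v / sqrt(drop(t(v) %*% Sw %*% v))
    if (v[which.max(abs(v))] < 0) v <- -v
    V[, j] <- v
  }
  dimnames(V) <- list(variables, paste0("LD", seq_len(m)))
  scores <- sweep(X, 2, dec$grand) %*% V
  centroids <- apply(scores, 2, function(s) tapply(s, dec$group, mean))
  res <- list(
    coefficients = V,
    standardized = V * sqrt(diag(Sw)),
    proportion = eig / sum(eig) * 100,
    scores = scores,
    centroids = centroids,
    eigenvalues = eig,
    group = dec$group
  )
  class(res) <- "lda_result"
  res
}

#' @export
print.lda_result <- function(x, ...) {
  cat("Fisher LDA\n")
  cat("Proportion of separation (%):",
      paste(sprintf("%.1f", x$proportion), collapse = " / "), "\n")
  cat("Normalized coefficients:\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Bayes factor for a group effect on recognition accuracy
#'
#' Accuracy values are Box-Cox transformed (profile-likelihood lambda on a
#' `[-2, 2]` grid of step 0.01; non-positive values are shifted up with a
#' message first), then the one-way group model is compared with the
#' intercept-only model through the BIC approximation
#' `BF01 = exp((BIC_group - BIC_null) / 2)`. Values above 1 favor the null
#' (no group effect).
#'
#' @param accuracy Numeric per-participant accuracies in `[0, 1]`.
#' @param group Group labels, same length.
#' @return List with `bf01`, `lambda`, `shift`.
#' @export
accuracy_bayes_factor <- function(accuracy, group) {
  if (stats::sd(accuracy) < 1e-12) {
    message("accuracy is constant across participants; Bayes factor undefined")
    return(list(bf01 = NA_real_, lambda = NA_real_, shift = 0))
  }
  shift <- 0
  y <- accuracy
  if (any(y <= 0)) {
    shift <- max(0.01, -min(y) + 0.01)
    message(sprintf("non-positive accuracy values shifted by +%.3g for Box-Cox",
                    shift))
    y <- y + shift
  }
  bc <- MASS::boxcox(y ~ 1, data = data.frame(y = y),
                     lambda = seq(-2, 2, 0.01), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  z <- if (abs(lambda) < 1e-9) log(y) else (y^lambda - 1) / lambda
  g <- factor(group)
  bic_null <- stats::BIC(stats::lm(z ~ 1))
  bic_group <- stats::BIC(stats::lm(z ~ g))
  list(bf01 = exp((bic_group - bic_null) / 2), lambda = lambda, shift = shift)
}

#' Univariate ANOVA follow-up with Welch post hocs and BH correction
#'
#' One-way ANOVA on a single variable, followed by all pairwise Welch
#' (unequal-variance) t-tests with Welch-Satterthwaite degrees of freedom and
#' Benjamini-Hochberg adjustment within the pairwise family.
#'
#' @inheritParams manova_roy
#' @param variable Name of the dependent variable column.
#' @param gate_posthoc If `TRUE`, post hocs are only run when the ANOVA is
#'   significant at `alpha` (the sequential chain used for error control);
#'   default `FALSE` reports them unconditionally.
#' @param alpha Significance level for the gate (default 0.05).
#' @return List with `anova` (`f`, `df1`, `df2`, `p`) and `posthoc` (tibble
#'   with columns `group1`, `group2`, `t`, `df`, `p`, `p_fdr`; empty when
#'   gated out).
#' @export
univariate_followup <- function(table, variable, group,
                                gate_posthoc = FALSE, alpha = 0.05) {
  y <- table[[variable]]
  g <- factor(if (length(group) == 1 && is.character(group)) table[[group]]
              else group)
  if (any(table(g) < 2)) stop("every group needs at least 2 rows", call. = FALSE)
  av <- stats::anova(stats::aov(y ~ g))
  res_anova <- list(f = av$`F value`[1], df1 = av$Df[1], df2 = av$Df[2],
                    p = av$`Pr(>F)`[1])
  empty <- tibble::tibble(group1 = character(), group2 = character(),
                          t = numeric(), df = numeric(), p = numeric(),
                          p_fdr = numeric())
  if (gate_posthoc && res_anova$p >= alpha) {
    return(list(anova = res_anova, posthoc = empty))
  }
  pairs <- utils::combn(levels(g), 2)
  ph <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tt <- stats::t.test(y[g == a], y[g == b], var.equal = FALSE)
    tibble::tibble(group1 = a, group2 = b,
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  ph <- do.call(rbind, ph)
  ph$p_fdr <- stats::p.adjust(ph$p, method = "BH")
  list(anova = res_anova, posthoc = ph)
}

#' One-tailed Pearson correlation
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param direction `"negative"` tests r < 0, `"positive"` tests r > 0.
#' @return List with `r`, `p`, `n`.
#' @export
one_tailed_pearson <- function(x, y, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (length(x) != length(y) || length(x) < 3) {
    stop("need paired vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, alternative = switch(direction,
                                                   negative = "less",
                                                   positive = "greater"))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Aggregate a metrics table to participant means
#'
#' Collapses trial-level rows to one row per participant, averaging the
#' twelve haptic variables and keeping `group` and `accuracy`.
#'
#' @param metrics A metrics tibble from [cohort_metrics()].
#' @return Tibble with one row per participant.
#' @export
aggregate_participants <- function(metrics) {
  sp <- split(metrics, metrics$participant_id)
  do.call(rbind, lapply(sp, function(d) {
    out <- d[1, c("participant_id", "group", "accuracy")]
    for (v in HAPTIC_VARIABLES) out[[v]] <- mean(d[[v]])
    out
  }))
}

#' Full group-discrimination analysis of a metrics table
#'
#' Reproduces the statistical stage on a metrics table: accuracy Bayes factor,
#' MANOVA (Roy's largest root) over the twelve haptic variables, Fisher LDA
#' with normalized coefficients and percent separation, univariate ANOVA +
#' Welch/BH follow-ups on the variables with the largest `|LD1|` coefficients,
#' and the two one-tailed correlations of exploration duration with mean SMC
#' (positive direction) and mean active cells (negative direction), BH-adjusted
#' as one family.
#'
#' @param metrics A metrics tibble from [cohort_metrics()] or
#'   [session_metrics()].
#' @param unit `"trial"` analyzes exploration-level rows (the default);
#'   `"participant"` aggregates each participant's haptic variables to means
#'   first.
#' @param n_top Number of top-`|LD1|` variables given univariate follow-ups.
#' @return A list of class `hapticube_analysis` with elements `unit`,
#'   `accuracy_bf`, `manova`, `lda`, `followups` (named list), `correlations`
#'   (tibble), and the analyzed `table`.
#' @export
analyze_cohort <- function(metrics, unit = c("trial", "participant"),
                           n_top = 3) {
  unit <- match.arg(unit)
  vars <- HAPTIC_VARIABLES
  tab <- if (unit == "participant") aggregate_participants(metrics) else metrics
  acc <- unique(metrics[, c("participant_id", "group", "accuracy")])
  accuracy_bf <- accuracy_bayes_factor(acc$accuracy, acc$group)
  man <- manova_roy(tab, vars, "group")
  lda <- lda_fit(tab, vars, "group")
  top <- vars[order(abs(lda$coefficients[, "LD1"]), decreasing = TRUE)]
  top <- top[seq_len(min(n_top, length(top)))]
  followups <- lapply(top, function(v) univariate_followup(tab, v, "group"))
  names(followups) <- top
  c1 <- one_tailed_pearson(tab$mean_smc, tab$exploration_duration, "positive")
  c2 <- one_tailed_pearson(tab$mean_active_cells, tab$exploration_duration,
                           "negative")
  correlations <- tibble::tibble(
    pair = c("mean_smc~exploration_duration",
             "mean_active_cells~exploration_duration"),
    direction = c("positive", "negative"),
    r = c(c1$r, c2$r), p = c(c1$p, c2$p)
  )
  correlations$p_fdr <- stats::p.adjust(correlations$p, method = "BH")
  res <- list(unit = unit, accuracy_bf = accuracy_bf, manova = man, lda = lda,
              followups = followups, correlations = correlations, table = tab)
  class(res) <- "hapticube_analysis"
  res
}

#' @export
print.hapticube_analysis <- function(x, ...) {
  cat(sprintf("Haptic exploration analysis (%s-level, %d rows)\n",
              x$unit, nrow(x$table)))
  cat(sprintf("Accuracy BF01 (null/group): %.2f (Box-Cox lambda %.2f)\n",
              x$accuracy_bf$bf01, x$accuracy_bf$lambda))
  cat(sprintf("MANOVA Roy's root = %.3f, F(%d, %d) = %.2f, p = %.4g\n",
              x$manova$statistic, x$manova$df1, x$manova$df2, x$manova$f,
              x$manova$p))
  cat(sprintf("LDA separation: %s\n",
              paste(sprintf("%.1f%%", x$lda$proportion), collapse = " / ")))
  for (v in names(x$followups)) {
    f <- x$followups[[v]]
    cat(sprintf("ANOVA %s: F(%d, %d) = %.2f, p = %.4g\n",
                v, f$anova$df1, f$anova$df2, f$anova$f, f$anova$p))
    ph <- f$posthoc
    for (i in seq_len(nrow(ph))) {
      cat(sprintf("  %s vs %s: t(%.1f) = %.2f, p_fdr = %.4g\n",
                  ph$group1[i], ph$group2[i], ph$df[i], ph$t[i], ph$p_fdr[i]))
    }
  }
  print(x$correlations)
  invisible(x)
}
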