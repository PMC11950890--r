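# Marker-comparison battery: nonparametric staging tests, paired ROC with
# DeLong comparison, covariate-adjusted rank correlations, and multivariate
# regression with Wilks' lambda term tests.

#' Kruskal-Wallis omnibus test across diagnostic groups
#'
#' Midrank-based H statistic with tie correction; p-value from the
#' chi-square approximation with k - 1 degrees of freedom (wraps
#' [stats::kruskal.test()]).
#'
#' @param values Numeric marker values.
#' @param groups Group label per value (>= 2 distinct groups).
#' @return List with `H`, `p_value`, `df`, `n`, `groups`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (length(values) != length(groups))
    stop("values and groups must have equal length", call. = FALSE)
  if (nlevels(droplevels(groups)) < 2L)
    stop("degenerate-design error: need >= 2 groups", call. = FALSE)
  kt <- stats::kruskal.test(values, droplevels(groups))
  list(H = unname(kt$statistic), p_value = unname(kt$p.value),
       df = unname(kt$parameter), n = length(values),
       groups = levels(droplevels(groups)))
}

#' Mann-Whitney U test
#'
#' U computed from midranks. For combined samples of size at most
#' `exact_max_n` (and by default) the p-value is obtained by exact
#' enumeration over all label assignments (valid under ties); otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param a,b Numeric samples (both nonempty).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`,
#'   referring to the location of `a` relative to `b`.
#' @param exact_max_n Largest combined sample size for which exact
#'   enumeration is used (default 16; set to 0 to force the approximation).
#' @return List with `U` (for sample `a`), `p_value`, `method`, `n1`, `n2`.
#' @export
mann_whitney <- function(a, b, alternative = c("two.sided", "less", "greater"),
                         exact_max_n = 16L) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be nonempty", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= exact_max_n) {
    p <- mw_exact_p(c(a, b), n1, U, alternative)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "degenerate",
                                 n1 = n1, n2 = n2))
    sigma <- sqrt(sigma2)
    p <- switch(alternative,
      two.sided = {
        cc <- max(abs(U - mu) - 0.5, 0)
        min(1, 2 * stats::pnorm(-cc / sigma))
      },
      greater = stats::pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE),
      less = stats::pnorm((U - mu + 0.5) / sigma))
    method <- "normal approximation"
  }
  list(U = U, p_value = p, method = method, n1 = n1, n2 = n2)
}

# Exact Mann-Whitney p by enumerating all C(n, n1) assignments of the
# pooled (possibly tied) values to group a. Two-sided p doubles the
# smaller tail (capped at 1), matching the tail convention of the normal
# approximation.
mw_exact_p <- function(pooled, n1, U_obs, alternative) {
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), n1)
  offset <- n1 * (n1 + 1) / 2
  Us <- colSums(matrix(r[idx], nrow = n1)) - offset
  p_ge <- mean(Us >= U_obs)
  p_le <- mean(Us <= U_obs)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Area under the ROC curve via the U-statistic identity
#'
#' AUC = U / (n_pos * n_neg) with ties counted 0.5, i.e. the probability
#' that a random positive scores above a random negative.
#'
#' @param scores Numeric marker values.
#' @param labels Logical or 0/1; `TRUE`/1 marks the positive class.
#' @param positive_direction `"greater"` if positives have larger scores
#'   (default); `"less"` flips the score sign first.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, positive_direction = c("greater", "less")) {
  positive_direction <- match.arg(positive_direction)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  if (positive_direction == "less") scores <- -scores
  r <- rank(scores)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' DeLong test for two correlated (paired) AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects using the
#' DeLong structural-components estimator of the covariance of correlated
#' AUCs (via [pROC::roc.test()]), z = (AUC_a - AUC_b) / SE(diff).
#'
#' @param scores_a,scores_b Paired marker values on identical subjects.
#' @param labels Logical/0-1 class labels.
#' @param alternative Sidedness of the test; default `"two.sided"`.
#' @return List with `auc_a`, `auc_b`, `delong_z`, `p_value`, `n_pos`,
#'   `n_neg`, and `degenerate` (TRUE when the variance of the AUC
#'   difference is zero, in which case `delong_z`/`p_value` are `NA`).
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("paired scores and labels must have equal length", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  auc_a <- roc_auc(scores_a, labels)
  auc_b <- roc_auc(scores_b, labels)
  out <- list(auc_a = auc_a, auc_b = auc_b, n_pos = sum(labels),
              n_neg = sum(!labels), degenerate = FALSE)
  # variance of the AUC difference from the structural components
  # (placement values); zero variance means the test is undefined.
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  var_diff <- stats::var(pa$v10 - pb$v10) / out$n_pos +
    stats::var(pa$v01 - pb$v01) / out$n_neg
  if (!is.finite(var_diff) || var_diff <= .Machine$double.eps) {
    out$degenerate <- TRUE
    out$delong_z <- NA_real_
    out$p_value <- NA_real_
    return(out)
  }
  roc_a <- pROC::roc(labels, scores_a, direction = "<", quiet = TRUE)
  roc_b <- pROC::roc(labels, scores_b, direction = "<", quiet = TRUE)
  tst <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE,
                        alternative = alternative)
  out$delong_z <- unname(tst$statistic)
  out$p_value <- unname(tst$p.value)
  out
}

# Placement values of the DeLong estimator via midranks: for each positive,
# the fraction of negatives it outranks (ties half), and symmetrically for
# negatives.
delong_placements <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  n_pos <- length(pos); n_neg <- length(neg)
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos); r_neg <- rank(neg)
  v10 <- (r_all[seq_len(n_pos)] - r_pos) / n_neg
  v01 <- 1 - (r_all[n_pos + seq_len(n_neg)] - r_neg) / n_pos
  list(v10 = v10, v01 = v01)
}

#' Partial Spearman correlation adjusted for covariates
#'
#' All variables (x, y, and covariates) are midrank-transformed; the
#' partial Pearson correlation of the ranked x and y given the ranked
#' covariates is computed from residuals of least-squares projections.
#' With no covariates this reduces exactly to the plain Spearman rho.
#' The p-value uses the t distribution with n - ncov - 2 df.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame / matrix of covariates, or `NULL`.
#' @return List with `rho`, `p_value`, `n`, `df`, `covariate_names`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    Z <- NULL; k <- 0L; cov_names <- character(0)
  } else {
    Z <- as.matrix(as.data.frame(covariates))
    if (nrow(Z) != n) stop("covariates must match x in length", call. = FALSE)
    k <- ncol(Z); cov_names <- colnames(Z)
  }
  if (n <= k + 2) stop("need n > #covariates + 2", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("x and y must be non-constant", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (k == 0) {
    rho <- stats::cor(rx, ry)
  } else {
    RZ <- apply(Z, 2, rank)
    Q <- qr(cbind(1, RZ))
    if (Q$rank < k + 1)
      stop("rank-deficient covariates", call. = FALSE)
    ex <- qr.resid(Q, rx)
    ey <- qr.resid(Q, ry)
    rho <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  }
  df <- as.integer(n - k - 2)
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(rho = rho, p_value = p, n = n, df = df, covariate_names = cov_names)
}

#' Reflect-and-square-root transform of cognitive scores
#'
#' t(x) = sqrt((max(x) + 1) - x), the conventional normalizing transform
#' for left-skewed scores. It is strictly decreasing, so the sign of
#' downstream associations inverts (a negative raw association yields a
#' positive coefficient on the transformed scale).
#'
#' @param scores Finite numeric scores.
#' @return Transformed scores.
#' @export
reflect_sqrt_transform <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  sqrt((max(scores) + 1) - scores)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Familywise alpha (default 0.05).
#' @param m Number of comparisons (>= 1).
#' @param digits Display rounding (default 3, so 0.05/3 prints as 0.017).
#' @return List with `alpha_corrected` (exact) and `alpha_display`
#'   (rounded to `digits`).
#' @export
bonferroni <- function(alpha = 0.05, m, digits = 3) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  a <- alpha / m
  list(alpha_corrected = a, alpha_display = round(a, digits))
}

#' Multivariate regression of cognitive scores on markers and covariates
#'
#' Fits the linear model block
#' `cbind(score_1, ..., score_q) ~ term_1 + ... + term_p` by least squares,
#' reports a multivariate test per term (Wilks' lambda converted to an
#' approximate F by Rao's transformation, type III sums of cross-products,
#' via [car::Anova()]), and post hoc univariate OLS fits per score with
#' coefficient confidence intervals. With a single dependent variable the
#' multivariate F per term equals the univariate partial F exactly.
#'
#' @param data Data frame of complete cases.
#' @param dependent Character vector of dependent (score) columns.
#' @param terms Character vector of independent-variable columns (e.g.
#'   fill state, SUVR, age, sex as 0/1, education in years). Coefficients
#'   are reported on raw scales.
#' @param conf_level Confidence level for univariate CIs (default 0.95).
#' @return Object of class `regression_result`: `multivariate` (data frame
#'   term / wilks_lambda / F / df1 / df2 / p_value), `univariate` (long
#'   data frame of per-score coefficients with CIs and t-test p),
#'   `n`, `dependent`, `terms`.
#' @export
fit_regression <- function(data, dependent, terms, conf_level = 0.95) {
  data <- as.data.frame(data)
  cols <- c(dependent, terms)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0)
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- data[stats::complete.cases(data[, cols, drop = FALSE]), , drop = FALSE]
  X <- stats::model.matrix(
    stats::reformulate(terms), data = data)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design; check collinearity among: ",
         paste(terms, collapse = ", "), call. = FALSE)
  }
  Y <- as.matrix(data[, dependent, drop = FALSE])
  fml <- stats::as.formula(
    paste0("cbind(", paste(dependent, collapse = ", "), ") ~ ",
           paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = data)
  multiv <- multivariate_term_tests(fit, terms, q = length(dependent))
  uni <- do.call(rbind, lapply(dependent, function(dv) {
    ufit <- stats::lm(stats::reformulate(terms, response = dv), data = data)
    cf <- summary(ufit)$coefficients
    ci <- stats::confint(ufit, level = conf_level)
    data.frame(score = dv, term = rownames(cf),
               estimate = cf[, 1], se = cf[, 2], t = cf[, 3],
               p_value = cf[, 4], ci_lower = ci[, 1], ci_upper = ci[, 2],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(multivariate = multiv, univariate = uni,
                 n = nrow(data), dependent = dependent, terms = terms,
                 fit = fit),
            class = "regression_result")
}

# Per-term Wilks' lambda with Rao's F approximation, type III.
multivariate_term_tests <- function(fit, terms, q) {
  if (q == 1L) {
    # Single dependent variable: Wilks reduces to the univariate partial F.
    av <- car::Anova(fit, type = "III")
    av <- av[terms, , drop = FALSE]
    Fv <- av[["F value"]]
    df1 <- av[["Df"]]
    df2 <- stats::df.residual(fit)
    lam <- 1 / (1 + Fv * df1 / df2)
    return(data.frame(term = terms, wilks_lambda = lam, F = Fv,
                      df1 = df1, df2 = df2, p_value = av[["Pr(>F)"]],
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  av <- car::Anova(fit, type = "III", test.statistic = "Wilks")
  sm <- summary(av, multivariate = TRUE)$multivariate.tests
  rows <- lapply(terms, function(tm) {
    tab <- sm[[tm]]
    # car stores the SSP matrices; recompute Wilks + Rao F explicitly so the
    # reported numbers are self-contained.
    H <- tab$SSPH; E <- tab$SSPE
    lam <- det(E) / det(E + H)
    p <- nrow(E)                       # number of responses
    df_h <- as.numeric(tab$df)         # hypothesis df
    df_e <- tab$df.residual
    tstat <- sqrt(ifelse(p^2 + df_h^2 - 5 > 0,
                         (p^2 * df_h^2 - 4) / (p^2 + df_h^2 - 5), 1))
    w <- df_e + df_h - (p + df_h + 1) / 2
    df1 <- p * df_h
    df2 <- w * tstat - (p * df_h - 2) / 2
    Fv <- ((1 - lam^(1 / tstat)) / lam^(1 / tstat)) * df2 / df1
    data.frame(term = tm, wilks_lambda = lam, F = Fv, df1 = df1, df2 = df2,
               p_value = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d; %d score(s) ~ %s\n", x$n,
              length(x$dependent), paste(x$terms, collapse = " + ")))
  print(x$multivariate, row.names = FALSE)
  invisible(x)
}
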