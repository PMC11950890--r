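# Marker-comparison battery: staging tests, ROC/DeLong, partial Spearman,
# reflect transform, multivariate regression, Bonferroni.

test_that("Kruskal-Wallis handles identical groups and hand-computed ranks", {
  same <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)

  # ranks {1,2} vs {3,4}: H = 12/(N(N+1)) * (R1^2/n1 + R2^2/n2) - 3(N+1)
  #                         = 12/20 * (9/2 + 49/2) - 15 = 2.4
  hand <- kruskal_wallis(c(1, 2, 10, 11), c("a", "a", "b", "b"))
  expect_equal(hand$H, 2.4)

  expect_error(kruskal_wallis(1:5, rep("a", 5)), "degenerate-design")
})

test_that("Kruskal-Wallis with 2 groups tracks the Mann-Whitney p", {
  set.seed(31)
  for (rep_i in 1:5) {
    a <- rnorm(25); b <- rnorm(25, 0.3)
    kw <- kruskal_wallis(c(a, b), rep(c("a", "b"), each = 25))
    mw <- mann_whitney(a, b, exact_max_n = 0L)
    expect_lt(abs(kw$p_value - mw$p_value), 0.01)
  }
})

test_that("Mann-Whitney U and p behave at the extremes", {
  id <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gt(id$p_value, 0.9)

  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)

  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney approximation matches exact enumeration at n = 8 + 8", {
  set.seed(32)
  for (rep_i in 1:6) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    if (rep_i > 3) {  # force ties
      a <- round(a); b <- round(b)
    }
    ex <- mann_whitney(a, b)                    # combined n = 16 -> exact
    ap <- mann_whitney(a, b, exact_max_n = 0L)  # normal approximation
    expect_identical(ex$method, "exact enumeration")
    expect_identical(ap$method, "normal approximation")
    # the approximation degrades slightly under heavy ties
    expect_lt(abs(ex$p_value - ap$p_value), if (rep_i > 3) 0.03 else 0.02)
  }
  # exact path agrees with wilcox.test's exact p when there are no ties
  set.seed(33)
  a <- rnorm(7); b <- rnorm(7)
  ex <- mann_whitney(a, b)
  wt <- wilcox.test(a, b, exact = TRUE)
  expect_equal(ex$U, unname(wt$statistic))
  expect_equal(ex$p_value, wt$p.value, tolerance = 1e-12)
})

test_that("AUC equals U/(n1 n2) with ties counted half, on every input", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)

  set.seed(34)
  scores <- rnorm(2000); labels <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.05)

  for (rep_i in 1:5) {
    s <- sample(1:6, 30, replace = TRUE)  # heavy ties
    l <- rbinom(30, 1, 0.5)
    if (sum(l) == 0 || sum(l) == 30) next
    mw <- mann_whitney(s[l == 1], s[l == 0], exact_max_n = 0L)
    expect_equal(roc_auc(s, l), mw$U / (sum(l) * sum(1 - l)),
                 tolerance = 1e-12)
    expect_equal(roc_auc(s, l), oracle_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("DeLong test flags degenerate pairs and is rank invariant", {
  set.seed(35)
  s <- rnorm(40); l <- rep(c(0, 1), 20)
  same <- delong_test(s, s, l)
  expect_equal(same$auc_a, same$auc_b)
  expect_true(same$degenerate)

  mono <- delong_test(s, exp(s) + 5, l)
  expect_equal(mono$auc_a, mono$auc_b)
  expect_true(mono$degenerate)  # identical ranks -> zero-variance difference
})

test_that("DeLong p agrees with a paired permutation oracle", {
  set.seed(36)
  n <- 40
  lab <- rep(c(TRUE, FALSE), each = n)
  latent <- rnorm(2 * n) + ifelse(lab, 0.8, 0)
  a <- latent + rnorm(2 * n, sd = 0.8)
  b <- 0.3 * latent + rnorm(2 * n, sd = 1)
  dl <- delong_test(a, b, lab)
  obs <- abs(dl$auc_a - dl$auc_b)
  # paired permutation: randomly swap the two markers within subject
  set.seed(37)
  perm <- replicate(10000, {
    swap <- runif(2 * n) < 0.5
    pa <- ifelse(swap, b, a); pb <- ifelse(swap, a, b)
    abs(roc_auc(pa, lab) - roc_auc(pb, lab))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(dl$p_value - p_perm), 0.03)
})

test_that("partial Spearman reduces to Spearman and obeys the matrix identity", {
  set.seed(38)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  plain <- partial_spearman(x, y)
  expect_equal(plain$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)

  expect_equal(partial_spearman(x, exp(x))$rho, 1)

  z <- data.frame(age = rnorm(60, 70, 5), sex = rbinom(60, 1, 0.5),
                  edu = rnorm(60, 14, 3))
  ps <- partial_spearman(x, y, z)
  # precision-matrix formula on the rank-correlation matrix
  R <- cor(cbind(rank(x), rank(y), rank(z$age), rank(z$sex), rank(z$edu)))
  P <- solve(R)
  rho_mat <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(ps$rho, rho_mat, tolerance = 1e-10)
  expect_identical(ps$df, 60L - 3L - 2L)
})

test_that("partial Spearman is invariant under monotone transforms", {
  set.seed(39)
  x <- rexp(50); y <- -x + rnorm(50)
  z <- data.frame(c1 = rnorm(50))
  base <- partial_spearman(x, y, z)
  warped <- partial_spearman(log(x), y^3, data.frame(c1 = exp(z$c1)))
  expect_equal(base$rho, warped$rho, tolerance = 1e-12)
  expect_error(partial_spearman(x, y, data.frame(a = z$c1, b = 2 * z$c1)),
               "rank-deficient")
})

test_that("reflect-and-square-root transform reverses rank order", {
  x <- c(10, 25, 25, 30)
  t_x <- reflect_sqrt_transform(x)
  expect_equal(t_x[4], 1.0)  # at the maximum: sqrt(max + 1 - max)
  set.seed(40)
  r <- rnorm(100)
  tr <- reflect_sqrt_transform(r)
  expect_true(all(diff(tr[order(r)]) <= 0))
  y <- rnorm(100)
  expect_equal(cor(r, y, method = "spearman"),
               -cor(tr, y, method = "spearman"), tolerance = 1e-12)
  expect_error(reflect_sqrt_transform(c(1, NA)), "finite")
})

test_that("Bonferroni correction matches the three-comparison convention", {
  expect_equal(bonferroni(0.05, 1)$alpha_corrected, 0.05)
  expect_equal(bonferroni(0.05, 3)$alpha_display, 0.017)
  expect_equal(bonferroni(0.05, 5)$alpha_corrected, 0.01)
  expect_error(bonferroni(0.05, 0), "m must be")
})

test_that("multivariate regression reduces to univariate partial F for one score", {
  set.seed(41)
  n <- 80
  d <- data.frame(fill = runif(n, 0, 60), suvr = runif(n, 1, 2),
                  age = rnorm(n, 70, 6), sex = rbinom(n, 1, 0.5),
                  education = rnorm(n, 14, 3))
  d$score <- 20 - 0.1 * d$fill - 2 * d$suvr + rnorm(n)
  fit <- fit_regression(d, "score", c("fill", "suvr", "age", "sex", "education"))
  uni <- summary(lm(score ~ fill + suvr + age + sex + education, d))$coefficients
  for (tm in c("fill", "suvr", "age")) {
    row <- fit$multivariate[fit$multivariate$term == tm, ]
    expect_equal(row$F, unname(uni[tm, "t value"]^2), tolerance = 1e-10)
    expect_equal(row$p_value, unname(uni[tm, "Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("multivariate Wilks term tests match car's approximate F", {
  set.seed(42)
  n <- 70
  d <- data.frame(fill = runif(n, 0, 60), age = rnorm(n, 70, 6),
                  sex = rbinom(n, 1, 0.5))
  d$s1 <- 25 - 0.08 * d$fill + rnorm(n)
  d$s2 <- 1 - 0.02 * d$fill + rnorm(n, sd = 0.5)
  fit <- fit_regression(d, c("s1", "s2"), c("fill", "age", "sex"))
  av <- car::Anova(lm(cbind(s1, s2) ~ fill + age + sex, d), type = "III",
                   test.statistic = "Wilks")
  sm <- summary(av, multivariate = TRUE)$multivariate.tests
  for (tm in c("fill", "age", "sex")) {
    got <- fit$multivariate[fit$multivariate$term == tm, ]
    ref <- sm[[tm]]
    lam_ref <- det(ref$SSPE) / det(ref$SSPE + ref$SSPH)
    expect_equal(got$wilks_lambda, lam_ref, tolerance = 1e-12)
  }
  # coefficient recovery: estimates carry the generating signs
  uni <- fit$univariate
  expect_lt(uni$estimate[uni$score == "s1" & uni$term == "fill"], 0)
})

test_that("regression coverage: true slope falls in its 95% CI at nominal rate", {
  set.seed(43)
  hits <- 0
  n_rep <- 300
  for (i in seq_len(n_rep)) {
    n <- 120
    x <- runif(n); w <- rnorm(n)
    y <- 1 - 2 * x + 0.5 * w + rnorm(n)
    d <- data.frame(y = y, x = x, w = w)
    fit <- fit_regression(d, "y", c("x", "w"))
    ci <- fit$univariate[fit$univariate$term == "x", c("ci_lower", "ci_upper")]
    if (ci$ci_lower <= -2 && -2 <= ci$ci_upper) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.93)
})

test_that("regression rejects rank-deficient designs by name", {
  d <- data.frame(y = rnorm(20), a = 1:20, b = 2 * (1:20))
  expect_error(fit_regression(d, "y", c("a", "b")), "collinear")
  expect_error(fit_regression(d, "y", c("a", "missing_col")), "not found")
})
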