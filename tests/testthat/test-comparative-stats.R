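test_that("Pearson correlation handles exact and null cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, 2 * x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_equal(pearson(c(1, 0, -1, 0), c(0, 1, 0, -1))$r, 0)
  expect_error(pearson(x, rep(1, 5)), "constant")
  expect_error(pearson(x, x[1:3]), "length")
  # affine invariance
  set.seed(6)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pearson(a, b)$r, pearson(2 + 3 * a, -1 + 0.5 * b)$r)
})

test_that("BM covariance equals root-to-MRCA path lengths", {
  tf <- tempfile(); writeLines("((A:1,B:1):1,C:2);", tf)
  tr <- read_newick(tf)
  V <- bm_covariance(tr)
  expect_equal(V["A", "A"], 2); expect_equal(V["B", "B"], 2)
  expect_equal(V["C", "C"], 2)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0); expect_equal(V["B", "C"], 0)
  # star tree: diagonal; ultrametric: constant diagonal
  writeLines("(A:1,B:1,C:1,D:1);", tf)
  Vs <- bm_covariance(read_newick(tf))
  expect_equal(unname(Vs), diag(4))
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", tf)
  quartet <- read_newick(tf)
  expect_error(bm_covariance(ape::unroot(quartet)), "unrooted|root")
})

test_that("lambda transform scales only the off-diagonal", {
  V <- matrix(c(2, 1, 1, 2), 2, 2)
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(c(2, 2)))
  expect_equal(lambda_transform(V, 0.5)[1, 2], 0.5)
  expect_equal(diag(lambda_transform(V, 0.5)), diag(V))
  expect_error(lambda_transform(V, 1.5), "\\[0, 1\\]")
})

test_that("PGLS reduces to OLS for lambda 0 on an ultrametric tree", {
  set.seed(41)
  tr <- yule_tree(24)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  x <- simulate_bm(tr, 50, 30)
  y <- 1 + 0.1 * x + rnorm(24, 0, 0.4)
  names(y) <- names(x)
  f <- pgls_fit(y, x, tr, lambda_mode = "fixed", lambda_fixed = 0)
  ols <- lm(y ~ x)
  expect_equal(unname(f$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(f$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-8)
  expect_equal(unname(f$t_stats), unname(summary(ols)$coefficients[, 3]),
               tolerance = 1e-8)
  # exact linear response: zero residuals, slope p -> 0
  y2 <- 2 + 0.05 * x
  f2 <- pgls_fit(y2, x, tr, lambda_mode = "fixed", lambda_fixed = 1)
  expect_lt(f2$p_values[2], 1e-12)
  expect_equal(unname(f2$coefficients), c(2, 0.05), tolerance = 1e-8)
})

test_that("ML lambda matches a dense-grid profile argmax", {
  set.seed(43)
  tr <- yule_tree(32)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  x <- simulate_bm(tr, 50, 30)
  y <- 1 + 0.05 * x + simulate_bm(tr, 0.5, 0, lambda_true = 0.6)
  names(y) <- names(x)
  f <- pgls_fit(y, x, tr)
  # dense-grid oracle over the same profile likelihood
  C <- bm_covariance(tr)[names(y), names(y)]
  X <- cbind(1, x[names(y)])
  prof <- function(lam) {
    V <- lambda_transform(C, lam)
    R <- chol(V)
    Z <- backsolve(R, cbind(y, X), transpose = TRUE)
    b <- qr.solve(Z[, -1], Z[, 1])
    r <- Z[, 1] - Z[, -1] %*% b
    n <- length(y)
    -0.5 * (n * log(2 * pi * sum(r^2) / n) + 2 * sum(log(diag(R))) + n)
  }
  grid <- seq(0, 1, length.out = 10001)
  dense <- grid[which.max(vapply(grid, prof, numeric(1)))]
  expect_lt(abs(f$lambda - dense), 2e-4)
})

test_that("PGLS agrees with nlme::gls under corPagel at fixed lambda", {
  skip_if_not_installed("nlme")
  set.seed(47)
  tr <- yule_tree(28)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  x <- simulate_bm(tr, 50, 30)
  y <- 1 + 0.08 * x + simulate_bm(tr, 1, 0)
  names(y) <- names(x)
  df <- data.frame(y = y[tr$tip.label], x = x[tr$tip.label],
                   sp = tr$tip.label)
  for (lam in c(0.25, 0.7, 1)) {
    f <- pgls_fit(y, x, tr, lambda_mode = "fixed", lambda_fixed = lam)
    g <- nlme::gls(y ~ x, data = df, method = "ML",
                   correlation = ape::corPagel(lam, tr, form = ~sp,
                                               fixed = TRUE))
    expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
    expect_equal(f$log_likelihood, as.numeric(stats::logLik(g)),
                 tolerance = 1e-6)
  }
})

test_that("normality pre-check matches the scipy omnibus oracle", {
  x <- c(10.00246, 10.597491, 9.451724, 8.218816, 9.090658, 8.016707,
         10.120287, 12.68043, 9.015587, 8.75905, 10.979684, 10.713774,
         10.210828, 8.139064, 9.941496, 11.390606, 7.311571, 9.084768,
         6.197555, 7.420925, 6.31653, 9.529818, 7.465107, 10.542529,
         10.313502, 9.626138, 4.966481, 8.922614, 9.902998, 10.226618,
         6.939728, 9.044493, 8.042962, 8.382326, 12.121797, 8.384931,
         9.934957, 11.76878, 8.832799, 9.776596)
  r <- g4therm:::dagostino_k2(x)
  expect_equal(r$k2, 1.0883416501725542, tolerance = 1e-9)
  expect_equal(r$p, 0.5803227729852358, tolerance = 1e-9)
  expect_equal(normality_check(x)$class, "normal")
  # lognormal sample classified via the log10 branch
  set.seed(51)
  ln <- exp(rnorm(500))
  expect_equal(normality_check(ln)$class, "lognormal")
  nm <- rnorm(500)
  expect_equal(normality_check(nm)$class, "normal")
  bim <- c(rnorm(250, -4, 0.3), rnorm(250, 4, 0.3))
  expect_equal(normality_check(bim)$class, "neither")
  expect_error(normality_check(rnorm(5)), "n >= 8")
})

test_that("one-way ANOVA matches the pooled t-test identity and separates", {
  set.seed(53)
  g1 <- rnorm(12, 0); g2 <- rnorm(15, 0.5)
  a <- anova_oneway(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 25L)
  # Tukey adjusted p >= unadjusted pairwise p (same pooled variance)
  g3 <- rnorm(10, 1)
  a3 <- anova_oneway(list(a = g1, b = g2, c = g3))
  vals <- c(g1, g2, g3)
  grp <- rep(c("a", "b", "c"), c(12, 15, 10))
  un <- pairwise.t.test(vals, grp, p.adjust.method = "none",
                        pool.sd = TRUE)$p.value
  for (k in seq_len(nrow(a3$pairwise))) {
    i <- a3$pairwise$group_i[k]; j <- a3$pairwise$group_j[k]
    raw <- if (i %in% rownames(un) && j %in% colnames(un) &&
               !is.na(un[i, j])) un[i, j] else un[j, i]
    expect_gte(a3$pairwise$adjusted_p[k] + 1e-12, raw)
  }
  # identical values shifted by large constants: full separation
  sep <- suppressWarnings(
    anova_oneway(list(a = rep(0, 4), b = rep(100, 4), c = rep(200, 4))))
  expect_equal(sep$p, 0)
  expect_true(all(sep$pairwise$adjusted_p < 1e-10))
  expect_error(anova_oneway(list(a = 1, b = c(1, 2))), "at least 2 values")
  expect_error(anova_oneway(list(a = c(1, 2))), "at least 2 groups")
})
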