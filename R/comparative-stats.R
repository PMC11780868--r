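# Pearson correlation, one-way ANOVA with normality pre-checks and pairwise
# comparisons, and PGLS regression under Brownian-motion covariance with
# Pagel's lambda.

#' Pearson correlation with a two-sided test
#'
#' @param x,y Numeric vectors of equal length (>= 3), non-constant.
#' @return List with `r`, `p`, `t` and `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       t = unname(ct$statistic), n = length(x))
}

#' Brownian-motion covariance matrix of a rooted tree
#'
#' `V[i, j]` is the shared root-to-MRCA path length of leaves i and j;
#' `V[i, i]` is the root-to-leaf depth.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return Covariance matrix with tip-label dimnames.
#' @export
bm_covariance <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree", call. = FALSE)
  # a pure star (single internal node) is treated as rooted at its centre
  if (!ape::is.rooted(tree) && tree$Nnode != 1L) {
    stop("tree is unrooted; root it first (e.g. root_midpoint())", call. = FALSE)
  }
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged. `lambda = 1` is pure Brownian motion, `lambda = 0` removes all
#' phylogenetic covariance.
#'
#' @param V Covariance matrix.
#' @param lambda Value in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must be in [0, 1]", call. = FALSE)
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

# GLS fit of y on X under covariance V (via Cholesky whitening). Returns the
# pieces needed for both the profile likelihood and the final inference.
gls_core <- function(y, X, V) {
  n <- length(y)
  R <- tryCatch(chol(V), error = function(e) {
    stop("covariance matrix is not positive definite", call. = FALSE)
  })
  logdetV <- 2 * sum(log(diag(R)))
  Z <- backsolve(R, cbind(y, X), transpose = TRUE)  # whitened [y X]
  yt <- Z[, 1]
  Xt <- Z[, -1, drop = FALSE]
  XtX <- crossprod(Xt)
  beta <- tryCatch(solve(XtX, crossprod(Xt, yt)), error = function(e) {
    stop("singular design under phylogenetic covariance", call. = FALSE)
  })
  resid <- yt - Xt %*% beta
  rss <- sum(resid^2)
  s2_ml <- rss / n
  ll <- -0.5 * (n * log(2 * pi * s2_ml) + logdetV + n)
  list(beta = drop(beta), rss = rss, XtX = XtX, loglik = ll, s2_ml = s2_ml)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y = X beta + e` with `e ~ N(0, sigma2 * V(lambda))`, where
#' `V(lambda)` is the lambda-transformed Brownian-motion covariance of the
#' tree. In `"ml"` mode lambda maximizes the profile likelihood over `[0, 1]`
#' (a 101-point grid followed by golden-section refinement to tolerance
#' 1e-6); `"fixed"` mode uses `lambda_fixed`. Coefficient tests are
#' two-sided t tests with `n - p` degrees of freedom.
#'
#' @param y Named response vector (names = tree tip labels).
#' @param x Predictor vector (named) or matrix (rownames = tip labels); an
#'   intercept column is added internally.
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param lambda_mode `"ml"` (default) or `"fixed"`.
#' @param lambda_fixed Lambda value used when `lambda_mode = "fixed"`.
#' @return An object of class `pgls_fit`: coefficients, standard errors, t
#'   statistics, p values, `lambda`, `sigma2`, `log_likelihood`, `n`.
#' @export
pgls_fit <- function(y, x, tree, lambda_mode = c("ml", "fixed"),
                     lambda_fixed = NULL) {
  lambda_mode <- match.arg(lambda_mode)
  if (is.null(names(y))) stop("y must be named by tree tip labels", call. = FALSE)
  if (is.null(dim(x))) {
    x <- matrix(x, ncol = 1, dimnames = list(names(x), "x"))
  }
  tips <- tree$tip.label
  if (!setequal(names(y), tips) || !setequal(rownames(x), tips)) {
    stop("names of y/x do not match tree tip labels", call. = FALSE)
  }
  y <- y[tips]
  X <- cbind(`(Intercept)` = 1, x[tips, , drop = FALSE])
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("more coefficients than observations", call. = FALSE)
  C <- bm_covariance(tree)[tips, tips]

  profile_ll <- function(lam) gls_core(y, X, lambda_transform(C, lam))$loglik

  if (lambda_mode == "fixed") {
    if (is.null(lambda_fixed)) stop("lambda_fixed required", call. = FALSE)
    lambda <- lambda_fixed
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  } else {
    grid <- seq(0, 1, length.out = 101)
    ll <- vapply(grid, profile_ll, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    if (lo == hi) {
      lambda <- grid[i]
    } else {
      opt <- optimize(profile_ll, interval = c(lo, hi), maximum = TRUE,
                      tol = 1e-6)
      lambda <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
    }
  }

  fit <- gls_core(y, X, lambda_transform(C, lambda))
  sigma2 <- fit$rss / (n - p)
  covb <- sigma2 * solve(fit$XtX)
  se <- sqrt(diag(covb))
  tstat <- fit$beta / se
  pval <- 2 * pt(-abs(tstat), df = n - p)
  structure(list(coefficients = setNames(fit$beta, colnames(X)),
                 se = setNames(se, colnames(X)),
                 t_stats = setNames(tstat, colnames(X)),
                 p_values = setNames(pval, colnames(X)),
                 lambda = lambda, sigma2 = sigma2,
                 sigma2_ml = fit$s2_ml,
                 log_likelihood = fit$loglik,
                 n = n, df_residual = n - p,
                 lambda_mode = lambda_mode),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (n = %d, lambda = %.4f [%s], sigma2 = %.4g, logLik = %.3f)\n",
              x$n, x$lambda, x$lambda_mode, x$sigma2, x$log_likelihood))
  tab <- cbind(Estimate = x$coefficients, `Std.Error` = x$se,
               t = x$t_stats, `p` = x$p_values)
  print(tab)
  invisible(x)
}

# D'Agostino-Pearson omnibus normality statistic (skewness + kurtosis).
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 8) stop("need n >= 8 for the omnibus test", call. = FALSE)
  xc <- x - mean(x)
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  if (m2 == 0) stop("zero variance", call. = FALSE)
  g1 <- m3 / m2^1.5
  # skewness z (D'Agostino 1970 transformation)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2g1 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2g1 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  Z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis z (Anscombe-Glynn transformation)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  denom <- 1 + xx * sqrt(2 / (A - 4))
  # signed cube root keeps the transform defined for strongly platykurtic data
  term2 <- sign(denom) * abs((1 - 2 / A) / denom)^(1 / 3)
  Z2 <- ((1 - 2 / (9 * A)) - term2) * sqrt(9 * A / 2)
  K2 <- Z1^2 + Z2^2
  list(k2 = K2, p = pchisq(K2, df = 2, lower.tail = FALSE),
       z_skew = Z1, z_kurt = Z2)
}

#' Normality / lognormality pre-check
#'
#' D'Agostino-Pearson omnibus K2 test on the raw values and, when all values
#' are positive, on their log10 transform. Returns the first of raw/log that
#' passes at `alpha`, else `"neither"`.
#'
#' @param x Numeric vector, `n >= 8`.
#' @param alpha Significance level of the pre-check.
#' @return List with `class` ("normal", "lognormal" or "neither") and the
#'   raw/log test results.
#' @export
normality_check <- function(x, alpha = 0.05) {
  raw <- dagostino_k2(x)
  logres <- NULL
  if (raw$p > alpha) {
    cls <- "normal"
  } else if (all(x > 0)) {
    logres <- dagostino_k2(log10(x))
    cls <- if (logres$p > alpha) "lognormal" else "neither"
  } else {
    cls <- "neither"  # lognormal branch not applicable
  }
  list(class = cls, raw = raw, log = logres)
}

#' One-way ANOVA with Tukey-Kramer pairwise comparisons
#'
#' Classical one-way F test across groups, with Tukey-Kramer adjusted
#' pairwise comparisons from the studentized range distribution. With
#' `transform = "auto"` a log10 transform is applied when
#' [normality_check()] on the pooled values selects "lognormal".
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param transform "none", "log10" or "auto".
#' @return List with `F`, `df_between`, `df_within`, `p`, a `pairwise` table
#'   and the applied `transform`.
#' @export
anova_oneway <- function(groups, transform = c("none", "log10", "auto")) {
  transform <- match.arg(transform)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  if (transform == "auto") {
    transform <- if (all(vals > 0) &&
                     normality_check(vals)$class == "lognormal") "log10" else "none"
  }
  if (transform == "log10") {
    if (any(vals <= 0)) stop("log10 transform needs positive values", call. = FALSE)
    groups <- lapply(groups, log10)
  }
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   grp = factor(rep(names(groups),
                                    vapply(groups, length, 1L))))
  fit <- aov(value ~ grp, data = df)
  an <- anova(fit)
  Fval <- an$`F value`[1]
  pval <- an$`Pr(>F)`[1]
  msw_zero <- an$`Mean Sq`[2] <= 1e-12 * max(an$`Mean Sq`[1], 1)
  if (msw_zero) { Fval <- Inf; pval <- 0 }
  tk <- TukeyHSD(fit)$grp
  pw <- data.frame(do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE)),
                   mean_diff = tk[, "diff"],
                   adjusted_p = tk[, "p adj"],
                   row.names = NULL, stringsAsFactors = FALSE)
  names(pw)[1:2] <- c("group_i", "group_j")
  if (msw_zero) {
    # perfect separation: studentized range is degenerate
    pw$adjusted_p <- ifelse(pw$mean_diff != 0, 0, 1)
  }
  list(F = Fval, df_between = an$Df[1], df_within = an$Df[2],
       p = pval, pairwise = pw, transform = transform)
}
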