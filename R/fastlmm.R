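# Profiled-REML solver for the Gaussian model y = X b + (1 | g) + e with a
# single random intercept. Used for the thousands of per-permutation refits in
# coefficient_permutation_test, where the generic mixed-model machinery is the
# bottleneck; the observed (reported) fit always comes from lme4. The two are
# numerically identical (checked against lme4 in the test suite): for
# V = I + theta * Z Z' with theta = var_g / var_e, block structure gives
# V^{-1} and log|V| in closed form, leaving a one-dimensional REML profile
# over log(theta).

fast_lmm_prepare <- function(X, group) {
  g <- as.integer(factor(group))
  idx <- split(seq_along(g), g)
  nk <- lengths(idx)
  Sx <- t(vapply(idx, function(ii) colSums(X[ii, , drop = FALSE]),
                 numeric(ncol(X))))
  list(X = X, idx = idx, nk = nk, Sx = Sx, XtX = crossprod(X),
       n = nrow(X), p = ncol(X))
}

fast_lmm_fit <- function(prep, y) {
  Sy <- vapply(prep$idx, function(ii) sum(y[ii]), numeric(1))
  Xty <- crossprod(prep$X, y)
  yty <- sum(y^2)
  nk <- prep$nk; Sx <- prep$Sx; XtX <- prep$XtX
  n <- prep$n; p <- prep$p
  crit <- function(lth) {
    th <- exp(lth)
    w <- th / (1 + th * nk)
    A <- XtX - crossprod(Sx * w, Sx)
    b <- Xty - crossprod(Sx * w, Sy)
    beta <- solve(A, b)
    rss <- (yty - sum(w * Sy^2)) - sum(beta * b)
    (n - p) * log(rss / (n - p)) + sum(log1p(th * nk)) +
      determinant(A, logarithm = TRUE)$modulus
  }
  # profile over log(theta); the lower bound behaves as the theta -> 0 (OLS)
  # limit, so a boundary solution degrades gracefully to a fixed-intercept fit
  opt <- stats::optimize(crit, c(-14, 14), tol = 1e-7)
  th <- exp(opt$minimum)
  w <- th / (1 + th * nk)
  A <- XtX - crossprod(Sx * w, Sx)
  b <- Xty - crossprod(Sx * w, Sy)
  beta <- drop(solve(A, b))
  s2 <- ((yty - sum(w * Sy^2)) - sum(beta * b)) / (n - p)
  se <- sqrt(diag(solve(A)) * s2)
  names(beta) <- names(se) <- colnames(prep$X)
  list(beta = beta, se = se, t = beta / se,
       var_group = th * s2, var_resid = s2)
}
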