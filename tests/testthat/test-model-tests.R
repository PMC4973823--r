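test_that("the internal REML solver is numerically identical to lme4", {
  set.seed(7)
  for (r in 1:12) {
    n <- 40
    g <- sample(rep(c("a1", "a2"), each = n / 2))
    sex <- rbinom(n, 1, 0.5)
    y <- 2 + 1.5 * sex + rep(rnorm(2), length.out = n)[as.integer(factor(g))] + rnorm(n)
    X <- cbind(`(Intercept)` = 1, sex = sex)
    f <- assocnet:::fast_lmm_fit(assocnet:::fast_lmm_prepare(X, g), y)
    m <- lme4::lmer(y ~ sex + (1 | g), REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
    expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-5)
    expect_equal(unname(f$se), unname(coef(summary(m))[, 2]), tolerance = 1e-4)
    vc <- as.data.frame(lme4::VarCorr(m))
    expect_equal(f$var_group, vc$vcov[1], tolerance = 1e-3)
    expect_equal(f$var_resid, vc$vcov[2], tolerance = 1e-3)
  }
})

test_that("coefficient test recovers a planted sex effect on node strength", {
  sc <- simulate_scenario("sex_effect", seed = 31)
  res <- coefficient_permutation_test(sc$gbi, sc$attributes,
                                      strength ~ sex + (1 | area),
                                      n_perm = 100, seed = 32)
  expect_gt(res$observed, 0)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$fit$term, c("(Intercept)", "sexM"))
  expect_named(res$ranef_variance)
  expect_equal(res$n_perm, 100)
  # the same test via node permutations also sees the (real) effect
  res_node <- coefficient_permutation_test(sc$gbi, sc$attributes,
                                           strength ~ sex + (1 | area),
                                           kind = "node", n_perm = 200, seed = 33)
  expect_lt(res_node$p_value, 0.05)
})

test_that("coefficient test supports plain fixed-effect models", {
  sc <- simulate_scenario("sex_effect", seed = 41)
  res <- coefficient_permutation_test(sc$gbi, sc$attributes,
                                      strength ~ sex + gregariousness,
                                      focal = "gregariousness",
                                      n_perm = 50, seed = 42)
  expect_equal(res$focal, "gregariousness")
  expect_gt(res$observed, 0)
  expect_error(coefficient_permutation_test(sc$gbi, sc$attributes,
                                            strength ~ sex, focal = "nope",
                                            n_perm = 10, seed = 1),
               "not in model matrix")
  expect_error(coefficient_permutation_test(sc$gbi, sc$attributes,
                                            density ~ sex, n_perm = 10),
               "left-hand side")
})

test_that("mantel test: identity, negation and the exhaustive oracle", {
  m1 <- random_symmetric_net(1, n = 6)$weights
  res <- mantel_test(m1, m1, n_perm = 200, seed = 1)
  expect_equal(res$observed, 1)
  expect_lte(res$p_value, 1 / 200 + 1e-9)
  neg <- mantel_test(m1, max(m1) - m1 - diag(max(m1), nrow(m1)), n_perm = 99, seed = 2)
  expect_lt(neg$observed, -0.9)
  expect_error(mantel_test(m1, m1[1:4, 1:4]), "identical dimensions")
  # exhaustive 4! relabelings vs large-n_perm Monte Carlo
  set.seed(5)
  for (k in 1:3) {
    a <- matrix(runif(16), 4); a <- (a + t(a)) / 2; diag(a) <- 0
    b <- matrix(runif(16), 4); b <- (b + t(b)) / 2; diag(b) <- 0
    exact <- oracle_mantel_exact(a, b, "two_sided")
    mc <- mantel_test(a, b, n_perm = 4000, seed = k)$p_value
    expect_lt(abs(mc - exact), 0.05)
  }
})

test_that("mantel correlation agrees with vegan's statistic", {
  a <- random_symmetric_net(3, n = 8)$weights
  b <- random_symmetric_net(4, n = 8)$weights
  ours <- mantel_test(a, b, n_perm = 10, seed = 1)$observed
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 9)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("MRQAP recovers a planted coefficient structure", {
  set.seed(6)
  n <- 8
  x1 <- matrix(runif(n * n), n); x1 <- (x1 + t(x1)) / 2; diag(x1) <- 0
  x2 <- matrix(runif(n * n), n); x2 <- (x2 + t(x2)) / 2; diag(x2) <- 0
  # a whisper of noise keeps the residual variance strictly positive, which
  # t-statistic-based double-semi-partialling needs
  eps <- matrix(rnorm(n * n, sd = 1e-6), n); eps <- (eps + t(eps)) / 2; diag(eps) <- 0
  y <- 2 * x1 + eps
  res <- mrqap_dsp(y, list(a = x1, b = x2), n_perm = 300, seed = 7)
  expect_equal(res$terms$coefficient, c(2, 0), tolerance = 1e-4)
  expect_lte(res$terms$p_value[1], 0.01)
  expect_gt(res$terms$p_value[2], 0.05)
  expect_error(mrqap_dsp(y, list(a = x1, b = 2 * x1)), "collinear")
})

test_that("single-predictor MRQAP agrees in decision with the Mantel test", {
  set.seed(8)
  agree <- 0
  for (k in 1:12) {
    n <- 7
    a <- matrix(runif(n * n), n); a <- (a + t(a)) / 2; diag(a) <- 0
    signal <- runif(1) < 0.5
    b <- if (signal) a + matrix(rnorm(n * n, sd = 0.1), n) else
      matrix(runif(n * n), n)
    b <- (b + t(b)) / 2; diag(b) <- 0
    p1 <- mantel_test(b, a, n_perm = 500, seed = k)$p_value
    p2 <- mrqap_dsp(b, list(a = a), n_perm = 500, seed = k)$terms$p_value
    agree <- agree + ((p1 < 0.05) == (p2 < 0.05))
  }
  expect_gte(agree, 10)
})

test_that("MRQAP DSP p-values track exhaustive relabeling on 5 nodes", {
  set.seed(9)
  n <- 5
  x <- matrix(runif(n * n), n); x <- (x + t(x)) / 2; diag(x) <- 0
  y <- x + matrix(rnorm(n * n, sd = 0.4), n); y <- (y + t(y)) / 2; diag(y) <- 0
  # exhaustive: all 120 relabelings of the DSP residual matrix
  keep <- row(y) != col(y)
  X <- cbind(1, x[keep])
  fit_t <- function(Xm, yv) {
    XtXi <- solve(crossprod(Xm))
    b <- drop(XtXi %*% crossprod(Xm, yv))
    r <- yv - Xm %*% b
    se <- sqrt(diag(XtXi) * sum(r^2) / (length(yv) - ncol(Xm)))
    (b / se)[2]
  }
  t_obs <- fit_t(X, y[keep])
  ek <- lm.fit(cbind(rep(1, sum(keep))), x[keep])$residuals
  E <- matrix(0, n, n); E[keep] <- ek
  perms <- gtools_permutations(n)
  t_null <- apply(perms, 1, function(p) fit_t(cbind(1, E[p, p][keep]), y[keep]))
  exact <- mean(abs(t_null - mean(t_null)) >= abs(t_obs - mean(t_null)))
  mc <- mrqap_dsp(y, list(x = x), n_perm = 4000, seed = 10)$terms$p_value
  expect_lt(abs(mc - exact), 0.06)
})

test_that("partial correlations are bounded and consistent with t", {
  set.seed(11)
  n <- 9
  x <- matrix(runif(n * n), n); x <- (x + t(x)) / 2; diag(x) <- 0
  y <- 0.7 * x + matrix(rnorm(n * n, sd = 0.3), n); y <- (y + t(y)) / 2; diag(y) <- 0
  res <- mrqap_dsp(y, list(x = x), n_perm = 50, seed = 12)
  pr <- res$terms$partial_r
  expect_true(abs(pr) <= 1)
  expect_equal(sign(pr), sign(res$terms$t))
})
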