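test_that("dyad tallies match hand counts in both sampling-unit modes", {
  g <- toy_gbi()
  # union mode: P1 = {a,b},{c}; P2 = {a,c}
  tu <- tally_dyads(g, "union")
  expect_equal(tu$x["a", "b"], 1)      # together in P1
  expect_equal(tu$y_a["a", "b"], 1)    # P2: a seen without b
  expect_equal(tu$y_a["b", "a"], 0)
  expect_equal(tu$y_ab["a", "b"], 0)
  expect_equal(tu$y_ab["a", "c"], 1)   # P1: both seen, apart
  expect_equal(tu$x["a", "c"], 1)      # P2
  expect_equal(tu$d["a", "b"], 2)
  # per-row mode: 3 sampling units
  tr <- tally_dyads(g, "rows")
  expect_equal(tr$x["a", "b"], 1)
  expect_equal(tr$y_a["a", "b"], 1)    # row 3 has a without b
  expect_equal(tr$y_a["c", "a"], 1)    # row 2
  expect_true(all(tr$y_ab == 0))       # structurally impossible per group row
})

test_that("simple ratio and half-weight indices follow the printed formulas", {
  # x = 3, y_AB = 1, y_A = 2, y_B = 2
  t <- structure(list(
    x = matrix(c(0, 3, 3, 0), 2), y_ab = matrix(c(0, 1, 1, 0), 2),
    y_a = matrix(c(0, 2, 2, 0), 2), d = matrix(c(0, 8, 8, 0), 2),
    ids = c("A", "B"), n_units = 8, period_mode = "union"),
    class = "dyad_tally")
  expect_equal(association_index(t, "sri")$weights["A", "B"], 3 / 8)    # 0.375
  expect_equal(association_index(t, "hwi")$weights["A", "B"], 3 / 6)    # 0.5
})

test_that("index limits: always together gives 1, never together gives 0", {
  always <- as_gbi(matrix(1L, 5, 2), c("a", "b"), period = 1:5)
  expect_equal(assoc_network(always)$weights["a", "b"], 1)
  apart <- as_gbi(rbind(c(1L, 0L), c(0L, 1L))[rep(1:2, 4), ], c("a", "b"),
                  period = rep(1:4, each = 2))
  net <- assoc_network(apart)
  expect_equal(net$weights["a", "b"], 0)
  expect_true(net$mask["a", "b"])      # sampled dyad, genuinely zero
})

test_that("unsampled dyads are masked and carry zero weight", {
  # individual e is on the roster but never observed: its denominators are 0
  # e and f are on the roster but never observed: the e-f denominator is 0
  s <- tibble::tibble(period = c("1", "1"),
                      members = list(c("a", "b"), c("c", "d")))
  g <- build_gbi(s, roster = letters[1:6])
  net <- assoc_network(g)
  expect_true(net$mask["a", "b"])
  expect_true(net$mask["a", "c"])          # both seen in period 1, apart
  expect_true(net$mask["a", "e"])          # a seen without e: d = 1
  expect_false(net$mask["e", "f"])         # neither ever sampled: d = 0
  expect_equal(unname(net$weights[, "e"]), rep(0, 6))
  t <- tally_dyads(g)
  expect_equal(t$d["e", "f"], 0)
  expect_equal(t$d["a", "e"], 1)
})

test_that("HWI is at least SRI, equal only without solo sightings", {
  for (seed in 1:10) {
    g <- random_sparse_gbi(seed)
    sri <- assoc_network(g, "sri")$weights
    hwi <- assoc_network(g, "hwi")$weights
    expect_true(all(hwi - sri >= -1e-12), info = seed)
    t <- tally_dyads(g)
    solo <- t$y_a + t(t$y_a)
    has_solo <- solo > 0 & t$x > 0
    expect_true(all(hwi[has_solo] > sri[has_solo]), info = seed)
    expect_equal(hwi[solo == 0], sri[solo == 0], info = seed)
    expect_true(all(sri >= 0 & sri <= 1 & hwi >= 0 & hwi <= 1), info = seed)
  }
})

test_that("tallies and indices agree with the per-period enumeration oracle", {
  for (seed in 1:8) {
    g <- random_sparse_gbi(seed, n = 8, P = 12)
    o <- oracle_tally_union(g)
    t <- tally_dyads(g, "union")
    expect_equal(unname(t$x), o$x, info = seed)
    expect_equal(unname(t$y_ab), o$y_ab, info = seed)
    expect_equal(unname(t$y_a), o$y_a, info = seed)
    expect_equal(unname(t$d), o$d, info = seed)
    expect_equal(unname(assoc_network(g, "sri")$weights), oracle_sri(g), info = seed)
    expect_equal(unname(assoc_network(g, "hwi")$weights), oracle_hwi(g), info = seed)
  }
})

test_that("indices are invariant under relabeling of individuals", {
  g <- random_sparse_gbi(21)
  set.seed(2)
  perm <- sample(ncol(g$matrix))
  g2 <- as_gbi(g$matrix[, perm], g$ids[perm], period = g$meta$period)
  w1 <- assoc_network(g)$weights
  w2 <- assoc_network(g2)$weights
  expect_equal(w2[g$ids, g$ids], w1)
})

test_that("multiple group memberships within a period count once (union mode)", {
  # individual a appears in two groups of the same period with b in one of them
  m <- rbind(c(1L, 1L, 0L), c(1L, 0L, 1L))
  g <- as_gbi(m, c("a", "b", "c"), period = c(1, 1))
  t <- tally_dyads(g, "union")
  expect_equal(t$x["a", "b"], 1)
  expect_equal(t$d["a", "b"], 1)
  expect_equal(assoc_network(g)$weights["a", "b"], 1)
})

test_that("interaction rates divide by actor exposure and keep direction", {
  log <- tibble::tibble(
    actor = c(rep("A", 10), rep("B", 2)),
    receiver = c(rep("B", 10), rep("A", 2))
  )
  net <- interaction_rate_network(log, exposure = c(A = 5, B = 5))
  expect_true(net$directed)
  expect_equal(net$weights["A", "B"], 2)     # 10 events / 5 h
  expect_equal(net$weights["B", "A"], 0.4)   # 2 events / 5 h
  expect_error(interaction_rate_network(log, exposure = c(A = 5, B = 0)),
               "exposure")
  empty <- interaction_rate_network(log[0, ], exposure = c(A = 1, B = 1),
                                    ids = c("A", "B"))
  expect_true(all(empty$weights == 0))
})

test_that("rate networks are rank-identical to counts under equal exposure", {
  set.seed(4)
  log <- tibble::tibble(actor = sample(letters[1:5], 60, TRUE),
                        receiver = sample(letters[1:5], 60, TRUE))
  log <- log[log$actor != log$receiver, ]
  expo1 <- setNames(rep(2, 5), letters[1:5])
  counts <- interaction_rate_network(log, setNames(rep(1, 5), letters[1:5]))
  rates <- interaction_rate_network(log, expo1)
  expect_equal(rank(counts$weights), rank(rates$weights))
})

test_that("affiliation residuals behave like regression residuals", {
  g <- random_sparse_gbi(31, n = 6, P = 20)
  t <- tally_dyads(g)
  n <- length(g$ids)
  # constant predictor: gaussian residuals are centred indices
  const <- matrix(1, n, n)
  res <- affiliation_index(t, list(space = const), family = "gaussian")
  ut <- upper.tri(const) & t$d > 0
  idx <- assoc_network(g)$weights
  expect_equal(res$weights[ut], idx[ut] - mean(idx[ut]), tolerance = 1e-10)
  # indices exactly linear in a predictor: all residuals 0
  pred <- idx * 2 + 0.1
  diag(pred) <- 0
  res2 <- affiliation_index(t, list(p = pred), family = "gaussian")
  expect_lt(max(abs(res2$weights[ut])), 1e-10)
  # matches an independent least-squares solve
  set.seed(9)
  sp <- matrix(runif(n * n), n); sp <- (sp + t(sp)) / 2; diag(sp) <- 0
  res3 <- affiliation_index(t, list(space = sp), family = "gaussian")
  X <- cbind(1, sp[ut])
  beta <- solve(crossprod(X), crossprod(X, idx[ut]))
  expect_equal(res3$weights[ut], unname(idx[ut] - X %*% beta)[, 1], tolerance = 1e-10)
  # binomial family: deviance residuals near zero mean, collinearity detected
  res4 <- affiliation_index(t, list(space = sp), family = "binomial")
  expect_lt(abs(mean(res4$weights[ut])), 0.5)
  expect_error(affiliation_index(t, list(a = sp, b = 2 * sp)), "collinear")
})

test_that("thresholding follows the strictly-greater convention", {
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- c(0.1, 0.5, 0.9)
  m <- m + t(m)
  net <- new_network(m, letters[1:3])
  suppressWarnings({
    b <- threshold_network(net, 0.5, "binarize")
    expect_equal(sort(b$weights[upper.tri(b$weights)]), c(0, 0, 1))
    expect_equal(sum(threshold_network(net, 0, "binarize")$weights) / 2, 3)
    expect_equal(sum(threshold_network(net, 0.9, "binarize")$weights), 0)
    p <- threshold_network(net, "mean", "prune")
    expect_equal(sort(p$weights[upper.tri(p$weights)]), c(0, 0, 0.9))
  })
  expect_warning(threshold_network(net, 0.5), "caution")
})
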