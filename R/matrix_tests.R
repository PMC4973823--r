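# Dyadic-matrix regression tests. Matrix cells are non-independent (each row
# and column shares an individual), so significance comes from node-relabeling
# permutations: rows and columns are permuted simultaneously, preserving the
# dyadic dependence structure.

as_square_matrix <- function(x, arg = "matrix") {
  if (inherits(x, "assoc_net")) x <- x$weights
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    abort(paste0(arg, " must be a square matrix or assoc_net"))
  }
  x
}

offdiag <- function(m) m[row(m) != col(m)]

#' Mantel test for matrix correlation
#'
#' Correlation between the corresponding off-diagonal elements of two square
#' matrices, with significance from simultaneous row-and-column (node label)
#' permutations of the second matrix. The matrix correlation coefficient is the
#' effect size.
#'
#' @param m1,m2 Square matrices (or `assoc_net` objects) of equal dimension.
#' @param n_perm Number of permutations.
#' @param method `"pearson"` or `"spearman"`.
#' @param tail `"two_sided"` (default), `"upper"` or `"lower"`.
#' @param seed Optional integer seed.
#' @param conservative Use the (1 + k)/(1 + n) p-value variant?
#' @return A `perm_test` with the matrix correlation as observed statistic.
#' @export
mantel_test <- function(m1, m2, n_perm = 1000,
                        method = c("pearson", "spearman"),
                        tail = c("two_sided", "upper", "lower"),
                        seed = NULL, conservative = FALSE) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  m1 <- as_square_matrix(m1, "m1")
  m2 <- as_square_matrix(m2, "m2")
  if (!all(dim(m1) == dim(m2))) abort("matrices must have identical dimensions")
  n <- nrow(m1)
  seed <- resolve_seed(seed)
  v1 <- offdiag(m1)
  observed <- cor(v1, offdiag(m2), method = method)
  nulls <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(v1, offdiag(m2[p, p]), method = method)
  }, numeric(1))
  pv <- perm_pvalue(observed, nulls, tail, conservative)
  new_perm_test(
    statistic = paste0("mantel_r(", method, ")"),
    observed = observed, null_values = nulls, p_value = pv,
    effect = c(matrix_correlation = observed),
    tail = tail,
    config = list(method = method, n_perm = n_perm, seed = seed)
  )
}

#' MRQAP with double-semi-partialling
#'
#' Multiple regression of a dyadic response matrix on dyadic predictor
#' matrices, with per-predictor significance by the double-semi-partialling
#' procedure: the focal predictor is regressed on the remaining predictors, its
#' residual matrix is node-relabel-permuted, and the model is refitted with the
#' permuted residuals in place of the focal predictor; the observed
#' t-statistic is compared with the resulting null t-statistics. Partial
#' correlation coefficients are reported as effect sizes.
#'
#' @param y Square response matrix (or `assoc_net`).
#' @param predictors Named list of square predictor matrices (or `assoc_net`s).
#' @param n_perm Number of permutations per predictor.
#' @param tail `"two_sided"` (default), `"upper"` or `"lower"`.
#' @param seed Optional integer seed.
#' @param conservative Use the (1 + k)/(1 + n) p-value variant?
#' @return An `mrqap` object whose `terms` tibble has one row per predictor:
#'   `term`, `coefficient`, `t`, `partial_r`, `p_value`. Methods: [tidy()],
#'   [glance()].
#' @export
mrqap_dsp <- function(y, predictors, n_perm = 1000,
                      tail = c("two_sided", "upper", "lower"),
                      seed = NULL, conservative = FALSE) {
  tail <- match.arg(tail)
  y <- as_square_matrix(y, "y")
  if (!length(predictors)) abort("at least one predictor is required")
  if (is.null(names(predictors)) || any(!nzchar(names(predictors)))) {
    names(predictors) <- paste0("x", seq_along(predictors))
  }
  predictors <- lapply(predictors, as_square_matrix, arg = "predictor")
  n <- nrow(y)
  if (any(vapply(predictors, nrow, 0L) != n)) {
    abort("all matrices must share the response's dimension")
  }
  seed <- resolve_seed(seed)
  keep <- row(y) != col(y)
  yv <- y[keep]
  Xv <- vapply(predictors, function(m) m[keep], numeric(sum(keep)))
  X <- cbind(`(Intercept)` = 1, Xv)
  if (qr(X)$rank < ncol(X)) {
    drop1 <- qr(X)$pivot[-seq_len(qr(X)$rank)]
    abort(paste0("collinear predictors: ",
                 paste(colnames(X)[drop1], collapse = ", ")))
  }
  fit_t <- function(Xmat, yvec) {
    XtXi <- solve(crossprod(Xmat))
    beta <- drop(XtXi %*% crossprod(Xmat, yvec))
    res <- yvec - drop(Xmat %*% beta)
    df <- length(yvec) - ncol(Xmat)
    se <- sqrt(diag(XtXi) * sum(res^2) / df)
    names(beta) <- colnames(Xmat)
    list(beta = beta, t = beta / se, df = df)
  }
  obs <- fit_t(X, yv)
  terms <- names(predictors)
  out <- vector("list", length(terms))
  for (k in seq_along(terms)) {
    col_k <- k + 1L                       # after intercept
    Xo <- X[, -col_k, drop = FALSE]
    ek <- lm.fit(Xo, X[, col_k])$residuals
    Ek <- matrix(0, n, n)
    Ek[keep] <- ek
    nulls <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      Ep <- Ek[p, p]
      f <- fit_t(cbind(Xo, .e = Ep[keep]), yv)
      unname(f$t[".e"])
    }, numeric(1))
    pv <- perm_pvalue(unname(obs$t[col_k]), nulls, tail, conservative)
    out[[k]] <- tibble(
      term = terms[k],
      coefficient = unname(obs$beta[col_k]),
      t = unname(obs$t[col_k]),
      partial_r = unname(obs$t[col_k] / sqrt(obs$t[col_k]^2 + obs$df)),
      p_value = pv
    )
  }
  structure(list(terms = do.call(rbind, out),
                 intercept = unname(obs$beta[1]),
                 n = n, n_perm = n_perm, tail = tail, seed = seed),
            class = "mrqap")
}

#' @export
print.mrqap <- function(x, ...) {
  cat("MRQAP (double-semi-partialling), ", x$n_perm, " permutations, ",
      x$n, " nodes\n", sep = "")
  print(as.data.frame(x$terms), row.names = FALSE, digits = 4)
  invisible(x)
}
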