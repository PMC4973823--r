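# Dyad tallies and association indices. For each unordered dyad A-B over the
# sampling units: x = units where A and B occurred in the same group, y_AB =
# both identified but never together, y_A / y_B = only one of the pair
# identified. The simple ratio index is x / (x + y_AB + y_A + y_B); the
# half-weight index halves the solo terms to correct for missed joint
# identifications.

#' Tally dyadic co-occurrence counts from a GBI
#'
#' Computes the per-dyad sufficient statistics for association indices. With
#' `period_mode = "union"` (default) the sampling unit is the sampling period:
#' all groups within a period are pooled, a dyad counts as together if it
#' shared a group at least once within the period, and as both-seen-apart if
#' both were identified in the period but never in the same group. With
#' `period_mode = "rows"` every group row is its own sampling unit (suitable
#' for instantaneous group records), in which case both-seen-apart is
#' structurally zero.
#'
#' @param gbi A `gbi` object.
#' @param period_mode `"union"` or `"rows"`.
#' @return An object of class `dyad_tally`: list of N x N matrices `x`
#'   (together), `y_ab` (both seen, apart), `y_a` (row individual seen without
#'   column individual), `d` (denominator: units where at least one was
#'   identified), plus `ids` and `n_units`.
#' @export
tally_dyads <- function(gbi, period_mode = c("union", "rows")) {
  stopifnot(inherits(gbi, "gbi"))
  period_mode <- match.arg(period_mode)
  g <- gbi$matrix
  n <- ncol(g)
  if (period_mode == "rows") {
    x <- crossprod(g)
    ca <- colSums(g)
    cab <- x
    n_units <- nrow(g)
  } else {
    per <- factor(gbi$meta$period, levels = unique(gbi$meta$period))
    counts <- rowsum(g, per)
    identified <- (counts > 0) + 0L
    ca <- colSums(identified)
    cab <- crossprod(identified)
    n_units <- nlevels(per)
    if (max(counts) <= 1L) {
      # no individual occurs twice within a period: row co-membership counts
      # are exactly period-level together counts
      x <- crossprod(g)
    } else {
      x <- matrix(0L, n, n)
      for (p in levels(per)) {
        gp <- g[per == p, , drop = FALSE]
        x <- x + ((crossprod(gp) > 0) + 0L)
      }
    }
  }
  storage.mode(x) <- "double"
  storage.mode(cab) <- "double"
  y_ab <- cab - x
  y_a <- matrix(ca, n, n) - cab          # row individual seen, column not
  d <- matrix(ca, n, n) + matrix(ca, n, n, byrow = TRUE) - cab
  diag(x) <- diag(y_ab) <- diag(y_a) <- diag(d) <- 0
  dimnames(x) <- dimnames(y_ab) <- dimnames(y_a) <- dimnames(d) <-
    list(gbi$ids, gbi$ids)
  structure(list(x = x, y_ab = y_ab, y_a = y_a, d = d,
                 ids = gbi$ids, n_units = n_units, period_mode = period_mode),
            class = "dyad_tally")
}

#' @export
print.dyad_tally <- function(x, ...) {
  cat("<dyad_tally> ", length(x$ids), " individuals over ", x$n_units,
      " sampling unit(s) [", x$period_mode, " mode]\n", sep = "")
  invisible(x)
}

#' Association-index network from dyad tallies
#'
#' Converts dyad tallies into a weighted undirected network using the simple
#' ratio index `x / (x + y_AB + y_A + y_B)` or the half-weight index
#' `x / (x + y_AB + (y_A + y_B) / 2)`. Dyads never sampled (denominator zero)
#' carry weight 0 and are flagged in the network's `mask` so downstream
#' statistics can include or exclude them.
#'
#' @param tally A `dyad_tally` object from [tally_dyads()].
#' @param index `"sri"` (simple ratio) or `"hwi"` (half-weight).
#' @return An `assoc_net` with `edge_kind = "association_index"`.
#' @export
association_index <- function(tally, index = c("sri", "hwi")) {
  stopifnot(inherits(tally, "dyad_tally"))
  index <- match.arg(index)
  x <- tally$x
  solo <- tally$y_a + t(tally$y_a)
  den <- switch(index,
                sri = x + tally$y_ab + solo,
                hwi = x + tally$y_ab + solo / 2)
  w <- ifelse(den > 0, x / den, 0)
  diag(w) <- 0
  new_network(w, tally$ids, directed = FALSE, edge_kind = "association_index",
              mask = tally$d > 0)
}

#' Build an association network straight from a GBI
#'
#' Convenience pipeline: [tally_dyads()] then [association_index()].
#'
#' @inheritParams tally_dyads
#' @inheritParams association_index
#' @return An `assoc_net`.
#' @export
#' @examples
#' s <- tibble::tibble(period = c("P1", "P1", "P2"),
#'                     members = list(c("a", "b"), "c", c("a", "c")))
#' assoc_network(build_gbi(s), index = "sri")
assoc_network <- function(gbi, index = c("sri", "hwi"),
                          period_mode = c("union", "rows")) {
  association_index(tally_dyads(gbi, period_mode), index)
}

#' Directed interaction-rate network from an interaction log
#'
#' Converts a log of directed interactions (e.g. grooming bouts) into a
#' directed network of rates, dividing each actor's summed counts or durations
#' by its observation effort, so that differing observation effort between
#' individuals does not masquerade as differing sociality.
#'
#' @param interactions Tibble with columns `actor`, `receiver`, and optionally
#'   `weight` (count or duration; default 1 per record), `period`, `location`.
#' @param exposure Named numeric vector of per-individual observation effort
#'   (e.g. hours observed). Every individual with outgoing records must have
#'   positive exposure.
#' @param ids Optional registry order; defaults to the union of actors,
#'   receivers and `names(exposure)` in first-seen order.
#' @return A directed `assoc_net` with `edge_kind = "rate"`.
#' @export
interaction_rate_network <- function(interactions, exposure, ids = NULL) {
  stopifnot(is.data.frame(interactions))
  if (nrow(interactions) > 0 &&
      !all(c("actor", "receiver") %in% names(interactions))) {
    abort("interactions must have 'actor' and 'receiver' columns")
  }
  if (is.null(ids)) {
    ids <- unique(c(as.character(interactions$actor),
                    as.character(interactions$receiver), names(exposure)))
  }
  if (nrow(interactions) > 0 && any(interactions$actor == interactions$receiver)) {
    abort("self-interactions (actor == receiver) are not allowed")
  }
  w <- if ("weight" %in% names(interactions)) as.numeric(interactions$weight)
       else rep(1, nrow(interactions))
  if (any(w < 0)) abort("interaction weights must be >= 0")
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(interactions) > 0) {
    idx <- cbind(match(as.character(interactions$actor), ids),
                 match(as.character(interactions$receiver), ids))
    if (anyNA(idx)) abort("interaction log names individuals missing from ids")
    for (r in seq_len(nrow(idx))) m[idx[r, 1], idx[r, 2]] <- m[idx[r, 1], idx[r, 2]] + w[r]
  }
  expo <- exposure[match(ids, names(exposure))]
  active <- rowSums(m) > 0
  if (any(active & (is.na(expo) | expo <= 0))) {
    abort(paste0("zero or missing exposure with non-zero interaction count for: ",
                 paste(ids[active & (is.na(expo) | expo <= 0)], collapse = ", ")))
  }
  expo[is.na(expo) | expo <= 0] <- 1   # inactive individuals: rate row is 0 anyway
  m <- m / expo
  new_network(m, ids, directed = TRUE, edge_kind = "rate")
}

#' Generalized affiliation indices
#'
#' Residuals of a regression of association on structural predictors (e.g.
#' spatial overlap, joint gregariousness), isolating active affiliation from
#' association explained by structure. Under the binomial family (default) the
#' joint count `x` out of denominator `d` for each sampled dyad is modelled by
#' logistic regression and deviance residuals are returned; under the gaussian
#' family the association indices themselves are modelled by ordinary least
#' squares.
#'
#' @param x A `dyad_tally` (required for the binomial family) or an
#'   `assoc_net` of precomputed indices (gaussian family only).
#' @param predictors Named list of symmetric N x N structural predictor
#'   matrices.
#' @param family `"binomial"` or `"gaussian"`.
#' @param index Index used for the gaussian response when `x` is a tally.
#' @return An `assoc_net` with `edge_kind = "residual"`; unsampled dyads carry
#'   0 and are masked.
#' @export
affiliation_index <- function(x, predictors, family = c("binomial", "gaussian"),
                              index = c("sri", "hwi")) {
  family <- match.arg(family)
  index <- match.arg(index)
  if (!length(predictors)) abort("at least one structural predictor is required")
  if (is.null(names(predictors)) || any(!nzchar(names(predictors)))) {
    names(predictors) <- paste0("pred", seq_along(predictors))
  }
  if (inherits(x, "dyad_tally")) {
    ids <- x$ids; n <- length(ids)
    sampled <- x$d > 0
  } else if (inherits(x, "assoc_net")) {
    if (family == "binomial") abort("binomial family requires a dyad_tally (x of d trials)")
    ids <- x$ids; n <- length(ids)
    sampled <- if (is.null(x$mask)) matrix(TRUE, n, n) else x$mask
  } else abort("x must be a dyad_tally or assoc_net")
  for (p in predictors) {
    if (!is.matrix(p) || !all(dim(p) == n)) abort("predictor matrices must be N x N")
    if (!isSymmetric(unname(p), tol = 1e-8)) abort("predictor matrices must be symmetric for undirected data")
  }
  ut <- upper.tri(matrix(0, n, n)) & sampled
  X <- vapply(predictors, function(p) p[ut], numeric(sum(ut)))
  X <- matrix(X, ncol = length(predictors),
              dimnames = list(NULL, names(predictors)))
  # constant predictors are absorbed by the intercept (regression on the
  # intercept alone centres the response)
  constant <- apply(X, 2, function(v) stats::var(v) == 0)
  X <- cbind(`(Intercept)` = 1, X[, !constant, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    abort(paste0("collinear structural predictors: ", paste(bad, collapse = ", ")))
  }
  if (family == "binomial") {
    xs <- x$x[ut]; ds <- x$d[ut]
    dat <- as.data.frame(X[, -1, drop = FALSE])
    form <- if (ncol(dat)) cbind(xs, ds - xs) ~ . else cbind(xs, ds - xs) ~ 1
    fit <- stats::glm(form, data = dat, family = stats::binomial())
    res <- stats::residuals(fit, type = "deviance")
  } else {
    y <- if (inherits(x, "dyad_tally")) {
      net <- association_index(x, index); net$weights[ut]
    } else x$weights[ut]
    fit <- lm.fit(X, y)
    res <- fit$residuals
  }
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  w[ut] <- res
  w <- w + t(w)
  new_network(w, ids, directed = FALSE, edge_kind = "residual", mask = sampled)
}

# --- internal fast path for permutation loops -------------------------------
#
# Under group swaps constrained by sampling period, which periods an individual
# is identified in never change, so for the union sampling unit both index
# denominators are invariant across replicates:
#   SRI denominator = periods where at least one of the pair was identified,
#   HWI denominator = (periods_A + periods_B) / 2.
# Only the joint-count matrix x must be recomputed. The cache below stores the
# invariant pieces; index_matrix_fast() then costs one crossprod per replicate.

tally_cache <- function(gbi, period_mode = "union") {
  g <- gbi$matrix
  n <- ncol(g)
  if (period_mode == "rows") {
    ca <- colSums(g)
    cam <- matrix(ca, n, n)
    cache <- list(mode = "rows", ca_sum = cam + t(cam), max_mult = 1L)
  } else {
    per <- factor(gbi$meta$period, levels = unique(gbi$meta$period))
    counts <- rowsum(g, per)
    identified <- (counts > 0) + 0L
    ca <- colSums(identified)
    cab <- crossprod(identified)
    cam <- matrix(ca, n, n)
    cache <- list(mode = "union", per = per,
                  sri_den = cam + t(cam) - cab,
                  hwi_den = (cam + t(cam)) / 2,
                  mask = (cam + t(cam) - cab) > 0,
                  max_mult = max(counts))
  }
  cache$ids <- gbi$ids
  cache
}

index_matrix_fast <- function(gmat, cache, index = "sri") {
  n <- ncol(gmat)
  if (cache$mode == "union" && cache$max_mult > 1L) {
    x <- matrix(0, n, n)
    for (p in levels(cache$per)) {
      gp <- gmat[cache$per == p, , drop = FALSE]
      x <- x + ((crossprod(gp) > 0) + 0)
    }
  } else {
    x <- crossprod(gmat)
  }
  if (cache$mode == "rows") {
    den <- if (index == "sri") cache$ca_sum - x else cache$ca_sum / 2
  } else {
    den <- if (index == "sri") cache$sri_den else cache$hwi_den
  }
  w <- ifelse(den > 0, x / den, 0)
  diag(w) <- 0
  w
}
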