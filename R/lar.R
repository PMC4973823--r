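# Lagged association rate: the probability that a dyad associated at one
# sampling time is associated again a lag tau later, conditional on both
# members being identified at the later time. Describes the temporal stability
# of relationships and helps choose a sampling period over which samples can be
# treated as independent.

#' Lagged association rate
#'
#' For every ordered pair of sampling times (t, t + tau) the estimator pools,
#' over dyads, the count of pairs together at both times over the count of
#' pairs together at t with both members identified at t + tau; lags are
#' aggregated into bins. The expected rate under random re-grouping,
#' `(mean group size - 1) / (N - 1)`, is attached as the `null_rate`.
#'
#' @param gbi A `gbi` object. Sampling times are taken from `meta$time` when
#'   present, otherwise periods are spaced one time unit apart in order of
#'   first appearance.
#' @param bins Numeric vector of bin breakpoints for the lags; defaults to
#'   `n_bins` log-spaced bins spanning the observed lags.
#' @param n_bins Number of default bins.
#' @param period_mode `"union"` (dyads compared between sampling periods) or
#'   `"rows"` (between group records).
#' @return A tibble of class `lar_curve` with columns `lag` (bin midpoint in
#'   time units), `rate`, `n_pairs` (numerator opportunities per bin, i.e.
#'   together-at-t pairs re-identified); bins with no data are dropped.
#'   Attributes: `null_rate`, `n_individuals`. Method: [autoplot()].
#' @export
lagged_association_rate <- function(gbi, bins = NULL, n_bins = 8,
                                    period_mode = c("union", "rows")) {
  stopifnot(inherits(gbi, "gbi"))
  period_mode <- match.arg(period_mode)
  g <- gbi$matrix
  n <- ncol(g)
  if (period_mode == "union") {
    per <- factor(gbi$meta$period, levels = unique(gbi$meta$period))
    if (nlevels(per) < 2) abort("need at least 2 distinct sampling periods")
    tm <- tapply(gbi$meta$time, per, function(x) x[1])
    tm <- as.numeric(tm)
    if (anyNA(tm)) tm <- seq_len(nlevels(per))
    counts <- rowsum(g, per)
    identified <- counts > 0
    max_mult <- max(counts)
    together <- lapply(levels(per), function(p) {
      gp <- g[per == p, , drop = FALSE]
      crossprod(gp) > 0
    })
    ident <- lapply(seq_len(nlevels(per)), function(i) identified[i, ])
  } else {
    if (nrow(g) < 2) abort("need at least 2 group records")
    tm <- gbi$meta$time
    if (anyNA(tm)) tm <- seq_len(nrow(g))
    together <- lapply(seq_len(nrow(g)), function(i) tcrossprod(g[i, ]) > 0)
    ident <- lapply(seq_len(nrow(g)), function(i) g[i, ] > 0)
  }
  K <- length(together)
  ut <- upper.tri(matrix(0, n, n))
  pair_idx <- utils::combn(K, 2)
  lags <- abs(tm[pair_idx[2, ]] - tm[pair_idx[1, ]])
  keep <- lags > 0
  pair_idx <- pair_idx[, keep, drop = FALSE]
  lags <- lags[keep]
  if (!length(lags)) abort("all sampling times coincide; no positive lags")
  if (is.null(bins)) {
    lo <- min(lags); hi <- max(lags)
    if (lo == hi) {
      bins <- c(lo * 0.999, hi * 1.001)
    } else {
      bins <- unique(exp(seq(log(lo * 0.999), log(hi * 1.001),
                             length.out = n_bins + 1)))
    }
  }
  bin <- cut(lags, bins, include.lowest = TRUE)
  num <- den <- numeric(nlevels(bin))
  for (q in seq_along(lags)) {
    b <- as.integer(bin[q])
    if (is.na(b)) next
    t1 <- pair_idx[1, q]; t2 <- pair_idx[2, q]
    tog1 <- together[[t1]][ut]
    both2 <- (outer(ident[[t2]], ident[[t2]], "&"))[ut]
    den[b] <- den[b] + sum(tog1 & both2)
    num[b] <- num[b] + sum(tog1 & together[[t2]][ut])
  }
  mids <- (head(bins, -1) + bins[-1]) / 2
  ok <- den > 0
  mean_gs <- mean(rowSums(gbi$matrix))
  out <- tibble(lag = mids[ok], rate = num[ok] / den[ok], n_pairs = den[ok])
  attr(out, "null_rate") <- (mean_gs - 1) / (n - 1)
  attr(out, "n_individuals") <- n
  class(out) <- c("lar_curve", class(out))
  out
}

#' @export
print.lar_curve <- function(x, ...) {
  cat("Lagged association rate (", attr(x, "n_individuals"), " individuals); ",
      "null rate under random grouping = ",
      signif(attr(x, "null_rate"), 4), "\n", sep = "")
  NextMethod()
}
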