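# Precision and repeatability of node metrics: bootstrap over sampling units
# and split-half rank correlation. Both treat the sampling period (or group
# record) as the resampling unit, since observations within a unit are not
# independent.

metric_fun <- function(metric) {
  switch(metric,
         strength = node_strength, degree = node_degree,
         betweenness = node_betweenness,
         eigenvector = function(net) suppressWarnings(node_eigenvector(net)),
         pagerank = node_pagerank, reach = node_reach,
         abort(paste0("unknown metric: ", metric)))
}

#' Bootstrap confidence intervals for a node metric
#'
#' Resamples sampling periods with replacement, rebuilds the association
#' network and recomputes the metric, returning percentile intervals per
#' individual. Resamples on which the metric is undefined are redrawn and
#' counted.
#'
#' @param gbi A `gbi` object.
#' @param metric Node metric name (see [node_metrics()]).
#' @param index `"sri"` or `"hwi"`.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param level Interval coverage level.
#' @param period_mode Sampling-unit convention; `"union"` resamples periods,
#'   `"rows"` resamples group records.
#' @param seed Optional integer seed.
#' @return Tibble with columns `id`, `estimate`, `lower`, `upper`; attribute
#'   `n_redrawn` counts redrawn resamples.
#' @export
bootstrap_metric_ci <- function(gbi, metric = "strength",
                                index = c("sri", "hwi"), n_boot = 500,
                                level = 0.95,
                                period_mode = c("union", "rows"),
                                seed = NULL) {
  stopifnot(inherits(gbi, "gbi"), n_boot >= 100, level > 0, level < 1)
  index <- match.arg(index)
  period_mode <- match.arg(period_mode)
  fun <- metric_fun(metric)
  seed <- resolve_seed(seed)
  est <- fun(assoc_network(gbi, index, period_mode))
  per <- factor(gbi$meta$period, levels = unique(gbi$meta$period))
  units <- if (period_mode == "union") levels(per) else seq_len(nrow(gbi$matrix))
  boot <- matrix(NA_real_, n_boot, length(gbi$ids))
  redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      take <- sample(units, replace = TRUE)
      rows <- if (period_mode == "union") {
        unlist(lapply(seq_along(take), function(k) which(per == take[k])))
      } else take
      # resampled periods must stay distinct sampling units
      meta_b <- gbi$meta[rows, ]
      if (period_mode == "union") {
        reps <- unlist(lapply(seq_along(take), function(k) rep(k, sum(per == take[k]))))
        meta_b$period <- paste0(meta_b$period, "#", reps)
      }
      gb <- new_gbi(gbi$matrix[rows, , drop = FALSE], gbi$ids, meta_b)
      v <- tryCatch(fun(assoc_network(gb, index, period_mode)),
                    error = function(e) NULL)
      if (!is.null(v)) { boot[b, ] <- v; break }
      redrawn <- redrawn + 1L
      if (redrawn > 10 * n_boot) abort("metric undefined on almost every resample")
    }
  }
  alpha <- (1 - level) / 2
  out <- tibble(
    id = gbi$ids,
    estimate = unname(est),
    lower = apply(boot, 2, quantile, probs = alpha),
    upper = apply(boot, 2, quantile, probs = 1 - alpha)
  )
  attr(out, "n_redrawn") <- redrawn
  out
}

#' Split-half repeatability of a node metric
#'
#' Partitions the sampling periods into two disjoint halves, builds a network
#' from each, and returns the Spearman rank correlation of the node metric
#' between halves. High repeatability indicates stable individual network
#' positions; data sampled from independent random re-grouping give
#' correlations near zero.
#'
#' @param gbi A `gbi` object with at least 4 sampling periods.
#' @param metric Node metric name.
#' @param index `"sri"` or `"hwi"`.
#' @param split `"odd_even"` (periods alternate) or `"first_second"` halves.
#' @return One-row tibble with `split`, `rho`, `n_periods`.
#' @export
split_half_repeatability <- function(gbi, metric = "strength",
                                     index = c("sri", "hwi"),
                                     split = c("odd_even", "first_second")) {
  stopifnot(inherits(gbi, "gbi"))
  index <- match.arg(index)
  split <- match.arg(split)
  fun <- metric_fun(metric)
  per <- factor(gbi$meta$period, levels = unique(gbi$meta$period))
  np <- nlevels(per)
  if (np < 4) abort("need at least 4 sampling periods to split")
  sel <- if (split == "odd_even") {
    as.integer(per) %% 2 == 1
  } else {
    as.integer(per) <= np %/% 2
  }
  halves <- lapply(list(sel, !sel), function(s) {
    m <- gbi$matrix[s, , drop = FALSE]
    new_gbi(m, gbi$ids, gbi$meta[s, ])
  })
  v <- lapply(halves, function(h) fun(assoc_network(h, index)))
  if (sd(v[[1]]) == 0 || sd(v[[2]]) == 0) {
    abort("metric constant within a half; repeatability undefined")
  }
  tibble(split = split, rho = cor(rank(v[[1]]), rank(v[[2]])), n_periods = np)
}
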