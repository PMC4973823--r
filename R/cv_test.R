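# Test for preferred and avoided associations: if relationships are
# differentiated, the spread of association indices is larger than expected
# when individuals associate at random given the constraints. The test
# statistic is the coefficient of variation of the indices, which doubles as
# an interpretable effect size (observed CV vs mean randomized CV).

#' Coefficient of variation of association indices
#'
#' CV = sd / mean over the off-diagonal dyad values (upper triangle for
#' undirected networks). Dyads whose index is undefined (never-sampled pairs,
#' flagged in the network's mask) may be included as zeros or excluded; the
#' choice changes the CV, so it is explicit.
#'
#' @param net An `assoc_net`.
#' @param include_unsampled Include never-sampled dyads as zeros (default) or
#'   drop them?
#' @return A single number.
#' @export
network_cv <- function(net, include_unsampled = TRUE) {
  m <- net$weights
  keep <- if (net$directed) row(m) != col(m) else upper.tri(m)
  if (!include_unsampled && !is.null(net$mask)) keep <- keep & net$mask
  vals <- m[keep]
  if (length(vals) < 2) abort("need at least 2 dyads with defined indices")
  mu <- mean(vals)
  if (mu == 0) abort("mean association index is 0; CV undefined")
  # population standard deviation: the CV of the realized set of dyad values
  sqrt(mean((vals - mu)^2)) / mu
}

#' Permutation test for preferred/avoided associations
#'
#' Compares the CV of the observed association-index network with its
#' distribution over constrained data-stream (group-swap) randomizations of the
#' GBI. The p-value is the proportion of randomized networks whose CV is at
#' least the observed CV, so a small p indicates more differentiated
#' relationships than expected at random given the constraints.
#'
#' @param gbi A `gbi` object.
#' @param index `"sri"` or `"hwi"`.
#' @param n_perm Number of permuted networks (1000 or more recommended).
#' @param constraints Strata for the group swaps; see
#'   [permute_datastream_groups()].
#' @param period_mode Sampling-unit convention; see [tally_dyads()].
#' @param include_unsampled Passed to [network_cv()].
#' @param swaps_per_step,burn_in,seed Chain controls; see
#'   [permute_datastream_groups()].
#' @param conservative Use the (1 + k) / (1 + n) p-value variant?
#' @return A `perm_test` object: observed statistic, null vector, `p_value`,
#'   and the effect-size pair (observed CV, mean null CV). Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @export
preferred_association_test <- function(gbi, index = c("sri", "hwi"),
                                       n_perm = 1000, constraints = "period",
                                       period_mode = c("union", "rows"),
                                       include_unsampled = TRUE,
                                       swaps_per_step = 1, burn_in = 1000,
                                       seed = NULL, conservative = FALSE) {
  index <- match.arg(index)
  period_mode <- match.arg(period_mode)
  observed <- network_cv(assoc_network(gbi, index, period_mode), include_unsampled)
  stream <- permute_datastream_groups(gbi, n_perm, constraints,
                                      swaps_per_step, burn_in, seed)
  # when swaps cannot move an individual across sampling units, the index
  # denominators are invariant and only the joint counts need recomputation
  fast <- (period_mode == "rows" && include_unsampled) ||
    (period_mode == "union" && "period" %in% constraints)
  if (fast) {
    cache <- tally_cache(gbi, period_mode)
    keep <- upper.tri(matrix(0, length(gbi$ids), length(gbi$ids)))
    if (!include_unsampled) keep <- keep & cache$mask
    nulls <- null_distribution(stream, function(g) {
      v <- index_matrix_fast(g$matrix, cache, index)[keep]
      mu <- mean(v)
      sqrt(mean((v - mu)^2)) / mu
    })
  } else {
    nulls <- null_distribution(stream, function(g) {
      network_cv(assoc_network(g, index, period_mode), include_unsampled)
    })
  }
  p <- perm_pvalue(observed, nulls, "upper", conservative)
  new_perm_test(
    statistic = paste0("cv(", index, ")"),
    observed = observed, null_values = nulls, p_value = p,
    effect = c(observed_cv = observed, mean_null_cv = mean(nulls)),
    tail = "upper",
    config = list(index = index, n_perm = n_perm, constraints = constraints,
                  swaps_per_step = swaps_per_step, burn_in = burn_in,
                  seed = stream$seed)
  )
}

new_perm_test <- function(statistic, observed, null_values, p_value, effect,
                          tail, config) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = statistic, observed = observed,
                 null_values = null_values, p_value = p_value,
                 effect = effect, tail = tail,
                 n_perm = length(null_values), config = config),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test: ", x$statistic, "\n", sep = "")
  cat("  observed = ", signif(x$observed, 5),
      ", null mean = ", signif(mean(x$null_values), 5),
      " (", x$n_perm, " permutations)\n", sep = "")
  cat("  P[", x$tail, "] = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}
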