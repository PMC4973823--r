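# broom-style tidiers for the test objects.

#' Tidy a permutation test
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `observed`, `null_mean`, `null_sd`,
#'   `p_value`, `n_perm`, `tail`.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         null_mean = mean(x$null_values), null_sd = sd(x$null_values),
         p_value = x$p_value, n_perm = x$n_perm, tail = x$tail)
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) tidy.perm_test(x, ...)

#' Tidy a permutation-corrected coefficient test
#'
#' @param x A `coef_perm_test`.
#' @param ... Unused.
#' @return Tibble of model terms (`term`, `estimate`, `std.error`,
#'   `statistic`) with the permutation p-value (`p_rand`) attached to the
#'   focal term.
#' @export
tidy.coef_perm_test <- function(x, ...) {
  out <- x$fit
  out$p_rand <- ifelse(out$term == x$focal, x$p_value, NA_real_)
  out
}

#' @rdname tidy.coef_perm_test
#' @return `glance()`: one-row tibble with the focal coefficient, its naive
#'   t-statistic, the permutation p-value, null mean and permutation count.
#' @export
glance.coef_perm_test <- function(x, ...) {
  naive_t <- x$fit$statistic[x$fit$term == x$focal]
  tibble(focal = x$focal, estimate = x$observed, statistic = naive_t,
         null_mean = mean(x$null_values), p_rand = x$p_value,
         n_perm = x$n_perm, metric = x$metric, kind = x$config$kind)
}

#' Tidy an MRQAP fit
#'
#' @param x An `mrqap` object.
#' @param ... Unused.
#' @return The per-predictor tibble: `term`, `coefficient`, `t`, `partial_r`,
#'   `p_value`.
#' @export
tidy.mrqap <- function(x, ...) x$terms

#' @rdname tidy.mrqap
#' @export
glance.mrqap <- function(x, ...) {
  tibble(n = x$n, n_perm = x$n_perm, tail = x$tail,
         n_predictors = nrow(x$terms))
}

#' Tidy a community partition
#'
#' @param x A `net_communities` object.
#' @param ... Unused.
#' @return The membership tibble (`id`, `community`).
#' @export
tidy.net_communities <- function(x, ...) x$membership

#' @rdname tidy.net_communities
#' @export
glance.net_communities <- function(x, ...) {
  tibble(n_communities = x$n_communities, modularity = x$modularity)
}
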