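# ggplot2 views of test results: the convention throughout is a histogram of
# the permutation null with the observed statistic as a vertical line.

perm_hist <- function(null_values, observed, xlab) {
  df <- tibble(value = null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = observed, colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = xlab, y = "permutations") +
    ggplot2::theme_minimal()
}

#' Plot a permutation test
#'
#' Histogram of the null distribution with the observed statistic in red.
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_test <- function(object, ...) {
  perm_hist(object$null_values, object$observed, object$statistic) +
    ggplot2::ggtitle(paste0("P[", object$tail, "] = ",
                            format.pval(object$p_value, digits = 3)))
}

#' Plot a permutation-corrected coefficient test
#'
#' Histogram of the randomized focal coefficients with the observed coefficient
#' in red.
#'
#' @param object A `coef_perm_test`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coef_perm_test <- function(object, ...) {
  perm_hist(object$null_values, object$observed,
            paste0("coefficient: ", object$focal)) +
    ggplot2::ggtitle(paste0("P_rand[", object$tail, "] = ",
                            format.pval(object$p_value, digits = 3)))
}

#' Plot a lagged association rate curve
#'
#' Rate against lag (log-scaled lag axis) with the expected rate under random
#' re-grouping as a dashed line.
#'
#' @param object A `lar_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lar_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lag, y = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "null_rate"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag (time units)", y = "lagged association rate") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
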