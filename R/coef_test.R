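# Permutation-corrected coefficients for (mixed) linear models of node
# metrics. Node metrics are non-independent, so the model's own t-statistics
# cannot be trusted; instead the focal coefficient is re-estimated on each
# randomized dataset — for data-stream permutations the network and the metric
# are recomputed from every permuted GBI — and the observed coefficient is
# located within that null distribution.

#' Permutation-corrected coefficient test for a node-metric model
#'
#' Fits `metric ~ fixed terms (+ (1 | group))` to the observed network's node
#' metric, then recomputes the focal coefficient over randomized datasets. With
#' `kind = "datastream"` each replicate swaps observations within the GBI
#' (constrained by stratum), rebuilds the association network, recomputes the
#' metric and refits the model — so the null respects each individual's number
#' of sightings and the sampling structure. With `kind = "node"` the attribute
#' rows are permuted across individuals and the network stays fixed.
#'
#' The observed model is fitted with [lme4::lmer()] when a random intercept is
#' present (full coefficient/SE/t table and variance components are reported);
#' permutation refits use an internal profiled-REML solver for the same model.
#'
#' @param gbi A `gbi` object.
#' @param attributes Tibble with an `id` column and the model's covariates.
#' @param formula Model formula; the left-hand side names a node metric
#'   (`strength`, `degree`, `eigenvector`, `pagerank`, `betweenness`, `reach`),
#'   the right-hand side contains fixed terms and at most one random intercept
#'   `(1 | group)`.
#' @param index Association index for network construction.
#' @param focal Name of the focal model-matrix coefficient; defaults to the
#'   first non-intercept column.
#' @param n_perm Number of permutations.
#' @param kind `"datastream"` (group swaps, recommended) or `"node"`.
#' @param constraints Strata for data-stream swaps, e.g. `c("period",
#'   "location")` to control for time and space.
#' @param tail `"upper"`, `"lower"` or `"two_sided"`.
#' @param period_mode Sampling-unit convention; see [tally_dyads()].
#' @param swaps_per_step,burn_in,seed Chain controls.
#' @param conservative Use the (1 + k)/(1 + n) p-value variant?
#' @return A `coef_perm_test`: the fitted model table (`fit`), random-effect
#'   variances, focal coefficient, null coefficient vector and permutation
#'   p-value. Methods: [tidy()], [glance()], [autoplot()].
#' @export
coefficient_permutation_test <- function(gbi, attributes,
                                         formula = strength ~ sex + (1 | area),
                                         index = c("sri", "hwi"), focal = NULL,
                                         n_perm = 1000,
                                         kind = c("datastream", "node"),
                                         constraints = c("period", "location"),
                                         tail = c("upper", "lower", "two_sided"),
                                         period_mode = c("union", "rows"),
                                         swaps_per_step = 1, burn_in = 1000,
                                         seed = NULL, conservative = FALSE) {
  stopifnot(inherits(gbi, "gbi"))
  index <- match.arg(index)
  kind <- match.arg(kind)
  tail <- match.arg(tail)
  period_mode <- match.arg(period_mode)

  metric_name <- all.vars(formula[[2]])
  if (length(metric_name) != 1 || !metric_name %in% metric_names) {
    abort(paste0("the formula's left-hand side must be one node metric (",
                 paste(metric_names, collapse = ", "), ")"))
  }
  bars <- lme4::findbars(formula)
  if (length(bars) > 1) abort("at most one random intercept term is supported")
  group_var <- if (length(bars)) deparse(bars[[1]][[3]]) else NULL
  if (length(bars) && deparse(bars[[1]][[2]]) != "1") {
    abort("only random intercepts, (1 | group), are supported")
  }
  fixed_rhs <- lme4::nobars(formula[[3]])
  fixed_formula <- stats::as.formula(paste(".metric ~", deparse(fixed_rhs)))
  fixed_only <- stats::as.formula(paste("~", deparse(fixed_rhs)))

  attrs <- align_attributes(attributes, gbi$ids)

  compute_metric <- function(g) {
    net <- assoc_network(g, index, period_mode)
    switch(metric_name,
           strength = node_strength(net), degree = node_degree(net),
           betweenness = node_betweenness(net),
           eigenvector = suppressWarnings(node_eigenvector(net)),
           pagerank = node_pagerank(net), reach = node_reach(net))
  }

  observed_metric <- compute_metric(gbi)
  dat <- attrs
  dat$.metric <- unname(observed_metric)

  X <- model.matrix(fixed_only, data = dat)
  if (qr(X)$rank < ncol(X)) abort("rank-deficient fixed-effect design")
  if (is.null(focal)) {
    focal <- setdiff(colnames(X), "(Intercept)")[1]
    if (is.na(focal)) abort("no non-intercept fixed term to test")
  }
  if (!focal %in% colnames(X)) {
    abort(paste0("focal coefficient '", focal, "' not in model matrix (",
                 paste(colnames(X), collapse = ", "), ")"))
  }

  # observed fit: lme4 when a random intercept is present, otherwise lm
  if (!is.null(group_var)) {
    if (!group_var %in% names(dat)) abort(paste0("no such grouping column: ", group_var))
    lform <- stats::as.formula(paste(".metric ~", deparse(fixed_rhs),
                                     "+ (1 |", group_var, ")"))
    mfit <- suppressMessages(lme4::lmer(
      lform, data = dat, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))
    ct <- lme4::fixef(mfit)
    se <- sqrt(diag(as.matrix(stats::vcov(mfit))))
    vc <- as.data.frame(lme4::VarCorr(mfit))
    ranef_var <- setNames(vc$vcov, vc$grp)
    observed_coef <- unname(ct[focal])
    fit_tbl <- tibble(term = names(ct), estimate = unname(ct),
                      std.error = unname(se), statistic = unname(ct / se))
  } else {
    mfit <- lm(fixed_formula, data = dat)
    sm <- summary(mfit)$coefficients
    ranef_var <- c(Residual = summary(mfit)$sigma^2)
    observed_coef <- unname(coef(mfit)[focal])
    fit_tbl <- tibble(term = rownames(sm), estimate = sm[, 1],
                      std.error = sm[, 2], statistic = sm[, 3])
  }

  # null coefficients
  dropped <- 0L
  if (kind == "datastream") {
    stream <- permute_datastream_groups(gbi, n_perm, constraints,
                                        swaps_per_step, burn_in, seed)
    prep <- if (!is.null(group_var)) fast_lmm_prepare(X, dat[[group_var]]) else NULL
    fi <- match(focal, colnames(X))
    # fast metric recomputation: index denominators are invariant under swaps
    # that cannot move an individual across sampling units
    fast <- metric_name %in% c("strength", "degree") &&
      (period_mode == "rows" || "period" %in% constraints)
    cache <- if (fast) tally_cache(gbi, period_mode)
    metric_null <- if (fast) {
      function(g) {
        w <- index_matrix_fast(g$matrix, cache, index)
        if (metric_name == "strength") rowSums(w) else rowSums(w > 0)
      }
    } else function(g) unname(compute_metric(g))
    nulls <- null_distribution(stream, function(g) {
      y <- metric_null(g)
      if (!is.null(prep)) {
        f <- tryCatch(fast_lmm_fit(prep, y), error = function(e) NULL)
        if (is.null(f)) { dropped <<- dropped + 1L; return(NA_real_) }
        f$beta[fi]
      } else {
        unname(lm.fit(X, y)$coefficients[fi])
      }
    })
  } else {
    stream <- permute_node_labels(attrs, NULL, n_perm, seed)
    y <- unname(observed_metric)
    fi_name <- focal
    nulls <- null_distribution(stream, function(a) {
      d2 <- a
      d2$.metric <- y
      Xp <- model.matrix(fixed_only, data = d2)
      if (!is.null(group_var)) {
        f <- tryCatch(fast_lmm_fit(fast_lmm_prepare(Xp, d2[[group_var]]), y),
                      error = function(e) NULL)
        if (is.null(f)) { dropped <<- dropped + 1L; return(NA_real_) }
        unname(f$beta[fi_name])
      } else {
        unname(lm.fit(Xp, y)$coefficients[fi_name])
      }
    })
  }
  nulls_ok <- nulls[!is.na(nulls)]
  if (dropped > 0) {
    inform(paste0(dropped, " replicate(s) dropped due to non-convergent fits"))
  }
  p <- perm_pvalue(observed_coef, nulls_ok, tail, conservative)
  structure(list(
    formula = formula, metric = metric_name, focal = focal,
    fit = fit_tbl, ranef_variance = ranef_var, model = mfit,
    observed = observed_coef, null_values = nulls_ok,
    p_value = p, tail = tail, n_perm = length(nulls_ok), dropped = dropped,
    config = list(index = index, kind = kind, constraints = constraints,
                  n_perm = n_perm, swaps_per_step = swaps_per_step,
                  burn_in = burn_in, seed = stream$seed)
  ), class = "coef_perm_test")
}

#' @export
print.coef_perm_test <- function(x, ...) {
  cat("Permutation-corrected coefficient test (", x$config$kind,
      " permutations)\n", sep = "")
  cat("  model: ", deparse(x$formula), "  [index: ", x$config$index, "]\n", sep = "")
  print(as.data.frame(x$fit), row.names = FALSE, digits = 4)
  if (length(x$ranef_variance)) {
    cat("  variance components: ",
        paste(names(x$ranef_variance), signif(x$ranef_variance, 4),
              sep = " = ", collapse = ", "), "\n", sep = "")
  }
  cat("  focal '", x$focal, "': observed = ", signif(x$observed, 5),
      ", null mean = ", signif(mean(x$null_values), 5),
      ", P[", x$tail, "] = ", format.pval(x$p_value, digits = 3),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}
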