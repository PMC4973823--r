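# Sampling-effort power analysis. Two quantities govern how well an observed
# association network mirrors the true one: the social differentiation S (the
# coefficient of variation of the true association indices across dyads) and
# the sampling effort H (the mean number of joint identifications per dyad,
# i.e. the expected number of sampling units in which a dyad is recorded
# together). Their product governs precision: the correlation between true and
# estimated edges is approximately
#     r = sqrt(S^2 H / (1 + S^2 H)),
# so the effort needed to reach a target correlation is
#     H = r^2 / (S^2 (1 - r^2)).
# A moderately differentiated population (S ~ 0.2) needs H ~ 44 ("about 50")
# for r = 0.8; S ~ 0.6 needs H ~ 5; an extremely differentiated one (S ~ 10)
# needs H ~ 0.02 — a single joint sighting is already informative.

#' Simulate a matrix of true dyadic association probabilities
#'
#' Draws gamma-distributed association probabilities with a given mean and
#' coefficient of variation (the social differentiation S), symmetric with a
#' zero diagonal. Values exceeding 1 are clipped; the expected clipped mass
#' must be small.
#'
#' @param n Number of individuals (>= 3).
#' @param S Coefficient of variation of the true indices (> 0).
#' @param mean_p Mean association probability, in (0, 1).
#' @param seed Optional integer seed.
#' @return An n x n symmetric matrix with attribute `clip_rate` (fraction of
#'   dyads clipped at 1).
#' @export
simulate_true_association_network <- function(n, S, mean_p = 0.05, seed = NULL) {
  stopifnot(n >= 3, S > 0, mean_p > 0, mean_p < 1)
  shape <- 1 / S^2
  scale <- mean_p * S^2
  expected_clip <- pgamma(1, shape, scale = scale, lower.tail = FALSE)
  if (expected_clip > 0.05) {
    abort(paste0("mean_p and S imply heavy clipping at 1 (expected fraction ",
                 signif(expected_clip, 3), "); use a smaller mean_p"))
  }
  if (!is.null(seed)) set.seed(seed)
  nd <- n * (n - 1) / 2
  p <- rgamma(nd, shape = shape, scale = scale)
  clip <- p > 1
  p[clip] <- 1
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- p
  m <- m + t(m)
  attr(m, "clip_rate") <- mean(clip)
  m
}

#' Closed-form correlation between true and observed networks
#'
#' `sqrt(S^2 H / (1 + S^2 H))`: the expected Pearson correlation between true
#' and estimated association indices for social differentiation `S` and mean
#' joint identifications per dyad `H`.
#'
#' @param S Social differentiation (> 0).
#' @param H Mean joint identifications per dyad (>= 0).
#' @return Correlation in \[0, 1\].
#' @export
expected_sampling_correlation <- function(S, H) {
  stopifnot(S > 0, H >= 0)
  sqrt(S^2 * H / (1 + S^2 * H))
}

#' Correlation between true and observed networks, by simulation
#'
#' Simulates gamma-distributed true dyadic association probabilities with
#' differentiation `S`, samples each dyad over a Poisson number of sampling
#' units with expectation `H / mean_p` (so joint identifications per dyad
#' average `H`), estimates the indices by the simple ratio, and returns the
#' mean Pearson correlation between true and estimated edges over replicates.
#'
#' @param S Social differentiation (> 0).
#' @param H Mean joint identifications per dyad (> 0).
#' @param n_individuals Number of individuals per replicate.
#' @param mean_p Mean true association probability.
#' @param n_replicates Number of simulation replicates.
#' @param seed Optional integer seed.
#' @return One-row tibble of class `power_estimate`: `S`, `H`, `r` (mean
#'   correlation), `n_replicates`, `n_dyads`.
#' @export
sampling_correlation <- function(S, H, n_individuals = 30, mean_p = 0.05,
                                 n_replicates = 200, seed = NULL) {
  stopifnot(S > 0, H > 0, n_individuals >= 5, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  shape <- 1 / S^2
  scale <- mean_p * S^2
  if (pgamma(1, shape, scale = scale, lower.tail = FALSE) > 0.05) {
    abort("mean_p and S imply heavy clipping at 1; use a smaller mean_p")
  }
  nd <- n_individuals * (n_individuals - 1) / 2
  d_mean <- H / mean_p
  rs <- numeric(n_replicates)
  used <- 0L
  for (b in seq_len(n_replicates)) {
    p <- pmin(rgamma(nd, shape = shape, scale = scale), 1)
    d <- rpois(nd, d_mean)
    ok <- d > 0
    if (sum(ok) < 3) next
    x <- rbinom(sum(ok), d[ok], p[ok])
    est <- x / d[ok]
    if (sd(est) == 0 || sd(p[ok]) == 0) next
    used <- used + 1L
    rs[used] <- cor(p[ok], est)
  }
  if (used == 0) abort("no replicate produced enough sampled dyads")
  structure(tibble(S = S, H = H, r = mean(rs[seq_len(used)]),
                   n_replicates = used, n_dyads = nd),
            class = c("power_estimate", "tbl_df", "tbl", "data.frame"))
}

#' Sampling effort required for a target network accuracy
#'
#' Inverts the calibrated relation between social differentiation and network
#' accuracy: `H = r^2 / (S^2 (1 - r^2))` joint identifications per dyad are
#' needed for the observed network to correlate at `r_target` with the true
#' one. Decreasing in `S`: highly differentiated societies need less data.
#'
#' @param S Social differentiation (> 0).
#' @param r_target Target correlation, in (0, 1).
#' @return Required mean joint identifications per dyad (a number).
#' @export
required_sampling_effort <- function(S, r_target = 0.8) {
  stopifnot(S > 0)
  if (!is.numeric(r_target) || r_target <= 0 || r_target >= 1) {
    abort("r_target must lie strictly between 0 and 1")
  }
  r_target^2 / (S^2 * (1 - r_target^2))
}
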