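# Synthetic populations for simulation studies: a two-area population in which
# each individual carries a Poisson-distributed gregariousness score, the
# probability of being male increases with gregariousness, and each sampling
# period realizes independent dyadic associations with probability
# proportional to the pair's combined gregariousness — never across areas.
# A detection layer thins observations by class (e.g. inconspicuous females
# seen with 70% reliability) to study how sampling bias distorts networks.

#' Specification of a synthetic two-area population
#'
#' @param n_individuals Total number of individuals (split evenly across areas).
#' @param n_areas Number of areas.
#' @param gregariousness_means Poisson mean gregariousness per area; later
#'   areas are typically slightly more gregarious.
#' @param sex_link Strength of the gregariousness-sex link in \[0, 1\]:
#'   `P(male) = sex_link * g / max(g) + (1 - sex_link) / 2`. At 1 the male
#'   probability is proportional to gregariousness; at 0 sex is random.
#' @param n_periods Number of sampling periods.
#' @param edge_prob_scale Per-period probability that a within-area dyad
#'   associates is `edge_prob_scale * (g_i + g_j)`, clipped to \[0, 1\]. The
#'   default gives a mean dyadic probability of about 0.1.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_individuals = 40, n_areas = 2,
                            gregariousness_means = c(2, 3), sex_link = 1,
                            n_periods = 100, edge_prob_scale = 0.02) {
  stopifnot(n_individuals >= 4, n_areas >= 1,
            length(gregariousness_means) == n_areas,
            all(gregariousness_means > 0),
            sex_link >= 0, sex_link <= 1,
            n_periods >= 2, edge_prob_scale > 0)
  structure(list(n_individuals = n_individuals, n_areas = n_areas,
                 gregariousness_means = gregariousness_means,
                 sex_link = sex_link, n_periods = n_periods,
                 edge_prob_scale = edge_prob_scale),
            class = "population_spec")
}

#' Simulate a synthetic population's dyadic association events
#'
#' Draws per-individual gregariousness (Poisson, area-specific mean), allocates
#' sex with probability increasing in gregariousness, and realizes independent
#' dyadic association events in every sampling period with probability
#' proportional to combined gregariousness; individuals in different areas
#' never associate. Clipped edge probabilities are counted and reported as an
#' attribute.
#'
#' @param spec A [population_spec()].
#' @param seed Optional integer seed.
#' @return A `sim_population`: list with `events` (tibble `period`, `id1`,
#'   `id2`), `attributes` (tibble `id`, `sex`, `area`, `gregariousness`),
#'   `presence` (periods x individuals logical matrix, all `TRUE` until
#'   [apply_detection_bias()]), and `spec`.
#' @export
simulate_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_individuals
  area <- sort(rep_len(seq_len(spec$n_areas), n))
  g <- rpois(n, spec$gregariousness_means[area])
  if (all(g == 0)) abort("all gregariousness scores are 0; nothing can associate")
  p_male <- spec$sex_link * g / max(g) + (1 - spec$sex_link) * 0.5
  sex <- ifelse(runif(n) < p_male, "M", "F")
  ids <- sprintf("ind%02d", seq_len(n))
  # within-area dyads and their per-period association probabilities
  ut <- which(upper.tri(matrix(0, n, n)) & outer(area, area, "=="), arr.ind = TRUE)
  pr <- spec$edge_prob_scale * (g[ut[, 1]] + g[ut[, 2]])
  clipped <- mean(pr > 1)
  pr <- pmin(pr, 1)
  P <- spec$n_periods
  hits <- matrix(runif(nrow(ut) * P), nrow(ut), P) < pr
  ev <- which(hits, arr.ind = TRUE)
  events <- tibble(period = ev[, 2],
                   id1 = ids[ut[ev[, 1], 1]],
                   id2 = ids[ut[ev[, 1], 2]])
  events <- events[order(events$period), ]
  attributes <- tibble(id = ids, sex = sex, area = paste0("a", area),
                       gregariousness = g)
  out <- structure(list(events = events, attributes = attributes,
                        presence = matrix(TRUE, P, n, dimnames = list(NULL, ids)),
                        spec = spec),
                   class = "sim_population")
  attr(out, "clip_rate") <- clipped
  if (clipped > 0) inform(paste0(signif(100 * clipped, 3),
                                 "% of dyadic probabilities clipped at 1"))
  out
}

#' @export
print.sim_population <- function(x, ...) {
  cat("<sim_population> ", nrow(x$attributes), " individuals, ",
      x$spec$n_periods, " periods, ", nrow(x$events), " association events\n",
      sep = "")
  invisible(x)
}

#' Thin observations by class-dependent detection probability
#'
#' Each individual is detected in each sampling period independently with the
#' probability of its class (e.g. `c(F = 0.7, M = 1)`); an undetected
#' individual disappears from that period entirely, taking its dyadic events
#' with it. Models conspicuousness bias in field observation.
#'
#' @param sim A `sim_population`.
#' @param detection Named numeric vector of per-class detection probabilities;
#'   names must cover every value of `class_column`.
#' @param class_column Attribute column holding the class (default `"sex"`).
#' @param seed Optional integer seed.
#' @return The `sim_population` with its `presence` matrix thinned.
#' @export
apply_detection_bias <- function(sim, detection = c(F = 0.7, M = 1),
                                 class_column = "sex", seed = NULL) {
  stopifnot(inherits(sim, "sim_population"))
  if (!is.null(seed)) set.seed(seed)
  cls <- as.character(sim$attributes[[class_column]])
  if (!all(cls %in% names(detection))) {
    abort(paste0("detection probabilities missing for class(es): ",
                 paste(setdiff(unique(cls), names(detection)), collapse = ", ")))
  }
  pr <- unname(detection[cls])
  if (any(pr < 0 | pr > 1)) abort("detection probabilities must lie in [0, 1]")
  P <- nrow(sim$presence)
  keep <- matrix(runif(P * length(cls)), P) < matrix(pr, P, length(cls), byrow = TRUE)
  sim$presence <- sim$presence & keep
  sim
}

# union-find connected components over n nodes given integer edge endpoints
components_from_edges <- function(n, e1, e2) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(e1)) {
    a <- find(e1[k]); b <- find(e2[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 0L)
}

#' Group-by-individual matrix of a simulated population
#'
#' Converts per-period dyadic events into observed groups by taking the
#' connected components of each period's association graph among the detected
#' individuals ("gambit of the group" in reverse); detected individuals with no
#' events form singleton groups. Rows carry the period and the group's area as
#' location, so data-stream permutations can control for both.
#'
#' @param sim A `sim_population` (optionally after [apply_detection_bias()]).
#' @return A `gbi` object.
#' @export
population_gbi <- function(sim) {
  stopifnot(inherits(sim, "sim_population"))
  ids <- sim$attributes$id
  n <- length(ids)
  area <- as.character(sim$attributes$area)
  P <- nrow(sim$presence)
  e1 <- match(sim$events$id1, ids)
  e2 <- match(sim$events$id2, ids)
  ev_by_period <- split(seq_along(e1), factor(sim$events$period, levels = seq_len(P)))
  ind_idx <- integer(0); row_key <- character(0)
  for (p in seq_len(P)) {
    present <- sim$presence[p, ]
    sel <- ev_by_period[[p]]
    sel <- sel[present[e1[sel]] & present[e2[sel]]]
    comp <- components_from_edges(n, e1[sel], e2[sel])
    who <- which(present)
    if (!length(who)) next
    ind_idx <- c(ind_idx, who)
    row_key <- c(row_key, paste0(p, ".", comp[who]))
  }
  if (!length(ind_idx)) abort("no individuals detected in any period")
  key <- factor(row_key, levels = unique(row_key))
  m <- matrix(0L, nlevels(key), n, dimnames = list(NULL, ids))
  m[cbind(as.integer(key), ind_idx)] <- 1L
  first <- match(levels(key), row_key)
  period <- sub("\\..*$", "", levels(key))
  new_gbi(m, ids, tibble(period = period,
                         time = as.numeric(period),
                         location = area[ind_idx[first]]))
}

#' Simulate a ready-made study scenario
#'
#' `"sex_effect"`: gregariousness-linked sex allocation (`sex_link = 1`), full
#' detection — males really are more social. `"detection_bias"`: sex allocated
#' at random (`sex_link = 0`) but females detected with probability 0.7 —
#' any sex difference in the observed network is a sampling artefact.
#'
#' @param scenario `"sex_effect"` or `"detection_bias"`.
#' @param spec Base [population_spec()]; its `sex_link` is overridden by the
#'   scenario.
#' @param detection Detection probabilities for the bias scenario.
#' @param seed Optional integer seed.
#' @return List with `gbi`, `attributes` and the underlying `population`.
#' @export
simulate_scenario <- function(scenario = c("sex_effect", "detection_bias"),
                              spec = population_spec(),
                              detection = c(F = 0.7, M = 1), seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  spec$sex_link <- if (scenario == "sex_effect") 1 else 0
  pop <- simulate_population(spec)
  if (scenario == "detection_bias") pop <- apply_detection_bias(pop, detection)
  list(gbi = population_gbi(pop), attributes = pop$attributes, population = pop)
}
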