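# Constrained randomizations. Node-label permutations shuffle attributes while
# the network stays fixed. Data-stream permutations sequentially swap
# observations inside the raw data: group swaps exchange two individuals
# between two groups within the same stratum via a 2x2 checkerboard
# [[1,0],[0,1]] -> [[0,1],[1,0]], conserving group sizes (row sums),
# per-individual sighting counts (column sums) and per-stratum totals exactly;
# dyadic swaps exchange receivers between two interaction records in the same
# stratum, conserving per-individual out- and in-counts. Successive replicates
# of a sequential chain are serially correlated; `swaps_per_step` thins the
# chain and `burn_in` moves it away from the observed data before sampling.

new_perm_stream <- function(kind, n_perm, step_fun, seed, config = list()) {
  env <- new.env(parent = emptyenv())
  env$kind <- kind
  env$n_perm <- n_perm
  env$i <- 0L
  env$step_fun <- step_fun
  env$seed <- seed
  env$config <- config
  class(env) <- "perm_stream"
  env
}

#' @export
print.perm_stream <- function(x, ...) {
  cat("<perm_stream> kind = ", x$kind, ", ", x$i, "/", x$n_perm,
      " replicates drawn\n", sep = "")
  invisible(x)
}

#' Draw the next replicate from a permutation stream
#'
#' Streams are stateful: sequential data-stream chains must be consumed in
#' order. Returns `NULL` once `n_perm` replicates have been produced.
#'
#' @param stream A `perm_stream`.
#' @return The next randomized dataset (a `gbi`, an attribute tibble, or an
#'   interaction tibble depending on the stream kind), or `NULL` if exhausted.
#' @export
stream_next <- function(stream) {
  stopifnot(inherits(stream, "perm_stream"))
  if (stream$i >= stream$n_perm) return(NULL)
  stream$i <- stream$i + 1L
  stream$step_fun()
}

resolve_seed <- function(seed) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    inform(paste0("no seed supplied; using seed ", seed))
  }
  set.seed(seed)
  seed
}

# Stratum labels for GBI rows from the named constraint keys. Missing
# time/location constraints collapse to one shared stratum (all rows
# exchangeable), with a warning when the requested key carries no information.
row_strata <- function(meta, constraints) {
  constraints <- intersect(constraints, c("period", "location"))
  if (!length(constraints)) return(rep(1L, nrow(meta)))
  parts <- lapply(constraints, function(k) {
    v <- meta[[k]]
    if (all(is.na(v))) {
      warn(paste0("constraint '", k, "' has no values; treating all rows as one stratum"))
      v <- rep("", length(v))
    }
    v[is.na(v)] <- ""
    as.character(v)
  })
  as.integer(factor(do.call(paste, c(parts, sep = "\r"))))
}

#' Node-label permutations of an attribute table
#'
#' Each replicate independently permutes the rows of the attribute table across
#' individuals (all attribute columns move together), preserving the multiset
#' of attribute values exactly while leaving the network untouched. This is
#' the classical node permutation: it assumes the observed network is the true
#' network.
#'
#' @param attributes Tibble with an `id` column and one or more attribute
#'   columns.
#' @param column Focal column (used only to warn when it is constant and the
#'   test will be powerless).
#' @param n_perm Number of replicates.
#' @param seed Optional integer seed.
#' @return A `perm_stream` yielding attribute tibbles with `id` fixed and
#'   attribute rows permuted.
#' @export
permute_node_labels <- function(attributes, column = NULL, n_perm = 1000,
                                seed = NULL) {
  stopifnot(is.data.frame(attributes), "id" %in% names(attributes), n_perm >= 1)
  if (!is.null(column)) {
    if (!column %in% names(attributes)) abort(paste0("no such column: ", column))
    if (length(unique(attributes[[column]])) < 2) {
      warn(paste0("column '", column, "' is constant; permutation test will be powerless"))
    }
  }
  seed <- resolve_seed(seed)
  ids <- attributes$id
  vals <- attributes[setdiff(names(attributes), "id")]
  step <- function() {
    p <- sample.int(length(ids))
    out <- vals[p, , drop = FALSE]
    out$id <- ids
    as_tibble(out[c("id", setdiff(names(out), "id"))])
  }
  new_perm_stream("node", n_perm, step, seed)
}

# The swap loop runs over a locally owned copy of the GBI matrix (no function
# boundaries are crossed while it is being modified), so element assignment is
# in place rather than copy-on-modify.
run_group_swaps <- function(g, k, stratum_rows, cum_prob, max_proposals) {
  done <- 0L
  proposals <- 0L
  ns <- length(stratum_rows)
  while (done < k) {
    s <- stratum_rows[[findInterval(runif(1), cum_prob) + 1L]]
    rr <- s[sample.int(length(s), 2)]
    r1 <- rr[1]; r2 <- rr[2]
    v1 <- g[r1, ]; v2 <- g[r2, ]
    ci <- which(v1 == 1L & v2 == 0L)
    cj <- which(v1 == 0L & v2 == 1L)
    proposals <- proposals + 1L
    if (length(ci) && length(cj)) {
      i <- ci[sample.int(length(ci), 1)]
      j <- cj[sample.int(length(cj), 1)]
      g[r1, i] <- 0L; g[r1, j] <- 1L
      g[r2, i] <- 1L; g[r2, j] <- 0L
      done <- done + 1L
      proposals <- 0L
    } else if (proposals >= max_proposals) {
      abort(paste0("constraint saturation: no valid checkerboard found in ",
                   max_proposals, " proposals"))
    }
  }
  g
}

#' Sequential data-stream permutations of a GBI (group swaps)
#'
#' Markov-chain randomization of the group-by-individual matrix by repeated
#' constrained checkerboard swaps. Swaps only occur between rows in the same
#' stratum (the cross-product of the named constraint keys, e.g. sampling
#' period x location), so sighting counts, group sizes and stratum totals are
#' conserved exactly and individuals never move across strata.
#'
#' @param gbi A `gbi` object.
#' @param n_perm Number of replicates to yield.
#' @param constraints Character subset of `c("period", "location")`; rows are
#'   exchangeable only within the same combination. Empty vector = one stratum.
#' @param swaps_per_step Number of accepted swaps between successive yielded
#'   replicates (thinning).
#' @param burn_in Accepted swaps performed before the first replicate.
#' @param seed Optional integer seed.
#' @param max_proposals Proposal cap per accepted swap; exceeding it raises a
#'   constraint-saturation error.
#' @return A `perm_stream` yielding `gbi` objects tagged with attribute
#'   `n_swaps` (cumulative accepted swaps).
#' @export
permute_datastream_groups <- function(gbi, n_perm = 1000,
                                      constraints = "period",
                                      swaps_per_step = 1, burn_in = 1000,
                                      seed = NULL, max_proposals = 1e6) {
  stopifnot(inherits(gbi, "gbi"), n_perm >= 1, swaps_per_step >= 1, burn_in >= 0)
  seed <- resolve_seed(seed)
  strata <- row_strata(gbi$meta, constraints)
  stratum_rows <- split(seq_along(strata), strata)
  stratum_rows <- stratum_rows[lengths(stratum_rows) >= 2]
  if (!length(stratum_rows)) {
    abort("no stratum contains two or more groups; no swap is possible")
  }
  npairs <- vapply(stratum_rows, function(s) length(s) * (length(s) - 1) / 2, 0)
  cum_prob <- cumsum(npairs) / sum(npairs)
  state <- new.env(parent = emptyenv())
  state$g <- gbi$matrix
  state$total <- 0L
  do_swaps <- function(k) {
    g <- state$g
    state$g <- NULL                     # single reference: swaps are in place
    g <- run_group_swaps(g, k, stratum_rows, cum_prob, max_proposals)
    state$g <- g
    state$total <- state$total + as.integer(k)
  }
  first <- TRUE
  step <- function() {
    if (first) { do_swaps(burn_in + swaps_per_step); first <<- FALSE }
    else do_swaps(swaps_per_step)
    # swaps preserve the GBI invariants by construction; skip revalidation
    out <- new_gbi(state$g, gbi$ids, gbi$meta, validate = FALSE)
    attr(out, "n_swaps") <- state$total
    out
  }
  new_perm_stream("datastream_group", n_perm, step, seed,
                  list(constraints = constraints, swaps_per_step = swaps_per_step,
                       burn_in = burn_in))
}

#' Sequential data-stream permutations of an interaction log (dyadic swaps)
#'
#' Exchanges receivers between two directed interaction records in the same
#' stratum (e.g. A->C and B->D become A->D and B->C), conserving every
#' individual's outgoing and incoming record counts. Swaps producing
#' self-interactions are rejected.
#'
#' @param interactions Tibble with columns `actor`, `receiver` and optionally
#'   `period`, `location`, `weight`.
#' @inheritParams permute_datastream_groups
#' @return A `perm_stream` yielding interaction tibbles.
#' @export
permute_datastream_dyadic <- function(interactions, n_perm = 1000,
                                      constraints = "period",
                                      swaps_per_step = 1, burn_in = 1000,
                                      seed = NULL, max_proposals = 1e6) {
  stopifnot(is.data.frame(interactions), n_perm >= 1)
  if (nrow(interactions) < 2) abort("need at least two interaction records to swap")
  seed <- resolve_seed(seed)
  meta <- tibble(
    period = if ("period" %in% names(interactions)) as.character(interactions$period) else NA_character_,
    location = if ("location" %in% names(interactions)) as.character(interactions$location) else NA_character_
  )
  strata <- row_strata(meta, constraints)
  stratum_rows <- split(seq_along(strata), strata)
  stratum_rows <- stratum_rows[lengths(stratum_rows) >= 2]
  if (!length(stratum_rows)) abort("no stratum contains two or more records")
  npairs <- vapply(stratum_rows, function(s) length(s) * (length(s) - 1) / 2, 0)
  state <- new.env(parent = emptyenv())
  state$actor <- as.character(interactions$actor)
  state$receiver <- as.character(interactions$receiver)
  do_swaps <- function(k) {
    done <- 0L; proposals <- 0L
    while (done < k) {
      s <- stratum_rows[[sample.int(length(stratum_rows), 1, prob = npairs)]]
      rr <- s[sample.int(length(s), 2)]
      a1 <- state$actor[rr[1]]; a2 <- state$actor[rr[2]]
      c1 <- state$receiver[rr[1]]; c2 <- state$receiver[rr[2]]
      proposals <- proposals + 1L
      if (c1 != c2 && c2 != a1 && c1 != a2) {
        state$receiver[rr[1]] <- c2
        state$receiver[rr[2]] <- c1
        done <- done + 1L
        proposals <- 0L
      } else if (proposals >= max_proposals) {
        abort(paste0("constraint saturation: no valid receiver swap found in ",
                     max_proposals, " proposals"))
      }
    }
  }
  first <- TRUE
  step <- function() {
    if (first) { do_swaps(burn_in + swaps_per_step); first <<- FALSE }
    else do_swaps(swaps_per_step)
    out <- as_tibble(interactions)
    out$actor <- state$actor
    out$receiver <- state$receiver
    out
  }
  new_perm_stream("datastream_dyadic", n_perm, step, seed,
                  list(constraints = constraints, swaps_per_step = swaps_per_step,
                       burn_in = burn_in))
}

#' Null distribution of a statistic over a permutation stream
#'
#' Applies `statistic` to each replicate drawn from the stream and returns the
#' resulting vector, in stream order.
#'
#' @param stream A `perm_stream`.
#' @param statistic Function mapping one randomized dataset to one number.
#' @return Numeric vector of length `n_perm`.
#' @export
null_distribution <- function(stream, statistic) {
  stopifnot(inherits(stream, "perm_stream"), is.function(statistic))
  out <- numeric(stream$n_perm)
  for (i in seq_len(stream$n_perm)) {
    dat <- stream_next(stream)
    val <- tryCatch(statistic(dat), error = function(e) {
      abort(paste0("statistic failed on replicate ", i, ": ", conditionMessage(e)))
    })
    if (!is.numeric(val) || length(val) != 1) {
      abort(paste0("statistic must return one number (replicate ", i, ")"))
    }
    out[i] <- val
  }
  out
}

# Tail p-value per the printed convention: proportion of null values at least
# as extreme as observed, without adding the observed to numerator or
# denominator. `conservative = TRUE` uses (1 + #extreme) / (1 + n).
perm_pvalue <- function(observed, nulls, tail = c("upper", "lower", "two_sided"),
                        conservative = FALSE) {
  tail <- match.arg(tail)
  k <- switch(tail,
              upper = sum(nulls >= observed),
              lower = sum(nulls <= observed),
              two_sided = sum(abs(nulls - mean(nulls)) >= abs(observed - mean(nulls))))
  if (conservative) (1 + k) / (1 + length(nulls)) else k / length(nulls)
}
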