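# Shared fixtures: small GBIs and generators used across test files.

toy_sightings <- function() {
  tibble::tibble(
    period = c("P1", "P1", "P2"),
    members = list(c("a", "b"), "c", c("a", "c"))
  )
}

toy_gbi <- function() build_gbi(toy_sightings())

# random GBI with n individuals, P periods; each period a random partition
# into up to max_groups groups (every individual observed every period)
random_partition_gbi <- function(seed, n = 8, P = 6, max_groups = 3) {
  set.seed(seed)
  rows <- list(); per <- integer()
  for (p in seq_len(P)) {
    lab <- sample(seq_len(max_groups), n, replace = TRUE)
    for (l in unique(lab)) {
      rows[[length(rows) + 1L]] <- as.integer(lab == l)
      per <- c(per, p)
    }
  }
  as_gbi(do.call(rbind, rows), paste0("i", seq_len(n)), period = per)
}

# random GBI with incomplete observation (some individuals unseen per period)
random_sparse_gbi <- function(seed, n = 8, P = 10, p_obs = 0.7) {
  set.seed(seed)
  rows <- list(); per <- integer()
  for (p in seq_len(P)) {
    seen <- which(runif(n) < p_obs)
    if (length(seen) == 0) seen <- sample(n, 1)
    lab <- sample(seq_len(3), length(seen), replace = TRUE)
    for (l in unique(lab)) {
      r <- integer(n); r[seen[lab == l]] <- 1L
      rows[[length(rows) + 1L]] <- r
      per <- c(per, p)
    }
  }
  as_gbi(do.call(rbind, rows), paste0("i", seq_len(n)), period = per)
}

random_symmetric_net <- function(seed, n = 10, density = 0.5, max_w = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  w <- runif(n * (n - 1) / 2) * max_w * (runif(n * (n - 1) / 2) < density)
  m[upper.tri(m)] <- w
  m <- m + t(m)
  new_network(m, paste0("n", seq_len(n)),
              edge_kind = if (max_w <= 1) "association_index" else "count")
}
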