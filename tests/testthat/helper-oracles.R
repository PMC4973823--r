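# Independent brute-force oracles. These re-derive quantities by direct
# enumeration, deliberately avoiding the package's own code paths and igraph.

# per-period enumeration of dyad tallies (union mode)
oracle_tally_union <- function(gbi) {
  g <- gbi$matrix
  n <- ncol(g)
  periods <- unique(gbi$meta$period)
  x <- yab <- ya <- d <- matrix(0, n, n)
  for (p in periods) {
    gp <- g[gbi$meta$period == p, , drop = FALSE]
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        seen_i <- any(gp[, i] == 1)
        seen_j <- any(gp[, j] == 1)
        together <- any(gp[, i] == 1 & gp[, j] == 1)
        if (together) { x[i, j] <- x[i, j] + 1 }
        else if (seen_i && seen_j) { yab[i, j] <- yab[i, j] + 1 }
        else if (seen_i) { ya[i, j] <- ya[i, j] + 1 }
        else if (seen_j) { ya[j, i] <- ya[j, i] + 1 }
        if (seen_i || seen_j) d[i, j] <- d[i, j] + 1
      }
    }
  }
  x <- x + t(x); yab <- yab + t(yab); d <- d + t(d)
  list(x = x, y_ab = yab, y_a = ya, d = d)
}

oracle_sri <- function(gbi) {
  o <- oracle_tally_union(gbi)
  den <- o$x + o$y_ab + o$y_a + t(o$y_a)
  w <- ifelse(den > 0, o$x / den, 0); diag(w) <- 0
  w
}

oracle_hwi <- function(gbi) {
  o <- oracle_tally_union(gbi)
  den <- o$x + o$y_ab + (o$y_a + t(o$y_a)) / 2
  w <- ifelse(den > 0, o$x / den, 0); diag(w) <- 0
  w
}

# all shortest paths by path enumeration on a small weighted graph;
# betweenness by counting path pass-throughs (Brandes-free, O(n!)-ish, n <= 7)
oracle_betweenness <- function(w, weighted = TRUE) {
  n <- nrow(w)
  dist <- ifelse(w > 0, if (weighted) 1 / w else 1, Inf)
  diag(dist) <- 0
  # enumerate all simple paths between every pair, find shortest lengths
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- list()
      walk <- function(path, len) {
        last <- path[length(path)]
        if (last == t) { paths[[length(paths) + 1]] <<- list(path = path, len = len); return() }
        for (v in seq_len(n)) {
          if (!v %in% path && is.finite(dist[last, v])) walk(c(path, v), len + dist[last, v])
        }
      }
      walk(s, 0)
      if (!length(paths)) next
      lens <- vapply(paths, `[[`, 0, "len")
      best <- min(lens)
      short <- paths[abs(lens - best) < 1e-9]
      for (pp in short) {
        inner <- setdiff(pp$path, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(short)
      }
    }
  }
  btw
}

oracle_transitivity <- function(a) {
  a <- (a != 0) + 0
  n <- nrow(a)
  tri <- 0; triples <- 0
  for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    e <- a[i, j] + a[i, k] + a[j, k]
    if (e == 3) tri <- tri + 1
  }
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) return(NA_real_)
  3 * tri / triples
}

# weighted numeric assortativity straight from the edge list definition
oracle_assortativity <- function(w, values) {
  idx <- which(w != 0, arr.ind = TRUE)
  ww <- w[idx]
  xi <- values[idx[, 1]]; xj <- values[idx[, 2]]
  sw <- sum(ww)
  mi <- sum(ww * xi) / sw; mj <- sum(ww * xj) / sw
  num <- sum(ww * (xi - mi) * (xj - mj)) / sw
  den <- sqrt(sum(ww * (xi - mi)^2) / sw) * sqrt(sum(ww * (xj - mj)^2) / sw)
  num / den
}

# enumerate all connected labeled graphs on n nodes (n <= 5 practical)
all_connected_graphs <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  out <- list()
  is_connected <- function(a) {
    reach <- c(TRUE, rep(FALSE, n - 1))
    for (k in seq_len(n)) reach <- reach | (colSums(a[reach, , drop = FALSE]) > 0)
    all(reach)
  }
  for (code in seq_len(2^m - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    a <- matrix(0, n, n)
    for (e in which(bits == 1)) {
      a[pairs[1, e], pairs[2, e]] <- 1
      a[pairs[2, e], pairs[1, e]] <- 1
    }
    if (is_connected(a)) out[[length(out) + 1]] <- a
  }
  out
}

# exact Mantel p over all n! relabelings
oracle_mantel_exact <- function(m1, m2, tail = "two_sided") {
  n <- nrow(m1)
  off <- function(m) m[row(m) != col(m)]
  perms <- gtools_permutations(n)
  obs <- cor(off(m1), off(m2))
  rs <- apply(perms, 1, function(p) cor(off(m1), off(m2[p, p])))
  switch(tail,
         two_sided = mean(abs(rs - mean(rs)) >= abs(obs - mean(rs))),
         upper = mean(rs >= obs),
         lower = mean(rs <= obs))
}

# all permutations of 1..n (no extra packages)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}
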