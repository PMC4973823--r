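# Node- and network-level metrics. Standard graph algorithms are delegated to
# igraph; weighted shortest paths use distance = 1 / weight so that stronger
# edges are shorter, a convention that must be stated because path length on a
# weighted association network is otherwise undefined.

metric_names <- c("degree", "strength", "betweenness", "eigenvector",
                  "pagerank", "reach")

#' Node degree and strength
#'
#' Binary degree counts non-zero edges; strength sums edge weights. On a 0/1
#' network the two coincide. For directed networks `direction` selects total,
#' incoming or outgoing edges.
#'
#' @param net An `assoc_net` object.
#' @param direction `"total"`, `"in"` or `"out"`; in/out only for directed nets.
#' @return Named numeric vector in registry order.
#' @export
node_degree <- function(net, direction = c("total", "in", "out")) {
  direction <- match.arg(direction)
  if (!net$directed && direction != "total") {
    abort("in/out degree is undefined on an undirected network")
  }
  m <- net$weights != 0
  v <- switch(direction,
              total = if (net$directed) rowSums(m) + colSums(m) else rowSums(m),
              out = rowSums(m), `in` = colSums(m))
  setNames(as.numeric(v), net$ids)
}

#' @rdname node_degree
#' @export
node_strength <- function(net, direction = c("total", "in", "out")) {
  direction <- match.arg(direction)
  if (!net$directed && direction != "total") {
    abort("in/out strength is undefined on an undirected network")
  }
  m <- net$weights
  v <- switch(direction,
              total = if (net$directed) rowSums(m) + colSums(m) else rowSums(m),
              out = rowSums(m), `in` = colSums(m))
  setNames(as.numeric(v), net$ids)
}

#' Shortest-path betweenness centrality
#'
#' Count of shortest paths flowing through each node. In weighted mode edge
#' length is `1 / weight`, so strongly associated dyads are close.
#'
#' @param net An `assoc_net` object.
#' @param weighted Use weights (via the inverse-weight distance transform)?
#' @return Named numeric vector in registry order.
#' @export
node_betweenness <- function(net, weighted = TRUE) {
  if (any(net$weights < 0)) abort("betweenness requires non-negative weights")
  g <- as_igraph(net)
  w <- if (weighted && net$edge_kind != "binary") 1 / igraph::E(g)$weight else NA
  v <- igraph::betweenness(g, weights = w)
  setNames(as.numeric(v), net$ids)
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the weight matrix, scaled so the maximum is 1.
#' On a disconnected network the centrality is computed separately within each
#' component (each scaled to a component maximum of 1) with a warning, since
#' the global eigenvector concentrates all mass on the dominant component.
#'
#' @param net An undirected `assoc_net`.
#' @return Named numeric vector in registry order.
#' @export
node_eigenvector <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  v <- numeric(length(net$ids))
  if (comp$no > 1) {
    warn("network is disconnected; eigenvector centrality computed per component")
  }
  for (k in seq_len(comp$no)) {
    nodes <- which(comp$membership == k)
    if (length(nodes) == 1) { v[nodes] <- 0; next }
    sub <- net$weights[nodes, nodes, drop = FALSE]
    e <- eigen(sub, symmetric = !net$directed)
    vec <- abs(Re(e$vectors[, which.max(Re(e$values))]))
    v[nodes] <- vec / max(vec)
  }
  setNames(v, net$ids)
}

#' PageRank centrality
#'
#' Damped eigenvector-style centrality in which each node divides the
#' centrality it passes on by its out-degree; the vector sums to 1.
#'
#' @param net An `assoc_net`.
#' @param damping Damping factor in (0, 1).
#' @return Named numeric vector summing to 1, registry order.
#' @export
node_pagerank <- function(net, damping = 0.85) {
  if (!is.numeric(damping) || damping <= 0 || damping >= 1) {
    abort("damping must lie in (0, 1)")
  }
  g <- as_igraph(net)
  v <- igraph::page_rank(g, damping = damping)$vector
  setNames(as.numeric(v), net$ids)
}

#' Reach: fraction of the network within n steps
#'
#' Per node, the proportion of the other N - 1 nodes reachable in at most
#' `steps` binary steps ("n degrees of separation").
#'
#' @param net An `assoc_net`.
#' @param steps Number of steps, >= 1.
#' @return Named numeric vector in registry order.
#' @export
node_reach <- function(net, steps = 2) {
  stopifnot(steps >= 1)
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = NA)
  v <- (rowSums(d <= steps) - 1) / (length(net$ids) - 1)
  setNames(as.numeric(v), net$ids)
}

#' Node metrics as a tibble
#'
#' Computes a set of node metrics in registry order; the workhorse for
#' metric-based hypothesis tests.
#'
#' @param net An `assoc_net`.
#' @param metrics Character vector from `"degree"`, `"strength"`,
#'   `"betweenness"`, `"eigenvector"`, `"pagerank"`, `"reach"`.
#' @param direction Degree/strength direction for directed networks.
#' @param steps Steps for `"reach"`.
#' @param damping Damping for `"pagerank"`.
#' @param weighted Use weights for betweenness?
#' @return Tibble with column `id` plus one column per metric.
#' @export
node_metrics <- function(net, metrics = c("degree", "strength"),
                         direction = "total", steps = 2, damping = 0.85,
                         weighted = TRUE) {
  metrics <- match.arg(metrics, metric_names, several.ok = TRUE)
  out <- tibble(id = net$ids)
  for (m in metrics) {
    out[[m]] <- switch(m,
      degree = node_degree(net, direction),
      strength = node_strength(net, direction),
      betweenness = node_betweenness(net, weighted),
      eigenvector = node_eigenvector(net),
      pagerank = node_pagerank(net, damping),
      reach = node_reach(net, steps)) |> unname()
  }
  out
}

#' Network density
#'
#' Binary: number of edges over the number of possible dyads. Weighted: sum of
#' edge weights over the number of possible dyads.
#'
#' @param net An `assoc_net` with at least two individuals.
#' @param weighted Weighted (default) or binary density?
#' @return A single number.
#' @export
graph_density <- function(net, weighted = TRUE) {
  n <- length(net$ids)
  if (n < 2) abort("density requires at least 2 individuals")
  m <- net$weights
  vals <- if (net$directed) m[row(m) != col(m)] else m[upper.tri(m)]
  possible <- length(vals)
  if (weighted) sum(vals) / possible else sum(vals != 0) / possible
}

#' Weighted assortativity by a node attribute
#'
#' Correlation of the attribute values of connected individuals, weighting each
#' edge by its weight. For numeric attributes this is the edge-weighted Pearson
#' correlation over edge endpoints; for categorical attributes the weighted
#' assortativity coefficient `(sum(e_ii) - sum(a_i b_i)) / (1 - sum(a_i b_i))`
#' based on the weighted mixing matrix.
#'
#' @param net An `assoc_net`.
#' @param values Numeric vector, or character/factor for categorical
#'   assortment, in registry order (or named by id).
#' @return A number in \[-1, 1\].
#' @export
assortativity_coef <- function(net, values) {
  n <- length(net$ids)
  if (!is.null(names(values))) values <- values[net$ids]
  if (length(values) != n) abort("attribute values must align with the registry")
  if (anyNA(values)) abort("attribute values must not be missing")
  m <- net$weights
  if (!net$directed) {
    idx <- which(m != 0, arr.ind = TRUE)   # each undirected edge twice: symmetric
  } else {
    idx <- which(m != 0, arr.ind = TRUE)
  }
  if (nrow(idx) == 0) abort("network has no edges")
  w <- m[idx]
  if (is.numeric(values)) {
    if (stats::var(values) == 0) abort("attribute is constant; assortativity undefined")
    xi <- values[idx[, 1]]; xj <- values[idx[, 2]]
    sw <- sum(w)
    mi <- sum(w * xi) / sw; mj <- sum(w * xj) / sw
    cov <- sum(w * (xi - mi) * (xj - mj)) / sw
    vi <- sum(w * (xi - mi)^2) / sw
    vj <- sum(w * (xj - mj)^2) / sw
    if (vi == 0 || vj == 0) abort("attribute constant across connected nodes")
    cov / sqrt(vi * vj)
  } else {
    f <- factor(values)
    if (nlevels(f) < 2) abort("attribute is constant; assortativity undefined")
    k <- nlevels(f)
    e <- matrix(0, k, k)
    for (r in seq_len(nrow(idx))) {
      e[f[idx[r, 1]], f[idx[r, 2]]] <- e[f[idx[r, 1]], f[idx[r, 2]]] + w[r]
    }
    e <- e / sum(e)
    ai <- rowSums(e); bi <- colSums(e)
    (sum(diag(e)) - sum(ai * bi)) / (1 - sum(ai * bi))
  }
}

#' Transitivity (global clustering)
#'
#' The default `"ratio"` variant is the standard global clustering coefficient:
#' three times the number of triangles over the number of connected triples,
#' bounded in \[0, 1\]. The `"literal"` variant instead reports the count of
#' triads with three edges divided by the count with exactly two edges (an
#' unbounded ratio sometimes quoted informally).
#'
#' @param net An `assoc_net`; weights are binarized (non-zero = edge).
#' @param variant `"ratio"` or `"literal"`.
#' @return A single number.
#' @export
transitivity_coef <- function(net, variant = c("ratio", "literal")) {
  variant <- match.arg(variant)
  a <- (net$weights != 0) + 0
  if (net$directed) a <- ((a + t(a)) > 0) + 0
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) abort("no connected triples; transitivity undefined")
  tri <- sum(diag(a %*% a %*% a)) / 6
  if (variant == "ratio") {
    3 * tri / triples
  } else {
    open <- triples - 3 * tri           # triads with exactly two edges
    if (open == 0) abort("no two-edge triads; literal ratio undefined")
    tri / open
  }
}

#' Community detection by leading-eigenvector modularity
#'
#' Partitions an undirected weighted network by Newman's leading-eigenvector
#' modularity method and reports the modularity of the returned partition.
#'
#' @param net An undirected `assoc_net` with non-negative weights.
#' @return Object of class `net_communities`: list with `membership` (tibble
#'   of `id`, `community`), `modularity` and `n_communities`.
#' @export
detect_communities <- function(net) {
  if (net$directed) abort("community detection requires an undirected network")
  if (all(net$weights == 0)) abort("network has no edges")
  g <- as_igraph(net)
  cl <- igraph::cluster_leading_eigen(g, weights = igraph::E(g)$weight)
  memb <- as.integer(igraph::membership(cl))
  structure(list(
    membership = tibble(id = net$ids, community = memb),
    modularity = igraph::modularity(g, memb, weights = igraph::E(g)$weight),
    n_communities = length(unique(memb))
  ), class = "net_communities")
}

#' @export
print.net_communities <- function(x, ...) {
  cat("<net_communities> ", x$n_communities, " communities, modularity ",
      signif(x$modularity, 4), "\n", sep = "")
  invisible(x)
}

#' Rank correlation and linear fit between two node metrics
#'
#' Spearman rank correlation (average ranks on ties) together with the R^2 of
#' an ordinary least-squares fit of `v2` on `v1`; used to compare how node
#' metrics (e.g. strength before and after thresholding) order individuals.
#'
#' @param v1,v2 Numeric vectors in the same registry order (tibbles with an
#'   `id` column and one metric column are also accepted).
#' @return One-row tibble with `spearman_rho` and `r_squared`.
#' @export
metric_rank_correlation <- function(v1, v2) {
  pick <- function(v) {
    if (is.data.frame(v)) v <- v[[setdiff(names(v), "id")[1]]]
    as.numeric(v)
  }
  v1 <- pick(v1); v2 <- pick(v2)
  if (length(v1) != length(v2)) abort("metric vectors must have equal length")
  if (sd(v1) == 0 || sd(v2) == 0) abort("constant metric vector; correlation undefined")
  rho <- cor(rank(v1), rank(v2))
  fit <- lm(v2 ~ v1)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tibble(spearman_rho = rho, r_squared = r2)
}
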