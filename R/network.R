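# Weighted adjacency container and file formats. The N x N matrix is kept in
# registry order; the diagonal (self-edges) is always zero.

#' Construct a social network object
#'
#' Wraps an N x N non-negative weight matrix together with its individual
#' identifiers. Undirected networks must be symmetric; association-index
#' networks must have weights in \[0, 1\]. Non-zero diagonal entries are zeroed
#' with a warning (self-edges are rarely used when nodes are individuals).
#'
#' @param weights N x N numeric matrix of edge weights.
#' @param ids Character vector of individual identifiers (defaults to the
#'   matrix dimnames).
#' @param directed Logical; is the network directed?
#' @param edge_kind One of `"association_index"`, `"rate"`, `"count"`,
#'   `"residual"`, `"binary"`. Association-index weights are validated to lie
#'   in \[0, 1\]; residual networks may carry negative weights.
#' @param mask Optional logical N x N matrix marking dyads whose edge is
#'   defined (sampled). Dyads with a zero association-index denominator carry
#'   weight 0 and `mask = FALSE` so analyses can exclude them.
#' @return An object of class `assoc_net`.
#' @export
new_network <- function(weights, ids = rownames(weights), directed = FALSE,
                        edge_kind = c("association_index", "rate", "count",
                                      "residual", "binary"),
                        mask = NULL) {
  edge_kind <- match.arg(edge_kind)
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(weights)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) abort("individual identifiers must be unique")
  if (length(ids) != nrow(weights)) abort("ids length must match matrix dimension")
  storage.mode(weights) <- "double"
  if (any(!is.finite(weights))) abort("edge weights must be finite")
  if (edge_kind != "residual" && any(weights < 0)) abort("negative edge weights are not allowed")
  if (any(diag(weights) != 0)) {
    warn("non-zero diagonal entries (self-edges) ignored and set to 0")
    diag(weights) <- 0
  }
  if (!directed && !isSymmetric(unname(weights), tol = 1e-8)) {
    abort("undirected network requires a symmetric weight matrix")
  }
  if (edge_kind == "association_index" && any(weights > 1 + 1e-12)) {
    abort("association indices must lie in [0, 1]")
  }
  if (!is.null(mask)) {
    stopifnot(is.matrix(mask), all(dim(mask) == dim(weights)))
    mask <- mask & TRUE
    diag(mask) <- FALSE
  }
  dimnames(weights) <- list(ids, ids)
  structure(list(weights = weights, ids = ids, directed = directed,
                 edge_kind = edge_kind, mask = mask),
            class = "assoc_net")
}

#' @export
print.assoc_net <- function(x, ...) {
  nz <- if (x$directed) sum(x$weights > 0) else sum(x$weights[upper.tri(x$weights)] > 0)
  cat("<assoc_net> ", length(x$ids), " individuals, ", nz,
      if (x$directed) " directed" else " undirected", " edges (",
      x$edge_kind, ")\n", sep = "")
  invisible(x)
}

net_matrix <- function(net) {
  stopifnot(inherits(net, "assoc_net"))
  net$weights
}

# igraph view of a network; weighted edges, names preserved.
as_igraph <- function(net, weighted = TRUE) {
  m <- net$weights
  mode <- if (net$directed) "directed" else "undirected"
  igraph::graph_from_adjacency_matrix(m, mode = mode,
                                      weighted = if (weighted) TRUE else NULL,
                                      diag = FALSE)
}

#' Edge list of a network as a tibble
#'
#' @param net An `assoc_net` object.
#' @param keep_zero Keep dyads with weight 0?
#' @return Tibble with columns `id1`, `id2`, `weight` (one row per ordered pair
#'   for directed networks, per unordered pair otherwise).
#' @export
network_edges <- function(net, keep_zero = FALSE) {
  m <- net$weights
  idx <- if (net$directed) which(row(m) != col(m)) else which(upper.tri(m))
  w <- m[idx]
  out <- tibble(id1 = net$ids[row(m)[idx]], id2 = net$ids[col(m)[idx]], weight = w)
  if (!keep_zero) out <- out[out$weight != 0, ]
  out
}

#' Threshold a weighted network
#'
#' Either binarizes (weights strictly greater than the threshold become 1,
#' others 0) or prunes (weights at or below the threshold are set to 0,
#' others kept). Thresholding inflates both type I and type II error rates and
#' is discouraged for analysis; a warning is emitted.
#'
#' @param net An `assoc_net` object.
#' @param at Numeric threshold, or one of `"mean"`, `"half_mean"`,
#'   `"twice_mean"`, computed from the mean edge weight.
#' @param mode `"binarize"` or `"prune"`.
#' @param nonzero_only For the preset thresholds, average over non-zero edges
#'   only (default) or over all dyads.
#' @return A thresholded `assoc_net` (`edge_kind` `"binary"` for binarize).
#' @export
threshold_network <- function(net, at = "mean", mode = c("binarize", "prune"),
                              nonzero_only = TRUE) {
  stopifnot(inherits(net, "assoc_net"))
  mode <- match.arg(mode)
  m <- net$weights
  off <- if (net$directed) m[row(m) != col(m)] else m[upper.tri(m)]
  if (is.character(at)) {
    base <- if (nonzero_only) mean(off[off > 0]) else mean(off)
    at <- switch(match.arg(at, c("mean", "half_mean", "twice_mean")),
                 mean = base, half_mean = base / 2, twice_mean = 2 * base)
  }
  if (!is.numeric(at) || length(at) != 1 || at < 0) abort("threshold must be a single value >= 0")
  warn("thresholding a weighted network inflates error rates; use with caution")
  if (mode == "binarize") {
    w <- (m > at) + 0
    new_network(w, net$ids, net$directed, "binary")
  } else {
    w <- ifelse(m > at, m, 0)
    new_network(w, net$ids, net$directed,
                if (net$edge_kind == "residual") "residual" else net$edge_kind)
  }
}

#' Write a network to disk
#'
#' @param net An `assoc_net` object.
#' @param path Output path.
#' @param format `"square"` (square CSV, ids in header and first column),
#'   `"edgelist"` (CSV of `id1,id2,weight`; zero edges omitted) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("square", "edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "assoc_net"))
  if (format == "square") {
    df <- as.data.frame(net$weights)
    write.csv(cbind(id = net$ids, df), path, row.names = FALSE, quote = FALSE)
  } else if (format == "edgelist") {
    write.csv(as.data.frame(network_edges(net)), path, row.names = FALSE, quote = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network from disk
#'
#' Reads square-CSV, edge-list CSV or GraphML networks written by
#' [write_network()]. Square CSVs must carry the same identifier ordering in
#' the header row and the first column.
#'
#' @param path Input path.
#' @param format `"square"`, `"edgelist"` or `"graphml"`.
#' @param directed Logical; interpret edges as directed?
#' @param edge_kind Edge semantics for the resulting network; see
#'   [new_network()]. Default `"association_index"` when all weights are in
#'   \[0, 1\], else `"count"`.
#' @return An `assoc_net` object.
#' @export
read_network <- function(path, format = c("square", "edgelist", "graphml"),
                         directed = FALSE, edge_kind = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "square") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!identical(ids, colnames(m))) {
      abort("square CSV header and first column must carry identical ID orderings")
    }
    storage.mode(m) <- "double"
  } else if (format == "edgelist") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    ids <- unique(c(as.character(df$id1), as.character(df$id2)))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(match(df$id1, ids), match(df$id2, ids))] <- df$weight
    if (!directed) m[cbind(match(df$id2, ids), match(df$id1, ids))] <- df$weight
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    m <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
    ids <- igraph::V(g)$name
    dimnames(m) <- list(ids, ids)
    directed <- igraph::is_directed(g)
  }
  if (is.null(edge_kind)) {
    edge_kind <- if (all(m >= 0) && all(m <= 1)) "association_index" else "count"
  }
  new_network(m, ids, directed = directed, edge_kind = edge_kind)
}
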