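# Group-by-individual data: the raw substrate for gambit-of-the-group networks.
# Rows are observed groups (sampling units), columns are individuals; the column
# order is the individual registry, and every downstream matrix and attribute
# table must follow the same order.

#' Read a stream of group observations from a delimited file
#'
#' Reads a CSV of group sightings, one row per observed group, with columns
#' `period` (required), `time` and `location` (optional) and `members`, a
#' `;`-separated list of individual identifiers.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `period` (character), `time` (numeric or `NA`),
#'   `location` (character or `NA`) and `members` (list of character vectors),
#'   one row per group observation, in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("period,location,members", "P1,north,a;b", "P1,north,c"), f)
#' read_sightings(f)
read_sightings <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("period", "members") %in% names(raw))) {
    abort("sightings file must have 'period' and 'members' columns")
  }
  members <- strsplit(as.character(raw$members), ";", fixed = TRUE)
  members <- lapply(members, function(m) trimws(m[nzchar(trimws(m))]))
  for (i in seq_along(members)) {
    if (length(members[[i]]) == 0) {
      abort(paste0("empty member list on data line ", i))
    }
    if (anyDuplicated(members[[i]])) {
      abort(paste0("duplicate member within group on data line ", i, ": ",
                   paste(unique(members[[i]][duplicated(members[[i]])]), collapse = ", ")))
    }
  }
  bad <- which(is.na(raw$period) | !nzchar(as.character(raw$period)))
  if (length(bad)) abort(paste0("missing sampling period on data line ", bad[1]))
  tibble(
    period = as.character(raw$period),
    time = if ("time" %in% names(raw)) suppressWarnings(as.numeric(raw$time)) else NA_real_,
    location = if ("location" %in% names(raw)) as.character(raw$location) else NA_character_,
    members = members
  )
}

#' Build a group-by-individual matrix from group observations
#'
#' Converts a sightings tibble (see [read_sightings()]) into a binary K x N
#' group-by-individual (GBI) matrix: K observed groups by N individuals.
#' Individuals are ordered first-seen unless an explicit `roster` is supplied;
#' a roster may include individuals that were never observed, which are
#' retained as all-zero columns.
#'
#' @param sightings A tibble with columns `period`, `members` and optionally
#'   `time` and `location`, as returned by [read_sightings()].
#' @param roster Optional character vector fixing the identity and order of
#'   individuals. Every observed individual must appear in it.
#' @return An object of class `gbi`: a list with elements `matrix` (K x N
#'   binary integer matrix), `ids` (column identifiers) and `meta` (tibble of
#'   per-row `period`, `time`, `location`).
#' @export
#' @examples
#' s <- tibble::tibble(period = c("P1", "P1", "P2"),
#'                     members = list(c("a", "b"), "c", c("a", "c")))
#' build_gbi(s)
build_gbi <- function(sightings, roster = NULL) {
  stopifnot(is.data.frame(sightings))
  if (nrow(sightings) == 0) abort("cannot build a GBI from zero observations")
  if (!all(c("period", "members") %in% names(sightings))) {
    abort("sightings must have 'period' and 'members' columns")
  }
  members <- sightings$members
  if (!is.list(members)) members <- strsplit(as.character(members), ";", fixed = TRUE)
  members <- lapply(members, as.character)
  if (any(lengths(members) == 0)) abort("every group must have at least one member")
  dup <- vapply(members, anyDuplicated, 0L) > 0L
  if (any(dup)) abort(paste0("duplicate member within group(s): row ",
                             paste(which(dup), collapse = ", ")))
  seen <- unique(unlist(members))
  if (is.null(roster)) {
    ids <- seen
  } else {
    roster <- as.character(roster)
    if (anyDuplicated(roster)) abort("roster contains duplicate identifiers")
    unknown <- setdiff(seen, roster)
    if (length(unknown)) {
      abort(paste0("observed individuals missing from roster: ",
                   paste(unknown, collapse = ", ")))
    }
    ids <- roster
  }
  k <- length(members)
  m <- matrix(0L, k, length(ids), dimnames = list(NULL, ids))
  for (i in seq_len(k)) m[i, match(members[[i]], ids)] <- 1L
  meta <- tibble(
    period = as.character(sightings$period),
    time = if ("time" %in% names(sightings)) as.numeric(sightings$time) else NA_real_,
    location = if ("location" %in% names(sightings)) as.character(sightings$location) else NA_character_
  )
  new_gbi(m, ids, meta)
}

new_gbi <- function(matrix, ids, meta, validate = TRUE) {
  if (validate) {
    stopifnot(is.matrix(matrix), ncol(matrix) == length(ids), nrow(matrix) == nrow(meta))
    if (anyDuplicated(ids)) abort("individual identifiers must be unique")
    if (!all(matrix %in% c(0L, 1L))) abort("GBI entries must be 0 or 1")
    if (any(rowSums(matrix) < 1)) abort("every GBI row must contain at least one individual")
    storage.mode(matrix) <- "integer"
    colnames(matrix) <- ids
  }
  structure(list(matrix = matrix, ids = as.character(ids), meta = as_tibble(meta)),
            class = "gbi")
}

#' Construct a group-by-individual object from a binary matrix
#'
#' Low-level constructor for a `gbi` object from an existing K x N binary
#' matrix, e.g. data already in matrix form.
#'
#' @param matrix K x N binary matrix; column names are used as identifiers if
#'   `ids` is not given.
#' @param ids Character vector of N individual identifiers.
#' @param period Per-row sampling-period labels (length K). Defaults to one row
#'   per period. If all rows share one period, all rows are exchangeable under
#'   data-stream permutations.
#' @param time,location Optional per-row numeric timestamps and location labels.
#' @return A `gbi` object; see [build_gbi()].
#' @export
as_gbi <- function(matrix, ids = colnames(matrix), period = NULL,
                   time = NULL, location = NULL) {
  if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(matrix)))
  if (is.null(period)) period <- as.character(seq_len(nrow(matrix)))
  meta <- tibble(
    period = as.character(rep_len(period, nrow(matrix))),
    time = if (is.null(time)) NA_real_ else as.numeric(rep_len(time, nrow(matrix))),
    location = if (is.null(location)) NA_character_ else as.character(rep_len(location, nrow(matrix)))
  )
  new_gbi(matrix, ids, meta)
}

#' @export
print.gbi <- function(x, ...) {
  cat("<gbi> ", nrow(x$matrix), " groups x ", length(x$ids), " individuals, ",
      length(unique(x$meta$period)), " sampling period(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.gbi <- function(x) dim(x$matrix)

#' Per-individual observation counts
#'
#' Number of groups in which each individual was recorded (GBI column sums).
#' This margin is conserved exactly by data-stream group permutations.
#'
#' @param gbi A `gbi` object.
#' @return Tibble with columns `id` and `n_obs`.
#' @export
observation_counts <- function(gbi) {
  stopifnot(inherits(gbi, "gbi"))
  tibble(id = gbi$ids, n_obs = as.integer(colSums(gbi$matrix)))
}

#' Drop rarely observed individuals from a GBI
#'
#' Removes individuals seen in fewer than `min_observations` groups, together
#' with any groups left empty by the removal. Edges attached to rarely seen
#' individuals are typically very imprecise.
#'
#' @param gbi A `gbi` object.
#' @param min_observations Minimum number of sightings to retain an individual.
#' @return A filtered `gbi`; removed identifiers are attached as attribute
#'   `removed` and reported via a message.
#' @export
filter_individuals <- function(gbi, min_observations) {
  stopifnot(inherits(gbi, "gbi"), min_observations >= 0)
  n_obs <- colSums(gbi$matrix)
  keep <- n_obs >= min_observations
  if (!any(keep)) abort("filtering removed every individual")
  removed <- gbi$ids[!keep]
  m <- gbi$matrix[, keep, drop = FALSE]
  rows <- rowSums(m) > 0
  out <- new_gbi(m[rows, , drop = FALSE], gbi$ids[keep], gbi$meta[rows, ])
  if (length(removed)) {
    inform(paste0("removed ", length(removed), " individual(s) with < ",
                  min_observations, " observations: ",
                  paste(removed, collapse = ", ")))
  }
  attr(out, "removed") <- removed
  out
}

#' Retain a random subset of individuals
#'
#' Uniformly retains `ceiling(fraction * N)` individuals and drops groups left
#' empty, emulating incomplete identification of a population. Useful for
#' assessing how node metrics degrade when a fraction of individuals is missing.
#'
#' @param gbi A `gbi` object.
#' @param fraction Fraction of individuals to retain, in (0, 1].
#' @param seed Optional integer seed for reproducibility.
#' @return A `gbi` restricted to the retained individuals, with attribute
#'   `retained` listing them.
#' @export
subsample_individuals <- function(gbi, fraction, seed = NULL) {
  stopifnot(inherits(gbi, "gbi"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(gbi$ids)
  k <- ceiling(fraction * n)
  if (k < 2) abort("fraction too small: fewer than 2 individuals would remain")
  keep_ids <- sort(sample(gbi$ids, k))
  keep <- gbi$ids %in% keep_ids
  m <- gbi$matrix[, keep, drop = FALSE]
  rows <- rowSums(m) > 0
  out <- new_gbi(m[rows, , drop = FALSE], gbi$ids[keep], gbi$meta[rows, ])
  attr(out, "retained") <- gbi$ids[keep]
  out
}

# Align an attribute table (tibble with an `id` column) to a registry order.
align_attributes <- function(attributes, ids) {
  stopifnot(is.data.frame(attributes))
  if (!"id" %in% names(attributes)) abort("attribute table must have an 'id' column")
  if (anyDuplicated(attributes$id)) abort("attribute table has duplicate individuals")
  idx <- match(ids, attributes$id)
  if (anyNA(idx)) {
    abort(paste0("attributes missing for: ", paste(ids[is.na(idx)], collapse = ", ")))
  }
  as_tibble(attributes[idx, , drop = FALSE])
}
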