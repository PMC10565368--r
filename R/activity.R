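#' Truncate extreme station-level counts
#'
#' Replaces every station-level count `c` by `min(c, cap)`. Rare extreme
#' pulses (e.g. a trap placed next to a nest relocation) otherwise dominate
#' variability estimates; truncation caps their influence while leaving the
#' bulk of the data untouched. Applied before any aggregation.
#'
#' @param table Long-format activity `data.frame` with a `count` column.
#' @param cap Threshold (default 500 individuals per species, station and
#'   period).
#' @return The table with capped counts.
#' @export
apply_threshold <- function(table, cap = 500L) {
  if (!is.numeric(cap) || length(cap) != 1L || cap < 1)
    stop("configuration error: cap must be a single value >= 1",
         call. = FALSE)
  table$count <- pmin(table$count, cap)
  table
}

#' Aggregate station counts to site or land-cover-group level
#'
#' Sums counts over stations within each site (`level = "site"`), or further
#' over the sites of each land-cover group (`level = "group"`). Sums are
#' exact integer additions, so station-level structure is collapsed
#' losslessly. Thresholding, when used, must be applied before aggregation.
#'
#' @param table Long-format activity `data.frame` (`site`, `station`,
#'   `species`, `period`, `count`).
#' @param level `"site"` or `"group"`.
#' @param group_map Named character vector mapping site id to group label
#'   (required for `level = "group"`; sites mapping to `NA` are dropped).
#' @return A `data.frame` with columns `site` (or `group`), `species`,
#'   `period`, `count`, covering the full unit x species x period grid
#'   (absent combinations appear with count 0).
#' @export
aggregate_activity <- function(table, level = c("site", "group"),
                               group_map = NULL) {
  level <- match.arg(level)
  if (level == "group") {
    if (is.null(group_map))
      stop("group_map required for level = 'group'", call. = FALSE)
    unknown <- setdiff(unique(table$site), names(group_map))
    if (length(unknown))
      stop("key error: sites missing from group_map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    unit <- unname(group_map[table$site])
    keep <- !is.na(unit)
    table <- table[keep, , drop = FALSE]
    unit <- unit[keep]
  } else {
    unit <- table$site
  }
  agg <- stats::aggregate(
    list(count = table$count),
    by = list(unit = unit, species = table$species, period = table$period),
    FUN = sum)
  # complete the unit x species x period grid with zeros
  grid <- expand.grid(unit = sort(unique(agg$unit)),
                      species = sort(unique(agg$species)),
                      period = sort(unique(agg$period)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- merge(grid, agg, by = c("unit", "species", "period"),
               all.x = TRUE, sort = TRUE)
  out$count[is.na(out$count)] <- 0L
  names(out)[1] <- if (level == "group") "group" else "site"
  out[order(out[[1]], out$species, out$period), , drop = FALSE]
}

#' Build species-by-period count matrices per unit
#'
#' @param agg Aggregated activity from [aggregate_activity()].
#' @return Named list (one element per site/group) of integer matrices with
#'   species as rows and periods as columns.
#' @export
series_matrices <- function(agg) {
  unit_col <- names(agg)[1]
  periods <- sort(unique(agg$period))
  lapply(split(agg, agg[[unit_col]]), function(d) {
    M <- stats::xtabs(count ~ species + period, data = d)
    M <- matrix(as.numeric(M), nrow = nrow(M), dimnames = dimnames(M))
    M[, as.character(periods), drop = FALSE]
  })
}

# Exact multivariate hypergeometric draw: sample `target` individuals
# without replacement from cells with counts `cells`.
rmultihyper <- function(cells, target) {
  N <- sum(cells)
  picked <- sort.int(sample.int(N, target))
  cum <- cumsum(cells)
  tab <- tabulate(findInterval(picked - 1L, cum) + 1L,
                  nbins = length(cells))
  tab
}

#' Rarefy a species-by-period count matrix
#'
#' Draws `n_rep` independent subsamples of exactly `target` individuals
#' without replacement from the pooled species x period cells (multivariate
#' hypergeometric), preserving the joint species-time structure in
#' expectation: the expected rarefied count of a cell with `n_cell`
#' individuals is `n_cell * target / N`. Used to equalise total counts across
#' sites so that variability metrics are compared free of mean-variance
#' sampling artefacts.
#'
#' @param M Species x period count matrix (non-negative integers).
#' @param target Total number of individuals per replicate; must not exceed
#'   `sum(M)`.
#' @param n_rep Number of replicate draws.
#' @param seed Optional integer seed.
#' @return List of `n_rep` rarefied matrices with `dim(M)`.
#' @export
rarefy_matrix <- function(M, target, n_rep = 100L, seed = NULL) {
  N <- sum(M)
  if (target > N)
    stop("infeasible target: ", target, " exceeds total count ", N,
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (target == N) return(rep(list(M), n_rep))
  cells <- as.vector(M)
  lapply(seq_len(n_rep), function(r) {
    matrix(rmultihyper(cells, target), nrow = nrow(M),
           dimnames = dimnames(M))
  })
}

#' Rarefy one species' series to the minimum total between two groups
#'
#' For a species present in two land-cover groups, subsamples the
#' larger-total series down to the smaller total so the two series are
#' compared at equal sampling effort. Each replicate is a multivariate
#' hypergeometric draw over the species' period cells; the group already at
#' the minimum is returned unchanged.
#'
#' @param x_a,x_b Count vectors over periods for the species in groups A and
#'   B.
#' @param n_rep Number of replicates.
#' @param seed Optional integer seed.
#' @return List with elements `a` and `b`, each a `n_rep`-row matrix
#'   (replicates x periods), and `target`, the shared total.
#' @export
rarefy_between_groups <- function(x_a, x_b, n_rep = 100L, seed = NULL) {
  if (length(x_a) != length(x_b))
    stop("series must cover the same periods", call. = FALSE)
  if (sum(x_a) == 0 || sum(x_b) == 0)
    stop("logic error: species absent from a group must be filtered upstream",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  target <- min(sum(x_a), sum(x_b))
  draw <- function(x) {
    if (sum(x) == target)
      matrix(rep(x, n_rep), nrow = n_rep, byrow = TRUE)
    else
      t(vapply(seq_len(n_rep), function(r) rmultihyper(x, target),
               numeric(length(x))))
  }
  list(a = draw(x_a), b = draw(x_b), target = target)
}
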