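#' Subgroup index via the geometric-mean ratio
#'
#' The subgroup's index is the district index scaled by the ratio of
#' the geometric mean of the equity-subset tracer indicators in the
#' subgroup to the geometric mean in the district population:
#' `subgroup_uhcd = uhcd * GM(subgroup) / GM(district)`, capped at 100
#' (advantaged subgroups can have ratios above 1).  The flat geometric
#' mean over the subset is used, with the same floor rule as the index.
#'
#' @param sub_values Named equity-subset values for the subgroup.
#' @param dist_values Named equity-subset values for the district; the
#'   id sets must match exactly.
#' @param district_uhcd The district's index value.
#' @param floor Geometric-mean floor (default 0.1).
#' @param district_id,dimension,subgroup Optional labels carried into
#'   the result.
#' @return A one-row data.frame: `district_id`, `dimension`,
#'   `subgroup`, `ratio`, `subgroup_uhcd`, `gap`
#'   (`district_uhcd - subgroup_uhcd`; negative when the subgroup is
#'   better off).
#' @export
subgroup_index <- function(sub_values, dist_values, district_uhcd,
                           floor = 0.1, district_id = NA_character_,
                           dimension = NA_character_,
                           subgroup = NA_character_) {
  a <- setdiff(names(sub_values), names(dist_values))
  b <- setdiff(names(dist_values), names(sub_values))
  if (length(a) || length(b)) {
    stop("mismatched equity id sets; only in subgroup: ",
         paste(a, collapse = ", "), "; only in district: ",
         paste(b, collapse = ", "))
  }
  dist_values <- dist_values[names(sub_values)]
  ratio <- geometric_mean(as.numeric(sub_values), floor) /
    geometric_mean(as.numeric(dist_values), floor)
  sub_uhcd <- min(ratio * district_uhcd, 100)
  data.frame(district_id = district_id, dimension = dimension,
             subgroup = subgroup, ratio = ratio,
             subgroup_uhcd = sub_uhcd,
             gap = district_uhcd - sub_uhcd, stringsAsFactors = FALSE)
}

#' Subgroup indices for a whole subgroup table
#'
#' Applies [subgroup_index()] to every row of a long subgroup table,
#' pairing it with the district's own equity-subset values and index.
#'
#' @param subgroups Long subgroup table ([read_subgroup_table()]).
#' @param districts District table (source of the district-population
#'   equity values).
#' @param results Index results ([compute_indices()]).
#' @param registry A `uhc_registry`.
#' @param floor Geometric-mean floor.
#' @return Data.frame of equity results, one row per
#'   (district, dimension, subgroup).
#' @export
equity_table <- function(subgroups, districts, results,
                         registry = default_registry(), floor = 0.1) {
  eq <- intersect(registry$equity_subset, names(subgroups))
  if (!length(eq)) stop("no equity-subset columns in subgroup table")
  uhcd <- setNames(results$uhcd, results$district_id)
  out <- vector("list", nrow(subgroups))
  dmat <- as.matrix(districts[eq])
  rownames(dmat) <- districts$district_id
  for (i in seq_len(nrow(subgroups))) {
    did <- subgroups$district_id[i]
    if (!did %in% rownames(dmat) || !did %in% names(uhcd)) next
    sv <- unlist(subgroups[i, eq])
    if (anyNA(sv)) next
    out[[i]] <- subgroup_index(sv, dmat[did, ], uhcd[[did]], floor,
                               district_id = did,
                               dimension = subgroups$dimension[i],
                               subgroup = subgroups$subgroup[i])
  }
  do.call(rbind, out)
}

#' Fractional ranks with the worst-off first
#'
#' Units are sorted so that the worst-off comes first and given
#' fractional ranks `R_i = (i - 0.5) / n`; tied units share the mean of
#' their positions.  With `ascending_means_worst = TRUE` (default) a
#' smaller ranking value means worse off; set `FALSE` when larger
#' values indicate disadvantage (e.g. ranking districts by MPI).
#'
#' @param order_values Named numeric vector: unit -> ranking variable.
#' @param ascending_means_worst Flag, see above.
#' @return Named vector of fractional ranks in (0, 1).
#' @export
fractional_rank <- function(order_values, ascending_means_worst = TRUE) {
  n <- length(order_values)
  if (n < 2) stop("fractional ranks need >= 2 units")
  v <- if (ascending_means_worst) order_values else -order_values
  pos <- rank(v, ties.method = "average")
  setNames((pos - 0.5) / n, names(order_values))
}

#' Concentration index
#'
#' `C = (2 / (n * mu)) * sum(x_i * R_i) - 1` with midpoint fractional
#' ranks `R_i = (i - 0.5) / n` (no additional small-sample correction
#' is needed under this rank convention: C is exactly 0 for constant
#' values).  C > 0 when the quantity concentrates among the better-off
#' (larger ranks), C < 0 among the worse-off.
#'
#' @param values Numeric vector (mean must be positive).
#' @param fractional_ranks Ranks from [fractional_rank()], same order.
#' @return C in \[-1, 1\].
#' @export
concentration_index <- function(values, fractional_ranks) {
  if (length(values) != length(fractional_ranks)) {
    stop("values and ranks differ in length")
  }
  mu <- mean(values)
  if (mu <= 0) stop("concentration index needs a positive mean")
  n <- length(values)
  2 / (n * mu) * sum(values * fractional_ranks) - 1
}

#' Wagstaff achievement index
#'
#' The inequality-sensitive mean `A(v) = sum(w_i x_i) / sum(w_i)` with
#' weights `w_i = v * (1 - R_i)^(v - 1)`: the worst-off (smallest rank)
#' receive the largest weight.  `v = 1` collapses to the arithmetic
#' mean; the default `v = 2` satisfies `A = mu * (1 - C)` exactly under
#' the midpoint rank convention of [concentration_index()].
#'
#' @param values Numeric vector of percentages.
#' @param fractional_ranks Ranks from [fractional_rank()], worst-off
#'   first.
#' @param v Inequality-aversion parameter, `>= 1` (default 2).
#' @return The achievement index (same units as `values`).
#' @export
achievement_index <- function(values, fractional_ranks, v = 2) {
  if (v < 1) stop("aversion parameter v must be >= 1")
  if (length(values) != length(fractional_ranks)) {
    stop("values and ranks differ in length")
  }
  w <- v * (1 - fractional_ranks)^(v - 1)
  sum(w * values) / sum(w)
}
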