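#' Aggregation specification
#'
#' Controls how tracer indicators are combined into the index.
#'
#' * `geometric` (default): geometric means at every level
#'   (indicator -> area -> domain -> index), the construction used for
#'   the headline index.
#' * `arithmetic`: arithmetic means at every level.
#' * `flat_geometric`: the index is the geometric mean of all 24
#'   oriented indicators directly (equal indicator weights); area and
#'   domain scores are still reported hierarchically for reference.
#'
#' A positive floor is applied to every value entering a geometric mean
#' so that a single true zero (e.g. a district with no recorded cancer
#' screening) cannot annihilate the index.  The floor is in percentage
#' points and must lie in (0, 1) for geometric methods.
#'
#' @param method One of `"geometric"`, `"arithmetic"`, `"flat_geometric"`.
#' @param floor Percentage floor applied before logs (default 0.1).
#' @return An `aggregation_spec` object.
#' @export
aggregation_spec <- function(method = c("geometric", "arithmetic",
                                        "flat_geometric"),
                             floor = 0.1) {
  method <- match.arg(method)
  if (method != "arithmetic" && (floor <= 0 || floor >= 1)) {
    stop("floor must be in (0, 1) for geometric methods, got ", floor)
  }
  structure(list(method = method, floor = floor),
            class = "aggregation_spec")
}

#' Orient an indicator value for aggregation
#'
#' Coverage indicators are used as-is; adverse incidences (catastrophic
#' health expenditure, impoverishment) are complemented so that 100
#' always means best.
#'
#' @param value Percentage(s) in \[0, 100\].
#' @param orientation `"coverage"` or `"adverse_incidence"` (recycled).
#' @return Oriented percentage(s).
#' @export
orient <- function(value, orientation) {
  if (any(!is.na(value) & (value < 0 | value > 100))) {
    stop("value out of [0,100]: ",
         value[which(!is.na(value) & (value < 0 | value > 100))[1]])
  }
  orientation <- rep_len(orientation, length(value))
  ifelse(orientation == "adverse_incidence", 100 - value, value)
}

#' Floored geometric mean
#'
#' Each value is raised to `max(value, floor)` before taking
#' `exp(mean(log(.)))`, so the result lies in \[floor, 100\].
#'
#' @param values Non-empty numeric vector of percentages in \[0, 100\].
#' @param floor Positive floor (default 0.1).
#' @return The geometric mean.
#' @export
geometric_mean <- function(values, floor = 0.1) {
  if (length(values) == 0) stop("geometric_mean of an empty set")
  if (any(is.na(values))) stop("geometric_mean of missing values")
  if (any(values < 0 | values > 100)) stop("values out of [0,100]")
  exp(mean(log(pmax(values, floor))))
}

# mean dispatch used at every aggregation level
agg_mean <- function(values, spec) {
  if (spec$method == "arithmetic") mean(values)
  else geometric_mean(values, spec$floor)
}

#' Compute the UHC index for district records
#'
#' Implements the three-level aggregation: each tracer-area score is the
#' (geometric or arithmetic) mean of its oriented indicators, each
#' domain score the mean of its area scores, and the index `uhcd` the
#' mean of the five domain scores.  The service-coverage component is
#' the mean of the four non-financial domains; the financial-risk-
#' protection component is the FRP domain score.  Under
#' `flat_geometric`, `uhcd` (and the service-coverage component) are
#' flat geometric means over the constituent indicators instead, while
#' area and domain scores remain hierarchical for reference.
#'
#' All registry indicators must be present (run imputation first);
#' districts with any missing indicator raise an error naming it.
#'
#' @param districts District table (see [read_district_table()]).
#' @param registry A `uhc_registry`.
#' @param spec An [aggregation_spec()].
#' @return Data.frame with one row per district: `district_id`,
#'   `state_id`, `uhcd`, `service_coverage`,
#'   `financial_risk_protection`, `domain_<key>` and `area_<key>`
#'   columns, and a `tercile` factor (see [classify_terciles()]).
#' @export
compute_indices <- function(districts, registry,
                            spec = aggregation_spec()) {
  ids <- registry_ids(registry)
  miss <- setdiff(ids, names(districts))
  if (length(miss)) stop("district table lacks indicator(s): ",
                         paste(miss, collapse = ", "))
  vals <- as.matrix(districts[ids])
  if (anyNA(vals)) {
    hole <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("missing indicator ", ids[hole[2]], " for district ",
         districts$district_id[hole[1]],
         " (impute before computing the index)")
  }
  orientations <- registry_orientations(registry)
  adverse <- ids[orientations[ids] == "adverse_incidence"]
  vals[, adverse] <- 100 - vals[, adverse]

  n <- nrow(vals)
  area_keys <- names(registry$areas)
  dom_keys <- names(registry$domains)
  frp_key <- "frp"
  if (!frp_key %in% dom_keys) frp_key <- dom_keys[length(dom_keys)]

  # row-wise mean-per-spec, vectorized over districts
  agg_rows <- function(m) {
    if (spec$method == "arithmetic") rowMeans(m)
    else exp(rowMeans(log(pmax(m, spec$floor))))
  }
  area_scores <- matrix(NA_real_, n, length(area_keys),
                        dimnames = list(NULL, area_keys))
  for (ak in area_keys) {
    area_scores[, ak] <- agg_rows(vals[, registry$areas[[ak]],
                                       drop = FALSE])
  }
  dom_scores <- matrix(NA_real_, n, length(dom_keys),
                       dimnames = list(NULL, dom_keys))
  for (dk in dom_keys) {
    dom_scores[, dk] <- agg_rows(area_scores[, registry$domains[[dk]],
                                             drop = FALSE])
  }

  sc_doms <- setdiff(dom_keys, frp_key)
  if (spec$method == "flat_geometric") {
    gm_rows <- function(m) exp(rowMeans(log(pmax(m, spec$floor))))
    uhcd <- gm_rows(vals)
    sc_ids <- unlist(registry$areas[unlist(registry$domains[sc_doms])])
    sc <- gm_rows(vals[, sc_ids, drop = FALSE])
  } else {
    uhcd <- agg_rows(dom_scores)
    sc <- agg_rows(dom_scores[, sc_doms, drop = FALSE])
  }

  res <- data.frame(district_id = districts$district_id,
                    state_id = districts$state_id,
                    uhcd = uhcd,
                    service_coverage = sc,
                    financial_risk_protection = dom_scores[, frp_key],
                    stringsAsFactors = FALSE)
  colnames(dom_scores) <- paste0("domain_", dom_keys)
  colnames(area_scores) <- paste0("area_", area_keys)
  res <- cbind(res, as.data.frame(dom_scores), as.data.frame(area_scores))
  res$tercile <- classify_terciles(setNames(uhcd, districts$district_id))[
    districts$district_id]
  rownames(res) <- NULL
  res
}

#' Classify districts into performance terciles
#'
#' Districts are sorted by ascending index value (ties broken by
#' lexicographic `district_id`) and split into three contiguous rank
#' groups — `low`, `medium`, `high` — with sizes as equal as possible;
#' when `n` is not divisible by 3 the remainder goes one-per-group to
#' the lowest groups (n = 7 gives 3/2/2).
#'
#' @param indices Named numeric vector: district id -> index value.
#' @return Named character vector of labels `low` / `medium` / `high`.
#' @export
classify_terciles <- function(indices) {
  n <- length(indices)
  if (n < 3) stop("tercile classification needs >= 3 districts")
  ord <- order(indices, names(indices))
  base <- n %/% 3L
  r <- n %% 3L
  sizes <- base + c(r >= 1L, r >= 2L, 0L)
  labels <- rep(c("low", "medium", "high"), times = sizes)
  setNames(labels, names(indices)[ord])[names(indices)]
}

#' Summary statistics for index results
#'
#' Reports, for `uhcd`, the two components and every domain score:
#' count, median, inter-quartile range, standard deviation, min and
#' max, plus the share of districts whose `uhcd` exceeds a threshold.
#' Quantiles use linear interpolation (`type = 7`).
#'
#' @param results Output of [compute_indices()].
#' @param threshold Percentage threshold for the share statistic
#'   (default 50).
#' @return A list with `table` (one row per measure) and `above`
#'   (list: `n_above`, `n_total`, `percentage`, to one decimal).
#' @export
summarize_index <- function(results, threshold = 50) {
  stopifnot(nrow(results) >= 1)
  cols <- c("uhcd", "service_coverage", "financial_risk_protection",
            grep("^domain_", names(results), value = TRUE))
  stat_row <- function(v, label) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(measure = label, n = length(v), median = q[2],
               q1 = q[1], q3 = q[3],
               sd = if (length(v) > 1) sd(v) else 0,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(cols, function(cl) stat_row(results[[cl]], cl)))
  n_above <- sum(results$uhcd > threshold)
  list(table = tab,
       above = list(threshold = threshold, n_above = n_above,
                    n_total = nrow(results),
                    percentage = round(100 * n_above / nrow(results), 1)))
}

#' Compute the index for a single district
#'
#' Convenience wrapper around [compute_indices()] for one district,
#' given a named vector of raw (unoriented) indicator values.
#'
#' @param values Named numeric vector covering every registry indicator.
#' @inheritParams compute_indices
#' @return A list: `uhcd`, `service_coverage`,
#'   `financial_risk_protection`, `domain_scores`, `area_scores`.
#' @export
compute_index <- function(values, registry, spec = aggregation_spec()) {
  ids <- registry_ids(registry)
  miss <- setdiff(ids, names(values))
  if (length(miss)) stop("missing registry indicator(s): ",
                         paste(miss, collapse = ", "))
  df <- data.frame(district_id = "d", state_id = "s",
                   as.list(values[ids]), stringsAsFactors = FALSE,
                   check.names = FALSE)
  # terciles need >= 3 districts; pad with copies and keep the first row
  df <- rbind(df, transform(df, district_id = "d2"),
              transform(df, district_id = "d3"))
  res <- compute_indices(df, registry, spec)[1, ]
  dom <- unlist(res[grep("^domain_", names(res))])
  names(dom) <- sub("^domain_", "", names(dom))
  ar <- unlist(res[grep("^area_", names(res))])
  names(ar) <- sub("^area_", "", names(ar))
  list(uhcd = res$uhcd, service_coverage = res$service_coverage,
       financial_risk_protection = res$financial_risk_protection,
       domain_scores = dom, area_scores = ar)
}
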