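#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of average (mid) ranks; exactly 1 for identical
#' orderings.  Implemented directly on ranks so tests can cross-check
#' it against the classical `1 - 6 * sum(d^2) / (n (n^2 - 1))` formula
#' on tie-free permutations.
#'
#' @param rank_basis_a,rank_basis_b Named numeric vectors over the same
#'   district set (n >= 3).
#' @return Spearman's rho in \[-1, 1\].
#' @export
spearman_rho <- function(rank_basis_a, rank_basis_b) {
  a <- setdiff(names(rank_basis_a), names(rank_basis_b))
  b <- setdiff(names(rank_basis_b), names(rank_basis_a))
  if (length(a) || length(b)) {
    stop("mismatched district sets; only in a: ",
         paste(a, collapse = ", "), "; only in b: ",
         paste(b, collapse = ", "))
  }
  if (length(rank_basis_a) < 3) stop("needs >= 3 districts")
  rb <- rank_basis_b[names(rank_basis_a)]
  ra <- rank(rank_basis_a, ties.method = "average")
  rb <- rank(rb, ties.method = "average")
  # two fully tied rankings order the districts identically
  if (sd(ra) == 0 && sd(rb) == 0) return(1)
  if (sd(ra) == 0 || sd(rb) == 0) stop("constant ranking")
  cor(ra, rb)
}

# registry with one indicator removed; an emptied area (or domain) is
# dropped from the hierarchy
drop_indicator <- function(registry, id) {
  ind <- registry$indicators
  if (!id %in% ind$id) stop("unknown indicator: ", id)
  ind2 <- ind[ind$id != id, , drop = FALSE]
  areas <- lapply(registry$areas, setdiff, y = id)
  areas <- areas[lengths(areas) > 0]
  domains <- lapply(registry$domains, intersect, y = names(areas))
  domains <- domains[lengths(domains) > 0]
  structure(list(indicators = ind2, areas = areas, domains = domains,
                 equity_subset = setdiff(registry$equity_subset, id)),
            class = "uhc_registry")
}

#' Recompute the index under an alternative specification
#'
#' * `arithmetic` and `flat_geometric` delegate to [compute_indices()]
#'   with the matching [aggregation_spec()].
#' * `achievement_adjusted` replaces each tracer-area aggregation's
#'   plain mean with the achievement-weighted mean (`v = 2`) over the
#'   district's five wealth-quintile area scores, for areas whose
#'   indicators all carry quintile-disaggregated data; other areas fall
#'   back to the baseline geometric score (fallbacks are recorded in
#'   the `fallback_areas` attribute).  Domains and the index then
#'   aggregate geometrically as usual.
#'
#' @param districts Complete district table.
#' @param registry A `uhc_registry`.
#' @param variant One of `"arithmetic"`, `"flat_geometric"`,
#'   `"achievement_adjusted"`.
#' @param subgroups Subgroup table with wealth quintiles `q1`..`q5`
#'   (required for `achievement_adjusted`).
#' @param floor Geometric-mean floor.
#' @return Named numeric vector: district -> index under the variant.
#' @export
run_variant <- function(districts, registry,
                        variant = c("arithmetic", "flat_geometric",
                                    "achievement_adjusted"),
                        subgroups = NULL, floor = 0.1) {
  variant <- match.arg(variant)
  if (variant %in% c("arithmetic", "flat_geometric")) {
    res <- compute_indices(districts, registry,
                           aggregation_spec(variant, floor))
    return(setNames(res$uhcd, res$district_id))
  }
  wealth <- subgroups[subgroups$dimension == "wealth", , drop = FALSE]
  if (is.null(subgroups) || nrow(wealth) == 0) {
    stop("achievement_adjusted requires wealth-quintile subgroup data")
  }
  quints <- paste0("q", 1:5)
  qranks <- (seq_along(quints) - 0.5) / length(quints)  # poorest first
  eq <- registry$equity_subset
  ids <- registry_ids(registry)
  orientations <- registry_orientations(registry)
  vals <- as.matrix(districts[ids])
  adverse <- ids[orientations[ids] == "adverse_incidence"]
  vals[, adverse] <- 100 - vals[, adverse]
  rownames(vals) <- districts$district_id

  fallbacks <- character(0)
  out <- numeric(nrow(districts))
  names(out) <- districts$district_id
  for (d in districts$district_id) {
    wd <- wealth[wealth$district_id == d, , drop = FALSE]
    dom_scores <- numeric(0)
    for (dk in names(registry$domains)) {
      area_scores <- numeric(0)
      for (ak in registry$domains[[dk]]) {
        aids <- registry$areas[[ak]]
        base_score <- geometric_mean(vals[d, aids], floor)
        usable <- all(aids %in% eq) && all(aids %in% names(wd)) &&
          nrow(wd) == 5 && all(quints %in% wd$subgroup) &&
          !anyNA(wd[aids])
        if (usable) {
          wd5 <- wd[match(quints, wd$subgroup), , drop = FALSE]
          qscores <- apply(as.matrix(wd5[aids]), 1, geometric_mean,
                           floor = floor)
          area_scores[ak] <- achievement_index(qscores, qranks, v = 2)
        } else {
          fallbacks <- union(fallbacks, ak)
          area_scores[ak] <- base_score
        }
      }
      dom_scores[dk] <- geometric_mean(pmin(area_scores, 100), floor)
    }
    out[d] <- geometric_mean(pmin(dom_scores, 100), floor)
  }
  attr(out, "fallback_areas") <- fallbacks
  out
}

#' Leave-one-indicator-out rank stability
#'
#' Recomputes the index with each indicator dropped in turn (its area,
#' and domain, vanish if emptied) and reports the Spearman correlation
#' of the resulting ranking with the baseline ranking.
#'
#' @param districts Complete district table.
#' @param registry A `uhc_registry`.
#' @param baseline Named vector district -> baseline index (defaults to
#'   the geometric index computed here).
#' @param spec Aggregation for the re-computations (default geometric).
#' @return Named numeric vector: indicator id -> rho, with attributes
#'   `min_rho` and `min_indicator`.
#' @export
leave_one_out <- function(districts, registry, baseline = NULL,
                          spec = aggregation_spec()) {
  if (is.null(baseline)) {
    res <- compute_indices(districts, registry, spec)
    baseline <- setNames(res$uhcd, res$district_id)
  }
  ids <- registry_ids(registry)
  rhos <- vapply(ids, function(id) {
    reg2 <- drop_indicator(registry, id)
    r <- compute_indices(districts, reg2, spec)
    spearman_rho(baseline, setNames(r$uhcd, r$district_id))
  }, numeric(1))
  attr(rhos, "min_rho") <- min(rhos)
  attr(rhos, "min_indicator") <- names(rhos)[which.min(rhos)]
  rhos
}

#' Full sensitivity battery
#'
#' Baseline geometric index versus the arithmetic, flat-geometric and
#' (when subgroup data are supplied) achievement-adjusted variants,
#' plus the leave-one-indicator-out sweep.
#'
#' @inheritParams run_variant
#' @param drop_one Run the 24 leave-one-out recomputations (default
#'   `TRUE`).
#' @return A list of class `sensitivity_report`: `baseline` (named
#'   vector), `variants` (list of named vectors), `rho` (named vector
#'   per variant), `dropped_indicator_rhos`, `min_drop_rho`,
#'   `min_drop_indicator`.
#' @export
sensitivity_report <- function(districts, registry, subgroups = NULL,
                               floor = 0.1, drop_one = TRUE) {
  res <- compute_indices(districts, registry,
                         aggregation_spec("geometric", floor))
  baseline <- setNames(res$uhcd, res$district_id)
  variant_names <- c("arithmetic", "flat_geometric",
                     if (!is.null(subgroups)) "achievement_adjusted")
  variants <- lapply(setNames(variant_names, variant_names), function(v) {
    run_variant(districts, registry, v, subgroups = subgroups,
                floor = floor)
  })
  rho <- vapply(variants, function(v) spearman_rho(baseline, v),
                numeric(1))
  out <- list(baseline = baseline, variants = variants, rho = rho)
  if (drop_one) {
    loo <- leave_one_out(districts, registry, baseline,
                         aggregation_spec("geometric", floor))
    out$dropped_indicator_rhos <- loo
    out$min_drop_rho <- attr(loo, "min_rho")
    out$min_drop_indicator <- attr(loo, "min_indicator")
  }
  class(out) <- "sensitivity_report"
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity of district rankings (Spearman rho vs baseline)\n")
  for (v in names(x$rho)) cat(sprintf("  %-22s %.4f\n", v, x$rho[[v]]))
  if (!is.null(x$dropped_indicator_rhos)) {
    cat(sprintf("  drop-one minimum: %.4f (%s)\n",
                x$min_drop_rho, x$min_drop_indicator))
  }
  invisible(x)
}
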