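#' Inherit missing values from a parent district
#'
#' Approximates redistricting imputation: districts carved out of a
#' parent since the reference survey inherit the parent's values for
#' the listed indicators.  Single-step only — the parent must itself
#' have every listed value; chains are rejected.
#'
#' @param districts District table.
#' @param parent_map Named character vector: child district_id ->
#'   parent district_id.
#' @param indicator_ids Indicators eligible for inheritance.
#' @return The table with missing listed cells of each child copied
#'   from its parent.  Imputed cells are appended to the
#'   `imputed_cells` attribute (`district_id`, `indicator`, `method`).
#' @export
inherit_from_parent <- function(districts, parent_map, indicator_ids) {
  if (anyDuplicated(names(parent_map))) stop("duplicate child in parent_map")
  if (any(names(parent_map) == parent_map)) {
    stop("district mapped to itself: ",
         names(parent_map)[names(parent_map) == parent_map][1])
  }
  # reject cycles in the child -> parent graph (single-step semantics)
  for (start in names(parent_map)) {
    seen <- start
    cur <- start
    while (cur %in% names(parent_map)) {
      cur <- parent_map[[cur]]
      if (cur %in% seen) stop("cyclic parent_map involving ", cur)
      seen <- c(seen, cur)
    }
  }
  prov <- provenance(districts)
  for (child in names(parent_map)) {
    parent <- parent_map[[child]]
    ci <- match(child, districts$district_id)
    pi_ <- match(parent, districts$district_id)
    if (is.na(ci)) stop("child district not in table: ", child)
    if (is.na(pi_)) stop("parent district absent for child ", child,
                         ": ", parent)
    for (id in indicator_ids) {
      if (is.na(districts[[id]][ci])) {
        if (is.na(districts[[id]][pi_])) {
          stop("parent ", parent, " itself missing ", id, " for child ",
               child, " (single-step inheritance only)")
        }
        districts[[id]][ci] <- districts[[id]][pi_]
        prov <- rbind(prov, data.frame(district_id = child, indicator = id,
                                       method = "inherit",
                                       stringsAsFactors = FALSE))
      }
    }
  }
  attr(districts, "imputed_cells") <- prov
  districts
}

#' Hot-deck imputation within strata
#'
#' Each district with any missing target indicator (a recipient) draws
#' one donor uniformly at random — with replacement across recipients —
#' from the districts of the same stratum that are complete on all
#' target indicators, and copies the donor's values into its missing
#' cells.  Imputed values are therefore always members of the observed
#' donor value set.  Default strata are states.
#'
#' @param districts District table.
#' @param target_ids Indicators to impute.
#' @param strata Function of the table returning one stratum label per
#'   row (default: `state_id`).
#' @param seed Integer seed making the draws reproducible.
#' @param fallback_global If `TRUE`, strata without donors fall back to
#'   the pool of all complete districts instead of erroring.
#' @return The table with targets completed; provenance appended as in
#'   [inherit_from_parent()].
#' @export
hot_deck <- function(districts, target_ids,
                     strata = function(d) d$state_id,
                     seed = 1L, fallback_global = FALSE) {
  set.seed(seed)
  lab <- strata(districts)
  tv <- as.matrix(districts[target_ids])
  complete <- !apply(is.na(tv), 1, any)
  recipients <- which(!complete)
  if (!length(recipients)) return(districts)
  prov <- provenance(districts)
  for (ri in recipients) {
    donors <- which(complete & lab == lab[ri])
    if (!length(donors)) {
      if (fallback_global) donors <- which(complete)
      if (!length(donors)) {
        stop("no hot-deck donor in stratum '", lab[ri], "' for district ",
             districts$district_id[ri])
      }
    }
    donor <- donors[sample.int(length(donors), 1L)]
    for (id in target_ids) {
      if (is.na(districts[[id]][ri])) {
        districts[[id]][ri] <- districts[[id]][donor]
        prov <- rbind(prov, data.frame(
          district_id = districts$district_id[ri], indicator = id,
          method = "hotdeck", stringsAsFactors = FALSE))
      }
    }
  }
  attr(districts, "imputed_cells") <- prov
  districts
}

#' Regression imputation with state intercepts
#'
#' Fits, for each target indicator, an ordinary-least-squares model of
#' the target on the covariates plus state fixed intercepts over
#' complete cases, and fills missing targets with fitted values clamped
#' to \[0, 100\].  Used in the default pipeline for the catastrophic-
#' expenditure and impoverishment incidences.
#'
#' @param districts District table.
#' @param target_ids Indicators to impute.
#' @param covariate_ids Predictor indicators (must be complete on rows
#'   needing prediction).
#' @return The table with targets completed; fitted coefficients are
#'   attached as attribute `regression_coefs` (named list per target)
#'   and provenance appended.
#' @export
regression_impute <- function(districts, target_ids, covariate_ids) {
  prov <- provenance(districts)
  coefs <- list()
  multi_state <- length(unique(districts$state_id)) > 1L
  for (tid in target_ids) {
    dat <- districts[c("state_id", tid, covariate_ids)]
    names(dat)[2] <- ".y"
    cc <- complete.cases(dat)
    need <- length(covariate_ids) + 2L
    if (sum(cc) < need) {
      stop("regression imputation for ", tid, " needs >= ", need,
           " complete cases, found ", sum(cc))
    }
    rhs <- paste(c(if (multi_state) "state_id", covariate_ids),
                 collapse = " + ")
    fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = dat[cc, ])
    if (anyNA(coef(fit))) {
      stop("rank-deficient design for target ", tid,
           "; reduce the covariate set")
    }
    coefs[[tid]] <- coef(fit)
    holes <- which(is.na(districts[[tid]]))
    if (length(holes)) {
      pred <- predict(fit, newdata = dat[holes, , drop = FALSE])
      districts[[tid]][holes] <- pmin(pmax(pred, 0), 100)
      prov <- rbind(prov, data.frame(
        district_id = districts$district_id[holes], indicator = tid,
        method = "regression", stringsAsFactors = FALSE))
    }
  }
  attr(districts, "imputed_cells") <- prov
  attr(districts, "regression_coefs") <- coefs
  districts
}

#' Run the full imputation chain
#'
#' Applies, in order: parent inheritance (if a `parent_map` is given),
#' hot-deck for the service-capacity indicators (state strata), and
#' regression imputation for the financial-risk incidences.  After the
#' chain the table is complete on all registry indicators, or an error
#' names what is still missing.
#'
#' @param districts District table.
#' @param registry A `uhc_registry`.
#' @param parent_map Optional child -> parent map for redistricting.
#' @param seed Seed for the hot-deck draws.
#' @param hotdeck_domain Domain whose indicators go through hot-deck
#'   (default `"capacity"`).
#' @param regression_targets Indicators imputed by regression (default:
#'   the adverse-incidence indicators).
#' @param regression_covariates Covariates for the regression (default:
#'   insurance coverage).
#' @return A complete district table with provenance attributes.
#' @export
impute_all <- function(districts, registry = default_registry(),
                       parent_map = NULL, seed = 1L,
                       hotdeck_domain = "capacity",
                       regression_targets = NULL,
                       regression_covariates = "insurance") {
  ids <- registry_ids(registry)
  if (!is.null(parent_map) && length(parent_map)) {
    districts <- inherit_from_parent(districts, parent_map, ids)
  }
  cap_ids <- unlist(registry$areas[registry$domains[[hotdeck_domain]]])
  if (any(is.na(as.matrix(districts[cap_ids])))) {
    districts <- hot_deck(districts, cap_ids, seed = seed)
  }
  if (is.null(regression_targets)) {
    regression_targets <-
      ids[registry_orientations(registry)[ids] == "adverse_incidence"]
  }
  if (length(regression_targets) &&
      any(is.na(as.matrix(districts[regression_targets])))) {
    districts <- regression_impute(districts, regression_targets,
                                   regression_covariates)
  }
  # any indicator still missing (outside the configured routes) gets
  # state-stratified hot-deck as the catch-all
  rest <- setdiff(ids, c(cap_ids, regression_targets))
  if (any(is.na(as.matrix(districts[rest])))) {
    districts <- hot_deck(districts, rest, seed = seed + 1L)
  }
  still <- colSums(is.na(as.matrix(districts[ids])))
  if (any(still > 0)) {
    stop("indicators still missing after imputation: ",
         paste(names(still)[still > 0], collapse = ", "))
  }
  districts
}

provenance <- function(districts) {
  attr(districts, "imputed_cells") %||%
    data.frame(district_id = character(0), indicator = character(0),
               method = character(0), stringsAsFactors = FALSE)
}
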