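#' Per-state district counts emulated by the default simulation
#'
#' The default scenario spreads 687 districts over 33 states using the
#' published per-state district counts of the Indian analysis (from the
#' state-wise index table), so the unbalanced design — including a
#' single-district state — is reproduced.
#'
#' @return Integer vector of length 33 summing to 687.
#' @export
india_district_counts <- function() {
  c(27L, 51L, 75L, 13L, 3L, 38L, 24L, 30L, 4L, 19L, 20L, 33L, 9L, 11L,
    8L, 11L, 8L, 1L, 22L, 12L, 20L, 2L, 22L, 33L, 13L, 30L, 14L, 4L,
    31L, 30L, 2L, 33L, 34L)
}

#' Simulation configuration
#'
#' The stated world of the synthetic generator.  Indicator values are
#' produced as `domain target + indicator offset + state effect +
#' district effect`, clamped to \[0.1, 99.9\]; state effects are
#' `Normal(0, sigma_between^2)` and district effects
#' `Normal(0, sigma_within^2)`, so the latent between-state variance
#' share is `sigma_between^2 / (sigma_between^2 + sigma_within^2)`.
#' Defaults emulate the Indian district analysis: 33 states, 687
#' districts, variance components 31.5 / 13.9 (between share 69.4%),
#' domain targets at the published domain medians, a 7-point
#' poorest-quintile shortfall and an MPI correlated -0.5 with latent
#' quality.
#'
#' @param n_states Number of states (default 33).
#' @param districts_per_state Single count or per-state integer vector
#'   (default: the published 687-district distribution).
#' @param sigma_between SD of state effects in percentage points
#'   (default `sqrt(31.5)`).
#' @param sigma_within SD of district effects (default `sqrt(13.9)`).
#' @param domain_targets Named vector of target central values per
#'   domain, percentages in (0, 100).
#' @param indicator_offsets Optional named vector of per-indicator
#'   shifts added to the domain target (default: none).
#' @param sigma_indicator SD of independent per-cell noise (default 0:
#'   all indicators of a district share its latent quality exactly).
#' @param wealth_gap Mean shortfall of the poorest wealth quintile, in
#'   percentage points (default 7).
#' @param dimension_offsets Named shortfalls for the other disadvantaged
#'   subgroups (residence / religion / social_group).
#' @param subgroup_noise_sd SD of subgroup-level noise (default 2).
#' @param mpi_corr Target correlation between latent quality and the
#'   multidimensional poverty index; must be negative (default -0.5).
#' @param missing_rate Fraction of cells blanked by
#'   [inject_missingness()] when the pipeline requests it (default 0;
#'   [simulate_districts()] itself never produces missing cells).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated `simulation_config` object.
#' @export
simulation_config <- function(n_states = 33L,
                              districts_per_state = india_district_counts(),
                              sigma_between = sqrt(31.5),
                              sigma_within = sqrt(13.9),
                              domain_targets = c(rmnch = 64.8,
                                                 infectious = 82.8,
                                                 ncd = 9.8,
                                                 capacity = 54.9,
                                                 frp = 66.6),
                              indicator_offsets = NULL,
                              sigma_indicator = 0,
                              wealth_gap = 7,
                              dimension_offsets = c(residence = 3,
                                                    religion = 2,
                                                    social_group = 4),
                              subgroup_noise_sd = 2,
                              mpi_corr = -0.5,
                              missing_rate = 0,
                              seed = 1L) {
  if (length(districts_per_state) == 1L) {
    districts_per_state <- rep(as.integer(districts_per_state), n_states)
  }
  if (length(districts_per_state) != n_states) {
    stop("districts_per_state has length ", length(districts_per_state),
         " but n_states = ", n_states)
  }
  if (sigma_between < 0 || sigma_within < 0 || sigma_indicator < 0) {
    stop("standard deviations must be >= 0")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (any(domain_targets <= 0 | domain_targets >= 100)) {
    stop("domain targets must lie in (0, 100)")
  }
  if (mpi_corr > 0) stop("mpi_corr must be negative or zero")
  structure(list(n_states = as.integer(n_states),
                 districts_per_state = as.integer(districts_per_state),
                 sigma_between = sigma_between,
                 sigma_within = sigma_within,
                 domain_targets = domain_targets,
                 indicator_offsets = indicator_offsets,
                 sigma_indicator = sigma_indicator,
                 wealth_gap = wealth_gap,
                 dimension_offsets = dimension_offsets,
                 subgroup_noise_sd = subgroup_noise_sd,
                 mpi_corr = mpi_corr,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

clamp_pct <- function(x, lo = 0.1, hi = 99.9) pmin(pmax(x, lo), hi)

#' Generate a synthetic district indicator table
#'
#' Each district draws a latent quality `q = state effect + district
#' effect`; every indicator value is `domain target + offset + q`
#' (plus optional per-cell noise), clamped to \[0.1, 99.9\].  Adverse
#' incidences (catastrophic expenditure, impoverishment) are stored as
#' incidences (`100 -` the generated coverage-scale value) so the
#' orientation transform is exercised downstream.  The multidimensional
#' poverty index is a monotone-decreasing noisy transform of `q` whose
#' mixing weight is tuned by bisection until the empirical correlation
#' with `q` is within 0.005 of `mpi_corr`.
#'
#' The latent quality and state effects are attached as attributes
#' `latent_quality` and `state_effects` for variance-recovery checks.
#'
#' @param config A [simulation_config()].
#' @param registry A `uhc_registry`.
#' @return District table in [read_district_table()] layout; no cell is
#'   missing (use [inject_missingness()] for that).
#' @export
simulate_districts <- function(config = simulation_config(),
                               registry = default_registry()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nd <- config$districts_per_state
  n <- sum(nd)
  state_ids <- sprintf("S%02d", seq_len(config$n_states))
  state_of <- rep(state_ids, nd)
  district_ids <- sprintf("D%03d", seq_len(n))

  u <- rnorm(config$n_states, 0, config$sigma_between)
  e <- rnorm(n, 0, config$sigma_within)
  q <- u[match(state_of, state_ids)] + e

  ind <- registry$indicators
  miss_dom <- setdiff(unique(ind$domain), names(config$domain_targets))
  if (length(miss_dom)) {
    stop("no domain target for domain(s): ", paste(miss_dom, collapse = ", "))
  }
  offsets <- setNames(rep(0, nrow(ind)), ind$id)
  if (!is.null(config$indicator_offsets)) {
    unknown <- setdiff(names(config$indicator_offsets), ind$id)
    if (length(unknown)) stop("offset for unknown indicator: ",
                              paste(unknown, collapse = ", "))
    offsets[names(config$indicator_offsets)] <- config$indicator_offsets
  }

  df <- data.frame(district_id = district_ids, state_id = state_of,
                   stringsAsFactors = FALSE)
  for (k in seq_len(nrow(ind))) {
    id <- ind$id[k]
    center <- config$domain_targets[[ind$domain[k]]] + offsets[[id]]
    v <- center + q
    if (config$sigma_indicator > 0) {
      v <- v + rnorm(n, 0, config$sigma_indicator)
    }
    v <- clamp_pct(v)
    df[[id]] <- if (ind$orientation[k] == "adverse_incidence") 100 - v else v
  }

  df$mpi <- simulate_mpi(q, config$mpi_corr)
  attr(df, "latent_quality") <- setNames(q, district_ids)
  attr(df, "state_effects") <- setNames(u, state_ids)
  df
}

# MPI on [0,1], monotone decreasing in latent quality, with noise mixed
# in by bisection on the signal weight until cor(q, mpi) hits the
# target within 0.005.  Only the correlation (not the marginal law of
# MPI) matters downstream.
simulate_mpi <- function(q, target_corr) {
  n <- length(q)
  eps <- rnorm(n)
  # a degenerate (constant-quality) world gets pure-noise MPI
  if (sd(q) == 0 || target_corr == 0) return(pnorm(eps))
  qs <- as.numeric(scale(q))
  mpi_at <- function(a) pnorm(-(a * qs) + sqrt(max(1 - a^2, 0)) * eps)
  lo <- 0; hi <- 1
  for (iter in 1:60) {
    mid <- (lo + hi) / 2
    r <- cor(q, mpi_at(mid))
    if (abs(r - target_corr) < 0.005) break
    if (r > target_corr) lo <- mid else hi <- mid
  }
  mpi_at(mid)
}

#' Generate subgroup-disaggregated equity values
#'
#' For the wealth dimension all five quintiles are produced with a
#' linear gradient of `-wealth_gap, -wealth_gap/2, 0, +wealth_gap/2,
#' +wealth_gap` around the district value (so `q1`, the poorest, falls
#' short by `wealth_gap` on average and the quintile mean equals the
#' district value).  The other dimensions produce one disadvantaged
#' subgroup each (`rural`, `minority`, `sc_st`) with the configured
#' shortfall.  Independent noise of SD `subgroup_noise_sd` is added,
#' and values are clamped to \[0.1, 99.9\].
#'
#' @param districts Output of [simulate_districts()].
#' @inheritParams simulate_districts
#' @return Long subgroup table ([read_subgroup_table()] layout) covering
#'   the registry's equity subset.
#' @export
simulate_subgroups <- function(districts, config = simulation_config(),
                               registry = default_registry()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1000L)  # named substream: subgroups
  eq <- registry$equity_subset
  if (!length(eq)) stop("registry has an empty equity subset")
  n <- nrow(districts)
  gap <- config$wealth_gap
  groups <- data.frame(
    dimension = c(rep("wealth", 5), "residence", "religion", "social_group"),
    subgroup = c(paste0("q", 1:5), "rural", "minority", "sc_st"),
    offset = c(-gap, -gap / 2, 0, gap / 2, gap,
               -config$dimension_offsets[["residence"]],
               -config$dimension_offsets[["religion"]],
               -config$dimension_offsets[["social_group"]]),
    stringsAsFactors = FALSE
  )
  out <- list()
  for (g in seq_len(nrow(groups))) {
    block <- data.frame(district_id = districts$district_id,
                        dimension = groups$dimension[g],
                        subgroup = groups$subgroup[g],
                        stringsAsFactors = FALSE)
    for (id in eq) {
      noise <- if (config$subgroup_noise_sd > 0) {
        rnorm(n, 0, config$subgroup_noise_sd)
      } else 0
      block[[id]] <- clamp_pct(districts[[id]] + groups$offset[g] + noise)
    }
    out[[g]] <- block
  }
  do.call(rbind, out)
}

#' Blank cells to emulate survey gaps
#'
#' `MCAR` blanks every indicator cell independently with probability
#' `rate`; `by_domain` picks `round(rate * n)` districts and blanks
#' their whole service-capacity block (all indicators of `domain`),
#' emulating districts absent from the facility survey.
#'
#' @param districts District table.
#' @param pattern `"MCAR"` or `"by_domain"`.
#' @param rate Fraction in \[0, 1).
#' @param seed Integer seed.
#' @param registry A `uhc_registry`.
#' @param domain Domain key blanked under `by_domain` (default
#'   `"capacity"`).
#' @return The table with the selected cells set to `NA`.
#' @export
inject_missingness <- function(districts, pattern = c("MCAR", "by_domain"),
                               rate, seed = 1L,
                               registry = default_registry(),
                               domain = "capacity") {
  pattern <- match.arg(pattern)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(districts)
  set.seed(seed)
  ids <- intersect(registry_ids(registry), names(districts))
  n <- nrow(districts)
  if (pattern == "MCAR") {
    for (id in ids) {
      blank <- runif(n) < rate
      districts[[id]][blank] <- NA_real_
    }
  } else {
    aks <- registry$domains[[domain]]
    if (is.null(aks)) stop("unknown domain: ", domain)
    dom_ids <- unlist(registry$areas[aks])
    k <- round(rate * n)
    hit <- sample.int(n, k)
    for (id in dom_ids) districts[[id]][hit] <- NA_real_
    attr(districts, "blanked_districts") <- districts$district_id[sort(hit)]
  }
  districts
}
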