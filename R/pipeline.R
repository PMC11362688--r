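#' Pre-imputation completeness report
#'
#' Counts districts having every registry indicator present.
#'
#' @param districts District table.
#' @param registry A `uhc_registry`.
#' @return List: `n_complete`, `n_total`, `percentage` (one decimal).
#' @export
completeness_report <- function(districts, registry = default_registry()) {
  ids <- registry_ids(registry)
  n_total <- nrow(districts)
  if (n_total == 0) {
    return(list(n_complete = 0L, n_total = 0L, percentage = NA_real_))
  }
  cmpl <- !apply(is.na(as.matrix(districts[ids])), 1, any)
  list(n_complete = sum(cmpl), n_total = n_total,
       percentage = round(100 * sum(cmpl) / n_total, 1))
}

# Table-3-shaped per-state summary: n, median, IQR, tercile counts
state_table <- function(results) {
  split_res <- split(results, results$state_id)
  rows <- lapply(names(split_res), function(s) {
    r <- split_res[[s]]
    q <- quantile(r$uhcd, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(state = s, n = nrow(r), median = q[2], q1 = q[1], q3 = q[3],
               high = sum(r$tercile == "high"),
               medium = sum(r$tercile == "medium"),
               low = sum(r$tercile == "low"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Chains simulate (or load) -> impute -> index -> equity -> variance
#' decomposition -> sensitivity, writing one CSV per stage plus a
#' machine-readable JSON run log.  Deterministic given the config and
#' seed: all stage randomness is derived from the single top-level seed
#' via fixed offsets.
#'
#' The config is a YAML file (or an equivalent named list) with
#' optional blocks:
#' \preformatted{
#' seed: 1
#' out_dir: out
#' registry: <path, optional>
#' simulate:                 # omit when providing `input:`
#'   missing_pattern: by_domain
#'   missing_rate: 0.03
#'   <any simulation_config() argument>
#' input:
#'   districts: <csv path>
#'   subgroups: <csv path, optional>
#' index:
#'   method: geometric
#'   floor: 0.1
#' summary_threshold: 50
#' sensitivity:
#'   drop_one: true
#' }
#'
#' @param config Path to a YAML config, or a named list.
#' @param out_dir Output directory (overrides the config).
#' @param seed Seed (overrides the config).
#' @return Invisibly, a list with all in-memory stage results and
#'   `files` (the paths written).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- if (!is.null(cfg$registry)) load_registry(cfg$registry)
              else default_registry()
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    files[[name]] <<- p
  }

  # --- stage 1: obtain districts + subgroups -------------------------
  if (!is.null(cfg$input)) {
    districts <- read_district_table(cfg$input$districts, registry)
    subgroups <- if (!is.null(cfg$input$subgroups)) {
      read_subgroup_table(cfg$input$subgroups, registry)
    }
    sim_cfg <- NULL
  } else {
    sim_args <- cfg$simulate %||% list()
    missing_pattern <- sim_args$missing_pattern %||% "by_domain"
    missing_rate <- sim_args$missing_rate %||% 0
    sim_args$missing_pattern <- NULL
    known <- intersect(names(sim_args), names(formals(simulation_config)))
    sim_cfg <- do.call(simulation_config,
                       c(sim_args[known], list(seed = seed)))
    districts <- simulate_districts(sim_cfg, registry)
    subgroups <- simulate_subgroups(districts, sim_cfg, registry)
    if (missing_rate > 0) {
      districts <- inject_missingness(districts, missing_pattern,
                                      missing_rate, seed = seed + 2000L,
                                      registry = registry)
    }
    emit(districts, "districts.csv")
    emit(subgroups, "subgroups.csv")
  }

  completeness <- completeness_report(districts, registry)

  # --- stage 2: imputation -------------------------------------------
  parent_map <- NULL
  if (!is.null(cfg$parent_map)) {
    pm <- utils::read.csv(cfg$parent_map, stringsAsFactors = FALSE,
                          colClasses = "character")
    parent_map <- setNames(pm$parent_id, pm$child_id)
  }
  districts <- impute_all(districts, registry, parent_map = parent_map,
                          seed = seed + 3000L)
  imputed <- attr(districts, "imputed_cells") %||%
    data.frame(district_id = character(0), indicator = character(0),
               method = character(0))

  # --- stage 3: index ------------------------------------------------
  idx_cfg <- cfg$index %||% list()
  spec <- aggregation_spec(idx_cfg$method %||% "geometric",
                           idx_cfg$floor %||% 0.1)
  results <- compute_indices(districts, registry, spec)
  emit(results, "results.csv")
  summ <- summarize_index(results, cfg$summary_threshold %||% 50)
  emit(summ$table, "summary.csv")
  emit(state_table(results), "state_table.csv")

  # --- stage 4: equity -----------------------------------------------
  equity <- NULL
  if (!is.null(subgroups)) {
    equity <- equity_table(subgroups, districts, results, registry,
                           floor = spec$floor)
    emit(equity, "equity.csv")
  }

  # --- stage 5: variance decomposition -------------------------------
  uhcd <- setNames(results$uhcd, results$district_id)
  state_of <- setNames(results$state_id, results$district_id)
  decomp <- fit_null_model(uhcd, state_of, ci = TRUE)
  emit(data.frame(
    component = c("between_states", "within_state"),
    variance = c(decomp$sigma2_between, decomp$sigma2_within),
    se = c(decomp$se$sigma2_between, decomp$se$sigma2_within),
    ci_low = c(decomp$ci$sigma2_between[1], decomp$ci$sigma2_within[1]),
    ci_high = c(decomp$ci$sigma2_between[2], decomp$ci$sigma2_within[2]),
    share = c(decomp$share_between, decomp$share_within)),
    "variance.csv")
  emit(state_cv(uhcd, state_of), "state_cv.csv")
  mpi <- setNames(districts$mpi, districts$district_id)
  mpi_cor <- if (any(!is.na(mpi))) mpi_correlation(uhcd, mpi)

  # --- stage 6: sensitivity ------------------------------------------
  sens_cfg <- cfg$sensitivity %||% list()
  sens <- sensitivity_report(districts, registry, subgroups = subgroups,
                             floor = spec$floor,
                             drop_one = sens_cfg$drop_one %||% TRUE)
  sens_tab <- data.frame(variant = names(sens$rho),
                         rho = as.numeric(sens$rho),
                         stringsAsFactors = FALSE)
  if (!is.null(sens$dropped_indicator_rhos)) {
    sens_tab <- rbind(sens_tab, data.frame(
      variant = paste0("drop_", names(sens$dropped_indicator_rhos)),
      rho = as.numeric(sens$dropped_indicator_rhos)))
  }
  emit(sens_tab, "sensitivity.csv")

  # --- run log --------------------------------------------------------
  log <- list(
    package_version = as.character(utils::packageVersion("uhcd")),
    seed = seed,
    aggregation = list(method = spec$method, floor = spec$floor),
    completeness = completeness,
    n_districts = nrow(results),
    imputed_cells = nrow(imputed),
    imputed_by_method = as.list(table(imputed$method)),
    variance = list(sigma2_between = decomp$sigma2_between,
                    sigma2_within = decomp$sigma2_within,
                    share_between = decomp$share_between,
                    share_within = decomp$share_within),
    mpi_correlation = mpi_cor,
    sensitivity_rho = as.list(sens$rho),
    min_drop_rho = sens$min_drop_rho
  )
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files[["run_log.json"]] <- log_path

  invisible(list(districts = districts, subgroups = subgroups,
                 results = results, summary = summ, equity = equity,
                 decomposition = decomp, mpi_correlation = mpi_cor,
                 sensitivity = sens, completeness = completeness,
                 files = files))
}
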