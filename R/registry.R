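#' Load a tracer-indicator registry from a structured config file
#'
#' The registry is the three-level hierarchy that drives every
#' aggregation in the package: tracer indicators nest in tracer areas,
#' which nest in tracer domains.  The shipped default
#' (`system.file("extdata", "registry_default.yaml", package = "uhcd")`)
#' encodes the 24-indicator / 17-area / 5-domain set used for the Indian
#' district analysis; alternative sets (for example the WHO / World Bank
#' core set) are drop-in replacements with the same schema.
#'
#' The YAML schema is a `domains` list, each with `key`, `name` and an
#' `areas` list; each area has `key`, `name` and an `indicators` list;
#' each indicator has `id`, `name` and optionally
#' `orientation: adverse_incidence` (an incidence, complemented to
#' `100 - x` before aggregation; the default orientation is `coverage`).
#' An optional top-level `equity_subset` list names the indicator ids
#' used for subgroup analysis.
#'
#' @param config_path Path to a YAML registry config.
#' @return An object of class `uhc_registry`: a list with
#'   `indicators` (data.frame: `id`, `name`, `domain`, `area`,
#'   `orientation`, `in_equity_subset`, in config order), `areas`
#'   (named list area-key -> character vector of indicator ids),
#'   `domains` (named list domain-key -> character vector of area keys),
#'   and `equity_subset` (character vector).
#' @export
load_registry <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("registry config not found: ", config_path)
  }
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$domains)) {
    stop("registry config has no `domains` block: ", config_path)
  }
  rows <- list()
  areas <- list()
  domains <- list()
  for (dom in cfg$domains) {
    dkey <- dom$key
    if (is.null(dkey)) stop("domain without a `key` in ", config_path)
    if (dkey %in% names(domains)) stop("duplicate domain key: ", dkey)
    akeys <- character(0)
    for (area in dom$areas) {
      akey <- area$key
      if (is.null(akey)) stop("area without a `key` in domain ", dkey)
      if (akey %in% names(areas)) stop("duplicate area key: ", akey)
      ids <- character(0)
      for (ind in area$indicators) {
        if (is.null(ind$id)) stop("indicator without an `id` in area ", akey)
        orient <- ind$orientation %||% "coverage"
        if (!orient %in% c("coverage", "adverse_incidence")) {
          stop("unknown orientation for indicator ", ind$id, ": ", orient)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          id = ind$id,
          name = ind$name %||% ind$id,
          domain = dkey,
          area = akey,
          orientation = orient,
          stringsAsFactors = FALSE
        )
        ids <- c(ids, ind$id)
      }
      areas[[akey]] <- ids
      akeys <- c(akeys, akey)
    }
    domains[[dkey]] <- akeys
  }
  indicators <- do.call(rbind, rows)
  dup <- indicators$id[duplicated(indicators$id)]
  if (length(dup)) stop("duplicate indicator id: ", paste(dup, collapse = ", "))

  equity <- unlist(cfg$equity_subset) %||% character(0)
  missing_eq <- setdiff(equity, indicators$id)
  if (length(missing_eq)) {
    stop("equity subset id not in registry: ",
         paste(missing_eq, collapse = ", "))
  }
  indicators$in_equity_subset <- indicators$id %in% equity

  reg <- structure(
    list(indicators = indicators, areas = areas, domains = domains,
         equity_subset = indicators$id[indicators$in_equity_subset]),
    class = "uhc_registry"
  )
  validate_registry(reg)
  reg
}

#' The default 24-indicator registry
#'
#' @return The `uhc_registry` shipped with the package: 24 indicators in
#'   17 tracer areas and 5 tracer domains (RMNCH 3 areas / 6 indicators,
#'   infectious diseases 2/3, NCDs 4/5, service capacity and access 5/7,
#'   financial risk protection 3/3), with a 14-indicator equity subset.
#' @export
default_registry <- function() {
  load_registry(system.file("extdata", "registry_default.yaml",
                            package = "uhcd", mustWork = TRUE))
}

validate_registry <- function(reg) {
  ind <- reg$indicators
  stopifnot(is.data.frame(ind), nrow(ind) >= 1)
  # every indicator belongs to exactly one area and one domain
  for (id in ind$id) {
    hits <- vapply(reg$areas, function(v) id %in% v, logical(1))
    if (sum(hits) != 1L) {
      stop("indicator ", id, " appears in ", sum(hits), " areas")
    }
  }
  for (ak in names(reg$areas)) {
    hits <- vapply(reg$domains, function(v) ak %in% v, logical(1))
    if (sum(hits) != 1L) stop("area ", ak, " appears in ", sum(hits), " domains")
  }
  invisible(reg)
}

#' @export
print.uhc_registry <- function(x, ...) {
  cat("uhc_registry:", nrow(x$indicators), "indicators,",
      length(x$areas), "areas,", length(x$domains), "domains\n")
  for (dk in names(x$domains)) {
    n_ind <- sum(x$indicators$domain == dk)
    cat("  ", dk, ": ", length(x$domains[[dk]]), " areas, ",
        n_ind, " indicators\n", sep = "")
  }
  cat("equity subset:", length(x$equity_subset), "indicators\n")
  invisible(x)
}

# ids of indicators in registry order
registry_ids <- function(reg) reg$indicators$id

# orientation lookup vector, names = ids
registry_orientations <- function(reg) {
  setNames(reg$indicators$orientation, reg$indicators$id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
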