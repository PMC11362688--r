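#' Read a district indicator table
#'
#' Expects a comma-delimited file with a header row naming
#' `district_id`, `state_id`, indicator columns by registry id and an
#' optional `mpi` column (multidimensional poverty index, on 0--1).
#' Empty cells are missing values.  District and state ids are opaque
#' strings.
#'
#' @param path CSV file path.
#' @param registry A `uhc_registry`.
#' @return A data.frame with columns `district_id`, `state_id`, one
#'   numeric column per registry indicator (in registry order) and
#'   `mpi`; one row per district.
#' @export
read_district_table <- function(path, registry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(district_id = "character",
                                       state_id = "character"))
  for (col in c("district_id", "state_id")) {
    if (!col %in% names(df)) stop("district table lacks column ", col)
  }
  if (any(is.na(df$district_id) | df$district_id == "")) {
    stop("missing district_id in row(s) ",
         paste(which(is.na(df$district_id) | df$district_id == ""),
               collapse = ", "))
  }
  if (anyDuplicated(df$district_id)) {
    stop("duplicate district_id: ",
         paste(unique(df$district_id[duplicated(df$district_id)]),
               collapse = ", "))
  }
  ids <- registry_ids(registry)
  extra <- setdiff(names(df), c("district_id", "state_id", "mpi", ids))
  if (length(extra)) {
    warning("ignoring unknown indicator column(s): ",
            paste(extra, collapse = ", "))
    df <- df[setdiff(names(df), extra)]
  }
  for (id in intersect(ids, names(df))) {
    v <- df[[id]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) {
      stop("value out of [0,100] for district ", df$district_id[bad[1]],
           ", indicator ", id, ": ", v[bad[1]])
    }
  }
  if (!"mpi" %in% names(df)) df$mpi <- NA_real_
  bad_mpi <- which(!is.na(df$mpi) & (df$mpi < 0 | df$mpi > 1))
  if (length(bad_mpi)) {
    stop("mpi out of [0,1] for district ", df$district_id[bad_mpi[1]])
  }
  # registry indicators absent from the file are all-missing columns
  for (id in setdiff(ids, names(df))) df[[id]] <- NA_real_
  df[c("district_id", "state_id", ids, "mpi")]
}

#' Read a subgroup-disaggregated indicator table
#'
#' Long format: one row per (district, inequality dimension, subgroup),
#' header `district_id,dimension,subgroup,<equity indicator ids...>`.
#' Only equity-subset indicator columns are retained.
#'
#' @inheritParams read_district_table
#' @return A data.frame with `district_id`, `dimension`, `subgroup` and
#'   one numeric column per equity-subset indicator.
#' @export
read_subgroup_table <- function(path, registry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(district_id = "character"))
  for (col in c("district_id", "dimension", "subgroup")) {
    if (!col %in% names(df)) stop("subgroup table lacks column ", col)
  }
  eq <- registry$equity_subset
  extra <- setdiff(names(df), c("district_id", "dimension", "subgroup", eq))
  if (length(extra)) {
    warning("ignoring non-equity-subset column(s): ",
            paste(extra, collapse = ", "))
    df <- df[setdiff(names(df), extra)]
  }
  for (id in intersect(eq, names(df))) {
    v <- df[[id]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(bad)) {
      stop("subgroup value out of [0,100] for district ",
           df$district_id[bad[1]], ", indicator ", id)
    }
  }
  df
}

#' Write index results to CSV
#'
#' One row per district: `uhcd`, every domain score, the
#' service-coverage and financial-risk-protection components and the
#' tercile label.  Values round-trip through [read_results()] to at
#' least six significant digits.
#'
#' @param results Data.frame as returned by [compute_indices()].
#' @param path Output CSV path.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  if (anyDuplicated(results$district_id)) {
    stop("duplicate district_id in results: ",
         paste(unique(results$district_id[duplicated(results$district_id)]),
               collapse = ", "))
  }
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(district_id = "character"))
}
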