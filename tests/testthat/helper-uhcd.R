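# shared fixtures, all built in code

# independent oracle: direct log-sum geometric mean
oracle_gm <- function(v, floor = 0.1) exp(mean(log(pmax(v, floor))))

# district table whose ORIENTED values all equal `value` (adverse
# incidences are stored complemented so they orient back to `value`)
make_districts <- function(n = 6, value = 50, registry = default_registry(),
                           states = NULL) {
  ind <- registry$indicators
  df <- data.frame(
    district_id = sprintf("d%03d", seq_len(n)),
    state_id = states %||% rep(c("sA", "sB"), length.out = n),
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nrow(ind))) {
    df[[ind$id[k]]] <- if (ind$orientation[k] == "adverse_incidence") {
      rep(100 - value, n)
    } else {
      rep(value, n)
    }
  }
  df$mpi <- NA_real_
  df
}

# randomly varied oriented values in [lo, hi], seeded
make_random_districts <- function(n = 20, seed = 42, lo = 5, hi = 95,
                                  registry = default_registry()) {
  set.seed(seed)
  df <- make_districts(n, 50, registry)
  for (id in registry$indicators$id) {
    df[[id]] <- runif(n, lo, hi)
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny registry config written to a temp file
write_mini_registry <- function(extra_equity = NULL) {
  path <- tempfile(fileext = ".yaml")
  eq <- c("a1", extra_equity)
  yaml::write_yaml(list(
    domains = list(list(
      key = "dom1", name = "Domain 1",
      areas = list(list(
        key = "area1", name = "Area 1",
        indicators = list(list(id = "a1", name = "Indicator 1"))
      ))
    )),
    equity_subset = as.list(eq)
  ), path)
  path
}

oriented_matrix <- function(districts, registry) {
  ids <- registry$indicators$id
  m <- as.matrix(districts[ids])
  adverse <- ids[registry$indicators$orientation == "adverse_incidence"]
  m[, adverse] <- 100 - m[, adverse]
  m
}

# all permutations of 1..n as a (n! x n) matrix, built iteratively
all_permutations <- function(n) {
  p <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- matrix(0L, nrow(p) * k, k)
    row <- 1L
    for (i in seq_len(nrow(p))) {
      for (pos in seq_len(k)) {
        out[row, ] <- append(p[i, ], k, after = pos - 1L)
        row <- row + 1L
      }
    }
    p <- out
  }
  p
}
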