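#' Two-level null model: index variance between and within states
#'
#' Fits `y_ij = b0 + u_j + e_ij` with `u_j ~ N(0, sigma2_between)` and
#' `e_ij ~ N(0, sigma2_within)` by restricted maximum likelihood
#' (`lme4::lmer`), the standard estimator for variance components.  A
#' method-of-moments estimator ([moments_null_model()], one-way ANOVA
#' with the unbalanced-design correction) ships as an independent
#' cross-check.  Confidence intervals, when requested, come from the
#' profile likelihood on the SD scale and are squared; the reported SE
#' is the large-sample approximation `(upper - lower) / (2 * 1.96)` on
#' the variance scale.
#'
#' @param values Named numeric vector: district -> index value.
#' @param state_of Named character vector: district -> state.
#' @param ci Compute profile CIs and SEs (slower; default `FALSE`).
#' @return A list of class `variance_decomposition`: `sigma2_between`,
#'   `sigma2_within`, `share_between`, `share_within` (percentages),
#'   `intercept`, and when `ci = TRUE` also `se` and `ci` entries per
#'   component.
#' @export
fit_null_model <- function(values, state_of, ci = FALSE) {
  st <- state_of[names(values)]
  if (anyNA(st)) stop("state missing for district(s): ",
                      paste(names(values)[is.na(st)], collapse = ", "))
  if (length(unique(st)) < 2) {
    stop("between-state variance is unidentified with a single state")
  }
  dat <- data.frame(y = as.numeric(values), state = st)
  fit <- lme4::lmer(y ~ 1 + (1 | state), data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2b <- vc$vcov[vc$grp == "state"]
  s2w <- vc$vcov[vc$grp == "Residual"]
  out <- list(sigma2_between = s2b, sigma2_within = s2w,
              intercept = unname(lme4::fixef(fit)[1]))
  shares <- variance_shares(s2b, s2w)
  out$share_between <- shares[["share_between"]]
  out$share_within <- shares[["share_within"]]
  if (ci) {
    prof <- tryCatch(
      suppressWarnings(suppressMessages(
        stats::confint(fit, parm = c(".sig01", ".sigma"), quiet = TRUE))),
      error = function(e) {
        warning("profile CI failed (", conditionMessage(e),
                "); reporting NA intervals")
        matrix(NA_real_, 2, 2, dimnames = list(c(".sig01", ".sigma"),
                                               NULL))
      })
    ci_b <- prof[".sig01", ]^2
    ci_w <- prof[".sigma", ]^2
    out$ci <- list(sigma2_between = unname(ci_b),
                   sigma2_within = unname(ci_w))
    out$se <- list(sigma2_between = unname(diff(ci_b)) / (2 * 1.96),
                   sigma2_within = unname(diff(ci_w)) / (2 * 1.96))
  }
  class(out) <- "variance_decomposition"
  out
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Two-level null model (REML)\n")
  cat(sprintf("  between states: %.1f (%.1f%%)\n",
              x$sigma2_between, x$share_between))
  cat(sprintf("  within state:   %.1f (%.1f%%)\n",
              x$sigma2_within, x$share_within))
  invisible(x)
}

#' Method-of-moments variance components (one-way ANOVA)
#'
#' Independent oracle for [fit_null_model()]: `sigma2_within = MSW` and
#' `sigma2_between = (MSB - MSW) / n0` with the unbalanced-design
#' average group size `n0 = (N - sum(n_j^2) / N) / (J - 1)`.  Negative
#' moment estimates are truncated at 0.
#'
#' @inheritParams fit_null_model
#' @return List with `sigma2_between`, `sigma2_within`,
#'   `share_between`, `share_within`.
#' @export
moments_null_model <- function(values, state_of) {
  st <- state_of[names(values)]
  y <- as.numeric(values)
  if (length(unique(st)) < 2) stop("needs >= 2 states")
  N <- length(y)
  J <- length(unique(st))
  nj <- tapply(y, st, length)
  mj <- tapply(y, st, mean)
  gm <- mean(y)
  ssb <- sum(nj * (mj - gm)^2)
  ssw <- sum((y - mj[st])^2)
  msb <- ssb / (J - 1)
  msw <- ssw / (N - J)
  n0 <- (N - sum(nj^2) / N) / (J - 1)
  s2b <- max((msb - msw) / n0, 0)
  s2w <- msw
  c(list(sigma2_between = s2b, sigma2_within = s2w),
    as.list(variance_shares(s2b, s2w)))
}

#' Variance shares
#'
#' `share = 100 * sigma2 / (sigma2_between + sigma2_within)` for each
#' component; e.g. components 31.5 / 13.9 give 69.4% / 30.6%.
#'
#' @param sigma2_between,sigma2_within Non-negative variance
#'   components, not both zero.
#' @return Named vector `share_between`, `share_within` (percentages).
#' @export
variance_shares <- function(sigma2_between, sigma2_within) {
  if (sigma2_between < 0 || sigma2_within < 0) {
    stop("variance components must be >= 0")
  }
  tot <- sigma2_between + sigma2_within
  if (tot == 0) stop("both variance components are zero")
  c(share_between = 100 * sigma2_between / tot,
    share_within = 100 * sigma2_within / tot)
}

#' Per-state coefficient of variation
#'
#' `CV = 100 * SD / mean` per state using the sample SD.  States with a
#' single district have no dispersion estimate: they are omitted from
#' the table and listed in the `omitted` attribute.
#'
#' @inheritParams fit_null_model
#' @return Data.frame `state`, `n`, `mean`, `sd`, `cv`.
#' @export
state_cv <- function(values, state_of) {
  st <- state_of[names(values)]
  y <- as.numeric(values)
  nj <- tapply(y, st, length)
  keep <- names(nj)[nj >= 2]
  out <- data.frame(
    state = keep,
    n = as.integer(nj[keep]),
    mean = as.numeric(tapply(y, st, mean)[keep]),
    sd = as.numeric(tapply(y, st, sd)[keep]),
    stringsAsFactors = FALSE
  )
  out$cv <- 100 * out$sd / out$mean
  attr(out, "omitted") <- names(nj)[nj < 2]
  out
}

#' Correlation between the index and district poverty
#'
#' Pearson product-moment correlation (with the two-sided t-test
#' p-value) between the index and the multidimensional poverty index;
#' districts missing either value are excluded and counted.  Spearman
#' is available as an option.
#'
#' @param uhcd Named vector: district -> index.
#' @param mpi Named vector: district -> MPI (0--1).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List: `r`, `p_value`, `n_used`, `n_excluded`.
#' @export
mpi_correlation <- function(uhcd, mpi, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  common <- intersect(names(uhcd), names(mpi))
  x <- uhcd[common]
  y <- mpi[common]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("needs >= 3 districts with both values")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    stop("zero variance in uhcd or mpi")
  }
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method))
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_used = sum(ok),
       n_excluded = length(uhcd) - sum(ok))
}
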