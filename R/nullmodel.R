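#' Fit the negative-binomial background model on low-coverage windows
#'
#' The null distribution of the background sequencing signal is estimated
#' from "low coverage" windows: those with a read count at or below the
#' `low_coverage_quantile` quantile (inverse-ECDF quantile, so the cutoff is
#' an observed count value) of all window counts. On those windows a
#' negative binomial with mean `mu` and dispersion `k`
#' (variance `mu + mu^2 / k`) is fitted by the method of moments
#' (`mu` = sample mean, `k = mu^2 / (var - mu)`); when the sample variance
#' does not exceed the mean there is no detectable overdispersion and the
#' model degrades to Poisson(`mu`).
#'
#' When every window count is zero the model is flagged degenerate
#' (`mu = 0`); scanning against a degenerate null calls any window with a
#' count of at least 1.
#'
#' @param track A `window_track` from [count_windows()].
#' @param low_coverage_quantile Quantile defining the low-coverage cutoff
#'   (default 0.90).
#' @return A `null_model`: list with `family` ("nb" or "poisson"), `mu`, `k`
#'   (`Inf` for Poisson), `low_coverage_cutoff`, `n_windows_used`,
#'   `degenerate`.
#' @export
fit_null <- function(track, low_coverage_quantile = 0.9) {
  stopifnot(inherits(track, "window_track"), nrow(track) > 0L,
            low_coverage_quantile > 0, low_coverage_quantile <= 1)
  counts <- track$count
  cutoff <- as.numeric(stats::quantile(counts, low_coverage_quantile, type = 1L))
  low <- counts[counts <= cutoff]
  mu <- mean(low)
  v <- stats::var(low)
  if (is.na(v)) v <- 0
  if (mu > 0 && v > mu) {
    family <- "nb"
    k <- mu^2 / (v - mu)
  } else {
    family <- "poisson"
    k <- Inf
  }
  structure(
    list(family = family, mu = mu, k = k,
         low_coverage_cutoff = cutoff,
         n_windows_used = length(low),
         low_coverage_quantile = low_coverage_quantile,
         degenerate = mu == 0),
    class = "null_model"
  )
}

#' Upper-tail probability P(C >= c) under a null model
#'
#' @param null A `null_model`.
#' @param counts Integer vector of count values.
#' @return Numeric vector of tail probabilities.
#' @export
null_tail_prob <- function(null, counts) {
  stopifnot(inherits(null, "null_model"))
  if (null$degenerate) return(ifelse(counts <= 0, 1, 0))
  if (null$family == "nb") {
    stats::pnbinom(counts - 1, size = null$k, mu = null$mu, lower.tail = FALSE)
  } else {
    stats::ppois(counts - 1, lambda = null$mu, lower.tail = FALSE)
  }
}

#' Point probability P(C = c) under a null model
#' @noRd
null_point_prob <- function(null, counts) {
  if (null$degenerate) return(ifelse(counts == 0, 1, 0))
  if (null$family == "nb") {
    stats::dnbinom(counts, size = null$k, mu = null$mu)
  } else {
    stats::dpois(counts, lambda = null$mu)
  }
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf(
    "Background null model: %s(mu = %.4g%s), low-coverage cutoff = %g (%d windows)%s\n",
    x$family, x$mu,
    if (x$family == "nb") sprintf(", k = %.4g", x$k) else "",
    x$low_coverage_cutoff, x$n_windows_used,
    if (x$degenerate) " [degenerate: all counts zero]" else ""
  ))
  invisible(x)
}
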