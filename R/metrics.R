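#' The 37-point dissolution sampling schedule
#'
#' Sampling times in minutes: 2, 5, 10, 15, 30, 45 and 60 min, then every
#' 30 min until 960 min (16 h). This fixed grid is also the output layer of
#' the dissolution network (one neuron per time point).
#'
#' @return numeric vector of 37 times in minutes.
#' @export
dissolution_times <- function() c(2, 5, 10, 15, 30, 45, 60, seq(90, 960, 30))

#' Construct a dissolution profile
#'
#' @param times sampling times in minutes, strictly increasing.
#' @param released percent of dose released at each time; model predictions
#'   may mildly overshoot 100%.
#' @return a `dissolution_profile` object.
#' @export
dissolution_profile <- function(times = dissolution_times(), released) {
  stopifnot(is.numeric(times), is.numeric(released))
  if (length(times) != length(released)) {
    stop("times and released must have equal length", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(released))) {
    stop("released values must be finite", call. = FALSE)
  }
  structure(list(times = as.numeric(times), released = as.numeric(released)),
            class = "dissolution_profile")
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat(sprintf("<dissolution_profile> %d points, %.0f-%.0f min, release %.1f-%.1f%%\n",
              length(x$times), min(x$times), max(x$times),
              min(x$released), max(x$released)))
  invisible(x)
}

#' Pair a reference (measured) and a test (predicted) profile
#'
#' @param reference,test [dissolution_profile()] objects on the same grid.
#' @param weights optional positive per-point weights (default 1).
#' @return a `profile_pair` object.
#' @export
profile_pair <- function(reference, test, weights = NULL) {
  stopifnot(inherits(reference, "dissolution_profile"),
            inherits(test, "dissolution_profile"))
  if (length(reference$times) != length(test$times) ||
      any(abs(reference$times - test$times) > 1e-9)) {
    stop("reference and test profiles must share one time grid",
         call. = FALSE)
  }
  n <- length(reference$times)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  structure(list(reference = reference, test = test,
                 weights = as.numeric(weights)), class = "profile_pair")
}

#' Truncate a profile pair at 85% release
#'
#' Points where the reference (measured) profile has exceeded 85% release are
#' discarded, except the first such point, so only the informative part of
#' the curve enters the f2 similarity factor. Truncation is keyed to the
#' reference profile, matching regulatory practice.
#'
#' @param pair a [profile_pair()].
#' @return the truncated `profile_pair`.
#' @export
truncate_at_85 <- function(pair) {
  stopifnot(inherits(pair, "profile_pair"))
  r <- pair$reference$released
  over <- which(r > 85)
  keep <- if (length(over) == 0) seq_along(r) else seq_len(min(over))
  if (length(keep) < 3) {
    stop("too-short-profile: fewer than 3 points survive the 85% truncation",
         call. = FALSE)
  }
  profile_pair(
    dissolution_profile(pair$reference$times[keep], r[keep]),
    dissolution_profile(pair$test$times[keep], pair$test$released[keep]),
    pair$weights[keep])
}

#' f2 similarity factor
#'
#' `f2 = 50 log10( 100 * [1 + (1/n) sum w_t (R_t - T_t)^2]^(-1/2) )`.
#' Equals 100 for identical profiles and decreases with disagreement; a value
#' of 50 (mean squared difference 99) is the conventional similarity
#' threshold. Apply [truncate_at_85()] first when following the regulatory
#' convention; `f2()` itself evaluates the formula on the pair as given.
#'
#' @param pair a [profile_pair()] (already truncated if desired), with at
#'   least 3 points.
#' @return the f2 score (unbounded below, 100 at perfect agreement).
#' @export
f2 <- function(pair) {
  stopifnot(inherits(pair, "profile_pair"))
  r <- pair$reference$released
  t <- pair$test$released
  n <- length(r)
  if (n < 3) stop("f2 requires at least 3 points", call. = FALSE)
  msd <- sum(pair$weights * (r - t)^2) / n
  50 * log10(100 * (1 + msd)^(-0.5))
}

#' Root mean squared error between two profiles
#'
#' Computed on the full (untruncated) grid, in release-% units.
#'
#' @param pair a [profile_pair()].
#' @return RMSE in percent-released units.
#' @export
profile_rmse <- function(pair) {
  stopifnot(inherits(pair, "profile_pair"))
  r <- pair$reference$released
  t <- pair$test$released
  sqrt(sum((r - t)^2) / length(r))
}

#' Coefficient of determination between two profiles
#'
#' `R^2 = 1 - sum (T_t - R_t)^2 / sum (R_t - mean(R))^2`, the standard form
#' with the measured profile's variance in the denominator. Computed on the
#' full grid.
#'
#' @param pair a [profile_pair()].
#' @return R squared (at most 1; 0 for the mean predictor).
#' @export
profile_r2 <- function(pair) {
  stopifnot(inherits(pair, "profile_pair"))
  r <- pair$reference$released
  t <- pair$test$released
  ss_tot <- sum((r - mean(r))^2)
  if (ss_tot <= 0) {
    stop("degenerate-input: reference profile has zero variance",
         call. = FALSE)
  }
  1 - sum((t - r)^2) / ss_tot
}

#' All three profile-comparison metrics at once
#'
#' f2 with the 85% truncation rule; RMSE and R squared on the full grid.
#'
#' @param reference,test [dissolution_profile()] objects.
#' @return list with elements `f2`, `rmse`, `r2`.
#' @export
profile_metrics <- function(reference, test) {
  pair <- profile_pair(reference, test)
  list(f2 = f2(truncate_at_85(pair)),
       rmse = profile_rmse(pair),
       r2 = profile_r2(pair))
}

#' Mean-shift bias correction for reported concentrations
#'
#' CLS systematically under- or over-estimates components with unequal
#' spectral response; for reporting, every prediction is shifted by the
#' difference between the mean reference and mean predicted concentration, so
#' the shifted predictions are unbiased on average. Reporting-only: the
#' dissolution network receives the uncorrected means.
#'
#' @param predicted_means,reference_means equal-length numeric vectors of
#'   w/w % concentrations.
#' @return shifted predictions with `mean(shifted) == mean(reference_means)`.
#' @export
mean_shift_correction <- function(predicted_means, reference_means) {
  if (length(predicted_means) == 0 || length(reference_means) == 0) {
    stop("degenerate-input: empty concentration vectors", call. = FALSE)
  }
  if (length(predicted_means) != length(reference_means)) {
    stop("predicted and reference vectors must have equal length",
         call. = FALSE)
  }
  predicted_means + (mean(reference_means) - mean(predicted_means))
}
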