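# Temperature / pH relative-activity profiles and first-order inactivation
# half-lives. The half-life model is a single-exponential decay
# A(t) = 100 exp(-k t): the only model consistent with summarizing a
# stability course by one t1/2.

#' Normalize an activity profile to its optimum
#'
#' Relative-inhibition profiles are reported with the optimal condition
#' defined as 100 percent.
#'
#' @param conditions numeric vector of condition values (degrees C or pH).
#' @param inhibition raw inhibition measure per condition, >= 2 conditions,
#'   at least one > 0.
#' @param condition_kind `"temperature"` or `"pH"`.
#' @return an object of class `activity_profile`: list with
#'   `condition_kind`, `conditions`, `relative_inhibition` (percent,
#'   max exactly 100).
#' @examples
#' normalize_profile(c(40, 50, 60), c(0.8, 1.0, 0.1))$relative_inhibition
#' @export
normalize_profile <- function(conditions, inhibition,
                              condition_kind = c("temperature", "pH")) {
  condition_kind <- match.arg(condition_kind)
  conditions <- as.numeric(conditions); inhibition <- as.numeric(inhibition)
  if (length(conditions) != length(inhibition))
    stop_input("conditions and inhibition lengths differ")
  if (length(conditions) < 2L)
    stop_input("need >= 2 conditions")
  if (any(inhibition < 0))
    stop_input("inhibition values must be >= 0")
  mx <- max(inhibition)
  if (mx <= 0) stop_input("all-zero inhibition: profile is degenerate")
  structure(
    list(condition_kind = condition_kind, conditions = conditions,
         relative_inhibition = 100 * inhibition / mx),
    class = "activity_profile")
}

#' First-order inactivation half-life from a decay series
#'
#' Fits `A(t) = 100 exp(-k t)` by log-linear regression of `log(A)` on `t`
#' over points above a 5 percent detection floor (the log transform blows
#' up near zero); `t1/2 = log(2)/k`. The regression is weighted by `A^2`,
#' the delta-method variance stabilization for additive measurement noise
#' on an exponential: unweighted log-linear fitting lets the nearly-decayed
#' tail points, whose log values are noisiest, dominate the slope. When
#' the activity at the last observed
#' time is still above `censor_threshold` (default 50 percent), the decay
#' is too slow to quantify within the window and the result is censored:
#' `t_half` is then the lower bound `max(times)` (the ">480 min" reporting
#' convention) and `k_inact` is `NA`.
#'
#' A series whose activity increases over time violates the decay model;
#' a warning is issued and the regression is performed on the raw data
#' anyway (an upward slope yields a censored result).
#'
#' @param decay a [decay_series()] with >= 3 time points including t = 0.
#' @param min_activity_pct detection floor (percent) below which points are
#'   excluded from the log-linear fit.
#' @param censor_threshold percent activity at `t_max` above which the
#'   half-life is reported as censored (`> t_max`).
#' @param method `"loglinear"` (default, closed form) or `"nonlinear"`
#'   (least squares on the raw exponential, for heteroscedastic noise).
#' @return an object of class `half_life_result`: list with
#'   `condition_kind`, `condition_value`, `k_inact` (1/min), `t_half`
#'   (min), `censored`, `r_squared`. `t_half == log(2)/k_inact` holds
#'   whenever `censored` is `FALSE`.
#' @examples
#' d <- decay_series("temperature", 60, c(0, 10, 20), c(100, 50, 25))
#' fit_half_life(d)$t_half  # 10
#' @export
fit_half_life <- function(decay, min_activity_pct = 5, censor_threshold = 50,
                          method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  stopifnot(inherits(decay, "decay_series"))
  t <- decay$times; a <- decay$residual_activity
  if (length(t) < 3L) stop_input("need >= 3 time points, got %d", length(t))
  if (!any(t == 0)) stop_input("decay series must include t = 0")

  if (length(t) >= 2 && stats::coef(stats::lm(a ~ t))[[2]] > 0)
    warning("residual activity increases over time; decay model violated",
            call. = FALSE)

  censored <- a[which.max(t)] > censor_threshold

  keep <- a > min_activity_pct
  k <- r2 <- NA_real_
  if (sum(keep) >= 2) {
    if (method == "loglinear") {
      fit <- stats::lm(log(a[keep]) ~ t[keep], weights = a[keep]^2)
      k <- -stats::coef(fit)[[2]]
      r2 <- lm_r_squared(fit)
    } else {
      k0 <- -stats::coef(stats::lm(log(a[keep]) ~ t[keep],
                                   weights = a[keep]^2))[[2]]
      obj <- function(logk) sum((a - 100 * exp(-exp(logk) * t))^2)
      op <- stats::optim(log(max(k0, 1e-8)), obj, method = "BFGS",
                         control = list(maxit = 5000, reltol = 1e-12))
      k <- exp(op$par)
      r2 <- 1 - op$value / sum((a - mean(a))^2)
    }
  }
  if (!censored && (!is.finite(k) || k <= 0)) censored <- TRUE

  structure(
    list(condition_kind = decay$condition_kind,
         condition_value = decay$condition_value,
         k_inact = if (censored) NA_real_ else k,
         t_half = if (censored) max(t) else log(2) / k,
         censored = censored, r_squared = r2),
    class = "half_life_result")
}

#' @export
print.half_life_result <- function(x, ...) {
  cat(sprintf("<half_life_result %s = %s: t1/2 %s%.4g min%s>\n",
              x$condition_kind, format(x$condition_value),
              if (x$censored) "> " else "= ", x$t_half,
              if (x$censored) " (censored)" else
                sprintf(" (k = %.4g /min, r^2 = %.4f)", x$k_inact,
                        x$r_squared)))
  invisible(x)
}
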