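# Stoichiometry of inhibition (SI): x-intercept of the linear regression of
# fractional protease activity on the inhibitor:enzyme molar ratio. SI > 1
# indicates that part of the serpin pool is turned over as a substrate
# rather than trapping the protease.

#' Fractional activity of an inhibited reaction
#'
#' @param v_inhibited velocity of the inhibited enzyme reaction.
#' @param v_uninhibited velocity of the uninhibited reaction (> 0).
#' @return `v_inhibited / v_uninhibited` (vectorized).
#' @export
fractional_activity <- function(v_inhibited, v_uninhibited) {
  if (any(v_uninhibited <= 0))
    stop_input("uninhibited velocity must be > 0")
  v_inhibited / v_uninhibited
}

#' Stoichiometry of inhibition from a titration
#'
#' Ordinary least squares of fractional activity on the inhibitor:enzyme
#' ratio, restricted to the linear regime, with the stoichiometry of
#' inhibition reported as the x-intercept `-intercept/slope`. Points on the
#' post-intercept plateau (fractional activity <= `min_activity`, default
#' 0.05) are excluded: beyond the equivalence point activity is pinned near
#' zero and would bias the line. When fewer than 3 points survive the
#' floor (coarse titrations near SI = 1), the lowest-ratio sub-floor
#' points are added back until 3 are available - the first point at the
#' floor is the intercept itself and still lies on the line.
#'
#' @param series a [titration_series()].
#' @param fit_range optional length-2 numeric, ratios (inclusive) to use.
#' @param min_activity plateau-exclusion threshold on fractional activity.
#' @return an object of class `si_result`: list with `si`, `slope`,
#'   `intercept`, `r_squared`, `n_points`, `protease_id`.
#' @examples
#' ts <- titration_series("HNE", 0:2, c(1, 0.5, 0))
#' fit_si(ts)$si  # 2
#' @export
fit_si <- function(series, fit_range = NULL, min_activity = 0.05) {
  stopifnot(inherits(series, "titration_series"))
  r <- series$ratio; a <- series$fractional_activity
  in_range <- rep(TRUE, length(r))
  if (!is.null(fit_range)) {
    stopifnot(length(fit_range) == 2L)
    in_range <- r >= fit_range[1] & r <= fit_range[2]
  }
  keep <- in_range & a > min_activity
  if (sum(keep) < 3L) {
    low <- which(in_range & a <= min_activity)
    low <- low[order(r[low])]
    need <- 3L - sum(keep)
    keep[utils::head(low, need)] <- TRUE
  }
  if (sum(keep) < 3L)
    stop_input("need >= 3 usable points, got %d", sum(keep))
  fit <- stats::lm(a[keep] ~ r[keep])
  cf <- stats::coef(fit)
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  if (!is.finite(slope) || slope >= -1e-9)  # 0 up to rounding: no inhibition
    stop_input("non-inhibitory titration: fitted slope is %.3g (must be < 0)",
               slope)
  structure(
    list(si = -intercept / slope, slope = slope, intercept = intercept,
         r_squared = lm_r_squared(fit), n_points = sum(keep),
         protease_id = series$protease_id),
    class = "si_result")
}

#' @export
print.si_result <- function(x, ...) {
  cat(sprintf("<si_result '%s': SI = %.3f (slope %.4g, r^2 = %.4f, n = %d)>\n",
              x$protease_id, x$si, x$slope, x$r_squared, x$n_points))
  invisible(x)
}
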