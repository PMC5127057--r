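# Progress-curve kinetics of irreversible (suicide-substrate) inhibition:
# P(t) = v0/kobs * (1 - exp(-kobs t)) per curve, then kobs vs [I] by OLS
# (slope = k'app), then the substrate-competition correction
# ka = k'app * (1 + [S]/Km).

# (1 - exp(-x))/x, stable near x = 0.
exp_ratio <- function(x) {
  out <- ifelse(abs(x) < 1e-8, 1 - x / 2, (1 - exp(-x)) / x)
  out
}

pc_model <- function(t, v0, kobs, baseline) {
  baseline + v0 * t * exp_ratio(kobs * t)
}

#' Fit a single inhibition progress curve
#'
#' Fits the pseudo-first-order product-accumulation model
#' `P(t) = b + (v0/kobs) (1 - exp(-kobs t))` by bounded nonlinear least
#' squares. `v0` is the uninhibited substrate-hydrolysis velocity (signal/s)
#' and `kobs` the pseudo-first-order rate of protease loss (1/s). A baseline
#' offset `b` is estimated (and reported) when the t = 0 signal is nonzero;
#' for curves starting at zero it is pinned to 0.
#'
#' Starting values: `v0` from the slope of the first 10 percent of points,
#' `kobs` from a log-linear fit of (plateau - P). The optimizer is
#' `stats::nls` ("port", lower bounds `v0 >= 0`, `kobs >= 0`), tolerance
#' 1e-10, up to 10000 iterations. In the `kobs -> 0` limit the model
#' degenerates smoothly to the straight line `P = b + v0 t`.
#'
#' @param curve a [progress_curve()] with at least 5 points.
#' @param baseline `"auto"` (estimate an offset when the t = 0 signal is
#'   nonzero) or `"none"` (pin the offset to 0, the pure two-parameter
#'   model).
#' @return an object of class `progress_fit`: list with `curve_id`, `v0`,
#'   `kobs`, `baseline`, `rss`, `converged`, `plateau` (`v0/kobs`, `Inf`
#'   when `kobs` is 0) and `message` (diagnostics when not converged).
#' @seealso [run_association_pipeline()] for the full kobs -> ka pipeline.
#' @export
fit_progress_curve <- function(curve, baseline = c("auto", "none")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(curve, "progress_curve"))
  t <- curve$times; y <- curve$signal
  n <- length(t)
  if (n < 5L) stop_input("curve '%s': need >= 5 points, got %d",
                         curve$curve_id, n)
  if (diff(range(y)) == 0)
    stop_input("curve '%s': all-constant signal, degenerate fit",
               curve$curve_id)

  y0 <- if (t[1] == 0) y[1] else stats::approx(t, y, xout = 0, rule = 2)$y
  fit_baseline <- baseline == "auto" && abs(y0) > 1e-12 * max(abs(y))

  # starts: v0 from the first 10% of points, kobs from log(plateau - P)
  k_head <- max(3L, ceiling(0.1 * n))
  sl <- stats::coef(stats::lm(y[1:k_head] ~ t[1:k_head]))[[2]]
  v0_start <- max(sl, diff(range(y)) / diff(range(t)) * 1e-3, 1e-12)
  plateau_est <- max(y) + 0.05 * diff(range(y))
  resid_amp <- plateau_est - y
  pos <- resid_amp > 0 & t > 0
  kobs_start <- if (sum(pos) >= 2) {
    ks <- -stats::coef(stats::lm(log(resid_amp[pos]) ~ t[pos]))[[2]]
    if (is.finite(ks) && ks > 0) ks else 1 / max(t)
  } else 1 / max(t)

  dat <- data.frame(t = t, y = y)
  fo <- if (fit_baseline) {
    y ~ baseline + v0 * t * exp_ratio(kobs * t)
  } else {
    y ~ v0 * t * exp_ratio(kobs * t)
  }
  start <- if (fit_baseline) {
    list(v0 = v0_start, kobs = kobs_start, baseline = y0)
  } else {
    list(v0 = v0_start, kobs = kobs_start)
  }
  lower <- if (fit_baseline) c(0, 0, -Inf) else c(0, 0)

  fit <- tryCatch(
    stats::nls(fo, data = dat, start = start, lower = lower,
               algorithm = "port",
               control = stats::nls.control(maxiter = 10000, tol = 1e-10,
                                            warnOnly = FALSE)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    # fall back to direct minimization on the same objective
    obj <- function(p) {
      b <- if (fit_baseline) p[3] else 0
      sum((y - pc_model(t, max(p[1], 0), max(p[2], 0), b))^2)
    }
    p0 <- c(v0_start, kobs_start, if (fit_baseline) y0)
    op <- stats::optim(p0, obj, method = "Nelder-Mead",
                       control = list(maxit = 10000, reltol = 1e-12))
    v0 <- max(op$par[1], 0); kobs <- max(op$par[2], 0)
    b <- if (fit_baseline) op$par[3] else 0
    return(structure(
      list(curve_id = curve$curve_id, v0 = v0, kobs = kobs, baseline = b,
           rss = op$value, converged = op$convergence == 0,
           plateau = if (kobs > 0) v0 / kobs else Inf,
           message = sprintf("nls failed (%s); Nelder-Mead fallback",
                             conditionMessage(fit))),
      class = "progress_fit"))
  }

  cf <- stats::coef(fit)
  v0 <- unname(cf["v0"]); kobs <- unname(cf["kobs"])
  b <- if (fit_baseline) unname(cf["baseline"]) else 0
  structure(
    list(curve_id = curve$curve_id, v0 = v0, kobs = kobs, baseline = b,
         rss = sum(stats::resid(fit)^2), converged = TRUE,
         plateau = if (kobs > 0) v0 / kobs else Inf, message = NA_character_),
    class = "progress_fit")
}

#' @export
print.progress_fit <- function(x, ...) {
  cat(sprintf("<progress_fit '%s': v0 = %.4g /s, kobs = %.4g /s, rss = %.3g%s>\n",
              x$curve_id, x$v0, x$kobs, x$rss,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Regress kobs against inhibitor concentration
#'
#' Ordinary least squares of the per-curve pseudo-first-order rates on the
#' inhibitor concentrations. The slope is the apparent second-order
#' association constant k'app (attenuated by substrate competition); the
#' intercept is left free and reported for diagnostics.
#'
#' @param inhibitor numeric inhibitor concentrations (M), >= 3 distinct
#'   values.
#' @param kobs numeric pseudo-first-order rates (1/s), same length.
#' @return list with `slope` (k'app, 1/M/s), `intercept` (1/s),
#'   `r_squared`, and `points` (data.frame of the inputs).
#' @export
fit_kobs_vs_inhibitor <- function(inhibitor, kobs) {
  inhibitor <- as.numeric(inhibitor); kobs <- as.numeric(kobs)
  if (length(inhibitor) != length(kobs))
    stop_input("inhibitor and kobs lengths differ")
  if (length(unique(inhibitor)) < 3L)
    stop_input("need >= 3 distinct inhibitor concentrations, got %d",
               length(unique(inhibitor)))
  fit <- stats::lm(kobs ~ inhibitor)
  cf <- stats::coef(fit)
  r2 <- lm_r_squared(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]), r_squared = r2,
       points = data.frame(inhibitor = inhibitor, kobs = kobs))
}

#' Substrate-competition correction of the association constant
#'
#' The chromogenic reporter substrate competes with the serpin for the
#' protease active site, attenuating the observed association rate. The
#' true second-order constant is `ka = kapp_prime * (1 + S/Km)`. The
#' correction is unit-free in `S/Km`; `substrate_conc` and `km` must simply
#' share units.
#'
#' @param kapp_prime apparent second-order constant (slope of kobs vs
#'   \[I\], 1/M/s).
#' @param substrate_conc reporter substrate concentration (>= 0).
#' @param km Michaelis constant of the reporter substrate with this
#'   protease (> 0), same units as `substrate_conc`.
#' @return the corrected ka (same units as `kapp_prime`).
#' @examples
#' correct_association_constant(3.05e4, substrate_conc = 200, km = 114)
#' @export
correct_association_constant <- function(kapp_prime, substrate_conc, km) {
  if (!is_scalar_number(km) || km <= 0)
    stop_input("km must be > 0")
  if (!is_scalar_number(substrate_conc) || substrate_conc < 0)
    stop_input("substrate_conc must be >= 0")
  kapp_prime * (1 + substrate_conc / km)
}

#' Full progress-curve association pipeline
#'
#' Composes [fit_progress_curve()], [fit_kobs_vs_inhibitor()] and
#' [correct_association_constant()]: fits every curve recorded at a
#' nonzero inhibitor concentration, regresses the fitted kobs values on
#' \[I\] (converted from uM to M), and corrects the slope for substrate
#' competition. Curves at \[I\] = 0 are excluded from the regression
#' (kobs is undefined without inhibitor). A warning is issued when any
#' \[I\]/\[E\] < 1, where the pseudo-first-order assumption is strained.
#'
#' @param curves list of [progress_curve()] sharing the same substrate
#'   concentration; inhibitor concentrations must span >= 3 values.
#' @param km Michaelis constant of the reporter substrate (uM).
#' @return an object of class `association_fit`: list with `kapp_prime`
#'   (1/M/s), `intercept` (1/s), `r_squared`, `substrate_conc` (uM),
#'   `km` (uM), `ka` (1/M/s), `points` (\[I\] in M vs kobs), and
#'   `curve_fits` (the per-curve `progress_fit`s). The invariant
#'   `ka == kapp_prime * (1 + substrate_conc/km)` holds exactly.
#' @export
run_association_pipeline <- function(curves, km) {
  stopifnot(is.list(curves), length(curves) > 0)
  lapply(curves, function(cv) stopifnot(inherits(cv, "progress_curve")))
  s_conc <- unique(vapply(curves, `[[`, 0, "substrate_conc"))
  if (length(s_conc) != 1L)
    stop_input("curves do not share a substrate concentration: %s",
               paste(s_conc, collapse = ", "))
  use <- Filter(function(cv) cv$inhibitor_conc > 0, curves)
  if (length(unique(vapply(use, `[[`, 0, "inhibitor_conc"))) < 3L)
    stop_input("need curves at >= 3 distinct nonzero inhibitor concentrations")
  strained <- vapply(use, function(cv)
    cv$enzyme_conc > 0 && cv$inhibitor_conc / cv$enzyme_conc < 1, TRUE)
  if (any(strained))
    warning(sprintf(
      "%d curve(s) have [I]/[E] < 1; pseudo-first-order assumption strained",
      sum(strained)), call. = FALSE)

  fits <- lapply(use, fit_progress_curve)
  inhibitor_M <- vapply(use, `[[`, 0, "inhibitor_conc") * 1e-6
  kobs <- vapply(fits, `[[`, 0, "kobs")
  reg <- fit_kobs_vs_inhibitor(inhibitor_M, kobs)
  ka <- correct_association_constant(reg$slope, s_conc, km)
  structure(
    list(kapp_prime = reg$slope, intercept = reg$intercept,
         r_squared = reg$r_squared, substrate_conc = s_conc, km = km,
         ka = ka, points = reg$points, curve_fits = fits),
    class = "association_fit")
}

#' @export
print.association_fit <- function(x, ...) {
  cat(sprintf(
    "<association_fit: k'app = %.4g /M/s, ka = %.4g /M/s (Km = %g uM, [S] = %g uM), r^2 = %.4f>\n",
    x$kapp_prime, x$ka, x$km, x$substrate_conc, x$r_squared))
  invisible(x)
}
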