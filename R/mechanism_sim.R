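# Synthetic-data generator. Each simulator draws noise from a sub-seed
# derived from (scenario seed, curve/group index), so output is
# bit-reproducible and adding one series never shifts another's noise.

#' Kinetic simulation scenario
#'
#' Bundles the true mechanism parameters and assay design for
#' [simulate_progress_curves()]. Defaults mirror the characterization
#' conditions the package targets: 200 nM enzyme challenged with inhibitor
#' at 1-10x molar excess, 200 uM reporter substrate with Km = 114 uM, 20 min
#' reads, 2 percent Gaussian signal noise.
#'
#' @param ka_true true second-order association rate constant (1/M/s).
#' @param si_true true stoichiometry of inhibition (>= 1; consumed only by
#'   the titration generator and the ODE stress mode).
#' @param km Michaelis constant of the reporter substrate (uM).
#' @param substrate_conc reporter substrate concentration (uM).
#' @param enzyme_conc protease concentration (uM).
#' @param inhibitor_concs inhibitor concentrations (uM), one curve each.
#' @param v_max_signal maximal substrate-hydrolysis velocity (signal/s) at
#'   saturating substrate; free scale parameter (all recovery targets are
#'   scale-invariant).
#' @param duration read duration (s), or `NULL` (default) to let the
#'   simulator observe ~6 time constants of the slowest curve.
#' @param n_timepoints points per curve, or `NULL` (default) to sample
#'   densely enough that the fastest curve is resolved (several points per
#'   1/kobs), as a kinetic plate-reader protocol would.
#' @param noise_sd_frac Gaussian noise sd as a fraction of each curve's
#'   plateau.
#' @param seed integer seed; fixing it fixes every byte of output.
#' @return an object of class `kinetic_scenario`.
#' @export
kinetic_scenario <- function(ka_true = 8.4e4, si_true = 1.76, km = 114,
                             substrate_conc = 200, enzyme_conc = 0.2,
                             inhibitor_concs = c(1, 2, 4, 6, 8, 10) * 0.2,
                             v_max_signal = 0.002, duration = NULL,
                             n_timepoints = NULL, noise_sd_frac = 0.02,
                             seed = 1L) {
  stopifnot(ka_true > 0, si_true >= 1, km > 0, substrate_conc >= 0,
            enzyme_conc > 0, all(inhibitor_concs > 0), v_max_signal > 0,
            is.null(duration) || duration > 0,
            is.null(n_timepoints) || n_timepoints >= 5, noise_sd_frac >= 0)
  competition <- 1 + substrate_conc / km
  kobs <- ka_true * inhibitor_concs * 1e-6 / competition
  if (is.null(duration)) duration <- 6 / min(kobs)
  if (is.null(n_timepoints)) {
    # several samples per 1/kobs of the fastest curve, bounded for sanity
    n_timepoints <- min(601, max(61, ceiling(duration * max(kobs) / 0.25) + 1))
  }
  structure(
    list(ka_true = ka_true, si_true = si_true, km = km,
         substrate_conc = substrate_conc, enzyme_conc = enzyme_conc,
         inhibitor_concs = inhibitor_concs, v_max_signal = v_max_signal,
         duration = duration, n_timepoints = n_timepoints,
         noise_sd_frac = noise_sd_frac, seed = as.integer(seed)),
    class = "kinetic_scenario")
}

#' Simulate pseudo-first-order inhibition progress curves
#'
#' Inverts the analysis model: for each inhibitor concentration,
#' `kobs = ka_true * [I] / (1 + [S]/Km)` (with \[I\] in M) and
#' `P(t) = (v0/kobs) (1 - exp(-kobs t))` with
#' `v0 = v_max_signal * [S]/(Km + [S])`, plus additive Gaussian noise with
#' sd `noise_sd_frac x plateau`.
#'
#' With `ode = TRUE` the closed form is replaced by a mass-action
#' stress-test mode: protease E and inhibitor I are depleted by
#' `dE/dt = -k_inh E I`, `dI/dt = -si_true k_inh E I` (partition ratio
#' `(SI-1):1` - SI moles of inhibitor consumed per mole of protease
#' trapped), with `k_inh = ka/(1 + S/Km)` and substrate held at its
#' initial (excess) concentration; product accumulates at
#' `v_max_signal * (E/E0) * S/(Km+S)`. Integrated by fixed-step RK4.
#'
#' @param s a [kinetic_scenario()].
#' @param ode logical; use the branched mass-action mode.
#' @return list of [progress_curve()], one per inhibitor concentration.
#' @export
simulate_progress_curves <- function(s, ode = FALSE) {
  stopifnot(inherits(s, "kinetic_scenario"))
  times <- seq(0, s$duration, length.out = s$n_timepoints)
  v0 <- s$v_max_signal * s$substrate_conc / (s$km + s$substrate_conc)
  competition <- 1 + s$substrate_conc / s$km
  lapply(seq_along(s$inhibitor_concs), function(i) {
    I_uM <- s$inhibitor_concs[i]
    kobs <- s$ka_true * (I_uM * 1e-6) / competition
    clean <- if (ode) {
      ode_progress(times, v0, s$ka_true, s$si_true, s$enzyme_conc, I_uM,
                   s$substrate_conc, s$km)
    } else {
      (v0 / kobs) * (1 - exp(-kobs * times))
    }
    plateau <- v0 / kobs
    sig <- clean
    if (s$noise_sd_frac > 0) {
      set.seed(sub_seed(s$seed, i))
      sig <- clean + stats::rnorm(length(times), 0,
                                  s$noise_sd_frac * plateau)
    }
    # measured product signal cannot go negative
    sig <- pmax(sig, 0)
    progress_curve(sprintf("sim_I%g", I_uM), times, sig,
                   inhibitor_conc = I_uM, enzyme_conc = s$enzyme_conc,
                   substrate_conc = s$substrate_conc)
  })
}

# RK4 integration of the branched suicide-substrate system with substrate
# in constant excess. Concentrations in uM; ka in 1/M/s.
ode_progress <- function(times, v0, ka, si, E0, I0, S, km) {
  k_inh <- ka * 1e-6 / (1 + S / km)  # 1/uM/s
  deriv <- function(y) {
    E <- y[1]; I <- y[2]
    dE <- -k_inh * E * I
    c(dE, si * dE, v0 * (E / E0))
  }
  n_sub <- 20L
  y <- c(E0, I0, 0)
  out <- numeric(length(times))
  out[1] <- y[3]
  for (j in seq_len(length(times) - 1L)) {
    h <- (times[j + 1] - times[j]) / n_sub
    for (m in seq_len(n_sub)) {
      k1 <- deriv(y)
      k2 <- deriv(y + h / 2 * k1)
      k3 <- deriv(y + h / 2 * k2)
      k4 <- deriv(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      y[1:2] <- pmax(y[1:2], 0)
    }
    out[j + 1] <- y[3]
  }
  out
}

#' Simulate a stoichiometry-of-inhibition titration
#'
#' Clipped-linear partitioning model: fractional activity
#' `a(r) = max(0, 1 - r/si_true)` at inhibitor:enzyme ratio `r`, plus
#' Gaussian noise. The noiseless series lies exactly on the line up to the
#' x-intercept at `r = si_true`.
#'
#' @param si_true generating stoichiometry of inhibition (>= 1).
#' @param ratios inhibitor:enzyme ratios (default 0-10 by 0.5).
#' @param noise_sd Gaussian noise sd on fractional activity.
#' @param seed integer seed.
#' @param protease_id label for the series.
#' @param enzyme_conc enzyme concentration (uM), metadata only.
#' @return a [titration_series()].
#' @export
simulate_titration <- function(si_true, ratios = seq(0, 10, by = 0.5),
                               noise_sd = 0.01, seed = 1L,
                               protease_id = "sim", enzyme_conc = 0.2) {
  stopifnot(si_true >= 1, all(ratios >= 0), noise_sd >= 0)
  a <- pmax(0, 1 - ratios / si_true)
  if (noise_sd > 0) {
    set.seed(sub_seed(seed, 1L))
    a <- a + stats::rnorm(length(ratios), 0, noise_sd)
  }
  a <- pmax(a, 0)
  titration_series(protease_id, ratios, a, enzyme_conc = enzyme_conc)
}

#' Simulate a first-order inactivation decay
#'
#' `A(t) = 100 exp(-log(2) t / t_half_true)` plus Gaussian noise in
#' percentage points, floored at 0.
#'
#' @param t_half_true generating half-life (min).
#' @param times observation times (min), including 0.
#' @param noise_sd_pct Gaussian noise sd in percentage points.
#' @param seed integer seed.
#' @param condition_kind,condition_value condition metadata.
#' @return a [decay_series()].
#' @export
simulate_decay <- function(t_half_true, times = seq(0, 60, by = 5),
                           noise_sd_pct = 2, seed = 1L,
                           condition_kind = "temperature",
                           condition_value = 60) {
  stopifnot(t_half_true > 0, all(times >= 0), noise_sd_pct >= 0)
  a <- 100 * exp(-log(2) * times / t_half_true)
  if (noise_sd_pct > 0) {
    set.seed(sub_seed(seed, 1L))
    a <- a + stats::rnorm(length(times), 0, noise_sd_pct)
  }
  a <- pmax(a, 0)
  decay_series(condition_kind, condition_value, times, a)
}

#' Simulate a grouped fecal-protease inhibition assay
#'
#' Generates a healthy control group (PBS), a colitis group (DSS) whose
#' mean activity is `fold_dss` times the control, and one
#' "DSS + inhibitor" group per entry of `inhibition_pct` whose mean is the
#' DSS mean reduced by that percentage. Replicate noise is lognormal at
#' the given coefficient of variation (inter-animal variability is
#' multiplicative), mean-preserving, so `noise_cv = 0` reproduces the
#' group means exactly.
#'
#' @param control_mean mean activity of the PBS group.
#' @param fold_dss fold increase of the DSS group over PBS.
#' @param inhibition_pct named numeric vector: percent inhibition of the
#'   DSS activity achieved by each inhibitor.
#' @param n_per_group replicates per group (>= 2).
#' @param noise_cv lognormal coefficient of variation across replicates.
#' @param seed integer seed.
#' @return data.frame of measurements (`group_label`, `replicate_id`,
#'   `activity`) suitable for [summarize_groups()].
#' @export
simulate_fecal_assay <- function(control_mean = 1, fold_dss = 2.2,
                                 inhibition_pct = c(serpin1 = 30,
                                                    serpin2 = 35),
                                 n_per_group = 8, noise_cv = 0.25,
                                 seed = 1L) {
  stopifnot(control_mean > 0, fold_dss > 0, n_per_group >= 2, noise_cv >= 0)
  dss_mean <- control_mean * fold_dss
  means <- c(PBS = control_mean, DSS = dss_mean)
  if (length(inhibition_pct)) {
    nm <- names(inhibition_pct) %||% paste0("inh", seq_along(inhibition_pct))
    means <- c(means, stats::setNames(
      dss_mean * (1 - inhibition_pct / 100), paste0("DSS+", nm)))
  }
  sigma <- sqrt(log(1 + noise_cv^2))
  do.call(rbind, lapply(seq_along(means), function(g) {
    m <- means[g]
    x <- if (noise_cv > 0) {
      set.seed(sub_seed(seed, g))
      m * exp(stats::rnorm(n_per_group, -sigma^2 / 2, sigma))
    } else rep(m, n_per_group)
    data.frame(group_label = names(means)[g],
               replicate_id = sprintf("%s_%d", names(means)[g],
                                      seq_len(n_per_group)),
               activity = x, stringsAsFactors = FALSE)
  }))
}

#' Write simulated assays to the delimited schemas the readers consume
#'
#' @param curves list of `progress_curve` (or NULL).
#' @param path output file path.
#' @return the path, invisibly.
#' @keywords internal
write_progress_table <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(curve_id = cv$curve_id, time_s = cv$times, signal = cv$signal,
               inhibitor_uM = cv$inhibitor_conc, enzyme_uM = cv$enzyme_conc,
               substrate_uM = cv$substrate_conc)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

write_titration_table <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(protease_id = s$protease_id, ratio = s$ratio,
               fractional_activity = s$fractional_activity,
               enzyme_uM = s$enzyme_conc)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

write_decay_table <- function(series, path) {
  if (inherits(series, "decay_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(condition_kind = s$condition_kind,
               condition_value = s$condition_value,
               time_min = s$times, residual_pct = s$residual_activity)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
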