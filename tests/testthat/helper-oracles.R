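# Independent oracles used to cross-check the fitters. These deliberately
# avoid the package's own code paths: brute-force grids and closed-form
# textbook formulas only.

# Dense grid search over (v0, kobs) for the progress-curve model,
# minimizing the residual sum of squares directly; two zoom passes refine
# the coarse grid around its minimum so the (v0, kobs) valley is resolved.
oracle_grid_progress <- function(t, y, v0_range, kobs_range, n_grid = 121) {
  scan <- function(v0_range, kobs_range) {
    v0s <- seq(v0_range[1], v0_range[2], length.out = n_grid)
    ks <- seq(kobs_range[1], kobs_range[2], length.out = n_grid)
    best <- c(NA, NA, Inf)
    for (v0 in v0s) {
      for (k in ks) {
        pred <- (v0 / k) * (1 - exp(-k * t))
        rss <- sum((y - pred)^2)
        if (rss < best[3]) best <- c(v0, k, rss)
      }
    }
    best
  }
  dv <- diff(v0_range) / (n_grid - 1)
  dk <- diff(kobs_range) / (n_grid - 1)
  best <- scan(v0_range, kobs_range)
  for (pass in 1:2) {
    v0_range <- best[1] + c(-3, 3) * dv
    kobs_range <- best[2] + c(-3, 3) * dk
    dv <- diff(v0_range) / (n_grid - 1)
    dk <- diff(kobs_range) / (n_grid - 1)
    best <- scan(v0_range, kobs_range)
  }
  list(v0 = best[1], kobs = best[2], rss = best[3], dv = dv, dk = dk)
}

# Closed-form simple linear regression: slope, intercept, r^2.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  pred <- intercept + slope * x
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Streaming (one-pass Welford) mean, independent of mean()/sum() order.
oracle_stream_mean <- function(x) {
  m <- 0
  for (i in seq_along(x)) m <- m + (x[i] - m) / i
  m
}

make_curve <- function(v0, kobs, times = seq(0, 1200, by = 20), noise_sd = 0,
                       seed = NULL, baseline = 0, inhibitor = 1,
                       enzyme = 0.2, substrate = 200) {
  clean <- baseline + if (kobs > 0) (v0 / kobs) * (1 - exp(-kobs * times))
                      else v0 * times
  if (noise_sd > 0) {
    set.seed(seed)
    clean <- clean + rnorm(length(times), 0, noise_sd)
  }
  progress_curve("test", times, clean, inhibitor_conc = inhibitor,
                 enzyme_conc = enzyme, substrate_conc = substrate)
}

random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
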