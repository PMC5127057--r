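---
title: "Methods: progress-curve kinetics and biochemical profiling of serpins"
author: "serpintools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: progress-curve kinetics and biochemical profiling of serpins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpintools)
```

# The system being modelled

Serpins (serine protease inhibitors) act by an irreversible
suicide-substrate mechanism. The target protease attacks the serpin's
exposed reactive-center loop (RCL) as if it were a substrate; cleavage of
the scissile (P1–P1′) bond triggers a conformational collapse that drags
the protease along and traps it in a covalent complex. Two outcomes
compete at every encounter: trapping, or completed cleavage that releases
an inactive serpin. This branching is why the stoichiometry of inhibition
(SI) can exceed one, and why the kinetics are characterized by an
association rate constant rather than an equilibrium constant.

`serpintools` implements the downstream *analysis* of the standard
characterization assays. It does not model the assay chemistry itself:
signals enter as plate-reader time series, titrations, decay tables and
grouped activity measurements.

# Progress-curve kinetics

## Model

Under pseudo-first-order conditions ([I] ≥ [E], substrate in excess) the
product signal of a reporter-substrate reaction in the presence of an
irreversible inhibitor follows

$$P(t) = \frac{v_0}{k_{obs}}\left(1 - e^{-k_{obs} t}\right),$$

where $v_0$ is the uninhibited hydrolysis velocity (signal/s) and
$k_{obs}$ (s⁻¹) the pseudo-first-order rate at which active protease
disappears. The plateau is $v_0/k_{obs}$ and the initial slope is $v_0$.
Across inhibitor concentrations, $k_{obs}$ is linear in [I]; the slope is
the *apparent* second-order constant $k'_{app}$, attenuated by the
reporter substrate competing for the active site. The true association
constant is

$$k_a = k'_{app}\left(1 + \frac{[S]}{K_m}\right).$$

$K_m$ is a property of the protease–substrate pair and is an *input* here
(114 µM and 270 µM for the two target proteases the defaults emulate);
estimating it from saturation data is out of scope.

## Numerical choices

* `fit_progress_curve()` uses bounded nonlinear least squares
  (`stats::nls`, `"port"`, $v_0, k_{obs} \ge 0$), tolerance 1e-10, up to
  10,000 iterations. The model is evaluated as
  $v_0\,t\,\phi(k_{obs}t)$ with $\phi(x) = (1-e^{-x})/x$ computed by a
  series near 0, so the $k_{obs}\to 0$ limit degenerates smoothly to the
  straight line $P = v_0 t$ instead of overflowing.
* Starting values are derivative-free: $v_0$ from the slope of the first
  10 % of points, $k_{obs}$ from a log-linear fit of (plateau − P). If
  `nls` fails, a Nelder–Mead pass on the same objective is attempted and
  the result is flagged via `converged`.
* A baseline offset is estimated only when the t = 0 signal is nonzero
  (`baseline = "auto"`); instruments report either raw or blanked
  absorbance and the sources do not say which was used, so the code
  handles both and records the choice in the fit.
* The $k_{obs}$–[I] regression keeps a free intercept. Forcing the line
  through the origin would be the stronger assumption; the intercept is
  reported as a diagnostic (a large one flags reversible or slow-binding
  behaviour that the model excludes).
* Curves at [I] = 0 are never used in the regression — $k_{obs}$ is
  undefined without inhibitor — and curves with [I]/[E] < 1 only generate
  a warning, since the pseudo-first-order assumption degrades gradually.

# Stoichiometry of inhibition

Fractional activity $a = v_i/v_0$ is regressed on the molar ratio
$r = [I_0]/[E_0]$; SI is the x-intercept $-b/m$. Points with
$a \le 0.05$ (default, configurable) are excluded: beyond the
equivalence point the titration is pinned near zero and the plateau
would bias the line. One subtlety: on coarse titrations of a tight
inhibitor (SI near 1) fewer than three points can survive the floor. In
that case the lowest-ratio sub-floor points are pulled back in until
three are available — the first point at the floor is the equivalence
point itself and still lies on the line, so exactness on noiseless data
is preserved. The regression abscissa is the ratio, not an absolute
concentration, which makes SI invariant to rescaling all activities or
concentrations by a common factor.

# Stability profiling

Relative-activity profiles are normalized so the optimal condition reads
100 %. Inactivation time courses are summarized by a single first-order
decay $A(t) = 100\,e^{-kt}$, $t_{1/2} = \ln 2/k$ — the only model
consistent with reporting one half-life per condition, and the standard
operational model for thermal denaturation. No thermodynamic analysis
(T_m, ΔG, Arrhenius) is attempted.

Two numerical decisions matter:

* **Weighted log-linear fitting.** The decay rate is estimated by linear
  regression of $\log A$ on $t$, restricted to points above a 5 %
  detection floor and weighted by $A^2$. The weights are the delta-method
  variance stabilization for *additive* measurement noise on an
  exponential: unweighted log-linear fitting lets the nearly-decayed tail
  points, whose logarithms are noisiest, dominate the slope. At the 2 %
  (percentage-point) noise level the recovery tests use, the unweighted
  fit misses the generating half-life by up to ~30 % on unlucky seeds,
  while the weighted fit stays within 10 %; the package's tests measure
  exactly this. A full nonlinear option (`method = "nonlinear"`) is
  available but is not the default, to keep the estimator closed-form and
  deterministic.
* **Censoring.** When the residual activity at the last observed time is
  still above 50 %, the half-life is not quantifiable within the window:
  the result carries `censored = TRUE` and `t_half` equal to the window
  length, to be read as "> t_max" — the reporting convention used for
  highly stable conditions (e.g. "> 480 min" over an 8 h experiment).
  Whenever the true half-life is at least twice the observation window,
  this rule fires by construction ($A(t_{max}) \ge 2^{-1/2} > 50\,\%$).

# Activity and inhibition summaries

`percent_residual()` reports both residual percent (control = 100 %) and
its complement, because "reduced **to** 50 %" and "reduced **by** 30 %"
coexist in assay reports and the package deliberately does not interpret
ambiguous phrasing. `summarize_groups()` produces the per-group
mean ± SEM table (sample SD, $n-1$); significance testing
(Kruskal–Wallis, Dunn) is left to standard routines, which consume this
table directly.

# The synthetic-data generator

The generator's defaults *are* the assay conditions the analysis targets:
0.2 µM enzyme (0.3 µM for the second protease), inhibitor at 1–10× molar
excess over enzyme, 200 µM reporter substrate, $K_m$ = 114 µM, 2 %
Gaussian signal noise on progress curves, 1 % on titrations, 2 percentage
points on decays, and n = 8 lognormal replicates per group for the
grouped assay.

* **Progress curves** invert the analysis model exactly:
  $k_{obs,i} = k_a [I]_i/(1+[S]/K_m)$,
  $P_i(t) = (v_0/k_{obs,i})(1-e^{-k_{obs,i}t})$ plus Gaussian noise
  proportional to each curve's plateau. The absolute signal scale
  (`v_max_signal`) is a free parameter; every recovery target is
  scale-invariant, so nothing depends on it.
* **Sampling schedule.** The read duration and density default to
  "observe ~6 time constants of the slowest curve, resolve the fastest
  with several points per $1/k_{obs}$". A fixed 20-minute, 61-point
  schedule — a plausible instrument default — leaves fast curves
  (e.g. $k_{obs} \approx 0.45$ s⁻¹ at the highest inhibitor
  concentration of the faster protease) fully saturated by the first
  sample, and no estimator can recover a rate from a step function. The
  adaptive default is what a kinetic plate-reader protocol does in
  practice; both knobs can be pinned explicitly.
* **Titrations** use the clipped-linear partitioning model
  $a(r) = \max(0, 1 - r/SI)$.
* **Decays** are exact exponentials plus additive noise, floored at 0.
* **Grouped assays** draw mean-preserving lognormal replicates. The
  default CV of 25 % is a choice: the emulated study reports only
  mean ± SEM, and 25 % is typical inter-animal variability for fecal
  enzyme assays. With `noise_cv = 0` the group means reproduce the
  stated fold effects exactly.
* **Reproducibility.** One integer seed; every sub-series derives its
  RNG state from (seed, index), so adding a curve or group never shifts
  the noise of the others, and fixed seed means byte-identical output.
* A mass-action ODE mode (`ode = TRUE`, fixed-step RK4, partition ratio
  $(SI-1):1$, substrate held at its excess value) exists for
  stress-testing the closed-form assumption; it is not used by the
  recovery tests.

What a green recovery test establishes is that the *pipeline inverts its
own generating model* at realistic noise; it does not validate the model
against real instrument exports, drifting baselines, substrate depletion
or inner-filter effects, which the generator does not emulate.

# Sequence analyses

* `global_align()` is a three-state Gotoh dynamic program (global, affine
  gaps costing open + L·extend, end gaps penalized), BLOSUM62 by default
  with gap open 10 / extend 0.5 — the classic pairwise defaults, since
  the emulated analyses used external aligners without stating
  parameters. Tie-breaking is deterministic (diagonal > up > left), and
  inputs are internally put in a canonical order so that
  `global_align(a, b)` and `global_align(b, a)` return mirror-identical
  alignments. Percent identity divides by aligned columns by default;
  published identity percentages rarely state their denominator, so a
  shorter-sequence option is provided and exact reproduction of any
  particular published percentage is not promised.
* `label_p_positions()` is pure Schechter–Berger arithmetic: residue
  $j \le P1$ gets label $P(p_1-j+1)$, residue $j > P1$ gets
  $P(j-p_1)'$.
* `fragment_mass()` uses the standard monoisotopic (or average) residue
  mass table plus one water. Cysteine is unmodified by default — the
  cleavage-band mass that the site assignment relies on predates any
  alkylation step — with carbamidomethylation behind a flag.
* `map_cleavage_site()` enumerates candidate scissile bonds (optionally
  within the annotated RCL), ranks matches by |ppm error| and attaches
  P-labels when the P1 index is known. No match within tolerance returns
  an empty table, not an error: absence of a mass match is a result.
* `annotate_rcl()` transfers an RCL span (and P1) from an annotated
  reference through the global alignment; `find_hinge()` flags the first
  run of ≥ 4 small residues (G/A/S/V), the hinge signature of inhibitory
  serpins. Real serpin sequences are optional user input; the package
  ships only synthetic demonstration sequences.

# Units and conventions

Seconds and µM are canonical for kinetics; minutes for stability tables
(hours accepted on input and converted); rate constants in M⁻¹ s⁻¹
(inhibitor concentrations are converted to molar inside the regression);
1-based inclusive residue coordinates everywhere.

# Known limitations

* Irreversible one-step association only: no slow-binding, reversible or
  two-step induced-fit models.
* SI is the operational x-intercept; it is not decomposed into a
  mechanistic partition ratio.
* The decay model is single-exponential; biphasic inactivation would be
  summarized by an effective half-life and flagged only by a poor r².
* Percent-identity values depend on aligner parameters and denominator
  conventions and are not comparable across tools without care.
* The CLI's `simulate` subcommand covers the four assay generators with
  flat key–value scenario files; nested configuration is out of scope.
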