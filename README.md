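# serpintools

Quantitative analysis of serpin-class protease inhibitors for enzymology
and protein-biochemistry labs. Serpins inhibit serine proteases by an
irreversible *suicide-substrate* mechanism: the protease attacks the
serpin's exposed reactive-center loop (RCL), cleaves it, and is trapped in
a covalent complex. Characterizing such an inhibitor means answering four
questions, and this package implements the standard analysis for each:

1. **How fast does it inhibit?** Progress-curve kinetics under
   pseudo-first-order conditions. Each product-accumulation trace recorded
   at inhibitor concentration [I] is fit to

   P(t) = (v₀ / k_obs) · (1 − e^(−k_obs · t)),

   the k_obs values are regressed on [I] (slope = k′_app), and the
   competing chromogenic substrate is corrected for with

   k_a = k′_app · (1 + [S]/K_m),

   giving the true second-order association rate constant k_a (M⁻¹ s⁻¹).
2. **How much inhibitor does it take?** The stoichiometry of inhibition
   (SI), estimated as the x-intercept of the linear regression of
   fractional activity on the inhibitor:enzyme molar ratio [I₀]/[E₀].
   SI > 1 means part of the serpin pool is turned over as a substrate.
3. **How robust is it?** Temperature/pH activity profiles (optimum defined
   as 100 %) and first-order inactivation half-lives t½ = ln 2 / k, with
   censored reporting ("> t_max") when the decay is too slow to quantify
   within the observation window.
4. **Where is it cleaved?** Pairwise global alignment (Needleman–Wunsch
   with affine gaps) and percent identity, RCL annotation by projection
   from an annotated reference, Schechter–Berger P-position labels, and
   localization of the scissile bond from an observed fragment mass.

A seeded synthetic-data generator (`kinetic_scenario()`,
`simulate_progress_curves()`, `simulate_titration()`, `simulate_decay()`,
`simulate_fecal_assay()`) emulates every assay the pipeline consumes, so
the entire workflow is exercisable — and is tested by parameter recovery —
without any external data.

## Worked example

Simulate a full association-kinetics experiment (six progress curves,
[I] = 1–10 × [E], 200 µM substrate, K_m = 114 µM, 2 % signal noise) with a
generating k_a of 8.4 × 10⁴ M⁻¹ s⁻¹, then recover it:

```r
library(serpintools)

sc <- kinetic_scenario(ka_true = 8.4e4, km = 114, substrate_conc = 200,
                       enzyme_conc = 0.2, noise_sd_frac = 0.02, seed = 42)
curves <- simulate_progress_curves(sc)
fit <- run_association_pipeline(curves, km = 114)
fit
#> <association_fit: k'app = 2.894e+04 /M/s, ka = 7.971e+04 /M/s (Km = 114 uM, [S] = 200 uM), r^2 = 0.9979>
fit$curve_fits[[1]]
#> <progress_fit 'sim_I0.2': v0 = 0.001239 /s, kobs = 0.005947 /s, rss = 0.00417>
```

The recovered k_a (7.97 × 10⁴) is within 5 % of the generating value; the
per-curve fit reports the uninhibited hydrolysis velocity v₀ (signal/s)
and the pseudo-first-order inhibition rate k_obs (s⁻¹) for the weakest
inhibitor concentration.

Stoichiometry and stability, from the bundled example tables (synthetic,
generated by the package's own simulators):

```r
tit <- read_titration_table(system.file("extdata", "example_titration.csv",
                                        package = "serpintools"))
fit_si(tit[[1]])
#> <si_result 'HNE': SI = 1.737 (slope -0.5815, r^2 = 0.9990, n = 4)>

dec <- read_decay_table(system.file("extdata", "example_decays.csv",
                                    package = "serpintools"))
fit_half_life(dec[[2]])
#> <half_life_result temperature = 70: t1/2 = 21.01 min (k = 0.033 /min, r^2 = 0.9292)>

# a decay still above 50% at the end of an 8 h window is censored:
fit_half_life(decay_series("pH", 7, seq(0, 480, 60),
                           100 * 2^(-seq(0, 480, 60) / 4000)))
#> <half_life_result pH = 7: t1/2 > 480 min (censored)>
```

The SI of 1.74 means ~1.7 serpin molecules are consumed per protease
inhibited; the 70 °C half-life of 21 min is the time for the inhibitory
activity to drop to 50 %.

Grouped activity assays (e.g. fecal protease activity in a colitis model,
n = 8 per group, lognormal inter-animal noise):

```r
g <- summarize_groups(simulate_fecal_assay(seed = 42))
g
#>   group_label n mean_activity        sem
#> 1         PBS 8      1.047900 0.10920418
#> 2         DSS 8      2.078224 0.17127946
#> 3 DSS+serpin1 8      1.576688 0.09716829
#> 4 DSS+serpin2 8      1.506754 0.04619648
fold_change(g[g$group_label == "DSS", ], g[g$group_label == "PBS", ])
#> [1] 1.983229
```

## Command line

All functionality is reachable through one entry point,
`serpintools::run_cli()`:

```sh
Rscript -e 'quit(save="no", status=serpintools::run_cli())' -- \
    fit-kinetics --curves curves.csv --km-uM 114 --out fit.json
```

Subcommands: `simulate`, `fit-kinetics`, `fit-si`, `fit-stability`,
`profile`, `summarize-activity`, `identity`, `map-cleavage`. Every run
writes JSON with a provenance block and is byte-reproducible given the
same inputs and `--seed`. A launcher script is installed at
`system.file("exec", "serpintools", package = "serpintools")`.

## Vignette

`vignettes/serpin-kinetics.Rmd` documents the models and their
assumptions, the synthetic-data generator's stated world, numerical
choices (fit initialization, censoring, the weighted log-linear decay
fit), and known limitations.
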