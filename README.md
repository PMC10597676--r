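# traitspectrum

Trait-resolved community size spectrum modelling for marine food webs.

Size-structured ("size spectrum") models describe a marine community by
the abundance density N(w) of individuals of body mass w, and move
energy up the spectrum through size-based predation. Almost all of them
assume every predator eats prey a fixed factor smaller than itself — a
constant predator–prey mass ratio (PPMR), typically 100 for fish. Real
feeding is far more diverse: high-activity cephalopods (squids) chase
prey close to their own size (PPMR ≈ 25) and climb trophic levels as
they grow, while low-activity cephalopods (e.g. many octopods) keep
eating small zooplankton-sized prey throughout life, so their PPMR
*grows* with body size and their trophic position barely changes. The
same contrast describes planktivorous fishes and baleen whales.

`traitspectrum` is for modellers who want to ask what this diversity of
size-based feeding does to ecosystem structure and function. It
provides:

* a deterministic solver for the McKendrick–von Foerster equation with
  a growth-diffusion term, for four dynamic functional groups
  (zooplankton, low- and high-activity cephalopods, fish) over a static
  phytoplankton spectrum:

  ∂N/∂t = −∂(gN)/∂w − μN + ½ ∂²(fN)/∂w²,

  with growth g = K·V(w)·D(w,t), search rate V = y·w^α, lognormal
  size-selection kernels φ(w,w′) centred at the preferred PPMR β(w)
  (constant or allometric, β(w) = β₀(w/w_min)^γ), predation mortality
  as the prey-side view of the same encounter integrals, power-law
  senescence, and constant recruitment pinned at each group's smallest
  size class;
* the control vs trait-resolved simulation experiment: 3 fish-like
  control runs against the 27-run feeding+growth factorial (recruitment
  scalar × high-activity PPMR × low-activity PPMR-curve scaling), plus
  a feeding-only variant;
* emergent ecosystem metrics: biomass, somatic production, turnover
  time B/P, biomass stability (1/CV of total annual biomass),
  size-spectrum slope and intercept, and per-group trophic-position and
  realised-PPMR curves;
* synthetic input generators (seeded, reproducible) so the whole
  analysis runs without any external data.

## Worked example

A 200-year run of the default trait-resolved community (weekly step,
0.1 log10-g bins, metrics over the final 100 years):

```r
library(traitspectrum)
cfg <- default_model_config(years = 200, averaging_years = 100,
                            label = "demo")
sim <- run_simulation(cfg)
sim
#> sim_result 'demo': 200 yr
#>   zooplankton            final biomass 0.01486 g m-3
#>   ceph_low_activity      final biomass 0.06769 g m-3
#>   ceph_high_activity     final biomass 0.0006967 g m-3
#>   fish                   final biomass 0.06941 g m-3
#>   clipped biomass 0; max CFL 0.039
```

The four groups coexist; the high-activity group carries the smallest
standing stock (its fast growth burns through biomass), and the solver
stayed well inside its stability limit (CFL 0.039) without clipping any
negative densities.

```r
compute_run_metrics(sim)[, c("total_biomass", "production",
                             "turnover_time", "cv_biomass",
                             "spectrum_slope")]
#>  total_biomass production turnover_time cv_biomass spectrum_slope
#>          0.114    0.00601            19      0.257          -2.05
```

Community biomass is 0.114 g m⁻³ with a spectrum slope of −2.05 —
close to the Sheldon null of −2 (equal biomass per log mass interval).
The CV of 0.26 says total biomass oscillates visibly around its mean.
The emergent trophic roles reproduce the trait design:

```r
ms <- mean_state(sim)
relative_trophic_position("ceph_high_activity", ms)  # and low_activity
#> HA TP at 0.1 g / 1 kg: 3.36 / 4.37   (steep trophic allometry)
#> LA TP at 0.1 g / 1 kg: 2.55 / 3.34   (lower, flatter)
realised_ppmr("ceph_high_activity", ms)              # and low_activity
#> realised PPMR at 1 kg: HA 8, LA 152000
```

High-activity cephalopods feed at high trophic position on near-own-
size prey; low-activity cephalopods sit lower in the web eating prey
five orders of magnitude smaller.

The full experiment contrasts the 27-run feeding+growth set against
the 3 controls and summarizes percent changes of set medians:

```r
base <- default_model_config()   # 1000 yr, final-500-yr averaging
res <- run_experiment(build_control_set(base), build_fg_set(base))
res$summary
```

A command-line front end with `synth`, `run`, `sweep`, `metrics` and
`experiment` verbs lives at
`system.file("cli", "traitspectrum.R", package = "traitspectrum")`.

## Layout

* `R/`, `src/` — solver, trait configuration, experiment builders,
  metrics, synthetic inputs, I/O (compiled inner loop under `src/`)
* `vignettes/trait-resolved-size-spectra.Rmd` — model equations,
  defaults and their rationale, numerics, experiment design, known
  limitations
* `tests/testthat/` — unit and property tests (analytic oracles for
  kernels, advection, diffusion, decay, mass balance and trophic
  identities) plus the full-scale acceptance checks
* `inst/cli/traitspectrum.R` — command-line front end
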