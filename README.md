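# pHendo

Kinetic modelling and analysis of activity-dependent synaptic vesicle
endocytosis measured with pHluorin reporters.

## The problem

pHluorin fused to a vesicular transporter (e.g. vGlut-pHluorin) is
quenched in the acidic vesicle lumen, brightens ~20-fold on exocytosis,
and is requenched by reacidification after the vesicle is retrieved.
After a train of action potentials (APs) the bouton-averaged
fluorescence ΔF decays as a single exponential whose time constant
τ_endo reports endocytosis. That time constant is not fixed: it is
tuned by activity in two opposing phases —

* an **acceleration** that builds over the first ~15–25 APs at
  physiological temperature, persists for ~20 s after a burst and is
  dissipated by ~30 s (a Ca²⁺-triggered, dynamin-1
  phosphostate-dependent switch), and
* an approximately **linear slowing** with AP number (slope in s/AP)
  that steepens with external Ca²⁺ and is abolished by EGTA.

pHendo is for researchers who fit and interpret such traces. It
provides:

* a stochastic per-vesicle simulator of ΔF traces
  (available → surface → internalised → reacidified → re-primed, with
  recycling) whose effective time constant per burst is

  `τ_eff = τ₁ · (1 − α_max · a) + m · (n_AP − 1)`,

  where `a ∈ [0, 1]` is a saturating acceleration state incremented per
  AP (`a ← a + δ·(1 − a)`) that relaxes between events by
  `exp(−(Δt/τ_pers)^h)`;
* the standard decay-fitting protocols: single exponential with a
  reacidification temporal offset (~2.5 s at 37 °C, ~5 s at 30 °C),
  amplitude-normalised 1/Rate linear fits for compressed inter-burst
  windows, the remaining-fluorescence metric for single-AP responses,
  and rising-exponential fits of bafilomycin traces (recycling-pool
  size and exocytic rate);
* a closed-form biexponential endocytosis + reacidification model,
  `F(t) = (τ_e e^(−t/τ_e) − τ_r e^(−t/τ_r)) / (τ_e − τ_r)`, and a
  fit-bias analysis quantifying the τ error introduced by
  mis-specified reacidification;
* the analysis pipeline: tuning curves of τ vs AP number with per-cell
  normalisation and OLS slope/intercept, τ vs endocytic load,
  burst-train persistence protocols, genotype and calcium/EGTA
  presets, and population statistics (mean/SEM/CV, >3 SD outlier rule,
  one-sample/paired t and Kolmogorov–Smirnov tests).

Shipped parameter defaults (`inst/extdata/defaults_37C.yaml`,
`defaults_30C.yaml`) are produced by `calibrateDefaults()`, which
root-finds the kinetic parameters so that the *measured* population
behaviour — fits applied to simulated traces, averaged over the
cell-to-cell parameter distribution — reproduces the benchmark
physiology (42 % acceleration from 5 to 25 AP, 18 % slowing by 100 AP,
55 % more by 300 AP, a 0.058 s/AP population slope at 30 °C, and the
20 s/30 s persistence bounds).

## Worked example

```r
library(pHendo)

cell <- defaultKinetics("37C")
cell
#> CellKinetics: tau1 = 12 s, slope = 0.01555 s/AP
#>   acceleration: alpha_max = 0.6762 , delta_a = 0.1303 , tau_pers = 23.28 s (shape 5.88 )
#>   reacidification: 1.6 s; pool: 1200 vesicles, p_release = 0.05

tc <- normalizeCurve(
  runProtocolSuite(cell, stimuli = c(5, 25, 100), seed = 1),
  reference = 100)
tc
#> TuningCurveResult for cell
#>  n_ap freq   tau  tau_se adj_r2 converged peak_dF norm_tau
#>     5   10 8.027 0.12906 0.9897      TRUE   212.3   1.4767
#>    25   10 4.493 0.06107 0.9937      TRUE   740.8   0.8266
#>   100   10 5.436 0.15120 0.9729      TRUE   748.1   1.0000

percentChange(curveTaus(tc)[["5"]], curveTaus(tc)[["25"]], "accel")
#> [1] 44.02523
```

Reading the output: each row is one stimulus, fitted from the
(repeat-averaged) post-stimulus decay by the offset-exponential
protocol. The time constant falls from 8.0 s at 5 AP to 4.5 s at 25 AP
(a 44 % acceleration for this cell and seed) and rises again by 100 AP
— the two-phase tuning of endocytosis. `norm_tau` is each stimulus
relative to the cell's own 100 AP value, the convention used to
compare cells.

The fit-bias analysis reproduces the classic sanity check that a 1 s
change in reacidification barely corrupts a 10 s endocytosis estimate:

```r
reacidBias(10, 2.6, 1.6)
#> [1] 7.876901
#> attr(,"raw_bias")
#> [1] 11.70994
```

i.e. fitting a trace whose true reacidification is 2.6 s with a
protocol configured for 1.6 s inflates the fitted τ by about +8 %.

A thin command-line front end over the same functions is installed at
`inst/scripts/phendo` (subcommands `simulate`, `fit`, `protocol`,
`bias-scan`, `fixtures`).

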