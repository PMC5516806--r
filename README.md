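# tandemtox

Kinome occupancy profiling and tandem kinetic pathway models for
kinase-inhibitor systems toxicology.

Multi-kinase inhibitors such as sunitinib bind dozens of kinases beyond
their intended targets, and some of those off-target interactions drive
clinically limiting adverse reactions. `tandemtox` implements the in-silico
workflow for tracing such reactions to a mechanism:

1. **Occupancy profiling.** For each kinase with a measured dissociation
   constant K_d, the fraction occupied at the clinical unbound steady-state
   exposure C_p,u,ss is C/(K_d + C). Comparing the profiles of two drugs
   that share primary targets but differ in tolerability shortlists the
   off-target kinases occupied by the toxic drug only.
2. **IC50 fitting.** In-vitro inhibition curves (remaining-ATP signal vs
   inhibitor concentration) are fitted with a four-parameter logistic,
   `bottom + (top − bottom) / (1 + (c/IC50)^h)`, by uniformly weighted
   nonlinear least squares with non-negative plateaus.
3. **Tandem pathway simulation.** Three compact kinetic ODE models — the
   glycogen-phosphorylase regulatory cascade with competitive inhibition of
   phosphorylase kinase (PHK, rate `Vmax·S / (Km·(1 + I/Ki) + S)`, default
   Ki = 5.5 μM), the oxidative pentose-phosphate pathway (G6PD + 6PGD, the
   cell's NADPH source), and glutathione redox cycling (GPx/GR with an
   optional vitamin-E node that quenches H2O2 directly) — are chained
   *without* merging their equations. Only the fold-change of an interface
   metabolite crosses each boundary: drug → lower G6P endpoint → scaled
   G6P supply → lower NADPH/NADP+ ratio → scaled NADPH supply → lower GSH.
   Because only relative changes propagate, the models may live on
   different concentration scales; fold-changes are exactly invariant to
   rescaling any one model's units.

The predicted sequence — glycogen accumulation, G6P depletion, NADPH loss,
GSH loss, and restoration of GSH by a vitamin-E hydrogen-peroxide quench —
is the mechanistic chain linking competitive PHK inhibition to oxidative
stress, and the package's tests pin each link down quantitatively.

The package is written tidyverse-style: data frames in, tibbles out,
`tidy()`/`glance()` on fits, `autoplot()` on trajectories, dose scans and
fitted curves, and seedable synthetic-data generators so the whole pipeline
runs without any external download.

## Worked example

```r
library(tandemtox)

# A synthetic two-drug kinome: 50 kinases, 3 shared primary targets,
# 4 off-targets bound by drug A only.
gen <- generate_kinome_table(kinome_scenario(seed = 1))
pa  <- occupancy_profile(gen$affinities, gen$exposures, "drug_a")
pb  <- occupancy_profile(gen$affinities, gen$exposures, "drug_b")
differential_candidates(pa, pb)
#> # A tibble: 4 × 4
#>   kinase_id occupancy_a occupancy_b delta
#>   <chr>           <dbl>       <dbl> <dbl>
#> 1 KIN005          0.735           0 0.735
#> 2 KIN006          0.521           0 0.521
#> 3 KIN004          0.519           0 0.519
#> 4 KIN007          0.511           0 0.511
```

The four shortlisted kinases are exactly the planted off-targets: each is
majority-occupied by drug A at its clinical exposure (occupancy ≥ 0.5)
while drug B shows no measurable binding.

```r
# IC50 from a noisy synthetic inhibition assay (truth 5.5 uM, 5% CV)
fit <- fit_ic50(generate_assay_curve(
  assay_scenario(true_ic50 = 5.5, noise_cv = 0.05, seed = 7))$assay)
glance(fit)
#> # A tibble: 1 × 7
#>    ic50  hill   rss sigma     n converged extrapolated
#>   <dbl> <dbl> <dbl> <dbl> <int> <lgl>     <lgl>
#> 1  5.24 0.731  145.  5.38     9 TRUE      FALSE

# End-to-end tandem dose scan: drug -> glycogen cascade -> PPP -> GSH
scan <- run_tandem(tandem_chain(), drug_grid = c(0, 1, 10, 100))
dplyr::select(scan, drug_conc, glycogen, g6p_fold, nadph_ratio_fold, gsh)
#> # A tibble: 4 × 5
#>   drug_conc glycogen g6p_fold nadph_ratio_fold   gsh
#>       <dbl>    <dbl>    <dbl>            <dbl> <dbl>
#> 1         0    5000     1                1      180.
#> 2         1    5148.    0.987            0.988  180.
#> 3        10    5941.    0.914            0.920  179.
#> 4       100    7069.    0.808            0.819  177.
```

At 100 μM drug (≈18 × Ki) glycogen has accumulated 41% above baseline,
the G6P endpoint has dropped to 81% of baseline, the steady-state
NADPH/NADP+ ratio follows it down, and reduced glutathione declines —
each fold-change is the quantity handed across a tandem interface.
`autoplot(scan)` draws the full dose-response panel;
`gsh_vs_vitamin_e()` shows the antioxidant rescue under reduced NADPH
supply.

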