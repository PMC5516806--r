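---
title: "Methods: occupancy profiling and tandem pathway modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy profiling and tandem pathway modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemtox)
```

`tandemtox` models how off-target inhibition of phosphorylase kinase (PHK)
by a multi-kinase inhibitor propagates through glycogen metabolism and the
pentose-phosphate pathway into the glutathione redox system. This vignette
is the package's account of the science: the models, their assumptions,
the tunable parameters, the numerical choices, and what the synthetic-data
round-trips do and do not demonstrate.

## Occupancy profiling

At pharmacokinetic steady state the free intracellular drug concentration
equilibrates with the unbound plasma concentration $C_{p,u,ss}$, so the
fraction of a kinase occupied is the equilibrium binding isotherm

$$\theta = \frac{C_{p,u,ss}}{K_d + C_{p,u,ss}}.$$

`compute_occupancy()` is exactly this expression; `occupancy_profile()`
applies it across a panel. A censored $K_d$ ("no measurable binding") maps
to occupancy 0 rather than being dropped, so two drugs' profiles stay
comparable over the same kinase universe.

`differential_candidates()` shortlists kinases with
$\theta_A \ge$ `min_occ_a` and $\theta_B \le$ `max_occ_b`, ranked by
$\theta_A - \theta_B$ (ties broken lexicographically so output is
deterministic). There is no canonical threshold pair for "preferential
inhibition"; the defaults (0.5, 0.1) encode *majority occupancy by the
poorly tolerated drug, near-absent occupancy by the comparator* and are
exposed as ordinary arguments. With the bundled synthetic two-drug panel
these defaults recover exactly the planted off-target set, a four-kinase
shortlist analogous to a real sunitinib/sorafenib comparison.

## IC50 fitting

Inhibition assays report remaining substrate (e.g. residual ATP in a
luminescent kinase assay) versus inhibitor concentration. `fit_ic50()`
fits the four-parameter logistic

$$y(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
  {1 + (c/\mathrm{IC50})^{h}}$$

by uniformly weighted nonlinear least squares. Choices that matter:

* **Optimizer.** Levenberg-Marquardt (`minpack.lm`), multi-started from
  seven log-spaced IC50 guesses spanning the assayed concentrations, with
  IC50 parameterized on the log scale. The contract is the minimized
  residual sum of squares, not the particular minimizer.
* **Plateau constraints.** `top` and `bottom` are constrained
  non-negative: the signal is a concentration readout and cannot be
  negative, and an unconstrained lower plateau is poorly identified when
  the curve's tail is shallow. The Hill slope is constrained positive.
* **Hill slope.** Free by default; `fix_hill = 1` supports the common
  single-site convention. Noise-free synthetic curves are recovered to
  better than $10^{-4}$ relative error for $h \in \{0.5, 1, 2\}$.
* **Degeneracy.** A flat response vector (relative spread below
  $10^{-8}$) is rejected as non-identifiable rather than returning an
  arbitrary IC50; non-convergence is flagged, with parameters returned
  under a warning.

## The three kinetic models

All models use μM and minutes, no compartment volumes, and are integrated
with `deSolve::lsoda` (stiff-capable). Their parameter defaults are
self-consistent reference sets constructed so each model has a clean,
exactly known baseline; they are stand-ins for liver-like physiology, not
fitted measurements, and every default is documented in the constructors
(`glycogen_params()`, `ppp_params()`, `gsh_params()`). Perturbing them
with `jitter_params()` (log-normal, unit mean) is the package's robustness
probe: the qualitative claims below survive 20% parameter jitter.

### Glycogenolysis cascade

States: active/inactive glycogen phosphorylase (GPa/GPb), active/inactive
glycogen synthase (GSa/GSb), glycogen (glucosyl units), G6P. The drug
competitively inhibits PHK,

$$v_{PHK} = \frac{V_{max}\,[GPb]}{K_m\,(1 + I/K_i) + [GPb]},
\qquad K_i = 5.5\ \mu M,$$

raising the apparent $K_m$ only. The rate law is written with respect to
the protein substrate; a competitive term at the ATP site has the same
algebraic form with $S$ reinterpreted, so the dose-response shape is
unaffected. A shared phosphatase (PP1) reactivates GPb and activates GSb;
GS inactivation is coupled proportionally to scaled PHK activity — the
minimal one-parameter mechanism that makes PHK inhibition *raise* GS
activity. Glycogen synthesis saturates as $(1 - gly/gly_{cap})$ so
accumulation is bounded; the capacity sits 4x above baseline and is
inactive there. G6P is supplied at a constant lumped-hexokinase flux and
drained first-order into glycolysis.

Two conservation laws (GPa+GPb, GSa+GSb) hold to machine accuracy along
every trajectory and are asserted at $10^{-6}$ relative drift.

**Endpoint semantics.** Readouts are taken at the end of a fixed
1000-minute horizon (`endpoint_summary()`). The enzyme cascade and G6P
relax within minutes, while the glycogen pool turns over on a multi-1000
minute scale, so at the horizon the cascade is at quasi-steady state and
glycogen is still accumulating under drug. This is deliberate: at the
*full* fixed point the first-order glycolytic drain pins G6P back to
$k_{in}/k_{out}$ regardless of dose, whereas during net glycogen synthesis
G6P sits at $(k_{in} + v_{GP} - v_{GS})/k_{out}$, below baseline — the
transient depression that the downstream models consume. The drug-free
reference state is an exact fixed point (constructed by nested 1-D root
solves), so the zero-dose endpoint is horizon-independent.

### Oxidative pentose-phosphate pathway

G6PD and 6PGD follow bi-substrate Michaelis-Menten kinetics
$v = V_{max}\,\frac{A}{K_A + A}\,\frac{NADP}{K_N + NADP}$, each reducing
NADP⁺; a first-order demand reconverts NADPH; ribulose-5-phosphate is a
terminal sink (the non-oxidative branch is out of scope). "Initial G6P
content" is implemented as a clamped supply relaxing to the initial value
at `k_g6p_refresh`, so the *steady state* depends on the upstream G6P
dose change; setting `k_g6p_refresh = 0` gives the pure initial-condition
(depleting) variant. The pyridine pool NADP⁺+NADPH is conserved; the sink
species is excluded from steady-state detection since it grows linearly at
steady flux. The steady-state NADPH/NADP⁺ ratio is monotone nondecreasing
in the G6P level — the module's core claim.

### Glutathione redox cycle

Glutathione peroxidase consumes 2 GSH per H2O2; glutathione reductase
regenerates 2 GSH per GSSG using NADPH; NADPH is resupplied at
$k_{supply}\cdot NADP/NADP_{tot}$ — `k_nadph_supply` is the tandem
interface parameter, scaled by the upstream NADPH/NADP⁺ fold-change.
De-novo GSH synthesis and GSSG efflux are available but default to zero,
closing the glutathione moiety GSH + 2·GSSG (conserved to $10^{-6}$).

A feasibility boundary is intrinsic: the reductase flux is capped by its
saturable kinetics, so when the NADPH supply cannot match the H2O2 load
(below ≈2.45 μM/min against the 2 μM/min reference load) no steady state
exists — GSSG accumulates, then H2O2 grows without bound. Scan functions
flag such grid points `converged = FALSE` instead of reporting a
pseudo-steady value.

**Vitamin E** is a non-depleting pool quenching H2O2 with second-order
kinetics $k_q \cdot [vitE] \cdot [H_2O_2]$ (a depleting variant would add
a consumption term; the non-depleting reading reflects tocopherol
regeneration by the wider antioxidant network and is the default). As the
quench capacity grows it takes over the entire H2O2 load, the peroxidase
flux collapses, and GSH returns to the fully reduced pool — slightly
*above* the unstressed no-load set point observed with a standing GSSG
burden. Under half NADPH supply (the drug condition), GSH recovers from
40% to ≈100% of the unstressed baseline across the vitamin-E grid.

## Tandem coupling

`run_tandem()` executes the chain per dose: glycogen endpoint → G6P
fold-change → PPP steady state at scaled G6P → NADPH/NADP⁺ ratio
fold-change → glutathione steady state at scaled NADPH supply. Design
choices, each genuinely open and resolved as follows:

* **Fold-change, not absolute, propagation** (default). Independently
  parameterized models need not share baselines; only the *degree of
  change* is transferable. `propagate()` multiplies the mapped downstream
  input by the upstream ratio; an absolute mode exists for models sharing
  a scale.
* **Interface quantities.** Model 1 → 2: the G6P *endpoint* fold-change
  scales the PPP's initial/clamp G6P (initial-condition scaling; the
  upstream endpoint concentration is the natural reading of a "dose
  change" of G6P). A glucose-supply coupling is omitted because the PPP
  model as specified consumes G6P only. Model 2 → 3: the steady-state
  NADPH/NADP⁺ *ratio* fold-change scales `k_nadph_supply`, a
  supply-scaling interpretation chosen because the glutathione model's
  NADPH is itself dynamic.
* **No feedback** across interfaces — the chain is acyclic by
  construction, matching the biology (glutathione status does not
  regulate glycogenolysis on these time scales).
* **Unit-rescaling contract.** `rescale_params()` multiplies every
  concentration-dimensioned parameter by a factor; trajectories scale
  exactly, so every fold-change is invariant. The drug axis and the
  vitamin-E pool are treated as external (unscaled) quantities, which is
  what lets one dose grid serve any internal rescaling. Tests assert
  invariance to $10\times$ rescaling of each model separately.

A dose-0 run is the identity composition: all fold-changes are 1 and the
final GSH equals the standalone unperturbed glutathione baseline (asserted
at 0.1%). Failures at any dose (e.g. an infeasible downstream supply) are
recorded per-row and the scan continues.

## Numerical choices

* **Steady states** are found by integration with horizon doubling until
  the relative RHS norm $\max_i |\dot y_i| / \max(|y_i|, 10^{-8})$ falls
  below tolerance: $10^{-8}$ per minute for the PPP and glutathione
  models, $10^{-9}$ for the glycogen cascade, whose glycogen pool is the
  slow mode — a laxer cut-off would stop integration while glycogen still
  carries a visible offset from its fixed point. Tests cross-check every
  integrated steady state against an independent multidimensional
  root-solve of the RHS (log-space `pracma::fsolve` from neutral interior
  guesses, conservation laws substituted) at 0.1%, on the reference sets
  and on 10 jittered sets per model.
* **Integration tolerances** default to `rtol = 1e-8`, `atol = 1e-10`
  for trajectories (and tighter inside steady-state searches); endpoints
  move by less than 0.1% when tightened further, which is asserted.
  Negative excursions beyond $-10^{-6}$ abort with an error; smaller ones
  are clipped to zero.
* **Determinism.** All generators are pure functions of their scenario
  and seed (`withr::with_seed`; no global RNG state leaks). Result CSVs
  print doubles with 9 significant digits, so identical configurations
  yield byte-identical files.
* **Problem sizes.** The shipped tests run 50-kinase panels over 20
  seeds, 9-point assay curves, 10-point dose grids, and 10 jittered
  parameter sets per model — sizes at which every check completes in
  seconds while still exercising each contract.

## What the synthetic data does and does not show

The generators emulate the *structure* of the real inputs: a two-drug
kinome table with shared tight primaries (Kd 0.001-0.05 μM), drug-A-only
off-targets, and weak background binding (10-10,000 μM) at exposures of
0.5 μM; 4PL assay curves with multiplicative noise; jittered kinetic
parameters. The off-target Kd range (0.1-0.5 μM) is chosen, together with
the exposures, so that planted off-targets always clear the documented
shortlist thresholds — making exact recovery a construction-backed oracle
rather than a statistical hope. Deliberately *not* emulated: real kinase
identities or measured Kd spectra, correlated or heteroscedastic assay
noise, plasma-protein-binding calculations, and any absolute quantitative
agreement with tissue metabolite levels. Passing round-trips therefore
validate the pipeline's algebra, numerics and composition contracts — the
directional, fold-change-level claims — not the quantitative accuracy of
any particular parameterization against real physiology.

## Known limitations

* The three kinetic models are minimal mechanisms reproducing directional
  behaviour; they omit hormonal PHK activation, the non-oxidative PPP
  branch, the γ-glutamyl cycle, and catalase/peroxiredoxin competition.
* End-to-end GSH depletion through the default chain is modest (≈2% at
  100 μM drug) because the reference glutathione model sits on the robust
  shoulder of its supply curve; the steep collapse (GSH to 40% of
  baseline) appears once NADPH supply falls toward the feasibility
  boundary, as the half-supply vitamin-E scans show.
* The IC50 Hill slope is weakly identified from single 9-point curves at
  5% noise; replicates or `fix_hill = 1` are recommended in practice.
* SBML import/export is not provided; parameter sets travel as YAML
  (`write_params()`/`read_params()`), with reference sets under
  `inst/extdata/`.
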