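---
title: "Methods: a bistable switch model of the Epi/PrE decision and its single-cell analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a bistable switch model of the Epi/PrE decision and its single-cell analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fateswitch)
```

## The circuit model and its assumptions

`fateswitch` models the choice between the epiblast (Epi, NANOG-high) and
primitive endoderm (PrE, GATA-high) expression programs in a single cell
as a deterministic, bistable toggle switch. Two species, NANOG ($N$) and
endogenous GATA ($G$), repress each other; a third species, exogenous
GATA ($G_X$), is produced only while an induction pulse is applied and
feeds into the same repressive input on NANOG as endogenous GATA:

$$\frac{dN}{dt} = \alpha_N\, f_N(s)\, \frac{1}{1+\left(\frac{G+G_X}{K_{GN}}\right)^{h_N}} - \gamma_N N$$
$$\frac{dG}{dt} = \alpha_G\, f_G(s)\, \frac{1}{1+\left(\frac{N}{K_{NG}}\right)^{h_G}} - \gamma_G G$$
$$\frac{dG_X}{dt} = D\,u(t) - \gamma_X G_X$$

Modelling choices, and why:

* **Hill repression, no basal production, linear turnover.** The minimal
  form consistent with a two-node mutual-repression network without
  autoactivation. Net positive feedback arises from the double negation;
  no other feedback is assumed.
* **Summed GATA input.** The induced exogenous factor substitutes
  functionally for endogenous GATA, so both enter one repression term via
  $G+G_X$. $G_X$ itself is a pure forcing: its linear equation is
  decoupled and has the closed-form pulse response implemented in
  `gx_pulse()`, which the integration tests use as an oracle.
* **Dose heterogeneity only.** The per-cell maximum exogenous production
  rate $D$ is the single source of cell-to-cell variability. Everything
  else — initial state, parameters, signaling — is shared across a
  population.
* **Signaling enters one production term.** Two coupling hypotheses are
  implemented: `inhibits_nanog`, $f_N(s) = 1/(1+(s/K_s)^m)$ (the default,
  matching the conclusion that MAPK signaling restrains the Epi program),
  and `promotes_gata`, $f_G(s) = s^m/(K_s^m+s^m)$. The factor multiplies
  the production rate; an additive route cannot be excluded on the
  available evidence but would break the convenient property that $s$
  only rescales one nullcline.
* **No stochastic kinetics, no cell division, no cell–cell coupling.**
  The model is an ODE per cell; demographic effects such as differential
  proliferation of the two fates are deliberately out of scope.

### Units and parameter defaults

Time is in hours; concentrations are in arbitrary units scaled so that
the uncoupled NANOG level $\alpha_N/\gamma_N$ is $2$. All defaults live
in `inst/extdata/default-config.yaml` and are resolved by
`fate_model()`/`load_config()`; nothing is hard-coded in the operations.

| parameter | default | meaning |
|---|---|---|
| $\alpha_N,\alpha_G$ | 1 conc/h | maximal production rates |
| $K_{GN},K_{NG}$ | 0.3 conc | repression half-effect thresholds |
| $h_N,h_G$ | 4 | repression Hill exponents |
| $\gamma_N,\gamma_G,\gamma_X$ | 0.5 /h | first-order turnover (~1.4 h half-life) |
| $s$ | 1 | signaling level (0 = none, 1 = saturated) |
| $K_s$, $m$ | 1, 2 | signaling half-effect and cooperativity |
| pulse | $[0,6)$ h, chase to 30 h | induction protocol |
| dose distribution | lognormal, meanlog $-1.75$, sdlog $0.8$ | per-cell $D$ |

The rate constants, thresholds and signaling constants were **calibrated
jointly** against four qualitative constraints that the modelled
experiments impose: (i) at $s=1$ the autonomous system has exactly three
equilibria, two of them stable; (ii) a 6 h pulse with heterogeneous doses
splits a population bimodally by 30 h; (iii) NANOG relaxes from its
pre-culture level toward a lower steady state before the fates diverge;
and (iv) in the `inhibits_nanog` mode, lowering $s$ raises the critical
dose. Cooperativity $h=2$ with these production/turnover ratios fails
constraint (i) — the strong NANOG attenuation at saturated signaling
($f_N(1)=1/2$ at the calibrated $K_s$) leaves only the GATA-high state —
so the repression steps use $h=4$, a value well within the range of
cooperative transcriptional repression. With $K_s=1$ and $m=2$ both
coupling modes are bistable at $s=1$; the `promotes_gata` mode loses its
GATA-high state below $s\approx0.65$, which is biologically sensible
(without the PrE drive there is no PrE state) and is why its sweep
signature is exercised on the level grid $\{1, 0.85, 0.7\}$ while the
default grid for the preferred mode is $\{1, 0.5, 0.25\}$.

The dose distribution is log-normal (long-tailed and positive, like
induced-reporter distributions measured by flow cytometry), with its
median placed at the critical dose at $s=1$ so that a standard pulse
splits a population roughly in half — mimicking the experimental regime
the system was tuned to. Its log-sd of 0.8 gives the broad overlap that
makes threshold-based fate prediction a non-trivial problem.

### Initial conditions: the pre-culture convention

Cells are prepared in a MEK inhibitor, i.e. at $s=0$, before the pulse.
The default initial state is therefore $(N, G, G_X) =
(\alpha_N/\gamma_N, 0, 0)$ — the GATA-free NANOG steady state **at the
pre-culture signaling level** — even when the simulation itself runs at
$s>0$. In the `inhibits_nanog` mode this produces the observed early
transient in which NANOG first relaxes toward its lower in-experiment
steady level in all cells before the fates separate. In the other modes
$f_N \equiv 1$ and the convention coincides with the in-experiment
steady state.

## Numerical choices

* **Integration.** `deSolve::lsoda` (adaptive, stiff-capable) with
  `rtol = 1e-8`, `atol = 1e-10`. The pulse indicator uses the half-open
  interval $[t_\text{start}, t_\text{end})$ and integration is split at
  both boundaries so the input discontinuity never falls inside an
  adaptive step. Solver undershoots below zero are clipped in the
  returned traces; a robustness test checks that halving tolerances
  moves final states by less than $10^{-4}$ relative.
* **Fate assignment.** A cell's fate is the attractor its trajectory
  reaches: integration is extended beyond the chase until the rate norm
  drops below $10^{-6}$ (cap 300 h), and the settled state is assigned
  to the nearest stable equilibrium. No expression cutoff is involved;
  cells that fail to settle are flagged and excluded rather than
  guessed.
* **Equilibria.** Candidate roots come from a sign-change scan of the
  rate field restricted to the (explicit) GATA nullcline, then each seed
  is refined by a damped Newton iteration on the analytic Jacobian to a
  residual below $10^{-10}$ and classified by the Jacobian eigenvalues.
  Eigenvalues with $|\mathrm{Re}\,\lambda| \le 10^{-9}$ raise an error
  ("marginal"): the calibrated model should never sit at a bifurcation.
  Duplicates within $10^{-6}$ are merged; results are sorted by $N$
  descending.
* **Separatrix.** The saddle's stable manifold, obtained by integrating
  the time-reversed flow from two seeds offset $\pm10^{-5}$ along the
  stable eigenvector and truncating at the bounding box. A test checks
  that points just on either side flow to opposite attractors and that
  side-of-separatrix labels agree with forward-integrated basin labels
  on at least 99% of a test lattice.
* **Critical dose.** Bisection on the end-point fate to a relative
  bracket width of $10^{-4}$, with an informative error when both
  bracket ends give the same fate.
* **Quasi-potential.** The path-integral construction: trajectories are
  launched from a uniform lattice, and along each one the potential
  accumulates $\Delta U = -\lVert v\rVert^2\,\Delta t$ (trapezoidal in
  the squared speed), so $U$ is non-increasing along the flow by
  construction. Each trajectory is anchored at 0 on its attractor;
  per-basin surfaces take cell-wise minima over trajectories; the two
  basins are aligned by matching values at the saddle's grid cell (or
  the nearest cell defined in both basins), and the global minimum is
  shifted to 0. Unvisited cells are `NA`, never silently 0. The exact
  published variants of this construction differ in seeding density and
  smoothing; the alignment-at-the-saddle rule is this package's choice,
  and only relative depths within one surface should be interpreted.
* **ROC conventions.** Candidate thresholds are midpoints between
  consecutive distinct sorted values plus $\pm\infty$ sentinels;
  "positive" means the GATA/PrE outcome and the classification polarity
  is fixed (high reporter $\Rightarrow$ PrE), never auto-detected. The
  trapezoidal AUC of this construction equals the Mann–Whitney pair
  statistic with ties counted $\tfrac12$, which the tests verify against
  brute-force pair enumeration at $10^{-12}$. The Youden-optimal
  threshold breaks ties toward the **largest** cutoff — the most
  conservative call of differentiation. The bootstrap resamples cells
  (whole traces), not (cell, frame) pairs, because frames within a cell
  are strongly dependent; replicates that lose a class are redrawn (at
  most 100 times). A cumulative-exposure transform
  (`cumulative_exposure()`) is provided as an alternative classifier
  input.
* **Clustering and peaks.** Trace clustering uses Euclidean distance on
  `log1p`-transformed intensities with Ward linkage — robust to
  multiplicative noise; the metric and linkage are package choices, and
  labels are ordered by descending final expression so cluster 1 is
  always the high class. Histogram peak calls smooth the sample with a
  Gaussian kernel density (Silverman bandwidth unless overridden, 512
  grid points spanning the data) and keep local maxima with prominence
  at least 5% of the global maximum; the peak fold-change is the
  highest-to-lowest peak-position ratio.

## What the synthetic data do and do not emulate

`generate_timelapse()` and `generate_flow_snapshot()` produce per-cell
channel intensities by sampling the ODE population at frame boundaries
(default cadence 0.25 h, a typical time-lapse interval) and applying
$x\,e^{\varepsilon} + b$ with $\varepsilon \sim
\mathcal N(0, \sigma_\text{mult})$, $b \sim \mathcal N(0.1, 0.02)$
(defaults $\sigma_\text{mult}=0.2$; background 5% of the pre-culture
NANOG level). End-point labels can be flipped with probability
`label_flip` to emulate staining errors. Both noisy and noise-free
tables are returned so every downstream test can compare against a
clean oracle.

The generator reproduces the *structure* of the experiments — pulsed
heterogeneous induction, bimodal end-point distributions, noisy
positive intensities, occasional mislabels — but not photobleaching,
focal drift, segmentation or tracking errors, lineage (division) or
reversion events. Tests passing on these data therefore demonstrate
that the analytics are correct and that the model produces the
qualitative phenomenology; they do not certify performance on real
microscopy data, and the dose distribution is a stand-in, not a fit.

## Problem sizes

The test-suite and acceptance computations use deliberately desk-scale
sizes: 10 replicate synthetic experiments of 200 cells at 0.25 h cadence
for the ROC/prediction results; populations of 2000 cells (on a coarse
time grid) for end-point bimodality; 120–200 cells per level for
signaling sweeps; $40$–$50$-cell lattices for basin and potential grids
and a $400\times400$ lattice for the brute-force equilibrium oracle.

## Known limitations

* The functional forms and parameter values are a calibrated
  reconstruction constrained by the published qualitative behaviour, not
  a fitted copy of any reference implementation; quantities with units
  (e.g. the critical dose) are meaningful only within this package's
  unit conventions.
* The quasi-potential is a Lyapunov-like visualization device; its
  depths depend on seeding and alignment conventions and are not
  transition rates.
* Fate calling by attractor convergence can in principle leave cells
  unresolved near the separatrix within the 300 h cap; such cells are
  reported, and none occur under the default conditions exercised by
  the tests.
* The configuration loader validates keys and ranges but not mutual
  consistency beyond the documented invariants (e.g. it will accept
  parameter sets that are monostable; `find_equilibria()` then reports
  the actual structure).
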