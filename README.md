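# fateswitch

Deterministic modelling and single-cell analytics for the epiblast (Epi)
versus primitive endoderm (PrE) fate decision in embryonic stem cells.

In this system, a transient pulse of an exogenous, inducible GATA factor
(e.g. doxycycline-driven GATA4-mCherry) pushes individual cells across the
threshold of a bistable gene-regulatory switch formed by mutual repression
between NANOG (the Epi program) and endogenous GATA (the PrE program).
Which cells switch is set by the per-cell induction strength, and the
proportion of switching cells is tuned by FGF/MAPK signaling. `fateswitch`
implements the circuit model, the phase-plane and quasi-potential analysis
of its autonomous dynamics, heterogeneous population simulation through
pulse-chase protocols, and the measurement analytics used on single-cell
data: per-timepoint ROC fate prediction with bootstrap uncertainty,
hierarchical trace clustering, and smoothed-histogram peak detection. A
synthetic-data module emulates time-lapse and flow-cytometry experiments
so the entire stack runs without any external data.

## The model

Per cell, three ordinary differential equations describe NANOG (`N`),
endogenous GATA (`G`) and the exogenous GATA species (`G_X`):

```
dN/dt   = alpha_N f_N(s) / (1 + ((G + G_X)/K_GN)^h_N) - gamma_N N
dG/dt   = alpha_G f_G(s) / (1 + (N/K_NG)^h_G)         - gamma_G G
dG_X/dt = D u(t) - gamma_X G_X
```

Exogenous and endogenous GATA repress NANOG through their sum, since the
induced factor substitutes for the endogenous one. `u(t)` is 1 during the
induction pulse (default 6 h) and 0 afterwards; the per-cell maximum
exogenous production rate `D` is the only source of cell-to-cell
variability. MAPK signaling `s` couples in via `f_N(s) = 1/(1+(s/K_s)^m)`
(signaling inhibits NANOG production, the default mode) or
`f_G(s) = s^m/(K_s^m+s^m)` (signaling promotes GATA production).

With `G_X = 0` the autonomous `(N, G)` system is bistable: a
NANOG-high/GATA-low attractor (Epi), a NANOG-low/GATA-high attractor (PrE)
and a saddle whose stable manifold — the separatrix — divides the two
basins of attraction. A pulse differentiates exactly those cells whose
dose exceeds a critical value `D*`, and lowering `s` raises `D*` and
shrinks the PrE basin.

## Worked example

```r
library(fateswitch)

m <- fate_model()          # calibrated defaults, signaling inhibits NANOG
find_equilibria(m)
#> Equilibria of the autonomous circuit (3 found)
#>            N         G stability          Re(eig)
#>  0.999992000 0.0160704    stable -0.4943, -0.5057
#>  0.457012000 0.3132110    saddle   0.8534, -1.853
#>  0.000505994 2.0000000    stable       -0.5, -0.5

critical_dose(m, pulse_protocol(), bracket = c(0.01, 2))
#> [1] 0.1703803
```

Three steady states, two stable: the NANOG-high Epi state near
`(1, 0.016)` and the GATA-high PrE state near `(0, 2)`. A 6 h pulse flips
a cell when its dose exceeds `D* ≈ 0.17` (in units where maximal NANOG
production is 1 per hour).

Generate a noisy synthetic time-lapse and ask how well the exogenous
reporter predicts each cell's final fate:

```r
tl <- generate_timelapse(n = 200, seed = 1)   # 121 frames, 0.25 h cadence
gx <- trace_matrix(tl$noisy, "G_X")
times <- attr(gx, "times")

roc_frame(gx[, times == 6], tl$labels$fate)
#> ROC frame: 95 positives, 105 negatives
#>   AUC = 0.9646, optimal threshold = 0.37286 (J = 0.8180)

prediction_accuracy(gx, tl$labels$fate, 0.37286, frame = which(times == 6))
#> [1] 0.905
```

At the end of the pulse the reporter level separates future PrE from
future Epi cells with AUC 0.96, and the Youden-optimal threshold calls
90% of fates correctly. Sweeping the signaling level with paired dose
draws shows the mode signature — the NANOG-positive peak rises as
signaling falls while the GATA-positive peak stays put, and fewer cells
differentiate:

```r
signaling_sweep(m, pulse_protocol(), n = 150,
                s_levels = c(1, 0.5, 0.25), seed = 2)
#> Signaling sweep (paired dose draws across levels)
#>     s fraction nanog_high_peak gata_high_peak n_resolved
#>  1.00   0.5067           1.000              2        150
#>  0.50   0.4267           1.600              2        150
#>  0.25   0.4000           1.882              2        150
```

Phase-plane objects (`phase_portrait()`, `quasi_potential()`,
`separatrix()`, `basin_fraction()`) have print/plot methods; see the
methods vignette (`vignettes/fate-switch-methods.Rmd`) for the full
account of the model, the calibration of its defaults, and the analysis
conventions.

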