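---
title: "Modelling immunogenic versus tolerogenic cell fates with a toggle switch"
author: "togglefate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling immunogenic versus tolerogenic cell fates with a toggle switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(togglefate)
```

## The model

Antigen-presenting cells such as epidermal Langerhans cells can commit to an
immunogenic programme (driving effector T-cell activation) or a tolerogenic
programme (driving tolerance), and single-cell transcriptomes suggest that
many cells sit in between. `togglefate` describes this decision with the
classic two-programme toggle switch: each programme auto-amplifies its own
expression and represses the opposing one, both through sigmoidal (Hill)
kinetics, and decays at a constant rate. Writing $I$ and $T$ for the
activity of the immunogenic and tolerogenic programme,

$$
\frac{dI}{dt} = a\,\frac{I^n}{\theta^n + I^n}
             + b\,\frac{\theta^n}{\theta^n + T^n} - k\,I,
\qquad
\frac{dT}{dt} = a\,\frac{T^n}{\theta^n + T^n}
             + b\,\frac{\theta^n}{\theta^n + I^n} - k\,T .
$$

This is an *influence* model: the two variables are programme activities
(in practice, signature z-scores of programme-defining transcription
factors), not concentrations of single molecules, and the interactions
summarise the net effect of the underlying regulatory network.

At the default parameters $a=b=k=1$, $n=4$, $\theta=0.5$ the system is
tri-stable. Two mirror-symmetric attractors, **A** (high $I$, low $T$,
immunogenic) and **B** (low $I$, high $T$, tolerogenic), sit near
$(2.0,\,0.004)$ and its mirror image; a third, balanced attractor **C**
(*ambivalent*, both programmes equally active) sits exactly at $(1,1)$.
The location of **C** is forced algebraically: on the diagonal $I=T$ the
activation and repression terms sum to one, so the dynamics collapse to
$\dot x = 1 - x$ — a fact the test-suite exploits both as a fixed-point
identity and as an exact exponential solution, $x(t) = 1-(1-x_0)e^{-t}$,
against which the numerical integrator is verified to $10^{-6}$.

```{r fixed-points}
fp <- find_fixed_points(toggle_params())
fp
```

Each cell is interpreted as an initial condition: its position in the
$(I,T)$ plane is integrated forward until the velocity norm falls below a
tolerance, and the cell inherits the fate of the attractor its trajectory
reaches. Basins of attraction are separated by separatrices through the
two saddle points; cells near a separatrix are resolved by integration,
never by a distance heuristic.

## Parameters and numerical choices

| parameter | default | meaning |
|---|---|---|
| `a` | 1 | auto-amplification strength (unitless) |
| `b` | 1 | cross-inhibition strength |
| `k` | 1 | programme decay rate (1/time) |
| `n` | 4 | Hill coefficient (cooperativity) |
| `theta` | 0.5 | Hill threshold |
| `x_max` | 2.2 | phase-portrait window per axis |
| `t_max` | 100 | integration horizon (time units) |
| `conv_tol` | 1e-6 | velocity-norm convergence threshold |
| `attract_eps` | 0.05 | attractor-assignment radius |

`x_max = 2.2` is chosen so the window contains every attractor: at
saturation a programme is produced at rate $a+b$ and decays at rate $k$,
so the single-programme attractors sit near $(a+b)/k = 2$.

Trajectories are integrated with an adaptive Dormand–Prince 4(5) scheme
(`deSolve`, method `"ode45"`) at `rtol = 1e-8`, `atol = 1e-10`; the state
is clamped at zero against solver undershoot (the field itself cannot
drive a non-negative state negative, since $dI/dt \ge -kI$). Populations
of cells are integrated as one stacked system of independent
two-dimensional units, which keeps per-cell cost low. Cells whose
trajectories have not converged by `t_max` are retried once with a
tenfold horizon and otherwise reported as unconverged and excluded from
fate proportions (at the defaults this is virtually never triggered).

Fixed points are located by damped Newton iteration from a regular grid
of seeds (default $25 \times 25$), using the analytic Jacobian

$$
J_{11} = a\,h'(I) - k,\quad J_{12} = -b\,h'(T),\quad
h'(x) = \frac{n\,\theta^n x^{n-1}}{(\theta^n + x^n)^2},
$$

de-duplicated at $10^{-6}$ and classified by the eigenvalue real parts
(stable: both negative; saddle: mixed). The Jacobian is cross-checked
against finite differences, and the asymmetric attractor against an
independent root finder, in the test suite.

## Scoring cells and placing them on the portrait

Programme activity per cell is the unweighted mean of per-gene z-scores
over a gene signature, computed on normalized expression. Two deliberate
choices:

* the z-score divides by the **population** standard deviation (divide by
  $n$, not $n-1$); either convention is defensible and the choice is
  irrelevant after the min–max scaling below, but it is fixed and
  documented so results are exactly reproducible;
* genes absent from the matrix or constant across cells are dropped with
  a warning; a transcription factor may appear on **both** axes and is
  then scored independently in each — no exclusivity is enforced.

Raw z-scores (which can be negative) are mapped into the non-negative
state space by min–max scaling each axis to $[0, x_{\max}]$ over **all
cells analysed jointly** (pooled across conditions). Pooling is the
default because conditions compared on one portrait must share a
coordinate system; per-condition scaling would erase between-condition
shifts, which are precisely the quantity of interest. A per-condition
switch exists for sensitivity analyses. A degenerate axis (a single
distinct value) maps all cells to the window midpoint with a warning.

Min–max scaling is sensitive to extreme cells: a single outlier widens
the empirical range and compresses everyone else toward the middle of the
portrait. With signature sizes in the tens of genes per axis this is the
dominant source of classification noise; it is one reason the synthetic
benchmark below uses programme-scale signatures.

For library-size normalization the package provides a simple
median-library-size + $\log(1+x)$ transform. Pooled-deconvolution
normalization is deliberately out of scope; matrices normalized by other
tools are accepted as-is wherever a normalized layer is required.

## The synthetic benchmark

`generate_population()` emulates a droplet-style UMI experiment with
three latent fates. Counts are negative-binomial with lognormal per-cell
size factors (unit mean, sigma `depth_variation`); programme genes are
multiplicatively lifted by `effect_size` in cells of their matching fate
and by `sqrt(effect_size)` on both programmes in ambivalent cells, which
places ambivalent cells halfway between the corner clusters on the log
scale — i.e. near the diagonal after scoring. A gene planted on both
programmes (the dual-role case, e.g. a maturation factor required by both
fates) is lifted in both single-programme fates and is therefore nearly
non-discriminative between them, mirroring the homogeneous expression
such factors show in real data.

Defaults describe a two-condition stimulation experiment: 375
unstimulated cells with a near-equal three-way split
(34.93/33.60/31.47%) and 362 stimulated cells with an increased
immunogenic and reduced tolerogenic fraction (41.99/17.96/40.05%);
`base_mean = 2`, NB size 2 and `depth_variation = 0.3` are typical of
shallow droplet data. `n_signature_genes = 200` per programme reflects
the scale of a transcriptional programme (activation signatures run to
hundreds of differentially expressed genes) and was fixed by an
identifiability argument: the per-cell score noise shrinks with the
square root of the signature size, and at the default effect size of 4 a
programme of this size places the corner clusters well inside their
basins, so the planted fate proportions are recoverable to within a few
percent. Axes built from a handful of TFs alone give directionally
correct but attenuated proportions — exactly as one would expect when
estimating a programme from two genes.

What the generator does **not** emulate: ambient RNA, doublets, batch
effects, gene–gene correlation beyond the fate structure, or realistic
transcriptome-wide expression distributions. Passing the recovery
benchmark therefore demonstrates internal consistency of the
score–scale–integrate–assign pipeline under the stated noise model, not
performance on arbitrary real data.

Benchmark problem sizes, chosen to characterise the estimator precisely
while staying light: proportion recovery uses 1000 cells per condition
averaged over five seeds; the classification-versus-basin-oracle
comparison uses 500 random starting points against a $201^2$ basin map;
model selection benchmarks use 250 cells per condition.

## Selecting transcription-factor combinations

`enumerate_models()` builds all pairings of an immunogenic axis (the
anchor TF alone or with additional pool members) with every non-empty
subset of the tolerogenic pool — 62 candidates for the default pools
(IRF1/IRF4 versus KRAS, SOX4, IRF4, RELB, ELK1). Each candidate is run
through the full classification pipeline and scored against two
directional criteria on a stimulated-versus-unstimulated pair: the
stimulated immunogenic fraction must rise and the stimulated tolerogenic
fraction must fall. Ranking is by criteria satisfied, then by the margin
(sum of the two shifts); both criteria are configurable.

A known and instructive limitation: a TF planted on both axes
contributes an identical score component to each, which displaces cells
*along the diagonal* — the direction that separates nothing — while
adding variance. In a margin ranking, a configuration sharing a TF
between axes is therefore systematically dominated by the same
configuration with the shared TF dropped from one side, even when the
shared TF is genuinely part of both biological programmes. Margin-based
selection, in other words, measures discriminative power, not biological
completeness; conclusions about dual-role factors need orthogonal
evidence (e.g. regulon or perturbation data).

## Known limitations

* The dynamics are deterministic; stochastic switching between basins
  (finite-noise escape) is out of scope, so "trajectory" here is a model
  construct and carries no pseudotime meaning for real cells.
* Fate proportions inherit the scaling convention: results are invariant
  to per-gene affine transforms of expression but not to the choice of
  cell population over which scaling is pooled.
* Parameters are fixed, not fitted; changing them re-shapes the basin
  geometry and `find_fixed_points()`/`basin_map()` should be re-run to
  confirm tri-stability before classifying (`find_fixed_points()` may
  legitimately return fewer than three stable states for other
  parameter values).
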