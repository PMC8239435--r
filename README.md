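# togglefate

Cell-fate classification of single cells on a tri-stable toggle-switch
landscape, for transcriptomics of antigen-presenting cells (e.g. epidermal
Langerhans cells) that balance **immunogenic** against **tolerogenic**
programming.

Two transcriptional programmes, with activities $I$ (immunogenic) and $T$
(tolerogenic), auto-amplify themselves and mutually repress each other via
Hill kinetics, and decay at a constant rate:

$$
\frac{dI}{dt} = a\frac{I^n}{\theta^n+I^n} + b\frac{\theta^n}{\theta^n+T^n} - kI,
\qquad
\frac{dT}{dt} = a\frac{T^n}{\theta^n+T^n} + b\frac{\theta^n}{\theta^n+I^n} - kT.
$$

At the default parameters ($a=b=k=1$, $n=4$, $\theta=0.5$) the landscape is
tri-stable: an immunogenic attractor **A**, a tolerogenic attractor **B**
and a balanced "ambivalent" attractor **C** at exactly $(1,1)$. Each cell
is scored on the two programme axes (mean per-gene z-score over a gene
signature), min–max scaled into the phase portrait, and integrated (adaptive
Dormand–Prince 4(5)) to its attractor; per-condition fate proportions
summarise the population. The package also ranks candidate
transcription-factor combinations defining the two axes, and ships a seeded
negative-binomial generator of droplet-style UMI counts with known
ground-truth fates so the whole pipeline is testable end to end.

## Worked example

```r
library(togglefate)

## the attractor landscape at the default parameters
find_fixed_points(toggle_params())
#>          I        T stability         label    eig1 eig2
#> 1 1.996078 0.003922    stable A_immunogenic -0.9922   -1
#> 2 1.000000 1.000000    stable  C_ambivalent -0.5571   -1
#> 3 0.003922 1.996078    stable B_tolerogenic -0.9922   -1
#> 4 1.511575 0.488425    saddle          <NA>  1.0738   -1
#> 5 0.488425 1.511575    saddle          <NA>  1.0738   -1

## a synthetic two-condition experiment with known fate structure
cfg <- synth_config(seed = 42)   # 375 unstimulated + 362 TNF-stimulated cells
pop <- generate_population(cfg)
ax  <- synth_axes(cfg)           # the planted immunogenic/tolerogenic axes

res <- classify_cells(pop$matrix, pop$metadata, ax$x, ax$y)
summarize_fates(res)
#>      condition n_converged n_unconverged immunogenic pct_immunogenic
#> 1 unstimulated         375             0         132           35.20
#> 2          TNF         362             0         143           39.50
#>   tolerogenic pct_tolerogenic ambivalent pct_ambivalent
#> 1         124           33.07        119          31.73
#> 2          72           19.89        147          40.61
```

The generator planted 34.93/33.60/31.47% (immunogenic/tolerogenic/
ambivalent) in the unstimulated condition and 41.99/17.96/40.05% under
stimulation; the classifier recovers both splits and, in particular, the
stimulated rise in immunogenic and drop in tolerogenic cells. Other entry
points: `score_signature()` / `compare_conditions()` for per-cell signature
z-scores and Mann–Whitney condition contrasts, `basin_map()` for the
brute-force basin-of-attraction oracle, `plot_phase_portrait()` /
`plot_fate_pies()` for figures, `enumerate_models()` / `evaluate_models()`
for TF-combination ranking, and `run_pipeline()` (or
`inst/scripts/togglefate.R`) for file-driven runs with a YAML
configuration. See the vignette in `vignettes/toggle-switch-fates.Rmd` for
the model, the numerical choices and the synthetic benchmark design.

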