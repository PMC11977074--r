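# ilrpower

Bipolar Likert responses carry two complementary magnitudes — agreement and
disagreement with an item — which makes a response, once placed on the trait
continuum, a **two-part composition** `(x*, 100 - x*)`. Analyzing such data
with ordinary Euclidean statistics ignores that structure; mapping them to
the real line with the isometric log-ratio (ilr) transform restores it.
`ilrpower` is for psychometricians and applied statisticians who want to
know what that choice of scale does to the **statistical power of paired and
unpaired two-sample t-tests** when the distribution of respondent means is
heavy-tailed, i.e. when the central limit theorem cannot be relied on.

## The model in brief

A `K`-category response scale under a limit of quantification `p` sits on
the trait scale `[0, 100]` at the equidistant "star" values

    x* = lLOQ + sw (s - 1),   s = 1..K,
    lLOQ = 100 p/2,  uLOQ = 100 (1 - p/2),  sw = (uLOQ - lLOQ)/(K - 1),

and the bivariate ilr transform carries a star value to the real line:

    z = sqrt(0.5) ln( x* / (100 - x*) ),
    x* = 100 e^{y1} / (e^{y1} + e^{y2}),   y1 = sqrt(0.5) z = -y2.

Means of `I` item responses can only take values in a discrete **set of
possible means**; a Monte-Carlo engine draws respondent means from a
Laplace distribution (density `e^{-|x-mu|/b}/(2b)`, variance `2b²`), snaps
every draw to its nearest possible mean on the ilr scale and — via the
inverse ilr — on the original response scale, applies Student/Welch/paired
t-tests to both representations, and estimates

    DeltaPower = Power^ilr - Power^orig

over scenario grids (3600 scenarios per test type in the replication
design: K ∈ {4,5,6}, p ∈ {0.05,0.1,0.2}, I ∈ {1,2,4,6}, N ∈ {50,100},
10 variance pairs from {0.08,0.32,0.72,1.28}, Cohen's D ∈ {0.2,...,1}).

## Worked example

```r
library(ilrpower)

s <- star_scale(K = 5, p = 0.05)
s
#> Star response scale: K = 5, p = 0.05, kappa = 100
#>   lLOQ = 2.5, uLOQ = 97.5, step width = 23.75
#>   values:  2.50, 26.25, 50.00, 73.75, 97.50

round(ilr_scale(s), 2)
#> [1] -2.59 -0.73  0.00  0.73  2.59
```

The 5-category scale covers 95% of the trait continuum; its ilr image is
symmetric but *not* equidistant — the top gap is 38% of the ilr range
against 25% on the raw scale (`relative_edge_distance()`), which is what
inflates dispersion under heavy tails. A simulated ilr-scale mean of 0.82
is snapped along both analysis paths (`I = 2` items):

```r
snap_both_paths(0.82, s, I = 2)[c("mu_ilr", "mu_orig")]
#> mu_ilr = 0.7305   mu_orig = 4
```

— on the ilr scale it becomes the nearest achievable mean 0.73; carried
back through the inverse ilr (76.13) it snaps to star value 73.75, i.e. a
mean of 4 on the original 1–5 scale. One full power scenario:

```r
r <- run_scenario(scenario("unpaired", K = 5, p = 0.05, I = 2, N1 = 100,
                           s2_a = 1.28, D_effect = 0.4, n_runs = 1000, seed = 1))
r
#> unpaired | K=5 p=0.05 I=2 N1=100 N2=100 s2=(1.28,1.28) D=0.4 | 1000 runs
#>   Power^ilr = 0.8380  Power^orig = 0.8890  DeltaPower = -0.0510
```

Under this heavy-tailed, high-dispersion condition the ilr analysis *loses*
about 5 percentage points of power relative to the naive original-scale
analysis. Grid-level summaries come from `run_grid()` +
`aggregate_delta_power()` / `findings_report()`; see the vignette
(`vignettes/compositional-likert-power.Rmd`) for the full account of the
model, parameter choices and limitations.

A thin command-line front end over the same functions ships in
`inst/cli/ilrpower` (single `run`s or YAML/JSON-configured `grid`s with CSV
output).

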