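# dielnet

Periodic-gene detection and sparse directed network inference for diel
(day/night) RNA-seq time courses.

## The problem

A diel transcriptome experiment samples a tissue every few hours across
one or two day/night cycles with a handful of biological replicates —
here, the reference design is 12 time points (hours 2..46, every 4 h
over two days under a 20 h light / 4 h dark cycle) with 3 replicates.
Two questions follow. **Which genes are rhythmic?** — answered per gene
by wavelet power at the 24 h period tested against white-noise
surrogates, with a conservative consensus over replicate permutations.
**Who drives whom?** — answered by sparse autoregression: each gene's
expression at time *t* is regressed on all genes at times *t−1..t−p*,
and a nonconvex group penalty selects a small set of putative regulators
per target, stabilised by an ensemble over replicate resamples.

`dielnet` implements this whole chain as tested R functions, plus a
synthetic-data module that generates the same design with known ground
truth (planted phases, planted regulatory edges) so every stage can be
validated end to end without external data.

## Models at the core

* **Periodicity.** For gene series *x* (z-scored), the analytic Morlet
  CWT (ω₀ = 6) gives time-averaged power at the 24 h period, rectified
  by its exact white-noise expectation. Significance: rank p-value
  against 1000 z-scored Gaussian white-noise surrogates,
  p = (1 + #{null ≥ obs}) / (1 + 1000). A gene is *periodic* when
  p < 0.01 in **all** 30 replicate-permutation series. Peak time by
  first-harmonic regression: fit a·cos(2πt/24) + b·sin(2πt/24) + c,
  peak = (24/2π)·atan2(b, a) mod 24.
* **Co-expression.** Pearson r between replicate-mean z-scored series;
  undirected edge where r ≥ cutoff (0.7 / 0.8; signed, not |r|).
* **Directed network.** Per target *g*: ARX(p) regression with groups =
  each regulator's p lags, penalized by group SCAD
  (p_{λ,a}(‖β_g‖₂), a = 3.7), solved by exact group coordinate descent
  on a within-group orthonormalized design; penalty level by extended
  BIC (γ = 1) on least-squares refits with backward pruning. Repeated on
  M = 30 replicate-resampled matrices; edge i→j is *called* when
  selected in strictly more than 20 of 30 trials.

## Worked example

The `analysis/` directory holds the study as numbered drivers; each is a
thin script over the package functions and writes under `results/`:

```sh
Rscript analysis/01_simulate.R 1        # synthetic study, seed 1
Rscript analysis/02_expression.R
Rscript analysis/03_periodicity.R 1
Rscript analysis/04_coexpression.R
Rscript analysis/05_grn_ensemble.R 1
Rscript analysis/06_benchmark_recovery.R 1
```

Output from a run with seed 1:

```
simulated 300 genes x 36 samples -> results/data
planted: 100 periodic, 170 background, 30 ARX-coupled (18 true edges)
300 of 300 genes called expressed (RPM >= 1 in all replicates at >= 1 time)
100 of 300 expressed genes called periodic
planted periodic genes recovered: 100 / 100
median |peak-time error| on planted genes: 0.07 h
17% of periodic genes peak in the dark window
PCC >= 0.7: 100 genes linked by 1267 edges
PCC >= 0.8: 100 genes linked by 1006 edges
ARX(1): 2 edges (confidence > 20/30), 2 parents -> 2 children; 0 hub(s)
single-trial: median precision 0.95, median recall 0.97
ensemble (confidence > 20/30): median precision 1.00, median recall 0.89
```

Reading this: all 100 planted sinusoids (amplitudes 4–12 RPM) — and no
background or ARX gene — pass the consensus screen; estimated peak
times sit within ~0.1 h of the planted phases, and 17% peak in the 4 h
dark window (phases are uniform, so ≈ 4/24 ≈ 17% is expected). The
co-expression network connects genes of similar phase, and its edge set
shrinks as the cutoff rises. The planted periodic genes have no
regulatory coupling among themselves, so the ensemble honestly calls
almost no directed edges over them; on the ARX benchmark systems with
planted edges (the last two lines) the selection recovers the true
network at high precision and recall, and confidence filtering raises
precision over the single-trial level at a small cost in recall.

The same pipeline runs from one config on any counts + metadata TSV
pair (genes × samples; sample_id / day / hour / replicate):

```r
library(dielnet)
cfg <- pipeline_config(counts_path = "counts.tsv",
                       metadata_path = "metadata.tsv", seed = 1)
res <- run_pipeline(cfg, out_dir = "run1")
```

## Layout

```
R/                  package code (generators, expression, periodicity,
                    co-expression, group-SCAD ARX inference, ensemble,
                    pipeline)
src/group_scad.cpp  group coordinate-descent path solver
analysis/           numbered study drivers (write results/)
scripts/acceptance.R
tests/testthat/     unit, property and benchmark-scale suites
vignettes/methods.Rmd   models, parameters, design rationale
```
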