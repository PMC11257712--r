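---
title: "Consensus ICA: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ICA: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cicada)
```

## The model

Bulk and single-cell omics profiles are mixtures: cell types, transcriptional
programs, and technical artifacts superimpose in every sample. cicada models a
feature-by-sample matrix $X$ ($n$ features, $m$ samples) as a product

$$X \approx S\,M,$$

where the $k$ columns of $S$ ($n \times k$) are *independent components* —
signals over features that are as statistically independent and non-Gaussian
as possible — and the rows of $M$ ($k \times m$) are their *weights* across
samples. In practice a component's source column has a near-zero bulk and a
few strongly contributing features (positive or negative), which is what makes
components interpretable as pathways, cell types, or technical artifacts, and
what makes the weights usable as engineered features for stratification and
survival modelling.

A single fastICA run depends on its random initialization: components come
back in random order, with random sign, and — near non-identifiable or noisy
directions — with run-to-run variation. That stochasticity is the problem this
package exists to remove. Rather than clustering components from many runs,
cicada *matches* them: every run is aligned to a reference run
component-by-component (correlation of source columns, optimal one-to-one
assignment, sign flip), and the aligned runs are averaged. The per-component
mean matched correlation is reported as a *stability* score in $[0, 1]$.

## One ICA run

1. **Scaling.** Each feature row is centered (`scale_matrix`, mode
   `"center"`); `"center_unit_variance"` additionally rescales rows to unit
   variance. Centering is the minimal preprocessing whitening requires, so it
   is the default; variance rescaling is a choice the user makes when
   high-variance features should not dominate. Zero-variance features are
   rejected (they carry no information and break whitening); `read_matrix`
   drops them at load time with a logged count.
2. **Whitening.** The thin SVD $X = U D V^{\mathsf T}$ gives the rank-$k$
   whitened representation. `whiten()` exposes $Z = K X$ ($k \times m$,
   $Z Z^{\mathsf T}/m = I$) together with the feature-space scores $U_k$. The
   fixed-point iteration runs over the *feature* axis (each of the $n$
   features is an observation of a $k$-vector): sources are independent
   across features in this model, while weight rows across samples are
   typically near-Gaussian and would not be identifiable. Feature-axis score
   vectors are not re-centered: their means are $O(1/\sqrt{n})$ after row
   centering, negligible at the matrix sizes the method targets.
3. **Fixed-point iteration.** Symmetric (parallel) fastICA: all $k$ unmixing
   vectors are updated jointly with the chosen contrast (default `logcosh`
   with $a = 1$; `exp` and `cube` available) and re-orthonormalized by
   symmetric decorrelation each step. Symmetric estimation avoids the
   order-dependent error accumulation of deflation. Convergence is declared
   when $\max_j\,\bigl|1 - |\langle w_j^{new}, w_j^{old}\rangle|\bigr| <
   \text{tol}$ (default $10^{-6}$, `max_iter` 1000). Non-convergent runs are
   returned flagged, never raised.
4. **Back-mapping.** Source columns are rescaled to unit sample variance and
   the weights are the least-squares map $M = (S^{\mathsf T}S)^{-1}
   S^{\mathsf T} X$. Because the source columns span the same rank-$k$
   subspace for any rotation, $S M$ equals the rank-$k$ projection of the
   scaled data *exactly*, independent of where the iteration stopped — so
   reconstruction quality reflects the retained rank, not convergence luck.

## The consensus

`run_consensus()` executes `n_runs` (default 30) runs with seeds
`base_seed + i`, drops non-converged runs (warning when more than half drop),
and picks as reference the *medoid* run — the one with the highest mean
matched correlation to all others — rather than an arbitrary first run, so a
single bad run cannot anchor the consensus. Every other run is aligned to the
reference by `match_components()`: the $k \times k$ absolute-correlation
matrix between source columns is turned into an assignment problem
(cost $1 - |r|$) and solved exactly by a Hungarian
shortest-augmenting-path solver; ties resolve to the lowest component index.
Aligned runs are averaged elementwise — unweighted, because a
stability-weighted estimator would be harder to audit and the dropped-run
filter already removes the pathological cases. Stability of component $j$ is
the mean matched $|r|$ to the reference across the other runs (the
reference's trivial self-match is excluded to avoid inflating the score).

Finally each component is oriented so that its largest-magnitude source value
is positive, with the weight row flipped jointly — a deterministic convention
that leaves $S\,M$ unchanged and makes decompositions comparable across
datasets.

Scheduling never affects results: each run derives all randomness from its
own seed and results are collected in run order, so `n_workers` only changes
wall time. The whole decomposition is a pure function of
`(X, opts, n_runs, base_seed)`.

**How many components?** `suggest_max_components()` returns
$\lfloor m/3 \rfloor$: beyond roughly a third of the sample count, components
tend to be unstable. The CLI warns — but proceeds — when `k` exceeds this.

## Interpretation, clinical linkage, integration

- **Top features** (`top_features`): a component's source column is z-scored
  and thresholded at $|z| \ge 3$ by default. Positive and negative tails are
  kept separate, because usually only one direction of a component carries
  the biology. The threshold is exposed; 3 keeps roughly the expected
  handful of drivers on the heavy-tailed sources the method assumes.
- **Over-representation** (`overrepresentation`): upper-tail hypergeometric
  test per gene set, Benjamini–Hochberg adjusted within one
  (component, direction) family. The universe is the intersection of the
  analyzed matrix's features with the GMT universe, preventing inflation
  from features that were never testable. GSEA-style rank tests are out of
  scope; the sparse tails ICA produces are exactly the selections ORA was
  built for.
- **ANOVA** (`anova_weights`): one-way fixed-effects ANOVA of a weight row
  across one factor's levels, per factor, no interactions — the simplest
  reading, documented as such. Levels with fewer than two samples are
  dropped with a warning. Perfect separation (zero within-group variance) is
  reported as the smallest representable positive p with a `degenerate`
  flag rather than an error.
- **Cox** (`cox_weights`): univariate proportional-hazards fit per component
  (`survival::coxph`, Efron ties — more accurate than Breslow when tied
  event times arise). `event = 1` means the event occurred; right censoring
  only. Constant covariates short-circuit to $\beta = 0$, monotone
  likelihood is flagged, not raised. BH families are per factor and per
  survival analysis, across the $k$ components.
- **Integration** (`correlate_weights`, `build_component_graph`): Pearson
  correlation of weight rows across decompositions on shared samples
  (Spearman available), $t$-transform p-values, BH across all tested pairs,
  and an edge when $|r| \ge 0.5$ and $q \le 0.05$ (defaults; both exposed).
  Clusters are plain connected components — no community detection — keeping
  "correlated components are connected" literal and deterministic.

## The synthetic-data generator

`simulate_mixture()` draws what the model assumes: iid super-Gaussian sources
per feature — Laplace by default (excess kurtosis 3, matching the
few-strong-contributors shape) or `sparse_spikes` (2% of features large) —
standardized per column, mixed by a Gaussian matrix redrawn until its
condition number is $\le 100$ (so failed recovery indicates a method problem,
not an ill-posed instance), plus Gaussian noise. `add_batch_effect()` appends
an honest extra rank-1 term: a heavy-tailed feature shift times a
batch-indicator row — heavy-tailed because real platform effects move a
subset of features strongly, and because that makes the batch term itself an
independent component the decomposition can isolate (a Gaussian shift would
be unidentifiable against the noise subspace). `simulate_survival()` draws
exponential event times with log-hazard $\beta \cdot M_{j\cdot}$ and tunes
uniform censoring to the requested rate; `plant_gene_sets()` records a
tail-derived set plus a size-matched random decoy.

What the generator does *not* emulate: count noise (negative binomial,
library sizes), single-cell dropout, correlated feature blocks, or
non-linear batch distortions. Passing the recovery tests therefore shows the
estimator is correct under its own model, not that any particular real
dataset decomposes cleanly.

## Numerical choices and limitations

- Whitening refuses `k` above the numerical rank (tolerance
  $10 \cdot \max(n,m) \cdot \varepsilon \cdot d_1$) and reports the
  effective rank.
- Per-run seeds are `base_seed + i`: simple, collision-free, recorded in the
  output and in `metadata.json` so any decomposition is auditable.
- Decomposition files are written with 17 significant digits, so
  write/read round-trips are exact to within $10^{-12}$.
- Averaging aligned runs leaves an $O(\delta^2)$ cross-run term in
  $S M - X$ where $\delta$ is the per-run convergence error; noise-free
  reconstruction checks therefore tighten `tol` to $10^{-9}$.
- Validation problem sizes (chosen to exercise the estimator at realistic
  ratios while keeping the suite quick): $1000 \times 60$ with $k = 5$ for
  recovery and reproducibility, $500 \times 200$ for the batch workflow
  (the between-batch variance left after removal is bounded below by the
  chance association of the remaining weight rows with batch,
  about $1/(m-1)$, hence the larger $m$ there), 200 replicates at $m = 100$
  for Cox parameter recovery.
- Matching is exact (Hungarian) rather than greedy; for the component counts
  the one-third rule implies ($k \le m/3$), the $O(R^2 k^3)$ medoid search
  over $R$ runs is negligible next to the ICA iterations.
- Missing values are not imputed: `read_matrix` drops affected features (or
  errors, by policy). Imputation would silently distort sources.
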