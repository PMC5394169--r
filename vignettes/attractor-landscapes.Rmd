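---
title: "Hopfield attractor landscapes of disease progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hopfield attractor landscapes of disease progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
set.seed(1)
```

## The model

hopscape treats a cross-sectional, staged gene-expression dataset — normal
samples, early-disease samples, advanced-disease samples — as a set of
points on an energy landscape, in the spirit of Waddington's picture of
cell states rolling into valleys. The machinery is a Hopfield network over
the genes:

* **Training.** The weight between genes $i$ and $j$ is their Pearson
  correlation across *all* samples, stages pooled: $w_{ij} =
  \mathrm{PCC}(i, j)$, $w_{ii} = 0$. $W$ is symmetric with entries in
  $[-1, 1]$. No stage labels enter the weights: the learning is
  non-parametric, and whatever attractor structure emerges comes from
  similarity among the expression patterns alone.
* **Recall.** A sample's z-scored expression vector $P_{(0)}$ is relaxed
  by the synchronous sign update
  $$P_{(t+1)} = \mathrm{sgn}\!\left(P_{(t)} W\right),$$
  which drives the state to a bipolar ($\pm 1$) fixed point — an
  *attractor*, read as a stable cell phenotype. Samples with similar
  activity patterns converge to the same attractor.
* **Energy.** Every visited state is scored with the quadratic form
  $$E(P) = -\tfrac12\, P W P^{\mathsf T}.$$
  For the continuous original state this measures how tightly the sample
  aligns with the pooled correlation structure (the more coherent, the
  lower the energy); for bipolar states it is the landscape elevation.

Attractors are then characterised by their **width** — the mean pairwise
Euclidean distance among member samples' original z-scored vectors,
divided by $\sqrt{d}$ so that datasets of different dimensionality are
comparable (two independent standard-normal profiles sit at width
$\approx \sqrt 2$) — and their **depth** — the magnitude of the energy
drop from the members' original states to the attractor. Width is a proxy
for basin size: a wide attractor drains a heterogeneous set of samples.

### A note on energy descent under synchronous updates

For *asynchronous* (one-component-at-a-time) Hopfield dynamics the
quadratic energy above is a Lyapunov function. The update implemented
here is the *synchronous* whole-vector map, for which the guaranteed
non-increasing quantity is instead the bilinear form
$-P_{(t)} W P_{(t+1)}^{\mathsf T}$, and trajectories converge to a fixed
point or to a 2-cycle. Two practical consequences:

1. `run_recall()` detects 2-cycles and reports them as a distinct status;
   for a cycle the lower-energy member of the oscillating pair is taken
   as the terminal state.
2. On unstructured weight matrices the quadratic energy can rise
   transiently along a trajectory even though the dynamics still
   converge. On correlation-structured expression data — the regime this
   method exists for — we observe monotone quadratic descent on every
   trajectory, and the test suite asserts exactly that split: bilinear
   descent always, quadratic descent on structured data.

## The pipeline and its parameters

`hopfield_fit()` is the front door; `run_pipeline()` wraps it together
with the robustness and network analyses and writes a result bundle.

* **Feature selection** (`features`, `k`). Genes are ranked by raw-value
  variance (ranking must precede z-scoring, which equalises all variances
  to 1) and cut at the elbow of the variance-over-rank curve: the point
  of maximum perpendicular distance from the chord joining the curve's
  endpoints, both axes min–max normalised. The rule is deterministic and
  parameter-free; with a sharp breakpoint it lands on the first point of
  the flat tail. Published analyses that fixed a particular feature count
  can be reproduced with the `k` override, which is recorded as method
  `"fixed"`.
* **Z-scoring.** Per gene, mean 0, sd 1 with the conventional $n-1$
  denominator. Zero-variance genes are dropped with a warning (their
  correlations are undefined). The loader rejects missing values by
  default; per-gene mean imputation sits behind `impute = TRUE`.
* **Recall cap** (`max_iter`, default 100). Fixed points are typically
  reached in fewer than ten synchronous steps; the cap only matters for
  pathological inputs, and hitting it is reported as non-convergence,
  never silently accepted.
* **Sign ties.** A zero local field keeps the previous component's sign
  (+1 if that was itself zero). This makes the all-zero weight matrix an
  identity map and injects no directional bias.
* **Attractor labels.** Each attractor is named by the plurality stage of
  its members; ties go to the earliest stage in the configured order, so
  reruns are deterministic.
* **Perturbation** (`fraction = 0.5`, `n_replicates = 100`). Robustness
  is probed by replacing a fraction of the unordered gene-pair weights
  with Uniform(−1, 1) draws — one draw per pair, mirrored, so symmetry
  and the correlation range survive — and re-relaxing every sample. A
  sample *fails* when it no longer reaches its original attractor
  pattern exactly; plain non-convergence is reported separately.
  Replicate $r$ is seeded with `seed + r`, so results are reproducible
  and replicate-parallel streams never overlap.
* **Stage networks** (`n_network_genes = 100`, `alpha = 1e-4`). Within
  each stage, every gene pair with a two-sided correlation p-value
  $\le \alpha$ (standard $t$ statistic on $n-2$ df, no multiple-testing
  correction — the filter is a fixed raw threshold) becomes an edge.
  Edges present in *every* stage (pair identity only; sign and magnitude
  ignored) form the common set; subtracting it leaves each stage's
  *unique network*, the rewiring signature of that stage, with newly
  isolated genes dropped. By construction
  $|\text{unique}| = |\text{original}| - |\text{common}|$.
* **Landscape** (`grid_resolution = 100`). Samples are projected onto
  PC1/PC2 (component signs fixed so the dominant loading is positive);
  the scattered (PC1, PC2, energy) points — samples, intermediate
  trajectory states, and attractor patterns projected through the same
  rotation — are interpolated with an exact thin-plate-spline
  interpolator. Exactness at data sites is the property we insist on
  (the surface honours every computed energy); outside the convex hull
  of the data there is no interpolation support, so the surface is
  filled with the maximum observed energy, a plateau against which
  attractors read as basins. Intermediate trajectory states are included
  as anchors by default because their bipolar-scale energies carve the
  basins; `include_trajectories = FALSE` restricts the surface to the
  samples alone.

## What the synthetic generator emulates

`simulate_progression()` plants the structure the method assumes:
$S$ ordered stages, blocks of co-expressed genes, and two expression
*programs* (sign patterns over blocks) whose attractors the samples
should recover. A gene in block $b$ of a sample carrying program $p$ is

$$x = \text{baseline} + \mathrm{sign}_b(p)\,A_b + \text{jitter}_{b,s} +
\varepsilon,$$

with the jitter shared across a block within a sample (within-stage
co-expression) and $\varepsilon$ i.i.d. Gaussian. Two calibration choices
matter:

* `within_block_r` is the target *pooled* within-block correlation **at
  unit noise**: amplitude and jitter are solved from it once (95% of the
  signal variance from program sign flips across samples, 5% from
  jitter) and then held fixed. `noise_sd` therefore remains an
  independent dial — raising it genuinely degrades correlations and
  widens attractors instead of being rescaled away. At the default
  `noise_sd = 1` the realised pooled correlation matches the target to
  within a few percent.
* The default programs are opposed on **every** block (program 1 all +1,
  program 2 all −1). This is not cosmetic: a block whose sign is
  constant across all samples carries no program signal once genes are
  mean-centred, and its relaxed sign becomes jitter-driven, splitting
  one planted program across several attractors. Custom `programs`
  matrices are accepted, with that caveat documented.

Defaults mirror a small staged case-control study: 3 stages × 15
samples, 100 genes in 2 blocks, within-block correlation 0.8, unit
noise. `mixing` reassigns a fraction of each interior stage's samples to
the preceding stage's program, emulating heterogeneous mid-stages whose
samples split between the normal and disease attractors — the qualitative
behaviour reported for mid-grade tumours. `n_null_genes` appends inert
low-variance genes so the variance elbow has a breakpoint to find.

What the generator does **not** emulate: probe-level noise models, batch
structure, heavy-tailed intensities, or correlation between blocks beyond
what the shared programs induce. Passing tests on this generator
demonstrate that the estimators and dynamics are implemented correctly
and behave as designed under planted structure; they do not certify
performance on any particular clinical dataset.

## Worked example

```{r example}
library(hopscape)
sim <- simulate_progression(seed = 1)
fit <- hopfield_fit(sim$data, features = "all")
summary(fit)
```

The mid and disease stages share the disease attractor (the planted
progression maps both to the second program); with `mixing = 0.4` the
mid-stage splits between the two attractors in proportion to the mixing
rate. Robustness at the conventional 50% edge perturbation:

```{r robustness}
rob <- robustness_analysis(fit$X, fit$W, fit$attractors, fraction = 0.5,
                           n_replicates = 20, seed = 1)
rob
```

```{r landscape, fig.alt = "Energy landscape contour with samples and attractors"}
plot(fit)
```

## Numerical choices and degenerate inputs

* All-constant expression matrices, stages with fewer than 3 samples,
  dimension mismatches, and unknown stages are hard errors; constant
  genes and flat variance curves degrade with warnings.
* $|r| = 1$ maps to $p = 0$ by convention in the network filter.
* The thin-plate solve adds a tiny ridge only if the anchor
  configuration is numerically degenerate (e.g. collinear); coincident
  anchor coordinates are merged by averaging their energies first.
* Exact ties in the 2-cycle energy comparison resolve to the later
  state; exact ties in variance ranking resolve lexicographically by
  gene ID.

## Known limitations

* The width/depth estimators assume converged samples; trajectories that
  hit `max_iter` are excluded from membership and reported.
* The quadratic energy of a *continuous* original state can undercut the
  bipolar attractor energy when samples are very tightly correlated
  (z-scored components then exceed ±1 in magnitude). The
  basins-below-samples picture of the landscape is characteristic of the
  weak-correlation regime of real transcriptome data, not a theorem.
* Synchronous dynamics can 2-cycle; cycle members are reported, not
  hidden, and the terminal-state choice (lower energy) is a convention.
* Stage networks built from the generator's defaults are sparse at
  $\alpha = 10^{-4}$ with 15 samples per stage: within-stage correlation
  comes from the jitter share only. That is intentional (the planted
  signal lives in the between-program contrast), but it means synthetic
  network counts are small compared to the hundreds of edges a real
  cohort yields.

## Problem sizes

The test suite and the acceptance script run entirely on generated data
at the default study conditions (45 samples × 100 genes), with 20-seed
replication for the stochastic properties (program recovery, mid-stage
splitting, width growth with noise, fail-fraction monotonicity) and
exhaustive fixed-point enumeration at $d \le 12$ for the dynamics
oracle. A full pipeline run at these sizes completes in about a second.
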