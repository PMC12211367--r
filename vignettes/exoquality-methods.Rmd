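---
title: "Measuring the consistency of EV isolation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the consistency of EV isolation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoquality)
```

## The problem

Extracellular vesicles (EVs) are isolated from plasma and other biofluids by
very different laboratory procedures — capture-release beads,
membrane-affinity columns, phosphatidylserine-affinity beads,
ultracentrifugation — and the resulting isolates differ systematically in
particle size, yield, total protein and total RNA. No single assay certifies
the quality of an isolate, and the assays live on incomparable scales
(nanometres, particles/mL, micrograms), so a method-comparison metric has to
harmonize them first. The quantity this package estimates is *consistency*:
how similar are repeated characterizations of the same sample's isolate under
the same method?

## The model

The input is a long table of replicate-level measurements: one row per
sample × isolation method × assay × replicate. Five assays are canonical
(`size_mean_nm`, `particle_concentration_per_mL`, `protein_total`,
`rna_total`, `pdi`), but any assay label is accepted.

**Step 1 — probabilistic rescaling.** Within each assay, all values (pooled
across methods, samples and replicates by default) are mapped to their
mid-rank plotting positions $u = (\bar r - 0.5)/N$ under the assay's own
empirical CDF, with ties receiving averaged ranks. Every transformed value
lies strictly inside $(0, 1)$, the transformation is monotone, and because it
depends on ranks only it is invariant under any strictly increasing change of
an assay's measurement scale — the property that makes assays with different
units directly comparable, and the central invariant the test suite asserts
end to end.

**Step 2 — EV Inconsistency value (EVI).** For each (method, sample) cell
and each assay, take the standard deviation of the transformed values across
that cell's replicates, then aggregate the per-assay standard deviations over
the $n$ assays present in the cell. With the default mean aggregation,

$$\mathrm{EVI}_{m,s} = \frac{1}{n}\sum_{i=1}^{n}
  \sqrt{\operatorname{Var}\!\big[u_{m,s,i,\cdot}\big]},$$

which stays on the fractional scale of the transformed values: an EVI of 0.2
reads as an expected 20% deviation of the isolate on resampling.

**Step 3 — ExoQuality Index (EQI).** Per method,
$\mathrm{EQI}_m = 1 - \overline{\mathrm{EVI}}_{m,\cdot}$, the average taken
over samples only, reported as a fraction and a percentage. Higher is better;
with 4 replicates and mean aggregation the index is bounded below by
$1 - 0.577$.

**PDI.** When raw nanoparticle tracking analysis (NTA) size profiles are
available, the particle dispersity index is computed as
$\mathrm{PDI} = \max(\text{sizes}) / \sigma(\text{sizes})$ — dimensionless
and invariant under rescaling of all sizes. A monodisperse profile
($\sigma = 0$) has no finite PDI and raises an explicit degenerate-profile
error rather than returning infinity.

### Assumptions

After the rescaling, the variance observed across replicates is attributed
entirely to random error of the isolation procedure, not to the assay's own
scale or to the method's location bias. A method-level multiplicative bias
shifts where a method's values sit in the pooled reference distribution but,
to first order, not how far apart its replicates rank — the simulator's
bias-insensitivity check quantifies how well that holds (pooled ranking can
couple a bias into the local spacing of plotting positions, so the test
compares the effect against Monte-Carlo error rather than asserting exact
zero).

## Conventions left open, and the defaults chosen

Several analysis conventions are genuinely open; the package fixes a default
for each, exposes the alternative behind a flag, and `eqi_sweep()` recomputes
the per-method EQI under every combination so a reported index value can be
matched to the convention that produced it.

* **Aggregation over assays** (`aggregation`): default `"mean"`. A literal
  sum of five per-assay standard deviations could exceed 1 and would push the
  index off the percentage scale on which it is interpreted; the mean keeps
  EVI a fraction with the "20% deviation" reading. `"sum"` gives the literal
  aggregate standard deviation.
* **Replicate standard deviation** (`sd_mode`): default `"sample"` (n − 1),
  the small-sample convention appropriate to 4 replicates; `"population"`
  divides by n.
* **Plotting position** (`rank_convention`): default `"midrank"`
  ((r − 0.5)/N), symmetric and never saturating at 0 or 1; `"weibull"`
  (r/(N + 1)) is the common alternative.
* **Pooling scope** (`scope`): default `"all"` — one reference distribution
  per assay across all methods, which is what makes cross-method comparison
  meaningful. `"per_group"` and `"per_method"` support sensitivity analyses.
* **PDI numerator** (`max_def`): default `"max-size"`, the largest particle
  size present, which keeps the index dimensionless; `"mode-size"` uses the
  bin of maximal concentration for binned profiles.

## Numerical and edge-case choices

* Ties receive averaged ranks, so tied raw values always map to identical
  transformed values; an assay whose values are all equal collapses to 0.5
  exactly.
* A fitted `fit_ecdf()` mapping evaluated at new values interpolates
  linearly between reference plotting positions and clamps outside the
  reference range, so outputs never touch 0 or 1.
* (method, sample, assay) cells with fewer than 2 replicates are excluded
  from EVI with a warning — a variance needs at least two values — and the
  per-cell assay count n is reduced rather than imputing, which would
  manufacture consistency. A cell with no usable assay has undefined EVI.
* Replicate indices need not be consecutive; only multiplicity matters.
* All computations are deterministic given inputs and settings;
  `run_pipeline()` reruns byte-identically and writes every file atomically.

## The simulator

`simulate_study()` draws a complete crossed study from a known generative
model: per sample and assay a lognormal true value; per method and replicate
the observed value is truth × method bias × mean-one lognormal noise with the
method's replicate coefficient of variation (CV). Lognormal truths and
multiplicative noise were chosen because particle counts, protein and RNA
masses are positive and right-skewed. Optionally, per-replicate particle size
profiles are drawn from a two-component lognormal mixture (a main vesicle
population near 120 nm plus a heavier tail near 250 nm) and the size and PDI
records are then derived from those profiles through the NTA summaries.

The default scenario mirrors a replicated plasma comparison study: 11
samples (6 tumor, 5 healthy), 4 isolation methods, 5 assays, 4 replicates —
880 records. Default method CVs (5–20%) and biases (0.7–1.3×) span the
between-method spread typical of replicated EV characterization panels; the
paper-scale noise levels are not published, so these are scenario choices,
not estimates, fixed once in `default_methods()`.

What the simulator does *not* emulate: assay-specific detection limits and
censoring, correlated errors across assays within a replicate, batch and
operator effects, or any vesicle biophysics. Passing the recovery tests
therefore shows that the index ranks methods by replicate noise under a
clean multiplicative error model — not that it is robust to every artefact
of real instrument data.

`recovery_experiment()` is the validation harness: it reruns the full
pipeline (simulate → transform → EVI → EQI) under counter-derived child
seeds and reports how often the EQI ranking exactly inverts the known noise
ranking. The test suite runs it at CVs 0.02/0.10/0.30 with 100 runs and
requires at least 95% correct rankings and mean EVI monotone in CV; those
problem sizes (660–880 records per run, 100 runs) keep the whole suite
comfortably fast while leaving the Monte-Carlo error on the recovery
fraction small.

## Worked example

```{r example}
study <- simulate_study(sim_config(seed = 1))
res <- eqi(study)
res
glance(res)
```

The per-cell inconsistency matrix and plots:

```{r plots, fig.width = 6, fig.height = 3}
evi <- attr(res, "evi")
autoplot(evi)
autoplot(res)
```

And the convention sweep on the same data:

```{r sweep}
head(eqi_sweep(study))
```

## Limitations

* The index measures *consistency*, not correctness: a method that is
  reproducibly biased scores well. Pair it with orthogonal purity evidence
  (immunoassays, contamination panels) before ranking methods overall.
* With 4 replicates the per-cell standard deviation is itself noisy; the
  index is meaningful as an average over samples, not per cell.
* Pooled quantile transformation couples extreme method biases into the
  spacing of plotting positions; the per-method pooling scope is provided to
  check sensitivity.
* Significance testing between methods' EQI values is out of scope; the
  recovery experiment's Monte-Carlo spread is the provided uncertainty
  handle.
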