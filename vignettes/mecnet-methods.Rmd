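---
title: "Methods behind mecnet: electrochemistry, diversity null models and signed co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mecnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mecnet analyses microbial electrolysis cell (MEC) experiments along three
axes: reactor performance from the potentiostat current trace, community
structure from ASV count tables, and taxon-taxon association from signed
co-occurrence networks. This vignette explains the models and procedures,
the defaults and why they were chosen, and what the synthetic-data module
does and does not emulate.

## Electrochemical metrics

The raw signal is the current `I(t)` sampled every 30 s, together with the
projected anode area (m^2) and the liquid volume `V` (L).

* **Rebinning.** Groups of ten consecutive 30-s measurements are averaged
  into 5-min bins, timestamped at the group midpoint. A trailing partial
  group is averaged over the samples it has rather than dropped, so a peak
  at the very end of a batch cycle is not lost.
* **Peak current** for a window (typically one batch cycle) is the highest
  5-min bin inside it.
* **Total charge** is the trapezoidal integral of the *raw* trace over the
  window, with the boundary values linearly interpolated when the window
  bounds fall between samples. The integral is taken on the raw samples
  rather than the 5-min bins because charge is a property of the continuous
  signal; the bins exist to stabilise peak and lag readouts. On a smooth
  signal at 30-s sampling the trapezoid error is far below 0.1%.
* **Coulombic efficiency** is the charge divided by
  `F * V * sum(b_s * dC_s)` over the consumed substrates, where
  `F = 96,485.3` C/mol e-, `dC_s` is the consumed concentration (mol/L,
  consumption positive) and `b_s` the electrons released by complete
  oxidation to CO2: 8 for acetate, 14 for propionate, 20 for butyrate,
  from the balanced half-reactions (e.g. C2H3O2- + 2H2O -> 2CO2 + 7H+ +
  8e-). The `b` values are overridable for other substrates. CE above 1 on
  inconsistent inputs is reported as-is — clipping would hide a
  measurement problem.
* **Lag time** is the time from the start of the trace to the first 5-min
  bin whose current density exceeds 1 A/m^2 (the conventional threshold
  for "substantial" current in these reactors). A trace that never crosses
  returns `NA` flagged `crossed = FALSE` rather than a fake number;
  never crossing is a legitimate experimental outcome.

The window is always a parameter: per-cycle and cumulative efficiencies are
both expressible, since published analyses differ in which they report.

## Hill diversity and the Raup-Crick null model

Alpha diversity uses Hill numbers: `(sum p_i^q)^(1/(1-q))` (with the
`exp(-sum p log p)` limit at `q = 1`). The order `q` tunes how much
abundance matters: `q = 0` counts ASVs, `q = 1` counts "common" ASVs,
`q = 2` dominants. Pairwise dissimilarity is the two-sample local overlap
`(beta - 1)/(N - 1)` with `N = 2` and `beta = gamma / alpha`, the ratio of
the pooled to the mean within-sample Hill number; it is 0 for identical
compositions and 1 for disjoint ASV sets at any order.

Observed dissimilarities do not say whether two communities are more alike
than chance would make them. The Raup-Crick procedure answers that by
reassembling each sample at random — keeping its observed ASV richness and
read depth fixed — and scoring the observed dissimilarity as a percentile
of the null ensemble (999 iterations by default), with ties given half
weight so the score is unbiased under the null. Values below 0.05 mean
"significantly similar", above 0.95 "significantly dissimilar".

The assembly weighting is a design choice the original null-model
literature leaves open. mecnet draws ASVs into a null sample with
probability proportional to their *occupancy frequency* across the table
for `q = 0`, and to their metacommunity *mean relative abundance* for
abundance-weighted orders; reads beyond the one that guarantees presence
are distributed multinomially by mean relative abundance. Two
implementation details matter:

* Each sample gets one null ensemble and pairs compare matching
  iterations, reducing the assembly cost from one ensemble per *pair* to
  one per *sample*.
* The weighting is validated by self-calibration rather than against any
  external run: when communities are generated by the null process itself,
  the percentiles must be uniform on [0, 1]. The test suite checks this
  with 200 independent pairs at 199 iterations (Kolmogorov-Smirnov
  p > 0.01). The calibration fixture uses mild occupancy heterogeneity
  (weights within a factor of two) and per-sample richness between 12 and
  30 of 60 ASVs; under strong weight skew the occupancy estimate of the
  inclusion weights saturates and the percentiles drift conservative,
  which is a known property of occupancy-based null models, not a bug.

The Mantel test (Pearson correlation of off-diagonal distances, p from
joint row/column permutations) links community dissimilarity to
performance differences; it is implemented directly and cross-checked
against vegan in the tests.

## The network stage

Networks are built per habitat (anode and cathode biofilms behave
differently, so their samples are never pooled). The stages:

1. **Filter**: keep ASVs present in at least 2 samples of the group *and*
   exceeding 0.1% relative abundance in at least one sample. Both rules
   together remove singletons and ultra-rare noise without dropping
   habitat specialists.
2. **Merge**: ASVs within cophenetic distance epsilon are collapsed by
   single linkage, counts summed, the cluster labelled by its most
   abundant member. Amplicon denoisers can split one organism into two
   ASVs differing by a single base; such pairs otherwise show up as a
   spurious perfect positive edge. The default epsilon 0.004 is roughly
   one substitution over a 253-bp V4 fragment (1/253 = 0.004
   substitutions/site) — on a tree whose branch lengths are expected
   substitutions per site this captures exactly the one-base-pair case.
   It is configurable because tree scale varies with the inference model.
3. **Correlate**: Spearman rank correlation (average ranks for ties, p
   from the t approximation) on relative abundances, and SparCC on counts.
4. **Validate**: an edge requires `|rho| > 0.6` *and* `|r_sparcc| > 0.6`
   *and* both p-values `< 0.05` *and* agreeing signs. Requiring both
   models' p-values is the stricter of the possible readings and is the
   default here; a sign conflict between the models invalidates the edge
   because no sign could be defended. No multiple-testing correction is
   applied by default (mirroring common practice for these dual-criterion
   networks); a Benjamini-Hochberg option exists. Isolated nodes are
   dropped before summary statistics — node counts in published property
   tables are typically edge-touching nodes, not all filtered ASVs.
5. **Summarise**: node/edge counts, signed percentages (computed from
   counts, so they sum to exactly 100), edge density `2E/(N(N-1))`,
   modules and modularity from greedy modularity maximisation on the
   unsigned graph, and the mean local clustering coefficient (vertices of
   degree < 2, where the coefficient is undefined, are excluded from the
   average). Which community algorithm and which clustering statistic a
   given study used is rarely stated, so both are selectable
   (`louvain`, global transitivity) and no claim is made that module
   counts match any particular published table.

### SparCC

Read counts are compositional: closure to a fixed library size induces
spurious negative correlation among relative abundances. SparCC works on
log-ratio variances `t_ij = var(log(x_i/x_j))`, which are closure
invariant. Under the model `t_ij = w_i + w_j - 2 rho_ij sqrt(w_i w_j)` and
the sparsity assumption that most `rho_ij ~ 0`, the basis variances `w_i`
solve the linear system `(D-2) w + J w = rowSums(t)`; correlations follow
and are clipped to [-1, 1]. Pairs violating sparsity (|rho| above 0.1) are
excluded from the system one at a time — strongest first, up to 10
exclusions — and the system is re-solved. Sampling noise in the counts is
propagated by drawing fractions from Dirichlet(counts + 1) twenty times
and taking the element-wise median.

Numerical safeguards: every ASV must stay in at least two ratio equations,
and an exclusion whose re-solve produces a non-positive basis variance or
a correlation pinned at +-1 is undone — with few ASVs the reduced system
can lose identifiability, and a pinned correlation is a symptom, not a
signal. The estimator needs at least 4 samples and 4 ASVs.

Significance comes from a permutation null: each ASV column is permuted
independently across samples (destroying association, preserving
marginals), SparCC is recomputed, and `p = (1 + #{|r_null| >= |r_obs|}) /
(1 + B)` with `B = 99` bootstraps by default. The add-one rule keeps p in
(0, 1]; note that `B >= 20` is needed before any pair can clear
`p < 0.05`.

## The synthetic-data module

The generator exists so the full chain is testable without sequencing
data. It emulates:

* **Current traces**: zero current (plus Gaussian sensor noise, s.d.
  0.05 A/m^2) before the lag; after the lag, batch cycles every 2.5 days
  with a fast exponential rise on feeding (time constant ~1 min) and an
  exponential decay toward depletion; cycle peaks modulated by a logistic
  envelope reaching a 5 A/m^2 plateau at the peak day times a linear
  decline afterwards (default 40%), mimicking biofilm maturation and the
  later shift toward non-electrogenic carbon sinks. The envelope is a
  caricature of the published trace shapes, chosen for qualitative
  fidelity; it is not fit to any measured curve, because no quantitative
  biofilm-growth model is available to fit.
* **Count tables**: a logistic-normal-multinomial. Log-abundances are
  multivariate normal with unit variances and a mean profile spanning 4
  natural-log units (a few dominant taxa, many rare — the usual amplicon
  shape), optionally shifted per habitat; softmax gives proportions;
  multinomial sampling gives counts summing exactly to the library size
  (20,000 by default). All planted structure (positive/negative pairs)
  lives in the latent covariance, which is the regime SparCC's
  compositional model assumes. Sample sizes for the headline property
  checks are 60 samples (network sensitivity) and 500 samples (SparCC
  calibration), with 30 ASVs.
* **Trees**: a random bifurcating phylogeny with branch lengths uniform
  on [0.05, 0.3], onto which near-identical ASV pairs are grafted as
  cherries at cophenetic distance 0.002 — below the 0.004 merge radius,
  while every other pair sits far above it.

What it does **not** emulate: sequencing error and chimeras, ASV-inference
artefacts beyond the near-identical split, overdispersion beyond
multinomial (no Dirichlet-multinomial layer), phylogenetic signal in
abundances, temporal autocorrelation between samples, or mechanistic
electrode kinetics. Passing tests therefore demonstrate correctness of the
computational chain under a clean compositional model, not robustness to
every artefact of real amplicon data.

## Known limitations

* The dual criterion's Spearman leg is computed on relative abundances,
  where closure noise from the other taxa attenuates rank correlations —
  negative associations especially. At 60 samples a latent correlation of
  -0.8 sometimes yields an observed Spearman magnitude just under the 0.6
  cut-off, so pipeline sensitivity for planted signs sits near, not far
  above, the 0.8 mark; SparCC, designed for compositions, is the stabler
  leg.
* Raup-Crick percentiles are discrete (multiples of 1/iterations) and
  pairs sharing a sample share its null ensemble; for strict independence
  across pairs, score disjoint pairs.
* Greedy modularity is a heuristic; module counts should be read as
  indicative, and differ between algorithms on dense graphs.

## Reproducibility

Every stochastic routine takes an explicit seed; the pipeline derives
per-stage substreams from one master seed, so re-running a configuration
reproduces every output byte for byte, and adding a stage does not perturb
the draws of earlier stages.
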