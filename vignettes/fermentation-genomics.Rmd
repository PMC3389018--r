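---
title: "Fermentation functional genomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fermentation functional genomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermgenomics)
```

# The problem

Industrial lactic acid bacteria such as *Lactobacillus plantarum* express
largely the same gene complement across strains, so genotype–phenotype
matching cannot explain why the *same* strain behaves differently under
different fermentation regimes. The complementary strategy implemented here
is transcriptome–trait matching: grow one strain under a combinatorial set
of fermentation conditions (temperature, pH, NaCl, amino-acid dosage, O~2~
availability), record physiological phenotypes (maximum specific growth
rate µ~max~, biomass yield OD~max~, endpoint organic-acid concentrations),
measure genome-wide transcript levels, and mine the joint dataset for
condition–phenotype and transcript–phenotype associations.

`fermgenomics` implements that full analysis chain as composable, tested R
functions: design handling, two-channel array preprocessing, a
Bayesian-regularized t-test, a Mann–Whitney condition–phenotype screen,
random-forest transcript–metabolite association, an iterative grouped-gene
growth-rate signature search, condition-response network reconstruction
with functional-class enrichment, and inverted-repeat promoter-motif
discovery — plus a synthetic-study generator with planted ground truth that
makes every downstream claim testable without any external download.

# The fermentation design

The packaged study table (`table1_fermentations()`) records 30 pH-controlled
batch fermentors: a balanced fractional factorial over five factors
(0/300 mM NaCl, 1.1/2.0× amino acids, 28/37 °C, pH 5.2/5.8/6.4, N~2~/air
sparging) realizing 24 distinct condition tuples, plus replicated controls
spread over five fermentation days. Condition levels are categorical codes
and are compared exactly, never with floating tolerances.
`distinct_conditions()`, `phenotype_range()` and `validate_design()` expose
the design structure; the balance report counts distinct design points per
factor level and flags two-factor combinations the design never realizes
(whose interactions are therefore invisible).

One fermentor (F30) was run without in-growth sampling; it carries a
`transcriptome = FALSE` flag that excludes it from transcriptome-linked
analyses while keeping it in phenotype-only screens (both choices are
available via `include_f30`).

A note on one number: the recorded OD~max~ column has its maximum at
fermentor F17 (7.74); summaries quoting 7.73 round this to the value of the
runner-up fermentor. `phenotype_range()` reports what the table contains.

# Statistical models

## Mann–Whitney condition–phenotype screen

`phenotype_screen()` runs a two-sided Mann–Whitney U test for every
(comparison × phenotype) cell — one comparison per two-level factor and all
three pH pairs. The p-value is exact (full enumeration of the U
distribution) when the combined sample size is ≤ 12 and tie-free, and a
tie-corrected normal approximation with continuity correction otherwise.
Direction is reported from group medians (undefined on ties), so tests stay
two-sided. Benjamini–Hochberg correction is applied over the whole screen
as a single family; a per-phenotype family can be had by screening one
phenotype at a time. On the packaged design every comparison exceeds 12
samples, so the normal branch is the operative one; its null rejection rate
is calibrated by simulation in the test suite (≈ 0.046 at nominal 0.05).

## Bayesian-regularized differential expression

`cybert_test()` stabilizes gene-level variance at small n by shrinking the
pooled two-class variance toward a *background* variance: the mean pooled
variance over a sliding window (default 101 genes) of genes ranked by mean
expression. With prior weight λ (default 10 pseudo-observations),

$$ s^2_{reg} = \frac{\lambda s^2_{bg} + (n_A+n_B-2)\, s^2_{pooled}}
                    {\lambda + n_A + n_B - 2}, $$

and the statistic is referred to Student's t with
$\lambda + n_A + n_B - 2$ degrees of freedom, two-sided, followed by BH-FDR
over all genes. At λ = 0 this is *exactly* the pooled t-test (asserted to
1e-9 in the tests); when the window spans the whole gene list every gene
shares one background variance. Two properties worth knowing:

* Under a homoscedastic null the test is mildly **conservative** (observed
  p < 0.05 fraction ≈ 0.040 at n = 4 vs 4): the windowed prior stabilizes
  the denominator beyond what the nominal degrees of freedom credit. It is
  never anti-conservative in our simulations, and a median null study
  yields zero BH discoveries.
* Replicate fermentations are treated as independent samples within their
  class; no dye covariate is modelled (see the normalization section).

`de_by_factor()` fixes the contrast orientation: group A is always the high
level (37 °C, 300 mM, 2.0×, O~2~, the higher pH), so `ratio > 1` reads
"higher expression at the high level" throughout the package.

## Random-forest metabolite association

Metabolite phenotypes are dichotomized at the median (values at or below
the median are "low"; a tertile-extremes split is available) and a
1000-tree classification forest (Gini criterion, √p candidate features per
split) predicts the class from the transcriptome. Genes are ranked by mean
decrease in Gini impurity; `top_overlap()` intersects top-k lists across
phenotypes and `concordance()` counts jointly significant, same-direction
genes between two differential-expression contrasts. Gini importances of
correlated predictors share credit, so stability requires many trees; the
seed is mandatory and results are exactly reproducible given it.

## The iterative grouped-gene growth-rate signature

Single transcripts correlate too noisily with µ~max~, so
`iterate_signature()` searches for a *group* of genes whose averaged
expression tracks it. Iteration k scores groups of k genes from the current
pool by |Pearson r| between the group's average expression and µ~max~,
keeps the 300 best groups, and the union of their members becomes the next
(smaller) pool with k+1. Genes that matter recur in many top groups, so the
pool contracts; the search stops when an iteration fails to shrink the pool
(returning the previous pool) or k exceeds the pool size. Both Pearson and
Spearman correlations of the final set are reported, along with the
per-sample averaged expression for plotting (`autoplot()`).

Design choices where the procedure was genuinely open:

* *Group formation.* Groups are k-subsets of the pool, enumerated
  exhaustively while $\binom{|pool|}{k} \le$ `max_candidates` (200 000 by
  default — which makes iteration 1 exactly "top 300 single genes" and the
  result seed-independent whenever enumeration is exhaustive), and sampled
  uniformly (seeded, distinct members within a group) beyond that.
* *Scoring.* Absolute Pearson correlation, so coherently anti-correlated
  groups are retained with their sign reported.
* *Stopping.* "Fails to shrink" means the new pool is at least as large as
  the old one; the smaller previous pool is the result.

On default synthetic studies (a 47-gene planted signature at per-gene
correlation 0.9) the search converges in 3–5 iterations, recovers the
planted set with Jaccard ≳ 0.65 and reaches Pearson ≳ 0.99 for the averaged
set — the synthetic analogue of a ~47-gene set with R² ≈ 0.95. The exact
published gene list is not reproducible from scratch: it depends on the
deposited microarray data and an unstated grouping scheme.

## Response clouds, network and enrichment

A factor's *response cloud* is the set of genes with q < 0.05 and fold
change > 1.5 in that factor's contrast, split by direction. The fold
threshold is configurable because reasonable analyses have used both 1.5
and 2; 1.5 is the default here. pH (three levels) collapses to one factor:
a gene is pH-responsive if any pairwise contrast passes, with direction
taken from the widest (5.2 vs 6.4) contrast. Cloud members partition by
their exact factor set ("single or shared responses");
`network_from_clouds()` builds the bipartite factor–gene graph and
`export_network()` writes Cytoscape-compatible SIF or GraphML whose
re-import reproduces the node and edge multisets.
`enrichment()` scores functional classes by the upper-tail hypergeometric
probability against a flat gene→class map — no ontology graph propagation,
matching the custom functional classification this organism's annotation
uses.

## Inverted-repeat motif discovery

Dimeric transcription factors commonly bind inverted repeats
(arm–spacer–reverse-complement-arm). `find_inverted_repeats()` enumerates
every inverted repeat realized in the foreground promoters (arms 4–7 bp,
spacers 0–6 bp by default), counts promoters *containing* each candidate
(presence/absence, not site counts — an inverted repeat is its own reverse
complement, so forward-strand scanning finds sites planted on either
strand), and scores enrichment by the upper-tail hypergeometric p of
foreground presence within foreground + background, BH-adjusted. Candidates
below 30% foreground presence are dropped; near-duplicates (site-set
Jaccard > 0.8) merge into their best-scoring representative, which can be a
*nested* sub-palindrome of a longer planted repeat when the shorter arm
matches one extra promoter. Reported motifs carry a site list, a PWM (+0.5
pseudocounts) and per-column information content; `scan_motif()` performs a
both-strand log-odds scan at a fraction-of-maximum threshold. Windows
containing N never match; sequence-logo rendering is out of scope (the
PWM/IC tables are the logo's content).

Upstream regions come from `extract_upstream()`: 0-based half-open
coordinates, `[start − L, start)` for + genes and the reverse complement of
`[end, end + L)` for − genes, truncated and flagged at contig edges;
default L = 300 bp, the scale at which single promoters and their operators
live in this genome.

# The synthetic-study generator

`simulate_study()` exists so that every claim above is testable against a
known truth. Its defaults *are* the study conditions: the packaged
30-fermentor design, 3099 genes (29 transcriptome samples), log-normal
baseline expression (log2 mean 8, sd 2, mimicking array intensity ranges),
residual log2 noise 0.5, and the planted structures:

* 40 up + 40 down condition-responsive genes per factor at 2 log2 units —
  the effect scale at which a well-powered array study calls essentially
  everything, so recovery failures indicate implementation bugs, not power
  limits;
* a 47-gene µ~max~ signature at per-gene Pearson 0.9;
* a latent citrate→succinate *conversion activity*, high at 0 mM NaCl
  (0.7 vs 0.3) with substantial within-salt-group variation (sd 0.4):
  citrate falls and succinate rises with it (scale 6 mM each), producing
  the strong citrate–succinate anti-correlation (r ≈ −0.95) and a
  salt–citrate association that is significant but far from deterministic;
  5 metabolite-associated genes shift 3 log2 units per SD of this activity,
  so they — not the salt-responsive sets — are the best predictors of the
  citrate/succinate classes;
* phenotype effects mirroring the recorded associations (growth faster at
  37 °C and low pH, yield depressed by salt, acetate raised by aeration);
* the palindromic core `TTGTGCACAA` (flanked AG…TT) inserted on a random
  strand at a random offset into 80% of the O~2~-up promoters (300 bp,
  GC 0.45).

One global seed drives a hierarchy of per-component generator streams, so
switching a component off never perturbs the draws of another, and
identical configs give bit-identical studies. The probe-level mode (3
probes/gene, two channels, a smooth logistic intensity-dependent dye bias
of 0.6 log2 units on the Cy5 channel) gives the normalization stage
something real to remove.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: correlated gene–gene noise and batch/day effects,
heavy-tailed and intensity-dependent array noise, operon structure, genuine
regulatory pleiotropy between the planted sets, and fermentation kinetics
(phenotypes are endpoint values). Recovery rates on synthetic studies are
upper bounds on what the same thresholds achieve on real arrays.

# Preprocessing model

`lowess_normalize()` detrends M = log2(Cy5/Cy3) against
A = (log2 Cy5 + log2 Cy3)/2 per array (span 0.4, tricube weights, 3
robustness iterations — conventional two-channel defaults) and splits the
correction symmetrically between channels, so per-probe average intensity
is preserved exactly and a constant channel bias is removed completely.
`interslide_scale()` multiplies each array by one scalar equalizing total
linear signal at the geometric-mean target; `collapse_probes()` takes the
median probe intensity per gene (even counts: mean of the two middle
values). Loop-design/dye-swap linear modelling is deliberately not
implemented: the pipeline represents absolute per-channel expression after
normalization, and replicate arrays enter downstream tests as independent
samples.

# Numerical conventions and degenerate inputs

All expression is log2; every reported "ratio" is
$2^{\Delta \overline{\log_2}}$. Zero-variance genes score 0 in the
signature search; a zero standard error with zero mean difference gives
t = 0, p = 1. Ties at phenotype extremes resolve to the first record in
table order. Exact/approximate Mann–Whitney switching is at combined
n = 12. Constant µ~max~, empty groups, empty networks, overlapping DE
groups, non-positive intensities and sub-minimal group sizes are all
explicit errors with typed conditions (`fermgenomics_error_*`). PWM columns
are checked stochastic to 1e-9; information content uses a uniform
background, so it is bounded by 2 bits/column.

# Problem sizes used by the test suite

Unit tests run on reduced instances (hundreds of genes) chosen so each
property is exercised meaningfully; the end-to-end recovery checks run at
the full study scale — 3099 genes × 29 samples — with 5–10 replicate seeds
for stochastic claims, 50 null studies for the differential-expression
calibration and 200 for the screen calibration. These sizes give Monte-Carlo
standard errors comfortably below the asserted margins.

# Known limitations

* The published 47-gene signature, the 415/407 concordance counts, the
  exact Table-2 p-values and the 5 shared top-10 genes depend on the
  deposited GEO data and unstated analysis settings; the package
  demonstrates the *procedures* on planted synthetic analogues instead.
* The regularized t-test's q-values inherit the mild conservatism noted
  above.
* Motif discovery is restricted to inverted repeats by design; it is not a
  general PWM discovery engine.
* The pipeline store is file-based and single-machine; no database or web
  service is provided.
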