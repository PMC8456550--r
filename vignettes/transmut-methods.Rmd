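---
title: "Methods: mapping trans-regulatory mutations with transmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping trans-regulatory mutations with transmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transmut)
```

## The problem

A chemical mutagenesis screen in *S. cerevisiae* produces haploid mutants
whose expression of a focal reporter gene has shifted. Each mutant carries a
few dozen mutations, almost all irrelevant. transmut implements the
statistical chain that turns raw sequencing and cytometry readouts into a
set of *trans*-regulatory mutations and their properties:

1. filter freebayes variant calls to a trustworthy mutation list;
2. test each mutation for association with the phenotype using allele
   counts from two phenotypically extreme segregant pools (bulk segregant
   analysis, BSA-Seq);
3. call expression changes from 96-well plate cytometry with a permutation
   test that respects the nested plate variance structure;
4. contrast the resulting *trans*-regulatory set against the non-regulatory
   background (spectrum, genomic regions, amino-acid changes, regulator
   networks, eQTL overlap);
5. quantify mutagenesis loads and competitive fitness for follow-up
   experiments.

A seeded synthetic-data generator (`sim_config()` and the `simulate_*`
functions) produces every input with the statistical structure these
analyses assume, so the whole pipeline is exercised end to end without any
external download.

## Bulk-segregant association: the G-test on allele counts

A mutant is crossed to an unmutagenized mapper strain and a large spore
population is raised. Two bulks are collected from the 2.5% tails of the
fluorescence distribution and sequenced. For each mutation, the read counts
(ref/alt in low bulk, ref/alt in high bulk) form a 2x2 table; the
likelihood-ratio statistic

$$G = 2 \sum_{\text{cells}} O \ln (O / E),$$

with expectations from the table margins, is chi-square distributed with
1 df under the null of equal allele frequency in both bulks. Cells with
$O = 0$ contribute 0, natural logarithms are used throughout, and p-values
come from the continuous chi-square distribution without continuity
correction. A mutation is called associated when $p < 0.001$, i.e.
$G > 10.828$; with ~1800 tests per screen this costs about 1.8 expected
false positives. The signed variant of the statistic (`signed_association`)
attaches the direction of the frequency shift: positive when the mutant
allele is enriched in the high-fluorescence bulk.

Aneuploidies are handled by the same machinery at the chromosome scale:
reads on the candidate chromosome versus the rest of the genome in the two
bulks (`aneuploidy_g_test`), with candidates flagged beforehand from a
~1.4-fold coverage ratio against the median of the other chromosomes
(`detect_aneuploidy`; trisomies in segregant pools sit near 1.5-fold).

### Disambiguating linked candidates

Associated mutations closer than 25 cM (single-linkage chains within a
chromosome, `group_linked`) are usually driven by one causal site. The
published analyses report a "resampling test" for whether the top-G variant
is significantly stronger than its linked partners without specifying the
resampling scheme; `compare_linked_g` declares a parametric bootstrap as
the implementation: alternate counts for each variant and bulk are redrawn
as Binomial(observed depth, observed alternate frequency) and the p-value
is the fraction of resamples in which the nominally stronger variant fails
to out-score the weaker one. This uses only observed depths and
frequencies and is reproducible by seed. Physical positions are converted
to genetic distance at 0.4 cM/kb (the *S. cerevisiae* genome-wide average)
unless an explicit genetic map is supplied.

## Variant filtering and annotation

`filter_variants` applies the strict inequalities QUAL > 200, MQM > 27,
DP > 20, AO > 3, RO > 3, FREQ.REF > 0.1, PAIRED > 0.8, PAIREDR > 0.8,
SAP < 100, EPP < 50, RPP < 50. Two conventions are deliberate:

* **Missing annotation = rule passes.** The filter set was tuned to retain
  confirmed variants; absence of an optional INFO annotation is not
  evidence against a call. Removal counts per rule are attached for audit.
* **Multi-allelic records are decomposed per ALT allele before filtering**,
  with per-ALT INFO fields (comma lists) split alongside.

Annotation works in 1-based inclusive coordinates throughout (the yeast
annotation convention); BED-like interchange is converted at the boundary.
Codon effects are computed on the annotated coding strand and translated
with the standard genetic code; mutation spectra collapse complementary
changes (G>A and C>T are one class, G:C→A:T). A useful structural check,
enforced by exhaustive enumeration in the test suite: under EMS-type
transitions only, premature stops can arise solely from arginine,
glutamine and tryptophan codons.

## Plate cytometry and the two-level permutation test

The normalization chain is: per-cell size normalization (a single log-log
regression of fluorescence on cell size per sample — the multi-step
procedure used with real FCS data is intentionally simplified to its core),
plate position-effect correction, optional calibration onto an
expression-linear scale, autofluorescence subtraction, and scaling to the
reference strain mean.

Position effects are estimated from the ~20 control wells per plate with a
3-parameter linear model in numeric row and column; a full row/column
factor model would be unidentifiable from 20 controls. The correction is
additive and leaves the control mean unchanged. Replicate outliers beyond
5 MAD from the replicate median are dropped; when the MAD is exactly zero
nothing is dropped (a degenerate spread estimate should not discard data).
Calibration anchors are user-supplied and default to the identity, since
the fitted log-linear coefficients for the published reporter are not
available; a two-anchor curve with log-log slope 3 encodes the relation
"a 1% fluorescence change is a ~3% expression change".

Replicate measurements of the same strain at the same plate position are
more similar than measurements at different positions, so a naive t-test of
4 test replicates against a pooled reference panel is overpowered. The
two-level permutation test (`two_level_permutation_test`) draws, per
iteration, one panel position; computes the observed difference of means
`D_obs` against that position; pools the 8 values, resplits them at random
into two sets of four, giving `D_perm`; and scores `D = D_obs - D_perm`.
The p-value is the fraction of negative `D` among non-zero `D` (1 if all
are zero). Exact ties - for example when the random split reproduces the
original grouping - are detected with a scale-aware floating-point
tolerance so the p-value is invariant to shifting or rescaling all values.
Panel-position draws and permutations consume a single seeded generator
stream in that documented order. An expression change is *called* only when
it is both significant (p < 0.05) and larger than 1% in relative terms.

The same machinery serves to compare a single-site mutant against the EMS
mutant carrying the same mutation, with the EMS mutant's replicates
standing in for the panel; that usage is an interpretation, not a distinct
procedure.

## Set contrasts and enrichment

`compare_mutation_property` builds 2 x k tables (mutation set x category)
and applies the r x c G-test, df = (r-1)(c-1). Amino-acid change
frequencies are tabulated over a 21 x 21 (20 residues + stop) grid in
percent, with unobserved changes reported as absent rather than zero;
`aa_permutation_test` permutes set labels with set sizes fixed.
Over-dispersion of per-strain mutation counts is tested with the dispersion
index (variance/mean) against a parametric Poisson bootstrap at the sample
mean - the published analysis reports only "a resampling test", so the
statistic is declared here. eQTL-interval overlap takes the union of
intervals (order-independent, split-invariant), counts membership with
1-based inclusive ends, and reports the genome fraction covered against a
12.07 Mb genome.

All resampling p-values are raw resample fractions, matching the
"proportion of D values" convention of the source analyses, so they are bit
reproducible under a fixed seed and can be exactly 0 at finite resample
counts; the (k+1)/(n+1) correction is deliberately not applied.

## Regulator network inference

From three TF x target evidence matrices (binding, expression-activator,
expression-inhibitor), a TF is a level-1 regulator of the focal gene when
it has binding AND expression evidence on it, and a level-k regulator when
it has both on a level-(k-1) regulator. A TF reachable at several depths is
recorded at its minimum level (the published description does not say
whether level-2 excluded level-1 members; the minimum-level convention is
declared here). Self-regulating TFs never promote themselves across
levels. Edges carry "activates"/"inhibits"/"unknown" according to which
expression matrices support them.

## Fitness and mutagenesis loads

Competitive fitness is `exp(slope)` of the OLS regression of
`ln(YFP/GFP)` counts on generations of co-growth; the two-timepoint design
(before/after ~10 h) runs through the same code path. The 17:3 initial
mixing ratio is a generator default, not an estimator assumption.
Error-prone PCR loads use `Nmut = mu * D * L` with
`D = ln(output/input)/ln 2` summed over rounds; values are returned at full
precision with `round1()` provided for one-decimal reporting.

## What the synthetic generator emulates - and what it does not

`simulate_ems_cohort` draws per-strain mutation counts from a two-component
Poisson mixture (default components 15 and 32.8 with equal weights, mean
23.9). The mixture models rate heterogeneity across cells - the probable
cause of the observed non-Poisson counts - but its parameters are a free
configuration choice, not an inference from data. Spectrum defaults: 96.3%
G:C→A:T among SNVs, 2.7% indels, 69.4% of sites coding, positions uniform
over a 16-chromosome 12.07-Mb genome.

`simulate_cross_and_bulks` builds spores as per-chromosome Markov chains
over the strain's mutation sites with adjacent-site recombination from the
Haldane map function $r = (1 - e^{-2d/100})/2$ (no interference - adequate
for the pairwise linkage behaviour the analysis exercises), phenotypes as
the sum of inherited causal effects plus standard normal noise, truncation
selection of the 2.5% tails, and read counts Binomial at a Poisson-
distributed depth (default mean 105x).

**Spore population size.** The real experiment sorts bulks of 1.5e5 cells
from >1e8 spores, so bulk allele frequencies carry essentially no
spore-sampling variance and read sampling dominates. A desk-scale simulation
must preserve that regime: with tails of only ~125 spores the added
Binomial(125, 0.5) frequency variance inflates the per-variant type-I error
of the G-test roughly 14-fold at 100x depth, which would misrepresent the
experiment's operating characteristics. The default `n_spores = 40000`
(tails of 1000) keeps the spore-sampling contribution to the frequency
variance at a tenth of the read-sampling contribution while remaining fast;
configurations can scale it in either direction.

`simulate_plate_experiment` composes well values as
`truth x (1 + row/col gradient) x lognormal noise + autofluorescence`, with
controls at mirror-symmetric plate positions (so the control-mean gradient
is exactly centred) and a reference panel whose between-position log-sd is
sqrt(2) times the within-position log-sd - the nested structure that
motivates the two-level test. `simulate_competition_assay` follows
deterministic log-ratio dynamics sampled with Binomial counting noise
(`Inf` events gives noise-free fractions).

Features of real data deliberately not modelled: FCS event-level
artefacts, doublets and gating; sequencing error beyond binomial count
sampling; growth or selection inside bulks after sorting; mutation-rate
sequence context. Passing tests therefore validate the statistical
machinery under its stated assumptions, not instrument-level behaviour.

## Numerical choices and degenerate inputs

* G computed with `0 * ln(0/E) = 0`; tiny negative rounding clamped at 0;
  zero table margins are errors, not silent zeros.
* `compare_linked_g` refuses fewer than 100 resamples (unstable p).
* `summarize_well` falls back to the raw median with a warning when cell
  size is constant; it requires at least 100 events.
* Position-effect correction skips plates with fewer than 3 controls, with
  a warning.
* Calibration curves must be strictly increasing in both coordinates;
  queries beyond the anchors extrapolate along the end segments.
* `sim_config` validates probabilities, positivity, and
  `bulk_fraction < 0.5`; mixture weights are normalized.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to give tight Monte-Carlo error at
interactive speed: 1000 random tables for the G-test oracle comparison;
1000 synthetic null strains (2000 permutation iterations each) for the
two-level calibration; 200 power and 400 null cross simulations at 100x
coverage for the BSA operating characteristics; 100 competition
simulations spanning fitness 0.6-1.1 at 5000 events; exhaustive
enumeration over all 64 codons for the EMS nonsense property and over all
70 splits of 8 values for the permutation-test oracle.

## Known limitations

* The additive position-effect correction cannot perfectly invert a
  multiplicative gradient for strains far from the reference level (the
  residual error is second-order, (effect) x (gradient)).
* The linked-variant bootstrap conditions on observed depths and
  frequencies; it is a declared stand-in for an unspecified published
  procedure, as is the dispersion-index statistic.
* Genetic distances default to a genome-average map density; real
  recombination-rate variation along chromosomes is not modelled.
* The cytometry chain starts from per-cell (size, fluorescence) pairs or
  well summaries; binary FCS parsing and model-based gating are out of
  scope.

## A worked end-to-end example

```{r example}
cfg <- sim_config(n_strains = 1, coverage = 100)
cohort <- simulate_ems_cohort(cfg, seed = 7)
bulks <- simulate_cross_and_bulks(cohort, cfg, seed = 8)
calls <- call_associations(bulks, alpha = 0.001)
subset(calls, associated,
       select = c(variant_id, chrom, pos, G, p, sign, causal))
attr(calls, "expected_false_positives")
```

The causal mutation (and any variant linked to it) surfaces with a large
signed G; the expected false-positive count makes the multiple-testing
burden explicit.
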