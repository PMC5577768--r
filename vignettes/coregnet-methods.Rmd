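---
title: "Methods: seed-centred co-expression networks and downstream validation statistics"
author: "coregnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-centred co-expression networks and downstream validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coregnet)
```

## The problem this package addresses

Metabolic insecticide resistance in malaria vectors such as *Anopheles
gambiae* is driven by over-expression of detoxification enzymes (cytochrome
P450s, glutathione transferases, carboxylesterases, UGTs, ABC transporters),
but the transcription factors controlling that over-expression are hard to
identify directly. One productive strategy is indirect: collect a compendium
of expression contrasts, each comparing a field-derived resistant population
with a susceptible reference strain, and ask which transcripts co-vary with
a candidate regulator — a "seed" — across the whole compendium. Transcripts
whose log2 fold-change profile tracks the seed's profile across dozens of
independent contrasts are candidate targets of the regulator. The approach
applies to any seed; the motivating application is the small Maf
transcription factor, whose heterodimer with cnc (the insect Nrf2) binds
antioxidant response elements (AREs) upstream or downstream of
detoxification genes.

`coregnet` implements that analysis as a reusable pipeline: compendium
assembly, seed-centred correlation networks, a binomial model for how often
a transcript would be significant across experiments by chance, ARE motif
scanning of gene flanks, hypergeometric enrichment for short transcript
lists, and the statistics of the two validation arms (knockdown qPCR and
WHO-tube bioassays). A synthetic-data module generates all of these inputs
with known ground truth, which is how the package tests itself end to end.

## The compendium and its container

The central object is a transcript × experiment matrix of log2 fold changes
(resistant vs susceptible), with an optional parallel matrix of
per-experiment differential-expression calls (adjusted p ≤ 0.05, made
upstream by limma or similar — fitting those models is out of scope here;
the calls are inputs). Both live in a `ResistanceCompendium`, a
`SummarizedExperiment` subclass, so experiment metadata (population,
country, species, reference strain, accession) travels in `colData`.

Heterogeneous platforms rarely share a probe index, so `mergeExperiments()`
joins single-experiment tables onto a common transcript index — union join
by default, which preserves every observation for pairwise-complete
correlation; intersection is available when strictness matters more than
coverage. Probe-level matrices are reduced to transcript level by
`aggregateProbes()`, averaging log2 fold changes across a transcript's
probes (arithmetic mean on the log scale; a probe mapping to two
transcripts is an error, not a guess).

## Seed-centred correlation networks

`correlateWithSeeds()` computes, for each seed, the Pearson correlation
(Spearman optional) between the seed's profile and every transcript's
profile, using pairwise-complete observations. Correlations built on few
co-observed experiments are unstable, so pairs with fewer than `minOverlap`
(default 10 of 27) shared experiments are omitted and counted rather than
reported. `buildNetwork()` then applies the analysis's hard cutoff: an edge
exists when |r| ≥ 0.8 in the default *signed* mode — correlation and
anti-correlation are both biologically meaningful for a repressor/activator
— or when r ≥ 0.8 in *positive* mode. Both conventions appear in practice
and both are first-class here; the threshold is a design constant of the
analysis, not a significance test, so no edge-wise p-values or multiple
testing are involved. Edges are sorted by (seed, decreasing |r|, partner
id) so exports are byte-reproducible. A Euclidean row-distance companion
output (`seedEuclideanDistance()`) is provided for completeness; the edge
statistic itself is the correlation, since a ±0.8 cutoff is only meaningful
on a correlation scale.

Networks export as Cytoscape SIF, edge TSV, or GraphML (via igraph), which
replaces interactive viewers in a scripted pipeline.

For short member lists (the interesting networks here have ~3–250
partners), `hypergeometricEnrichment()` tests annotation categories with
the upper-tail hypergeometric probability P(X ≥ k) and Benjamini–Hochberg
adjustment across categories. Long-list enrichment through external web
services is deliberately out of scope.

## The binomial chance model

A transcript that is differentially expressed in many of the compendium's
experiments is interesting, but *some* recurrence arises by chance: on
these arrays roughly half of all called transcripts are significant in any
one experiment. The chance model treats per-experiment significance calls
as independent Bernoulli(p) events, with p estimated by
`estimateSuccessProbability()` as the unweighted mean over experiments of
the per-experiment significant fraction (that matches the verbal definition
"average number of significant transcripts as a proportion of transcripts
on the array"; a transcript-count-weighted variant is exposed for unequal
array sizes). For the motivating compendium this average is 0.4692; the
synthetic generator uses the same value as its default.

`binomialTail()` reports P(X ≥ k) — "significant in at least k of n
experiments" — computed as a log-space sum of `dbinom` point masses, exact
to enumeration at n = 27, with P(X ≥ 0) = 1 by construction.
`chanceAssessment()` applies this per transcript, adjusting n to the
transcript's non-missing call count, since a transcript absent from an
array cannot succeed there. The upper tail (not the point mass) is the
reported statistic, because the scientific question is "at least this
recurrent"; the point mass is exposed too. The model is used descriptively
on a handful of genes, so no multiple-testing correction is applied by
default (a BH option exists). Inter-experiment dependence (shared
populations or platforms) is knowingly ignored — that is the model's own
assumption, reproduced faithfully.

## ARE motif scanning of gene flanks

Regulatory input is assessed by scanning 2000 bp upstream and downstream of
each gene for the ARE, either as the IUPAC consensus
`TMAnnRTGAYnnGCRwwww` (the `areConsensus` constant) or as a JASPAR-style
position frequency matrix.

Conventions, each a deliberate choice:

* **Orientation.** Upstream/downstream are defined in transcription
  orientation, the regulatory-genomics convention: for a minus-strand gene
  the upstream flank lies 3′ of the gene in contig coordinates and is
  returned reverse-complemented, reading 5′→3′ relative to the gene.
* **Strands.** Both strands of each flank are scanned by default: AREs are
  orientation-variable and enhancer logic does not respect strand.
* **Edges.** Flanks truncate at contig boundaries with the realized length
  recorded, rather than erroring — real assemblies require it.
* **N handling.** An `N` in the genome matches nothing except the motif's
  any-base wildcard position; in PWM mode an `N` scores −∞, so an
  N-containing window can never reach a positive threshold.
* **Overlaps.** All hits are reported; no greedy masking.
* **Offsets.** The R API reports 1-based positions (the
  GRanges/Bioconductor idiom); BED export converts to 0-based half-open.

In PWM mode, counts become frequencies with a total pseudocount of 0.8
distributed by the background composition (uniform 0.25 by default), scores
are log2-odds against that background, and a window is a hit when its score
reaches a fraction (default 0.8) of the maximal achievable score. These are
common matrix-scan defaults; the consensus mode is the default overall
because the consensus string is the better-documented form of this motif.
A degenerate 0/1 matrix at threshold 1.0 reproduces consensus matching
exactly, which the test suite uses as a cross-check, along with a
brute-force per-offset rescoring oracle and `Biostrings::matchPWM`.

`flankPresenceTable()` assembles the per-gene presence/absence table
(upstream?, downstream?, both/either/none summary) that the analysis uses
to ask how many co-correlated transcripts carry the motif.

## qPCR: standard curves and ΔΔct

Knockdown validation rests on relative quantification.
`fitStandardCurve()` regresses Ct on log10(relative quantity) over a
dilution series (the canonical 1, 1:5, 1:25, 1:125 design) and converts the
slope to amplification efficiency; curves outside the MIQE 90–120% window
are flagged. Efficiency is a QC gate, not a correction: `deltaDeltaCt()`
assumes doubling chemistry (2^−ΔΔct), which is the ΔΔct method's own
assumption.

`deltaCt()` averages technical replicates, then normalizes each target
against the arithmetic mean Ct of the two housekeeping genes (geometric
mean on the expression scale) — standard practice where only the gene pair,
not the combination rule, is specified. Per-replicate ΔΔct values subtract
the comparator group's mean Δct; `welchTest()` compares Δct values between
treatment and comparator with Welch's unequal-variance t-test, biological
replicates being the unit of analysis.

One genuinely open choice: how to summarize per-replicate ratios into a
group ratio. The geometric mean (equivalently 2^−mean(ΔΔct)) is the
default because it makes the comparator group's own summary exactly 1 — the
self-normalization every ΔΔct analysis implicitly promises — and because
averaging on the log (cycle) scale is unbiased where the arithmetic mean of
ratios is Jensen-inflated under noise. Arithmetic mean and median are
available via `summary=`.

## Bioassay mortality statistics

WHO-tube results arrive as dead/exposed counts per replicate tube.
`mortalityAnova()` takes the tube as the experimental unit, transforms
per-tube mortality with the plain arcsine square root (`asin(sqrt(p))`; the
Freeman–Tukey variant is not used because nothing in the design calls for
it), and runs one-way ANOVA with Tukey HSD post hoc via the
studentized-range distribution. Bartlett's test checks variance
homogeneity; Shapiro–Wilk runs on the pooled ANOVA residuals, the standard
target when the test's object is not otherwise specified. Degenerate
inputs are defined rather than fatal: identical values in every tube give
F = 0 and Tukey p = 1; zero-variance groups make Bartlett undefined and
are reported as such. No Abbott correction for control mortality is
applied by default (an analysis that needs it can pre-adjust the counts).

With two groups, ANOVA collapses to the pooled t-test through F = t², and
Tukey's adjusted p equals the t-test p — both identities are exercised in
the tests as algebraic checks on the implementation.

## The synthetic-data generators

Every stage above is validated against generated data with known truth.
What the generators emulate — and what they do not — bounds what a passing
test suite demonstrates.

**Compendium** (`simulateCompendium()`). Module members follow a
latent-factor model: the seed's profile s is drawn once per experiment set,
and each member is `sign · s + noise`, with the noise SD solved so the
population member–seed correlation equals the requested ρ. This is the
simplest generative model with the correlation structure the network stage
assumes, and it supports anti-correlated members. Defaults are the study's
conditions: 27 experiments, a 14-member module at ρ = 0.9 around one seed,
seed SD of 1 log2 unit (a typical fold-change spread), background
significance probability 0.4692. Significance calls are i.i.d. Bernoulli —
deliberately mirroring the chance model's independence assumption — and
missingness is uniform MCAR, recorded in the truth output. Real compendia
violate all three idealizations (inter-experiment correlation from shared
platforms and populations, non-random missingness, non-Gaussian tails), so
recovery results here certify the machinery, not field performance. One
consequence of the latent-factor construction worth knowing: member–seed
*sample* correlations within a replicate are positively dependent through
the shared s, so whole-module recall fluctuates more across replicates than
an independent-member calculation would predict.

**Genome** (`simulateGenome()`). Contigs are i.i.d. draws from a base
composition; genes are laid out with at least a full flank of clearance so
plants can never collide; motif instances are concrete realizations of the
consensus planted at recorded offsets on recorded strands in recorded
flanks. The truth table is exact, so presence calls can be compared
gene-by-gene. Tests that require the motif to be *absent* elsewhere use a
G-free background composition, which makes the consensus (fixed TGA…GC
core) unrealizable by chance; a uniform background at these scan lengths
would produce occasional true chance hits, which is realistic but not a
truth-table test.

**qPCR plate** (`simulateQpcrPlate()`). Ct values follow
`base − log(1+E)(relative quantity) + sample offset + noise`, housekeepers
at quantity 1, with per-sample offsets that cancel through Δct (as loading
differences do in practice). Defaults: three biological × three technical
replicates, 0.2-cycle noise, doubling chemistry, and a knockdown ratio of
0.26 — the knockdown depth of the more effective construct in the
motivating experiments.

**Bioassay** (`simulateBioassay()`). Dead counts are Binomial(n, mortality)
per tube — exactly the sampling model the arcsine-ANOVA is meant to
stabilize. Defaults are 3 tubes of 25, the WHO design.

All generators are reproducible from one integer seed; the four generators
split that seed into separate streams so adding one stage never perturbs
another's draws.

## Numerical choices and problem sizes

* Binomial tails: log-space summation of point masses; exact 1 at k = 0.
* Correlations: `stats::cor(use = "pairwise.complete.obs")`, checked
  against a naive double-loop oracle to 1e-12 on small matrices.
* PWM scanning: vectorized window scoring over an integer-encoded
  sequence; ties at the threshold are included (score ≥ cutoff), and the
  summation order matches the per-offset oracle so equality is exact.
* Tukey p-values come from `ptukey`, which is numerically integrated;
  identity checks against the two-group t-test hold to ~1e-7 absolutely.
* Calibration tests use 10^4 null replicates for the Welch and ANOVA
  type-I error rates, 50 replicates of the 27 × 2014 compendium for network
  recovery, 200 noisy plates for ratio recovery, and 100 random 5-kb
  sequences for the PWM oracle — sizes chosen so each check has enough
  Monte-Carlo precision to be meaningful while the whole suite stays quick
  on a laptop.

## Known limitations

* The chance model inherits its independence assumption from the original
  analysis; with correlated experiments its tails are optimistic.
* Pairwise-complete correlation can use different experiment subsets for
  different partners of the same seed; `minOverlap` bounds but does not
  remove this.
* Consensus scanning is exact matching — a sequence one mismatch away from
  the consensus is invisible in consensus mode; PWM mode with a lower
  threshold is the tool for graded similarity.
* The ΔΔct implementation assumes doubling chemistry; efficiency results
  gate but do not correct (a Pfaffl-style correction would need per-gene
  efficiencies fed into the ratio formula, which the data model supports
  but the default path does not apply).
* Whether the original ±0.8 cutoff was applied to Pearson or rank
  correlation, and whether flank orientation was transcript- or
  contig-relative, are not recoverable from the source description; both
  options are exposed with the defaults argued above.
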