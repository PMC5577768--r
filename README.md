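# coregnet

Regulator discovery from compendia of insecticide-resistance expression
contrasts, for vector-biology and molecular-entomology groups working on
metabolic resistance in mosquitoes and other pest insects.

Detoxification genes (P450s, GSTs, COEs, UGTs, ABC transporters) are
over-expressed in resistant populations, but the transcription factors
driving them are hard to pin down directly. `coregnet` implements the
indirect route: given a compendium of transcript × experiment log2
fold-change contrasts (each comparing a resistant field population with a
susceptible reference strain), it asks which transcripts co-vary with a
candidate regulator — a *seed* such as the small Maf transcription factor —
and follows up with motif, recurrence and validation statistics.

The pipeline's core pieces:

* **Seed-centred correlation network.** For seed *s* and transcript *t*
  with profiles over experiments, the edge statistic is the
  pairwise-complete Pearson correlation *r(s, t)*; an edge exists when
  |*r*| ≥ τ (default τ = 0.8; signed mode keeps anti-correlations,
  positive mode requires *r* ≥ τ). A hard threshold, not a test.
* **Binomial chance model.** With per-experiment significance probability
  *p* (the average significant fraction per array, estimated from the
  call matrix), the probability that a null transcript is significant in
  at least *k* of *n* experiments is
  P(X ≥ k), X ~ Binomial(n, p).
* **ARE motif scanning.** Strand-aware extraction of 2000-bp flanks in
  transcription orientation, scanned for the antioxidant response element
  — IUPAC consensus `TMAnnRTGAYnnGCRwwww` or a JASPAR-style PFM scored as
  log2-odds with a threshold at a fraction of the maximal score.
* **Hypergeometric enrichment** with Benjamini–Hochberg adjustment for
  short member lists.
* **Validation-arm statistics.** Standard-curve amplification efficiency
  ((10^(−1/slope) − 1) × 100, MIQE 90–120% gate), two-housekeeper ΔΔct
  relative quantification with Welch's t on Δct, and arcsine-√ ANOVA with
  Tukey HSD, Bartlett and Shapiro–Wilk for WHO-tube mortality.
* **Synthetic-data generators** for all four input kinds, with exact
  ground truth, so the whole pipeline is testable without any downloads.

## Worked example

```r
library(coregnet)

# A study-scale compendium: 27 contrasts, 2000 background transcripts,
# one planted 14-member module around the seed at rho = 0.9.
cmp <- simulateCompendium(nExperiments = 27, nBackground = 2000,
  modules = list(moduleSpec("MafS", sprintf("MAF_M%02d", 1:14), rho = 0.9)),
  rngSeed = 42)

net <- buildNetwork(correlateWithSeeds(cmp, "MafS", minOverlap = 10),
                    threshold = 0.8, mode = "signed")
net
#> CoexpressionNetwork: 1 seed(s), 14 edge(s), signed mode, tau = 0.8
#>   MafS: 14 co-correlated transcript(s)
head(networkEdges(net), 3)
#>   seed_id partner_id         r n_pairs sign
#> 1    MafS    MAF_M14 0.9478596      27    +
#> 2    MafS    MAF_M01 0.9337869      27    +
#> 3    MafS    MAF_M12 0.9267551      27    +
```

All 14 planted members — and nothing else — cross the ±0.8 cutoff: at
n = 27 experiments a background |r| ≥ 0.8 is vanishingly rare.

```r
estimateSuccessProbability(cmp)
#> ChanceModel: n = 27 experiments, p(success) = 0.4659, p(failure) = 0.5341
chanceAssessment(cmp, c("MafS", "MAF_M01"))
#>   transcript_id n_called n_significant    p_tail
#> 1          MafS       27            13 0.5104425
#> 2       MAF_M01       27            11 0.7880537
```

Significance in 13 of 27 arrays is unremarkable when roughly 47% of calls
are significant anyway — the point of the chance model.

```r
are <- motifModel("ARE", consensus = areConsensus)
scanMotif(are, "TAATTGTGACTTGCGAAAA")
#>   start end strand               match score rel_score
#> 1     1  19      + TAATTGTGACTTGCGAAAA     1         1

sim <- simulateGenome(nGenes = 20, rngSeed = 42,
                      background = c(A = 1/3, C = 1/3, G = 0, T = 1/3))
pt <- flankPresenceTable(sim$genes, sim$genome, are)
attr(pt, "summary")
#>   both either   none
#>      5     10      5
```

The presence table (which genes carry an ARE upstream, downstream, both or
neither) matches the generator's plant plan exactly.

```r
plate <- simulateQpcrPlate(ratios = c(MafS = 0.26), rngSeed = 42)
deltaDeltaCt(deltaCt(plate))$groups
#>   gene   group     ratio n        t      df            p
#> 1 MafS     GFP 1.0000000 3       NA      NA           NA
#> 2 MafS MafS_kd 0.2593734 3 15.32087 3.99574 0.0001066244

ba <- simulateBioassay(mortality = c(GFP = 0.039, MafS_kd = 0.216),
                       rngSeed = 42)
mortalityAnova(ba)
#> WHO-bioassay mortality comparison [deltamethrin]
#>   GFP          3 tubes, mean mortality 5.3%
#>   MafS_kd      3 tubes, mean mortality 21.3%
#>   ANOVA (arcsine-transformed): F(1,4) = 8.077, p = 0.04677
#>     Tukey GFP vs MafS_kd: p = 0.04677
#>   Bartlett: K2 = 3.780, p = 0.05187
#>   Shapiro-Wilk (residuals): W = 0.9218, p = 0.5181
```

A true knockdown to 0.26 of control is recovered as 0.259 from a noisy
3 × 3-replicate plate, and a 3.9% → 21.6% mortality shift is detected at
p < 0.05 from three tubes of 25 — the realistic sensitivity of these
designs.

See `vignettes/coregnet-methods.Rmd` for the models, assumptions, defaults
and limitations in full.

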