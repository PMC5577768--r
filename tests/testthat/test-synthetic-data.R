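test_that("compendium generator is deterministic and respects the noise-free limit", {
  cfg <- list(nExperiments = 12L, nBackground = 30L,
              modules = list(moduleSpec("S", paste0("m", 1:5), rho = 1)),
              missingFraction = 0.1, rngSeed = 7L)
  a <- do.call(simulateCompendium, cfg)
  b <- do.call(simulateCompendium, cfg)
  expect_identical(foldChanges(a), foldChanges(b))
  expect_identical(significanceCalls(a), significanceCalls(b))

  # rho = 1 implies zero noise: members are exact (signed) copies of the seed
  noiseless <- simulateCompendium(nExperiments = 10L, nBackground = 0L,
    modules = list(moduleSpec("S", c("m1", "m2"), rho = 1, sign = "-")),
    rngSeed = 3L)
  fc <- foldChanges(noiseless)
  expect_equal(fc["m1", ], -fc["S", ])
  expect_equal(cor(fc["S", ], fc["m2", ]), -1)
})

test_that("member-seed correlation calibrates to the configured rho", {
  rs <- replicate(100, {
    cmp <- simulateCompendium(nExperiments = 27L, nBackground = 200L,
      modules = list(moduleSpec("S", paste0("m", 1:14), rho = 0.9)),
      rngSeed = sample.int(1e6, 1))
    fc <- foldChanges(cmp)
    mean(apply(fc[paste0("m", 1:14), ], 1, function(x) cor(x, fc["S", ])))
  })
  set.seed(1)
  expect_lt(abs(mean(rs) - 0.9), 0.03)
})

test_that("generative calibration tightens with many experiments", {
  cmp <- simulateCompendium(nExperiments = 500L, nBackground = 0L,
    modules = list(moduleSpec("S", paste0("m", 1:10), rho = 0.7)),
    rngSeed = 11L)
  fc <- foldChanges(cmp)
  rs <- apply(fc[paste0("m", 1:10), ], 1, function(x) cor(x, fc["S", ]))
  expect_lt(max(abs(rs - 0.7)), 0.1)
})

test_that("invalid module and config parameters are rejected with context", {
  expect_error(moduleSpec("badmod", "m1", rho = 1.2), "badmod")
  expect_error(moduleSpec("badmod", "m1", rho = 0), "badmod")
  expect_error(simulateCompendium(nExperiments = 2L), ">= 3")
  expect_error(
    simulateCompendium(modules = list(moduleSpec("S", c("a", "a"), 0.5))),
    "unique")
})

test_that("planted motifs are recoverable by exact string search at recorded coordinates", {
  sim <- simulateGenome(nGenes = 12, rngSeed = 5,
                        background = c(A = 1/3, C = 1/3, G = 0, T = 1/3))
  expect_gt(nrow(sim$truth), 0)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    seg <- as.character(Biostrings::subseq(sim$genome[[tr$contig]],
                                           tr$contig_start, tr$contig_end))
    expected <- if (tr$contig_strand == "+") tr$sequence else rc_chr(tr$sequence)
    expect_identical(seg, expected)
  }
})

test_that("minus-strand upstream plants land 3' of the gene in contig coordinates", {
  plan <- data.frame(gene = "GENE001", region = "upstream",
                     offset = 10, strand = "+")
  # force a minus-strand first gene by trying seeds until one appears
  for (s in 1:20) {
    sim <- simulateGenome(nGenes = 2, rngSeed = s, plantPlan = plan)
    st <- as.character(GenomicRanges::strand(sim$genes))[1]
    if (st == "-") break
  }
  expect_identical(st, "-")
  g_end <- GenomicRanges::end(sim$genes)[1]
  expect_gt(sim$truth$contig_start[1], g_end)
})

test_that("qPCR plate generator inverts through the ddCt pipeline", {
  # ratio 1, zero noise: every ddCt is 0
  p1 <- simulateQpcrPlate(ratios = c(g1 = 1), noiseSD = 0,
                          sampleEffectSD = 0, rngSeed = 2)
  dd1 <- deltaDeltaCt(deltaCt(p1))
  expect_equal(dd1$replicates$ddct, rep(0, nrow(dd1$replicates)))

  # ratio 0.25, doubling chemistry, zero noise: exact recovery
  p2 <- simulateQpcrPlate(ratios = c(g1 = 0.25), efficiency = 1,
                          noiseSD = 0, sampleEffectSD = 0, rngSeed = 2)
  dd2 <- deltaDeltaCt(deltaCt(p2))
  expect_equal(dd2$groups$ratio[dd2$groups$group == "MafS_kd"], 0.25)

  expect_error(simulateQpcrPlate(ratios = c(g1 = -1)), "positive")
})

test_that("noisy plates recover the published knockdown depth on average", {
  ratios <- vapply(1:200, function(i) {
    p <- simulateQpcrPlate(ratios = c(MafS = 0.26), noiseSD = 0.2,
                           bioReps = 3, rngSeed = i)
    dd <- deltaDeltaCt(deltaCt(p))
    dd$groups$ratio[dd$groups$group == "MafS_kd"]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.26) / 0.26, 0.05)
})

test_that("bioassay generator matches its binomial design", {
  z <- simulateBioassay(mortality = c(a = 0, b = 1), tubes = 4, rngSeed = 1)
  expect_true(all(z$dead[z$group == "a"] == 0))
  expect_true(all(z$dead[z$group == "b"] == z$exposed[z$group == "b"]))

  many <- simulateBioassay(mortality = c(g = 0.5), tubes = 1000,
                           perTube = 25, rngSeed = 4)
  expect_lt(abs(mean(many$dead / many$exposed) - 0.5), 0.02)

  expect_error(simulateBioassay(mortality = c(g = 1.5)), "\\[0, 1\\]")
})
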