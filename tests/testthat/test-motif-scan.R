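are <- motifModel("ARE", consensus = areConsensus)

test_that("GFF3 annotation round-trips and reports malformed coordinates", {
  sim <- simulateGenome(nGenes = 4, rngSeed = 2)
  d <- withr::local_tempdir()
  paths <- writeGenomeFiles(sim, d)
  genes <- readAnnotation(paths[["gff3"]])
  expect_equal(GenomicRanges::start(genes), GenomicRanges::start(sim$genes))
  expect_equal(GenomicRanges::end(genes), GenomicRanges::end(sim$genes))
  expect_equal(as.character(GenomicRanges::strand(genes)),
               as.character(GenomicRanges::strand(sim$genes)))
  expect_equal(genes$gene_id, sim$genes$gene_id)

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "ctg01\tsrc\tgene\t100\t50\t.\t+\t.\tID=g1"), bad)
  expect_error(readAnnotation(bad), "line 2")

  nogenes <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "ctg01\tsrc\texon\t10\t50\t.\t+\t.\tID=x1"), nogenes)
  expect_warning(out <- readAnnotation(nogenes), "no 'gene' features")
  expect_length(out, 0)
})

test_that("flank extraction follows coordinate arithmetic and strand convention", {
  contig <- Biostrings::DNAStringSet(random_dna(10000, seed = 6))
  names(contig) <- "c1"
  genes <- GenomicRanges::GRanges("c1", IRanges::IRanges(5001, 6000),
                                  strand = c("+"))
  genes$gene_id <- "gplus"
  fl <- extractFlanks(genes, contig, flankLen = 2000)
  expect_equal(as.character(fl$upstream[[1]]),
               as.character(Biostrings::subseq(contig[[1]], 3001, 5000)))
  expect_equal(as.character(fl$downstream[[1]]),
               as.character(Biostrings::subseq(contig[[1]], 6001, 8000)))

  minus <- GenomicRanges::GRanges("c1", IRanges::IRanges(5001, 6000),
                                  strand = "-")
  minus$gene_id <- "gminus"
  flm <- extractFlanks(minus, contig, flankLen = 2000)
  expect_equal(as.character(flm$upstream[[1]]),
               rc_chr(as.character(Biostrings::subseq(contig[[1]], 6001, 8000))))
  expect_equal(as.character(flm$downstream[[1]]),
               rc_chr(as.character(Biostrings::subseq(contig[[1]], 3001, 5000))))

  # truncation at contig edge records realized length
  edge <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 400), strand = "+")
  edge$gene_id <- "gedge"
  fle <- extractFlanks(edge, contig, flankLen = 2000)
  expect_equal(fle$info$upstream_length, 100L)
  expect_true(fle$info$upstream_truncated)
  expect_equal(as.character(fle$upstream[[1]]),
               as.character(Biostrings::subseq(contig[[1]], 1, 100)))

  expect_error(extractFlanks(
    GenomicRanges::GRanges("c9", IRanges::IRanges(1, 5), strand = "+",
                           gene_id = "x"), contig), "c9")
})

test_that("consensus scanning honours IUPAC degeneracy and strand symmetry", {
  hit <- scanMotif(are, "TAATTGTGACTTGCGAAAA", bothStrands = FALSE)
  expect_equal(hit$start, 1L)
  expect_equal(hit$strand, "+")

  # N in the sequence only matches the wildcard position
  seq_n <- "TAATTGTGACTTGCGAAAA"
  substr(seq_n, 1, 1) <- "N"          # position with code T: no match
  expect_equal(nrow(scanMotif(are, seq_n, bothStrands = FALSE)), 0L)
  seq_n2 <- "TAATTGTGACTTGCGAAAA"
  substr(seq_n2, 4, 4) <- "N"         # wildcard position: still a match
  expect_equal(nrow(scanMotif(are, seq_n2, bothStrands = FALSE)), 1L)

  # strand symmetry: hits on s mirror reverse-strand hits on revcomp(s)
  set.seed(10)
  s <- paste0(random_dna(300), "TAATTGTGACTTGCGAAAA", random_dna(100))
  h_fwd <- scanMotif(are, s)
  h_rc <- scanMotif(are, rc_chr(s))
  expect_equal(nrow(h_fwd), nrow(h_rc))
  L <- nchar(s); w <- motifWidth(are)
  mirrored <- sort(L - (h_rc$start + w - 1L) + 1L)
  expect_equal(sort(h_fwd$start), mirrored)
  expect_setequal(h_fwd$match, h_rc$match)
})

test_that("sequences shorter than the motif yield empty results, not errors", {
  expect_equal(nrow(scanMotif(are, "ACGT")), 0L)
  expect_equal(nrow(scanMotif(are, "")), 0L)
})

test_that("pwm scanning equals brute-force rescoring and matchPWM", {
  pfm <- consensusToPFM(areConsensus) * 10 + 1
  mot <- motifModel("pwmARE", pfm = pfm, thresholdFraction = 0.8)
  pw <- pwmScores(mot)
  for (case in 1:10) {
    s <- random_dna(2000, seed = 100 + case)
    got <- scanMotif(mot, s, bothStrands = FALSE)
    oracle <- brute_pwm_hits(pw$scores, pw$maxScore,
                             mot@thresholdFraction, s)
    expect_equal(got$start, oracle$start)
    expect_equal(got$score, oracle$score)
    # independent cross-check against Biostrings
    bm <- Biostrings::matchPWM(pw$scores, Biostrings::DNAString(s),
                               min.score = mot@thresholdFraction * pw$maxScore)
    expect_equal(got$start, BiocGenerics::start(bm))
  }
})

test_that("pwm relative score is 1 on the consensus-best sequence", {
  pfm <- consensusToPFM("TGACTCA") * 5
  mot <- motifModel("m", pfm = pfm, thresholdFraction = 0.99)
  best <- scanMotif(mot, "TGACTCA", bothStrands = FALSE)
  expect_equal(best$rel_score, 1)
  pw <- pwmScores(mot)
  expect_equal(best$score, pw$maxScore)
})

test_that("consensus mode equals pwm mode with a degenerate matrix at threshold 1", {
  mot_c <- motifModel("c", consensus = "TGASTCA")
  mot_p <- motifModel("p", pfm = consensusToPFM("TGASTCA"),
                      thresholdFraction = 1)
  for (case in 1:20) {
    s <- random_dna(500, seed = 200 + case)
    expect_equal(scanMotif(mot_c, s)$start, scanMotif(mot_p, s)$start)
  }
})

test_that("presence table equals the plant truth on synthetic genomes", {
  sim <- simulateGenome(nGenes = 20, rngSeed = 9,
                        background = c(A = 1/3, C = 1/3, G = 0, T = 1/3))
  pt <- flankPresenceTable(sim$genes, sim$genome, are)
  truth_up <- unique(sim$truth$gene_id[sim$truth$region == "upstream"])
  truth_down <- unique(sim$truth$gene_id[sim$truth$region == "downstream"])
  expect_setequal(pt$gene_id[pt$upstream], truth_up)
  expect_setequal(pt$gene_id[pt$downstream], truth_down)
  both <- intersect(truth_up, truth_down)
  expect_setequal(pt$gene_id[pt$category == "both"], both)
  expect_equal(unname(attr(pt, "summary")["both"]), length(both))

  # all-none plan in a G-free background: zero presence everywhere
  plan <- data.frame(gene = sim$genes$gene_id, region = "none")
  sim0 <- simulateGenome(nGenes = 20, rngSeed = 9, plantPlan = plan,
                         background = c(A = 1/3, C = 1/3, G = 0, T = 1/3))
  pt0 <- flankPresenceTable(sim0$genes, sim0$genome, are)
  expect_false(any(pt0$upstream | pt0$downstream))
  expect_equal(unname(attr(pt0, "summary")["none"]), 20L)
})

test_that("presence is invariant to reverse-complementing the genome", {
  sim <- simulateGenome(nGenes = 8, rngSeed = 13,
                        background = c(A = 1/3, C = 1/3, G = 0, T = 1/3))
  pt <- flankPresenceTable(sim$genes, sim$genome, are)
  flipped_genome <- Biostrings::reverseComplement(sim$genome)
  L <- Biostrings::width(sim$genome)[match(
    as.character(GenomicRanges::seqnames(sim$genes)), names(sim$genome))]
  flipped_genes <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(sim$genes),
    ranges = IRanges::IRanges(
      start = L - GenomicRanges::end(sim$genes) + 1L,
      end = L - GenomicRanges::start(sim$genes) + 1L),
    strand = ifelse(as.character(GenomicRanges::strand(sim$genes)) == "+",
                    "-", "+"))
  flipped_genes$gene_id <- sim$genes$gene_id
  pt2 <- flankPresenceTable(flipped_genes, flipped_genome, are)
  expect_equal(pt$upstream, pt2$upstream)
  expect_equal(pt$downstream, pt2$downstream)
})

test_that("hits export to BED6 with capped scaled scores", {
  sim <- simulateGenome(nGenes = 10, rngSeed = 21,
                        background = c(A = 1/3, C = 1/3, G = 0, T = 1/3))
  pt <- flankPresenceTable(sim$genes, sim$genome, are)
  bed <- withr::local_tempfile(fileext = ".bed")
  exportHitsBed(pt, bed)
  hits <- attr(pt, "hits")
  if (nrow(hits)) {
    got <- rtracklayer::import(bed, format = "BED")
    expect_equal(length(got), nrow(hits))
    expect_equal(BiocGenerics::start(got), hits$contig_start)
    expect_equal(BiocGenerics::end(got), hits$contig_end)
    expect_true(all(got$score >= 0 & got$score <= 1000))
  }
})

test_that("JASPAR matrix files parse into pwm motifs", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0000.1 testmotif",
               "A [ 10  0  5 ]",
               "C [  0 10  5 ]",
               "G [  0  0  0 ]",
               "T [  0  0  0 ]"), f)
  mot <- readJasparPfm(f)
  expect_s4_class(mot, "MotifModel")
  expect_equal(mot@name, "testmotif")
  expect_equal(motifWidth(mot), 3L)
  expect_equal(unname(mot@pfm["A", 1]), 10)
})
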