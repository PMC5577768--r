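## Per-generator seed offsets: one global integer seed, stream-split so the
## four generators draw from distinct, reproducible streams.
.sub_seed <- function(rngSeed, offset) {
  as.integer((as.numeric(rngSeed) * 7919 + offset) %% 2147483647)
}

#' Specify a planted co-regulated module
#'
#' A module is a seed transcript plus members whose fold-change profiles
#' share the seed's latent profile: member values are generated as
#' `x = sign * s + noise`, with the noise standard deviation solved so that
#' the population correlation between member and seed equals `rho`.
#'
#' @param seedId seed transcript id.
#' @param members character vector of member transcript ids.
#' @param rho target member-seed correlation, in (0, 1].
#' @param sign `"+"` for correlated members, `"-"` for anti-correlated.
#' @return a classed list consumed by [simulateCompendium()].
#' @export
moduleSpec <- function(seedId, members, rho, sign = "+") {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho > 1)
    stop("module '", seedId, "': rho must lie in (0, 1]")
  if (!sign %in% c("+", "-"))
    stop("module '", seedId, "': sign must be '+' or '-'")
  if (!length(members)) stop("module '", seedId, "': needs members")
  structure(list(seed_id = seedId, members = as.character(members),
                 rho = rho, sign = sign), class = "moduleSpec")
}

#' Simulate a fold-change compendium with planted co-regulated modules
#'
#' Emulates a compendium of resistant-vs-susceptible expression contrasts:
#' each experiment contributes one column of log2 fold changes. Module
#' members follow a latent-factor model around their seed's profile
#' (population correlation `rho`, sign as specified); background
#' transcripts are i.i.d. Gaussian and independent of everything.
#' Significance calls are i.i.d. Bernoulli per transcript per experiment —
#' `pSignificant` for background (mirroring the chance model's own
#' independence assumption), `pSignificantMember` for seeds and members.
#' Missing fold changes are inserted completely at random. Fully
#' reproducible from `rngSeed`.
#'
#' @param nExperiments number of experiments (default 27, the compendium
#'   scale of the motivating study); must be >= 3.
#' @param nBackground number of independent background transcripts.
#' @param modules list of [moduleSpec()]s; member ids must be unique across
#'   modules and disjoint from seed ids.
#' @param seedSD standard deviation of the latent seed profile, log2 units.
#' @param pSignificant per-experiment probability that a background
#'   transcript is called significant (default 0.4692, the average
#'   per-array significant proportion of the motivating compendium).
#' @param pSignificantMember same for seeds and members (defaults to
#'   `pSignificant`).
#' @param missingFraction fraction of fold-change entries set missing, in
#'   [0, 1).
#' @param rngSeed integer seed.
#' @return a [ResistanceCompendium] with `log2fc` and `significant` assays;
#'   ground truth available via [compendiumTruth()].
#' @examples
#' cmp <- simulateCompendium(nBackground = 50,
#'   modules = list(moduleSpec("MafS", paste0("M", 1:14), rho = 0.9)),
#'   rngSeed = 1)
#' cmp
#' @export
simulateCompendium <- function(nExperiments = 27L, nBackground = 2000L,
                               modules = list(
                                 moduleSpec("MafS", sprintf("MAF_M%02d", 1:14),
                                            rho = 0.9)),
                               seedSD = 1, pSignificant = 0.4692,
                               pSignificantMember = pSignificant,
                               missingFraction = 0, rngSeed = 1L) {
  if (nExperiments < 3L) stop("'nExperiments' must be >= 3")
  if (pSignificant < 0 || pSignificant > 1)
    stop("'pSignificant' must lie in [0, 1]")
  if (missingFraction < 0 || missingFraction >= 1)
    stop("'missingFraction' must lie in [0, 1)")
  modules <- lapply(modules, function(m) {
    if (!inherits(m, "moduleSpec")) do.call(moduleSpec, m) else m
  })
  seed_ids <- vapply(modules, `[[`, character(1), "seed_id")
  member_ids <- unlist(lapply(modules, `[[`, "members"))
  planted <- c(seed_ids, member_ids)
  if (anyDuplicated(planted))
    stop("seed/member ids must be unique across modules: ",
         paste(unique(planted[duplicated(planted)]), collapse = ", "))
  bg_ids <- sprintf("BG%05d", seq_len(nBackground))
  if (length(intersect(planted, bg_ids)))
    stop("module ids collide with background ids")
  set.seed(.sub_seed(rngSeed, 0L))
  exp_ids <- sprintf("E%02d", seq_len(nExperiments))
  fc <- matrix(NA_real_, length(planted) + nBackground, nExperiments,
               dimnames = list(c(planted, bg_ids), exp_ids))
  truth_rows <- list()
  for (m in modules) {
    s <- stats::rnorm(nExperiments, 0, seedSD)
    fc[m$seed_id, ] <- s
    noise_sd <- seedSD * sqrt(1 / m$rho^2 - 1)
    sgn <- if (m$sign == "+") 1 else -1
    for (mem in m$members) {
      x <- sgn * s + stats::rnorm(nExperiments, 0, noise_sd)
      fc[mem, ] <- x
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        seed_id = m$seed_id, member_id = mem, rho = m$rho, sign = m$sign,
        sample_r = stats::cor(s, x), stringsAsFactors = FALSE)
    }
  }
  if (nBackground)
    fc[bg_ids, ] <- matrix(stats::rnorm(nBackground * nExperiments, 0, seedSD),
                           nBackground, nExperiments)
  sig <- matrix(NA, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  sig[planted, ] <- stats::runif(length(planted) * nExperiments) <
    pSignificantMember
  if (nBackground)
    sig[bg_ids, ] <- stats::runif(nBackground * nExperiments) < pSignificant
  if (missingFraction > 0) {
    drop <- which(stats::runif(length(fc)) < missingFraction)
    fc[drop] <- NA_real_
  }
  cmp <- ResistanceCompendium(fc, significance = sig)
  S4Vectors::metadata(cmp)$truth <- list(
    modules = if (length(truth_rows)) do.call(rbind, truth_rows)
              else data.frame(),
    seed_ids = seed_ids,
    p_significant = pSignificant,
    p_significant_member = pSignificantMember,
    missing_fraction = missingFraction,
    missing_mechanism = "MCAR uniform",
    rng_seed = rngSeed)
  cmp
}

## Draw one concrete realization of an IUPAC consensus (N realized over
## A/C/G/T, never a literal N).
.realize_consensus <- function(consensus) {
  codes <- strsplit(toupper(consensus), "")[[1L]]
  paste(vapply(codes, function(cd) {
    set <- setdiff(.IUPAC_SETS[[cd]], "N")
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

#' Simulate a genome with planted motif instances in gene flanks
#'
#' Builds random contigs from a background base composition, lays
#' non-overlapping genes on alternating strands with at least `flankLen`
#' clearance on both sides, and plants concrete realizations of the motif
#' consensus at known offsets in the upstream and/or downstream flank of
#' selected genes (on a random or specified strand). The plant truth table
#' records every placement, so downstream presence calls can be checked
#' exactly.
#'
#' @param nGenes number of genes.
#' @param geneLength gene body length in bp.
#' @param flankLen flank clearance and scan length in bp (default 2000).
#' @param motif IUPAC consensus string (default [areConsensus]) or a
#'   consensus-mode [MotifModel-class].
#' @param plantPlan data.frame with columns `gene` (index or id), `region`
#'   (`"upstream"`, `"downstream"`, `"both"`, `"none"`) and optionally
#'   `offset` (1-based position within the gene-oriented flank) and
#'   `strand` (`"+"`/`"-"` relative to the flank). Default: regions drawn
#'   uniformly at random, random offsets and strands.
#' @param background named base sampling weights for contig sequence
#'   (default uniform over A/C/G/T).
#' @param contigLength contig length in bp; genes are distributed over as
#'   many contigs as needed.
#' @param rngSeed integer seed.
#' @return list with `genome` (named `DNAStringSet`), `genes` (`GRanges`
#'   with `gene_id`), and `truth` (data.frame: `gene_id`, `region`,
#'   `offset` on the gene-oriented flank, `flank_strand`, contig
#'   coordinates and the planted sequence).
#' @export
simulateGenome <- function(nGenes = 20L, geneLength = 1500L,
                           flankLen = 2000L, motif = areConsensus,
                           plantPlan = NULL,
                           background = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           contigLength = 60000L, rngSeed = 1L) {
  if (methods::is(motif, "MotifModel")) {
    if (motif@mode != "consensus")
      stop("planting needs a consensus-mode motif")
    motif <- motif@consensus
  }
  w <- nchar(motif)
  slot <- geneLength + 2L * flankLen + 200L
  per_contig <- (contigLength - flankLen) %/% slot
  if (per_contig < 1L)
    stop("contigLength too small for one gene with ", flankLen,
         " bp flank margin")
  n_contigs <- ceiling(nGenes / per_contig)
  set.seed(.sub_seed(rngSeed, 1L))
  bases <- c("A", "C", "G", "T")
  bg <- background[bases]
  contigs <- vapply(seq_len(n_contigs), function(i)
    paste(sample(bases, contigLength, replace = TRUE, prob = bg),
          collapse = ""), character(1))
  contig_ids <- sprintf("ctg%02d", seq_len(n_contigs))
  gene_ids <- sprintf("GENE%03d", seq_len(nGenes))
  g_contig <- contig_ids[((seq_len(nGenes) - 1L) %/% per_contig) + 1L]
  idx_on <- ((seq_len(nGenes) - 1L) %% per_contig)
  g_start <- flankLen + 100L + idx_on * slot + 1L
  g_end <- g_start + geneLength - 1L
  g_strand <- sample(c("+", "-"), nGenes, replace = TRUE)
  if (is.null(plantPlan)) {
    plantPlan <- data.frame(
      gene = gene_ids,
      region = sample(c("upstream", "downstream", "both", "none"),
                      nGenes, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  plantPlan$gene <- as.character(plantPlan$gene)
  if (all(grepl("^[0-9]+$", plantPlan$gene)))
    plantPlan$gene <- gene_ids[as.integer(plantPlan$gene)]
  if (!all(plantPlan$gene %in% gene_ids))
    stop("plant plan names unknown gene(s)")
  if (!all(plantPlan$region %in% c("upstream", "downstream", "both", "none")))
    stop("plant regions must be upstream/downstream/both/none")
  truth <- list()
  for (i in seq_len(nrow(plantPlan))) {
    gi <- match(plantPlan$gene[i], gene_ids)
    regions <- switch(plantPlan$region[i],
                      both = c("upstream", "downstream"),
                      none = character(0),
                      plantPlan$region[i])
    for (region in regions) {
      offset <- if ("offset" %in% names(plantPlan) &&
                    !is.na(plantPlan$offset[i]))
        as.integer(plantPlan$offset[i])
      else sample.int(flankLen - w + 1L, 1L)
      if (offset < 1L || offset + w - 1L > flankLen)
        stop("plant offset for ", gene_ids[gi], " (", region,
             ") does not fit within the flank")
      pstrand <- if ("strand" %in% names(plantPlan) &&
                     !is.na(plantPlan$strand[i])) plantPlan$strand[i]
                 else sample(c("+", "-"), 1L)
      # gene-oriented flank -> contig range of the flank
      if (g_strand[gi] == "+") {
        fs <- if (region == "upstream") g_start[gi] - flankLen
              else g_end[gi] + 1L
      } else {
        fs <- if (region == "upstream") g_end[gi] + 1L
              else g_start[gi] - flankLen
      }
      fe <- fs + flankLen - 1L
      cc <- .hit_to_contig(offset, w, g_strand[gi], pstrand, fs, fe)
      if (cc$end >= g_start[gi] && cc$start <= g_end[gi])
        stop("plant for ", gene_ids[gi], " collides with the gene body")
      inst <- .realize_consensus(motif)
      ins <- if (cc$strand == "+") inst
             else as.character(Biostrings::reverseComplement(
               Biostrings::DNAString(inst)))
      ci <- match(g_contig[gi], contig_ids)
      substr(contigs[ci], cc$start, cc$end) <- ins
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = gene_ids[gi], region = region, offset = offset,
        flank_strand = pstrand, contig = g_contig[gi],
        contig_start = cc$start, contig_end = cc$end,
        contig_strand = cc$strand, sequence = inst,
        stringsAsFactors = FALSE)
    }
  }
  genome <- Biostrings::DNAStringSet(contigs)
  names(genome) <- contig_ids
  genes <- GenomicRanges::GRanges(
    seqnames = g_contig,
    ranges = IRanges::IRanges(start = g_start, end = g_end),
    strand = g_strand)
  S4Vectors::mcols(genes)$gene_id <- gene_ids
  truth_df <- if (length(truth)) do.call(rbind, truth)
              else data.frame(gene_id = character(0), region = character(0),
                              offset = integer(0),
                              flank_strand = character(0),
                              contig = character(0),
                              contig_start = integer(0),
                              contig_end = integer(0),
                              contig_strand = character(0),
                              sequence = character(0))
  list(genome = genome, genes = genes, truth = truth_df)
}

#' Write a simulated genome to FASTA / GFF3 / TSV
#'
#' @param sim result of [simulateGenome()].
#' @param dir output directory (created if absent).
#' @return named character vector of the three file paths, invisibly.
#' @export
writeGenomeFiles <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  tsv <- file.path(dir, "plant_truth.tsv")
  Biostrings::writeXStringSet(sim$genome, fa)
  gr <- sim$genes
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- gr$gene_id
  S4Vectors::mcols(gr)$source <- "coregnet"
  rtracklayer::export(gr, gff, format = "GFF3")
  utils::write.table(sim$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fa, gff3 = gff, truth = tsv))
}

#' Simulate a qPCR plate with known knockdown ratios
#'
#' Generates long-format Ct values satisfying
#' `Ct = base - log(1+E)(relative quantity) + sample effect + noise` for a
#' treatment group with gene-specific knockdown ratios against a comparator
#' group at ratio 1, plus housekeeping genes at ratio 1 in both groups.
#' Sample effects (shared by every gene of a biological replicate, e.g.
#' loading differences) cancel through dCt.
#'
#' @param ratios named numeric vector: target gene -> true relative
#'   expression (treatment vs comparator); must be positive. Default
#'   `c(MafS = 0.26)`, the knockdown depth reported for the more efficient
#'   construct in the motivating study.
#' @param treatment,comparator group labels.
#' @param housekeepers housekeeping gene ids (default `c("S7", "EF")`).
#' @param bioReps biological replicates per group (default 3).
#' @param techReps technical replicates per well (default 3).
#' @param noiseSD technical Ct noise standard deviation, cycles.
#' @param sampleEffectSD per-sample Ct offset SD, cycles.
#' @param efficiency amplification efficiency E in (0, 1.2]; 1 = doubling.
#' @param rngSeed integer seed.
#' @return data.frame with columns `sample`, `group`, `gene`, `replicate`,
#'   `ct`; attribute `truth` records the design.
#' @export
simulateQpcrPlate <- function(ratios = c(MafS = 0.26),
                              treatment = "MafS_kd", comparator = "GFP",
                              housekeepers = c("S7", "EF"),
                              bioReps = 3L, techReps = 3L,
                              noiseSD = 0.2, sampleEffectSD = 0.3,
                              efficiency = 1, rngSeed = 1L) {
  if (any(ratios <= 0)) stop("knockdown ratios must be positive")
  if (is.null(names(ratios)) || any(!nzchar(names(ratios))))
    stop("'ratios' must be named by target gene")
  if (efficiency <= 0 || efficiency > 1.2)
    stop("'efficiency' must lie in (0, 1.2]")
  set.seed(.sub_seed(rngSeed, 2L))
  genes <- c(names(ratios), housekeepers)
  base_ct <- stats::setNames(stats::runif(length(genes), 20, 28), genes)
  rows <- list()
  for (grp in c(comparator, treatment)) {
    for (b in seq_len(bioReps)) {
      smp <- paste(grp, b, sep = "_")
      off <- stats::rnorm(1, 0, sampleEffectSD)
      for (g in genes) {
        q <- if (grp == treatment && g %in% names(ratios)) ratios[[g]] else 1
        mu <- base_ct[[g]] - log(q, base = 1 + efficiency) + off
        rows[[length(rows) + 1L]] <- data.frame(
          sample = smp, group = grp, gene = g,
          replicate = seq_len(techReps),
          ct = mu + stats::rnorm(techReps, 0, noiseSD),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(ratios = ratios, efficiency = efficiency,
                             treatment = treatment, comparator = comparator,
                             noise_sd = noiseSD, rng_seed = rngSeed)
  out
}

#' Simulate WHO-tube bioassay records
#'
#' Dead counts are Binomial(exposed, mortality) per replicate tube,
#' independent across tubes — the sampling model behind the
#' arcsine-transformed ANOVA.
#'
#' @param mortality named numeric vector: treatment group -> true 24-h
#'   mortality in [0, 1]. Default emulates a pyrethroid contrast between
#'   control-injected and knockdown mosquitoes.
#' @param tubes replicate tubes per group (default 3).
#' @param perTube mosquitoes per tube (default 25).
#' @param insecticide label carried through.
#' @param rngSeed integer seed.
#' @return data.frame with columns `insecticide`, `group`, `tube`,
#'   `exposed`, `dead`.
#' @export
simulateBioassay <- function(mortality = c(GFP = 0.039, MafS_kd = 0.216),
                             tubes = 3L, perTube = 25L,
                             insecticide = "deltamethrin", rngSeed = 1L) {
  if (any(mortality < 0 | mortality > 1))
    stop("mortalities must lie in [0, 1]")
  if (perTube < 1L) stop("'perTube' must be >= 1")
  if (is.null(names(mortality)))
    stop("'mortality' must be named by treatment group")
  set.seed(.sub_seed(rngSeed, 3L))
  out <- do.call(rbind, lapply(names(mortality), function(grp) {
    data.frame(insecticide = insecticide, group = grp,
               tube = seq_len(tubes), exposed = perTube,
               dead = stats::rbinom(tubes, perTube, mortality[[grp]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
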