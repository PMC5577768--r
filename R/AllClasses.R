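#' @import methods
#' @importFrom S4Vectors metadata DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ResistanceCompendium: a compendium of resistant-vs-susceptible contrasts
#'
#' Container for a transcript x experiment compendium of log2 fold changes
#' (resistant population vs susceptible reference), with an optional matching
#' matrix of per-experiment differential-expression calls (adjusted p <= 0.05
#' upstream). Extends [SummarizedExperiment::SummarizedExperiment]; the
#' `"log2fc"` assay is mandatory, the `"significant"` assay optional.
#' Experiment-level metadata (population, country, species, reference strain,
#' accession) lives in `colData`.
#'
#' @slot . inherits all slots from `SummarizedExperiment`.
#' @seealso [ResistanceCompendium()], [foldChanges()], [significanceCalls()]
#' @export
setClass("ResistanceCompendium", contains = "SummarizedExperiment")

setValidity("ResistanceCompendium", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!("log2fc" %in% an))
    return("assay 'log2fc' is required")
  fc <- SummarizedExperiment::assay(object, "log2fc")
  if (!is.numeric(fc))
    return("assay 'log2fc' must be numeric")
  if (any(is.infinite(fc), na.rm = TRUE))
    return("assay 'log2fc' contains non-finite values")
  if (anyDuplicated(rownames(object)))
    return("transcript ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    return("experiment ids (colnames) must be unique")
  if ("significant" %in% an) {
    sg <- SummarizedExperiment::assay(object, "significant")
    if (!is.logical(sg))
      return("assay 'significant' must be logical")
  }
  TRUE
})

#' CoexpressionNetwork: seed-centred thresholded correlation network
#'
#' Edges connect seed transcripts (designated regulators) to partner
#' transcripts whose fold-change profile across the compendium correlates
#' beyond a hard threshold. In `"signed"` mode an edge requires |r| >= tau
#' (correlation or anti-correlation); in `"positive"` mode r >= tau.
#'
#' @slot edges data.frame with columns `seed_id`, `partner_id`, `r`,
#'   `n_pairs`, `sign`, ordered by (seed, decreasing |r|, partner id).
#' @slot seeds character vector of seed transcript ids.
#' @slot threshold numeric correlation cutoff tau in (0, 1].
#' @slot mode `"signed"` or `"positive"`.
#' @seealso [buildNetwork()], [exportNetwork()]
#' @export
setClass("CoexpressionNetwork",
  representation(edges = "data.frame", seeds = "character",
                 threshold = "numeric", mode = "character"))

setValidity("CoexpressionNetwork", function(object) {
  e <- object@edges
  need <- c("seed_id", "partner_id", "r", "n_pairs", "sign")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold > 1)
    return("threshold must be a single value in (0, 1]")
  if (!object@mode %in% c("signed", "positive"))
    return("mode must be 'signed' or 'positive'")
  if (nrow(e)) {
    if (any(abs(e$r) > 1 + 1e-12)) return("|r| must be <= 1")
    ok <- if (object@mode == "signed") abs(e$r) >= object@threshold
          else e$r >= object@threshold
    if (!all(ok)) return("an edge violates the threshold condition")
    if (any(e$seed_id == e$partner_id)) return("self-edges are not allowed")
  }
  TRUE
})

#' ChanceModel: binomial model of recurrent significance by chance
#'
#' Models the number of independent experiments in which a transcript is
#' called significant, under the null that calls are independent
#' Bernoulli(p_success) events, where p_success is the average per-experiment
#' proportion of significant transcripts.
#'
#' @slot nExperiments integer count of experiments.
#' @slot pSuccess per-experiment probability of a significant call, in [0,1].
#' @seealso [estimateSuccessProbability()], [binomialTail()]
#' @export
setClass("ChanceModel",
  representation(nExperiments = "integer", pSuccess = "numeric"))

setValidity("ChanceModel", function(object) {
  if (length(object@nExperiments) != 1L || object@nExperiments < 1L)
    return("nExperiments must be a single count >= 1")
  if (length(object@pSuccess) != 1L || is.na(object@pSuccess) ||
      object@pSuccess < 0 || object@pSuccess > 1)
    return("pSuccess must be a single probability in [0, 1]")
  TRUE
})

#' MotifModel: a DNA motif as IUPAC consensus or position weight matrix
#'
#' In `"consensus"` mode the motif is a degenerate IUPAC string (codes
#' A, C, G, T, R, Y, W, M, S, K, B, D, H, V and N supported; N matches any
#' base including an N in the scanned sequence, all other codes match only
#' their unambiguous base set). In `"pwm"` mode the motif is a position
#' frequency matrix converted to log2-odds scores against a background base
#' distribution with a pseudocount, and a window is a hit when its score
#' reaches `thresholdFraction` of the maximal achievable score.
#'
#' @slot name motif name.
#' @slot mode `"consensus"` or `"pwm"`.
#' @slot consensus IUPAC consensus string (consensus mode).
#' @slot pfm 4 x width numeric count matrix, rows A, C, G, T (pwm mode).
#' @slot pseudocount total pseudocount distributed by background frequency.
#' @slot background named base frequencies (A, C, G, T), summing to 1.
#' @slot thresholdFraction score cutoff as a fraction of the maximum, (0,1].
#' @seealso [motifModel()], [scanMotif()], [areConsensus]
#' @export
setClass("MotifModel",
  representation(name = "character", mode = "character",
                 consensus = "character", pfm = "matrix",
                 pseudocount = "numeric", background = "numeric",
                 thresholdFraction = "numeric"))

setValidity("MotifModel", function(object) {
  if (!object@mode %in% c("consensus", "pwm"))
    return("mode must be 'consensus' or 'pwm'")
  if (object@mode == "consensus") {
    if (!nzchar(object@consensus))
      return("consensus must be non-empty in consensus mode")
    bad <- setdiff(strsplit(toupper(object@consensus), "")[[1]],
                   names(.IUPAC_SETS))
    if (length(bad))
      return(paste("unsupported IUPAC code(s):", paste(bad, collapse = ", ")))
  } else {
    p <- object@pfm
    if (!is.numeric(p) || nrow(p) != 4L)
      return("pfm must be a numeric matrix with 4 rows (A, C, G, T)")
    if (any(colSums(p) <= 0))
      return("every pfm column must have positive total count")
    if (any(p < 0)) return("pfm counts must be non-negative")
  }
  if (object@thresholdFraction <= 0 || object@thresholdFraction > 1)
    return("thresholdFraction must be in (0, 1]")
  bg <- object@background
  if (!all(c("A", "C", "G", "T") %in% names(bg)) || any(bg < 0) ||
      abs(sum(bg) - 1) > 1e-8)
    return("background must be named A/C/G/T frequencies summing to 1")
  TRUE
})
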