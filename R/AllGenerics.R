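#' Extract the log2 fold-change matrix
#'
#' @param x a [ResistanceCompendium].
#' @return numeric matrix, transcripts in rows, experiments in columns.
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' Extract the significance-call matrix
#'
#' @param x a [ResistanceCompendium].
#' @return logical matrix with the same axes as [foldChanges()], or `NULL`
#'   when no calls are attached.
#' @export
setGeneric("significanceCalls",
           function(x) standardGeneric("significanceCalls"))

#' Experiment-level metadata
#'
#' @param x a [ResistanceCompendium].
#' @return data.frame of per-experiment records (population, country,
#'   species, susceptible reference strain, accession) where available.
#' @export
setGeneric("experimentInfo", function(x) standardGeneric("experimentInfo"))

#' Correlate designated seed transcripts with every transcript
#'
#' Pairwise-complete correlation of each seed's fold-change profile with the
#' profile of every transcript in the compendium, the statistic behind the
#' seed-centred network. Pairs with fewer than `minOverlap` co-observed
#' experiments are omitted and counted in the `"skipped"` attribute.
#'
#' @param x a [ResistanceCompendium] or a numeric matrix (transcripts x
#'   experiments, `NA` for missing).
#' @param seedIds character vector of seed transcript ids; all must be rows
#'   of `x`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param minOverlap minimum number of experiments in which both profiles
#'   are observed (default 10, must be >= 3).
#' @return data.frame with columns `seed_id`, `partner_id`, `r`, `n_pairs`;
#'   attribute `skipped` records per-seed counts of omitted pairs (low
#'   overlap or undefined correlation).
#' @seealso [buildNetwork()]
#' @export
setGeneric("correlateWithSeeds",
  function(x, seedIds, method = c("pearson", "spearman"), minOverlap = 10L)
    standardGeneric("correlateWithSeeds"))

#' Estimate the per-experiment probability of a significant call
#'
#' The chance model's success probability is the unweighted mean, over
#' experiments, of the proportion of called transcripts that are significant
#' in that experiment (a transcript-count weighted mean is available).
#'
#' @param x a [ResistanceCompendium] carrying a `"significant"` assay, or a
#'   logical matrix (transcripts x experiments, `NA` for not-called).
#' @param weighted if `TRUE`, weight experiments by their number of
#'   non-missing calls instead of averaging per-experiment proportions.
#' @return a [ChanceModel].
#' @export
setGeneric("estimateSuccessProbability",
  function(x, weighted = FALSE) standardGeneric("estimateSuccessProbability"))
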