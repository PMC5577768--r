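#' Construct a ResistanceCompendium
#'
#' Assembles a transcript x experiment compendium from a log2 fold-change
#' matrix and, optionally, a matching logical matrix of per-experiment
#' differential-expression calls and a table of experiment metadata.
#'
#' @param foldChanges numeric matrix, transcripts in rows (unique rownames),
#'   experiments in columns (unique colnames); `NA` marks missing values.
#' @param significance optional logical matrix with identical dimnames.
#' @param experimentInfo optional data.frame, one row per experiment, with
#'   an `experiment_id` column matching the fold-change columns.
#' @return a [ResistanceCompendium-class] object.
#' @examples
#' fc <- matrix(rnorm(12), 4, 3,
#'              dimnames = list(paste0("t", 1:4), paste0("e", 1:3)))
#' ResistanceCompendium(fc)
#' @export
ResistanceCompendium <- function(foldChanges, significance = NULL,
                                 experimentInfo = NULL) {
  if (!is.matrix(foldChanges) || !is.numeric(foldChanges))
    stop("'foldChanges' must be a numeric matrix")
  if (is.null(rownames(foldChanges)) || is.null(colnames(foldChanges)))
    stop("'foldChanges' must carry transcript rownames and experiment colnames")
  assays <- list(log2fc = foldChanges)
  if (!is.null(significance)) {
    if (!identical(dimnames(significance), dimnames(foldChanges)))
      stop("'significance' must have the same dimnames as 'foldChanges'")
    storage.mode(significance) <- "logical"
    assays$significant <- significance
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(foldChanges))
  if (!is.null(experimentInfo)) {
    if (!"experiment_id" %in% names(experimentInfo))
      stop("'experimentInfo' must have an 'experiment_id' column")
    m <- match(colnames(foldChanges), experimentInfo$experiment_id)
    if (anyNA(m))
      stop("experimentInfo is missing experiment(s): ",
           paste(colnames(foldChanges)[is.na(m)], collapse = ", "))
    cd <- S4Vectors::DataFrame(experimentInfo[m, , drop = FALSE],
                               row.names = colnames(foldChanges))
  }
  se <- SummarizedExperiment::SummarizedExperiment(assays = assays,
                                                   colData = cd)
  methods::new("ResistanceCompendium", se)
}

#' @rdname foldChanges
#' @export
setMethod("foldChanges", "ResistanceCompendium", function(x) {
  SummarizedExperiment::assay(x, "log2fc")
})

#' @rdname significanceCalls
#' @export
setMethod("significanceCalls", "ResistanceCompendium", function(x) {
  if ("significant" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "significant")
  else NULL
})

#' @rdname experimentInfo
#' @export
setMethod("experimentInfo", "ResistanceCompendium", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' Ground truth of a simulated compendium
#'
#' For compendia produced by [simulateCompendium()], returns the generative
#' truth: the seed-to-member map with realized generative correlations and
#' the per-transcript significance probabilities. `NULL` for real data.
#'
#' @param x a [ResistanceCompendium].
#' @return a list with elements `modules` (data.frame: `seed_id`,
#'   `member_id`, `rho`, `sign`) and `p_significant`, or `NULL`.
#' @export
compendiumTruth <- function(x) {
  stopifnot(methods::is(x, "ResistanceCompendium"))
  S4Vectors::metadata(x)$truth
}

setMethod("show", "ResistanceCompendium", function(object) {
  cat("ResistanceCompendium:", nrow(object), "transcripts x",
      ncol(object), "experiments\n")
  fc <- foldChanges(object)
  cat(sprintf("  missing fold changes: %.1f%%\n", 100 * mean(is.na(fc))))
  sg <- significanceCalls(object)
  if (!is.null(sg))
    cat(sprintf("  significance calls attached (%.1f%% significant)\n",
                100 * mean(sg, na.rm = TRUE)))
  if (!is.null(S4Vectors::metadata(object)$truth))
    cat("  simulated (ground truth in compendiumTruth())\n")
  invisible(NULL)
})
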