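#' Construct a ChanceModel directly
#'
#' @param nExperiments number of independent experiments.
#' @param pSuccess per-experiment probability that a transcript is called
#'   significant, in [0, 1].
#' @return a [ChanceModel-class].
#' @seealso [estimateSuccessProbability()] to fit from a call matrix.
#' @export
chanceModel <- function(nExperiments, pSuccess) {
  methods::new("ChanceModel", nExperiments = as.integer(nExperiments),
               pSuccess = as.numeric(pSuccess))
}

#' Probability of failure under the model
#' @param model a [ChanceModel-class].
#' @return `1 - pSuccess`.
#' @export
pFailure <- function(model) {
  stopifnot(methods::is(model, "ChanceModel"))
  1 - model@pSuccess
}

setMethod("show", "ChanceModel", function(object) {
  cat(sprintf("ChanceModel: n = %d experiments, p(success) = %.4f, p(failure) = %.4f\n",
              object@nExperiments, object@pSuccess, 1 - object@pSuccess))
  invisible(NULL)
})

.estimate_p <- function(sig, weighted) {
  stopifnot(is.matrix(sig))
  if (!is.logical(sig)) storage.mode(sig) <- "logical"
  if (ncol(sig) < 1L) stop("need at least one experiment")
  called <- colSums(!is.na(sig))
  if (any(called == 0L))
    stop("experiment(s) with zero non-missing calls: ",
         paste(colnames(sig)[called == 0L], collapse = ", "))
  hits <- colSums(sig, na.rm = TRUE)
  p <- if (weighted) sum(hits) / sum(called) else mean(hits / called)
  chanceModel(ncol(sig), p)
}

#' @rdname estimateSuccessProbability
#' @export
setMethod("estimateSuccessProbability", "matrix",
  function(x, weighted = FALSE) .estimate_p(x, weighted))

#' @rdname estimateSuccessProbability
#' @export
setMethod("estimateSuccessProbability", "ResistanceCompendium",
  function(x, weighted = FALSE) {
    sig <- significanceCalls(x)
    if (is.null(sig))
      stop("compendium carries no significance calls")
    .estimate_p(sig, weighted)
  })

#' Upper-tail probability of recurrent significance
#'
#' P(X >= k) for X ~ Binomial(n, p) under the chance model: the probability
#' that a transcript with no real association is called significant in at
#' least k of n independent experiments. Computed as a log-space sum of
#' binomial point masses; `k = 0` returns exactly 1.
#'
#' @param model a [ChanceModel-class].
#' @param k integer count (vectorized), 0 <= k <= nExperiments.
#' @return numeric vector of tail probabilities.
#' @seealso [binomialPointMass()], [chanceAssessment()]
#' @export
binomialTail <- function(model, k) {
  stopifnot(methods::is(model, "ChanceModel"))
  n <- model@nExperiments
  p <- model@pSuccess
  k <- as.integer(k)
  if (any(k < 0L | k > n))
    stop("'k' must be between 0 and ", n)
  vapply(k, function(ki) {
    if (ki == 0L) return(1)
    lg <- stats::dbinom(ki:n, n, p, log = TRUE)
    m <- max(lg)
    if (!is.finite(m)) return(0)
    exp(m) * sum(exp(lg - m))
  }, numeric(1))
}

#' Binomial point mass under the chance model
#'
#' @inheritParams binomialTail
#' @return P(X = k), vectorized over `k`.
#' @export
binomialPointMass <- function(model, k) {
  stopifnot(methods::is(model, "ChanceModel"))
  n <- model@nExperiments
  k <- as.integer(k)
  if (any(k < 0L | k > n))
    stop("'k' must be between 0 and ", n)
  stats::dbinom(k, n, model@pSuccess)
}

#' Assess transcripts for more-frequent-than-chance significance
#'
#' For each requested transcript, counts the experiments (among those where
#' the transcript was called at all) in which it was significant, and
#' reports the upper-tail probability of seeing at least that many
#' significant calls under the chance model fitted to the full matrix. The
#' binomial n is adjusted per transcript to its non-missing call count: a
#' transcript absent from an array cannot succeed there.
#'
#' @param x a [ResistanceCompendium] with significance calls, or a logical
#'   matrix.
#' @param transcriptIds transcripts to assess; must be rows of `x`.
#' @param adjust if `TRUE`, append Benjamini-Hochberg adjusted tails (the
#'   model is used descriptively by default, so this is off).
#' @param weighted passed to [estimateSuccessProbability()].
#' @return data.frame with columns `transcript_id`, `n_called`,
#'   `n_significant`, `p_tail` (and `p_adjusted` when `adjust = TRUE`).
#' @export
chanceAssessment <- function(x, transcriptIds, adjust = FALSE,
                             weighted = FALSE) {
  sig <- if (methods::is(x, "ResistanceCompendium")) significanceCalls(x)
         else x
  if (is.null(sig)) stop("no significance calls available")
  stopifnot(is.matrix(sig))
  if (!is.logical(sig)) storage.mode(sig) <- "logical"
  unknown <- setdiff(transcriptIds, rownames(sig))
  if (length(unknown))
    stop("unknown transcript id(s): ", paste(unknown, collapse = ", "))
  model <- .estimate_p(sig, weighted)
  p <- model@pSuccess
  out <- do.call(rbind, lapply(transcriptIds, function(id) {
    calls <- sig[id, ]
    nc <- sum(!is.na(calls))
    k <- sum(calls, na.rm = TRUE)
    if (nc == 0L)
      stop("transcript '", id, "' has no non-missing calls")
    tail <- binomialTail(chanceModel(nc, p), k)
    data.frame(transcript_id = id, n_called = nc, n_significant = k,
               p_tail = tail, stringsAsFactors = FALSE)
  }))
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_tail, method = "BH")
  rownames(out) <- NULL
  out
}
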