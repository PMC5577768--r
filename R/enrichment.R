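#' Hypergeometric enrichment of a small transcript list
#'
#' For each annotation category, tests whether the member list contains more
#' category genes than expected from sampling without replacement out of the
#' universe: the upper-tail hypergeometric probability P(X >= k) with k
#' members in the category, list size n, category size K (restricted to the
#' universe) and universe size N. Benjamini-Hochberg q-values are computed
#' across the tested categories; the convention for an empty overlap is
#' P(X >= 0) = 1.
#'
#' @param memberIds character vector, the transcript list (e.g. a seed's
#'   co-correlated transcripts); must be a subset of `universeIds`.
#' @param annotation either a named list of character vectors
#'   (category -> gene ids) or a two-column data.frame (`category`, `gene`).
#' @param universeIds character vector of all transcripts considered.
#' @param alpha significance level used to set the `significant` flag on the
#'   adjusted values (default 0.05).
#' @return data.frame sorted by p with columns `category`, `k`, `n`, `K`,
#'   `N`, `p`, `q`, `significant`.
#' @export
hypergeometricEnrichment <- function(memberIds, annotation, universeIds,
                                     alpha = 0.05) {
  universeIds <- unique(as.character(universeIds))
  memberIds <- unique(as.character(memberIds))
  outside <- setdiff(memberIds, universeIds)
  if (length(outside))
    stop("member(s) outside the universe: ", paste(outside, collapse = ", "))
  if (is.data.frame(annotation)) {
    stopifnot(ncol(annotation) >= 2L)
    annotation <- split(as.character(annotation[[2L]]),
                        as.character(annotation[[1L]]))
  }
  if (!is.list(annotation) || is.null(names(annotation)))
    stop("'annotation' must be a named list or a (category, gene) data.frame")
  cats <- lapply(annotation, function(g) intersect(unique(g), universeIds))
  cats <- cats[lengths(cats) > 0L]
  if (!length(cats)) stop("no annotation category intersects the universe")
  N <- length(universeIds)
  n <- length(memberIds)
  rows <- lapply(names(cats), function(cn) {
    K <- length(cats[[cn]])
    k <- length(intersect(memberIds, cats[[cn]]))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cn, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q <= alpha
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
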