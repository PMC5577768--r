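.correlate_matrix <- function(x, seedIds, method, minOverlap) {
  stopifnot(is.matrix(x), is.numeric(x))
  minOverlap <- as.integer(minOverlap)
  if (minOverlap < 3L) stop("'minOverlap' must be >= 3")
  missing_seeds <- setdiff(seedIds, rownames(x))
  if (length(missing_seeds))
    stop("seed(s) absent from matrix: ", paste(missing_seeds, collapse = ", "))
  obs <- !is.na(x)
  res <- vector("list", length(seedIds))
  skipped <- integer(length(seedIds))
  names(skipped) <- seedIds
  tx <- t(x)
  for (i in seq_along(seedIds)) {
    s <- seedIds[i]
    sv <- x[s, ]
    np <- as.integer(obs %*% (!is.na(sv)))
    r <- suppressWarnings(
      stats::cor(sv, tx, use = "pairwise.complete.obs", method = method))[1L, ]
    keep <- np >= minOverlap & !is.na(r)
    skipped[i] <- sum(!keep)
    res[[i]] <- data.frame(seed_id = rep(s, sum(keep)),
                           partner_id = rownames(x)[keep],
                           r = unname(r[keep]),
                           n_pairs = np[keep],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "method") <- method
  attr(out, "min_overlap") <- minOverlap
  out
}

#' @rdname correlateWithSeeds
#' @export
setMethod("correlateWithSeeds", "matrix",
  function(x, seedIds, method = c("pearson", "spearman"), minOverlap = 10L) {
    .correlate_matrix(x, seedIds, match.arg(method), minOverlap)
  })

#' @rdname correlateWithSeeds
#' @export
setMethod("correlateWithSeeds", "ResistanceCompendium",
  function(x, seedIds, method = c("pearson", "spearman"), minOverlap = 10L) {
    .correlate_matrix(foldChanges(x), seedIds, match.arg(method), minOverlap)
  })

#' Euclidean distance from seeds to all transcripts
#'
#' Companion row-distance output to [correlateWithSeeds()]: the Euclidean
#' distance between fold-change profiles over co-observed experiments,
#' rescaled to the full experiment count to keep profiles with different
#' missingness comparable.
#'
#' @inheritParams correlateWithSeeds
#' @return data.frame with columns `seed_id`, `partner_id`, `distance`,
#'   `n_pairs`.
#' @export
seedEuclideanDistance <- function(x, seedIds, minOverlap = 10L) {
  if (methods::is(x, "ResistanceCompendium")) x <- foldChanges(x)
  stopifnot(is.matrix(x))
  missing_seeds <- setdiff(seedIds, rownames(x))
  if (length(missing_seeds))
    stop("seed(s) absent from matrix: ", paste(missing_seeds, collapse = ", "))
  res <- lapply(seedIds, function(s) {
    sv <- x[s, ]
    d2 <- sweep(x, 2L, sv)^2
    np <- rowSums(!is.na(d2))
    d <- sqrt(rowMeans(d2, na.rm = TRUE) * ncol(x))
    keep <- np >= minOverlap & !is.na(d)
    data.frame(seed_id = s, partner_id = rownames(x)[keep],
               distance = unname(d[keep]), n_pairs = unname(np[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build the thresholded seed-centred network
#'
#' Keeps the seed-partner correlations that pass the hard cutoff the analysis
#' uses in place of an edge-wise test: `|r| >= threshold` in `"signed"` mode
#' (correlation or anti-correlation both qualify) or `r >= threshold` in
#' `"positive"` mode. Seed self-edges are excluded; edges are ordered by
#' (seed, decreasing |r|, partner id) so outputs are reproducible.
#'
#' @param correlations data.frame from [correlateWithSeeds()].
#' @param threshold correlation cutoff tau in (0, 1]; default 0.8.
#' @param mode `"signed"` (default) or `"positive"`.
#' @return a [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(correlations, threshold = 0.8,
                         mode = c("signed", "positive")) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) stop("'threshold' must be in (0, 1]")
  e <- correlations[correlations$partner_id != correlations$seed_id, ,
                    drop = FALSE]
  keep <- if (mode == "signed") abs(e$r) >= threshold else e$r >= threshold
  e <- e[keep, , drop = FALSE]
  e$sign <- ifelse(e$r >= 0, "+", "-")
  e <- e[order(e$seed_id, -abs(e$r), e$partner_id), , drop = FALSE]
  rownames(e) <- NULL
  methods::new("CoexpressionNetwork",
               edges = e[, c("seed_id", "partner_id", "r", "n_pairs", "sign")],
               seeds = unique(correlations$seed_id),
               threshold = threshold, mode = mode)
}

#' Edge table of a network
#' @param network a [CoexpressionNetwork-class].
#' @return data.frame of edges.
#' @export
networkEdges <- function(network) {
  stopifnot(methods::is(network, "CoexpressionNetwork"))
  network@edges
}

#' Seed ids of a network
#' @param network a [CoexpressionNetwork-class].
#' @return character vector.
#' @export
networkSeeds <- function(network) {
  stopifnot(methods::is(network, "CoexpressionNetwork"))
  network@seeds
}

setMethod("show", "CoexpressionNetwork", function(object) {
  cat(sprintf("CoexpressionNetwork: %d seed(s), %d edge(s), %s mode, tau = %g\n",
              length(object@seeds), nrow(object@edges), object@mode,
              object@threshold))
  if (nrow(object@edges)) {
    per <- table(object@edges$seed_id)
    for (s in names(per))
      cat(sprintf("  %s: %d co-correlated transcript(s)\n", s, per[[s]]))
  }
  invisible(NULL)
})

#' Export a network for external viewers
#'
#' Writes the network in one of three formats: `"sif"` (Cytoscape simple
#' interaction format, lines `seed<TAB>coexpressed<TAB>partner`), `"tsv"`
#' (edge table with correlation and overlap columns), or `"graphml"`
#' (via igraph, with `r`, `n_pairs` and `sign` edge attributes).
#'
#' @param network a [CoexpressionNetwork-class].
#' @param path output file path.
#' @param format `"sif"`, `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(network, path, format = c("sif", "tsv", "graphml")) {
  stopifnot(methods::is(network, "CoexpressionNetwork"))
  format <- match.arg(format)
  e <- network@edges
  if (format == "sif") {
    lines <- if (nrow(e)) paste(e$seed_id, "coexpressed", e$partner_id,
                                sep = "\t") else character(0)
    writeLines(lines, path)
  } else if (format == "tsv") {
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- networkGraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Network as an igraph object
#'
#' @param network a [CoexpressionNetwork-class].
#' @return an [igraph::igraph] graph; vertices carry a logical `seed`
#'   attribute, edges carry `r`, `n_pairs` and `sign`.
#' @export
networkGraph <- function(network) {
  stopifnot(methods::is(network, "CoexpressionNetwork"))
  e <- network@edges
  verts <- unique(c(network@seeds, e$seed_id, e$partner_id))
  g <- igraph::graph_from_data_frame(
    e[, c("seed_id", "partner_id", "r", "n_pairs", "sign")],
    directed = FALSE,
    vertices = data.frame(name = verts, seed = verts %in% network@seeds))
  g
}
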