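#' Read a transcript x experiment matrix from TSV
#'
#' Reads the package's matrix dialect: tab-separated, UTF-8, a header row of
#' experiment ids, first column of transcript ids, no quoting. Empty cells
#' are missing values. Significance matrices may contain `0`, `1`, `TRUE`
#' or `FALSE`.
#'
#' @param path file path.
#' @param kind `"foldchange"` (numeric) or `"significance"` (logical).
#' @return a numeric or logical matrix with transcript rownames and
#'   experiment colnames.
#' @seealso [writeExpressionMatrix()], [mergeExperiments()]
#' @export
readExpressionMatrix <- function(path, kind = c("foldchange", "significance")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL, fileEncoding = "UTF-8")
  if (ncol(df) < 2L)
    stop("matrix TSV needs a transcript-id column plus >=1 experiment column")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated transcript id(s): ", paste(dup, collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  rownames(raw) <- ids
  if (anyDuplicated(colnames(raw)))
    stop("duplicated experiment id(s) in header")
  empty <- !nzchar(trimws(raw)) | toupper(trimws(raw)) == "NA"
  if (kind == "foldchange") {
    vals <- suppressWarnings(as.numeric(raw))
    bad <- !empty & is.na(vals)
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-numeric fold change '%s' at transcript '%s', experiment '%s'",
                   raw[w[1L], w[2L]], rownames(raw)[w[1L]], colnames(raw)[w[2L]]))
    }
    if (any(is.infinite(vals)))
      stop("non-finite fold change value(s) in ", path)
    out <- matrix(vals, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  } else {
    v <- toupper(trimws(raw))
    ok <- v %in% c("0", "1", "TRUE", "FALSE")
    bad <- !empty & !ok
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf("invalid significance value '%s' at transcript '%s', experiment '%s'",
                   raw[w[1L], w[2L]], rownames(raw)[w[1L]], colnames(raw)[w[2L]]))
    }
    out <- matrix(v %in% c("1", "TRUE"), nrow(raw), ncol(raw),
                  dimnames = dimnames(raw))
    out[empty] <- NA
  }
  out[empty] <- NA
  out
}

#' Write a transcript x experiment matrix as TSV
#'
#' Inverse of [readExpressionMatrix()]; missing values become empty cells,
#' logical matrices are written as `1`/`0`.
#'
#' @param x numeric or logical matrix with dimnames.
#' @param path output file path.
#' @param idColumn header label of the transcript-id column.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, idColumn = "transcript_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  chr <- if (is.logical(x)) ifelse(x, "1", "0")
         else format(x, trim = TRUE, digits = 15)
  chr[is.na(x)] <- ""
  df <- data.frame(rownames(x), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(idColumn, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Merge single-experiment tables onto one fold-change matrix
#'
#' Each input is a two-column table (transcript id, log2 fold change) from
#' one experiment. The union join keeps every transcript seen anywhere and
#' fills absences with missing values, preserving maximal data for
#' pairwise-complete correlation; the intersection join keeps only
#' transcripts shared by all experiments. Experiment order is preserved.
#'
#' @param tables named list of data.frames; names become experiment ids.
#'   The first column is the transcript id, the second the log2 fold change.
#' @param join `"union"` (default) or `"intersection"`.
#' @return numeric matrix (transcripts x experiments).
#' @export
mergeExperiments <- function(tables, join = c("union", "intersection")) {
  join <- match.arg(join)
  if (!length(tables)) stop("need at least one experiment table")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("'tables' must be a named list (names are experiment ids)")
  idsets <- lapply(tables, function(t) {
    ids <- as.character(t[[1L]])
    if (anyDuplicated(ids))
      stop("duplicated transcript id(s) within an experiment table: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids
  })
  all_ids <- if (join == "union") Reduce(union, idsets)
             else Reduce(intersect, idsets)
  if (!length(all_ids)) stop("empty intersection of transcript ids")
  out <- matrix(NA_real_, length(all_ids), length(tables),
                dimnames = list(all_ids, names(tables)))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    m <- match(all_ids, as.character(t[[1L]]))
    out[, j] <- as.numeric(t[[2L]])[m]
  }
  out
}

#' Aggregate probe-level values to transcript level
#'
#' Arrays measure probes; the network operates on transcripts. Values of
#' probes mapping to the same transcript are averaged per experiment (mean
#' of non-missing log2 fold changes); a transcript whose probes are all
#' missing in an experiment stays missing. Probes without a mapping are
#' dropped.
#'
#' @param x numeric matrix, probes in rows.
#' @param map data.frame with columns `probe_id` and `transcript_id`; a
#'   probe may map to at most one transcript.
#' @return numeric matrix, transcripts in rows (order of first appearance
#'   in `map`).
#' @export
aggregateProbes <- function(x, map) {
  stopifnot(is.matrix(x), all(c("probe_id", "transcript_id") %in% names(map)))
  map <- map[map$probe_id %in% rownames(x), , drop = FALSE]
  amb <- unique(map$probe_id[duplicated(map$probe_id)])
  amb <- amb[vapply(amb, function(p)
    length(unique(map$transcript_id[map$probe_id == p])) > 1L, logical(1))]
  if (length(amb))
    stop("probe(s) mapped to more than one transcript: ",
         paste(amb, collapse = ", "))
  map <- map[!duplicated(map$probe_id), , drop = FALSE]
  tids <- unique(map$transcript_id)
  out <- matrix(NA_real_, length(tids), ncol(x),
                dimnames = list(tids, colnames(x)))
  grp <- split(map$probe_id, factor(map$transcript_id, levels = tids))
  for (i in seq_along(grp)) {
    sub <- x[grp[[i]], , drop = FALSE]
    v <- colMeans(sub, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    out[i, ] <- v
  }
  out
}
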