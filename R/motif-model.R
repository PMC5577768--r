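## IUPAC degenerate base sets. N is the any-base wildcard and is the only
## code that also matches an N in the scanned sequence.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), M = c("A", "C"),
  S = c("C", "G"), K = c("G", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

#' The ARE consensus motif
#'
#' IUPAC consensus of the antioxidant response element, the binding site of
#' the cnc/Nrf2-Maf heterodimer: `TMAnnRTGAYnnGCRwwww` (M = A/C, R = A/G,
#' Y = C/T, w = A/T, n = any base).
#'
#' @format length-1 character vector.
#' @export
areConsensus <- "TMAnnRTGAYnnGCRwwww"

#' Construct a motif model
#'
#' Builds a [MotifModel-class] in consensus mode (from an IUPAC string) or
#' pwm mode (from a position frequency matrix). In pwm mode columns are
#' converted to log2-odds scores `log2(f / bg)` with frequencies
#' `f = (count + pseudocount * bg) / (total + pseudocount)`, and a scanned
#' window is a hit when its summed score reaches `thresholdFraction` of the
#' maximal achievable score.
#'
#' @param name motif name.
#' @param consensus IUPAC consensus string (consensus mode).
#' @param pfm 4 x width count matrix, rows A, C, G, T in order or named
#'   (pwm mode). Supply exactly one of `consensus` / `pfm`.
#' @param pseudocount total pseudocount added per column, distributed by the
#'   background frequencies (default 0.8, a common matrix-scan default).
#' @param background named base frequencies; default uniform 0.25.
#' @param thresholdFraction pwm hit cutoff as a fraction of the maximal
#'   score, in (0, 1]; default 0.8.
#' @return a [MotifModel-class].
#' @examples
#' motifModel("ARE", consensus = areConsensus)
#' @export
motifModel <- function(name, consensus = NULL, pfm = NULL,
                       pseudocount = 0.8,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       thresholdFraction = 0.8) {
  if (is.null(consensus) == is.null(pfm))
    stop("supply exactly one of 'consensus' or 'pfm'")
  if (!is.null(pfm)) {
    if (is.null(rownames(pfm))) rownames(pfm) <- c("A", "C", "G", "T")
    pfm <- pfm[c("A", "C", "G", "T"), , drop = FALSE]
    mode <- "pwm"
    consensus <- ""
  } else {
    mode <- "consensus"
    pfm <- matrix(numeric(0), 4, 0,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  }
  methods::new("MotifModel", name = name, mode = mode,
               consensus = as.character(consensus), pfm = pfm,
               pseudocount = pseudocount,
               background = background[c("A", "C", "G", "T")],
               thresholdFraction = thresholdFraction)
}

setMethod("show", "MotifModel", function(object) {
  if (object@mode == "consensus")
    cat(sprintf("MotifModel '%s': IUPAC consensus %s (width %d)\n",
                object@name, object@consensus, motifWidth(object)))
  else
    cat(sprintf("MotifModel '%s': PWM, width %d, threshold %.2f of max score\n",
                object@name, motifWidth(object), object@thresholdFraction))
  invisible(NULL)
})

#' Motif width in base pairs
#' @param motif a [MotifModel-class].
#' @return integer width.
#' @export
motifWidth <- function(motif) {
  stopifnot(methods::is(motif, "MotifModel"))
  if (motif@mode == "consensus") nchar(motif@consensus) else ncol(motif@pfm)
}

#' Degenerate count matrix of an IUPAC consensus
#'
#' Each column has count 1 for every base the IUPAC code allows and 0
#' elsewhere (the wildcard N allows all four). Useful for comparing
#' consensus scanning with pwm scanning of the equivalent 0/1 matrix.
#'
#' @param consensus IUPAC string.
#' @return 4 x width count matrix with rows A, C, G, T.
#' @export
consensusToPFM <- function(consensus) {
  codes <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(codes, names(.IUPAC_SETS))
  if (length(bad))
    stop("unsupported IUPAC code(s): ", paste(bad, collapse = ", "))
  bases <- c("A", "C", "G", "T")
  vapply(codes, function(cd) as.numeric(bases %in% .IUPAC_SETS[[cd]]),
         numeric(4)) -> m
  rownames(m) <- bases
  colnames(m) <- NULL
  m
}

#' Log2-odds score matrix of a pwm-mode motif
#'
#' @param motif a [MotifModel-class] in pwm mode.
#' @return list with the 4 x width `scores` matrix (rows A, C, G, T) and
#'   `maxScore`, the maximal achievable window score.
#' @export
pwmScores <- function(motif) {
  stopifnot(methods::is(motif, "MotifModel"))
  if (motif@mode != "pwm") stop("motif is not in pwm mode")
  pfm <- motif@pfm
  bg <- motif@background
  tot <- colSums(pfm) + motif@pseudocount
  freq <- sweep(pfm + motif@pseudocount * bg, 2L, tot, "/")
  sc <- log2(freq / bg)
  list(scores = sc, maxScore = sum(apply(sc, 2L, max)))
}

#' Read a JASPAR-format position frequency matrix
#'
#' Parses the plain-text JASPAR matrix format: a `>ID name` header line
#' followed by four lines `A [ counts... ]` (brackets optional), rows in
#' any order.
#'
#' @param path file path.
#' @param ... passed to [motifModel()] (pseudocount, background,
#'   thresholdFraction).
#' @return a [MotifModel-class] in pwm mode.
#' @export
readJasparPfm <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1L], ">"))
    stop("not a JASPAR matrix file (missing '>' header): ", path)
  hdr <- strsplit(sub("^>", "", lines[1L]), "\\s+")[[1L]]
  name <- if (length(hdr) >= 2L) hdr[2L] else hdr[1L]
  rows <- list()
  for (ln in lines[-1L][seq_len(min(4L, length(lines) - 1L))]) {
    base <- toupper(substr(trimws(ln), 1L, 1L))
    if (!base %in% c("A", "C", "G", "T"))
      stop("unexpected matrix row in JASPAR file: ", ln)
    nums <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", trimws(ln)))
    rows[[base]] <- as.numeric(strsplit(trimws(nums), "\\s+")[[1L]])
  }
  if (length(rows) != 4L || length(unique(lengths(rows))) != 1L)
    stop("JASPAR file must have four equal-length rows A, C, G, T")
  pfm <- rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  motifModel(name, pfm = pfm, ...)
}

## Score every window of an A/C/G/T/N index vector against a score matrix.
## N contributes -Inf so an N-containing window can never reach a positive
## threshold. Returns the numeric score per offset.
.score_windows <- function(idx, scores) {
  w <- ncol(scores)
  L <- length(idx)
  if (L < w) return(numeric(0))
  nwin <- L - w + 1L
  total <- numeric(nwin)
  for (j in seq_len(w)) {
    col <- scores[, j]
    v <- col[idx[j:(j + nwin - 1L)]]
    v[is.na(v)] <- -Inf
    total <- total + v
  }
  total
}

.seq_to_char <- function(sequence) {
  if (methods::is(sequence, "XString") || methods::is(sequence, "XStringSet"))
    sequence <- as.character(sequence)
  toupper(as.character(sequence)[1L])
}

## One-strand scan; returns data.frame(start, match, score, rel_score)
## with start 1-based on the scanned string.
.scan_strand <- function(motif, seqchr) {
  w <- motifWidth(motif)
  if (nchar(seqchr) < w)
    return(data.frame(start = integer(0), match = character(0),
                      score = numeric(0), rel_score = numeric(0)))
  if (motif@mode == "consensus") {
    sets <- .IUPAC_SETS[strsplit(toupper(motif@consensus), "")[[1L]]]
    rx <- paste0(vapply(sets, function(s) paste0("[", paste(s, collapse = ""),
                                                 "]"), character(1)),
                 collapse = "")
    m <- gregexpr(paste0("(?=", rx, ")"), seqchr, perl = TRUE)[[1L]]
    starts <- if (m[1L] == -1L) integer(0) else as.integer(m)
    data.frame(start = starts,
               match = if (length(starts))
                 substring(seqchr, starts, starts + w - 1L) else character(0),
               score = rep(1, length(starts)),
               rel_score = rep(1, length(starts)),
               stringsAsFactors = FALSE)
  } else {
    pw <- pwmScores(motif)
    idx <- match(strsplit(seqchr, "")[[1L]], c("A", "C", "G", "T"))
    sc <- .score_windows(idx, pw$scores)
    cut <- motif@thresholdFraction * pw$maxScore
    starts <- which(sc >= cut)
    data.frame(start = starts,
               match = if (length(starts))
                 substring(seqchr, starts, starts + w - 1L) else character(0),
               score = sc[starts],
               rel_score = sc[starts] / pw$maxScore,
               stringsAsFactors = FALSE)
  }
}

#' Scan a sequence for motif occurrences
#'
#' Reports every offset at which the motif matches (consensus mode) or
#' scores at least the threshold fraction of the maximal log2-odds score
#' (pwm mode). When `bothStrands = TRUE` the reverse complement is scanned
#' too; minus-strand hits are reported at their position on the forward
#' coordinates of the scanned sequence, with the matched sequence given in
#' motif orientation. A sequence shorter than the motif yields an empty
#' result. An `N` in the sequence is matched only by the wildcard code N/n
#' of a consensus motif and scores `-Inf` in pwm mode.
#'
#' @param motif a [MotifModel-class].
#' @param sequence a [Biostrings::DNAString], character string, or other
#'   XString over A/C/G/T/N.
#' @param bothStrands scan the reverse complement as well (default `TRUE`).
#' @return data.frame sorted by `start` with columns `start` (1-based on
#'   the forward scanned sequence), `end`, `strand` (`"+"`/`"-"` relative
#'   to the scanned sequence), `match`, `score`, `rel_score`.
#' @examples
#' scanMotif(motifModel("ARE", consensus = areConsensus),
#'           "TAATTGTGACTTGCGAAAA")
#' @export
scanMotif <- function(motif, sequence, bothStrands = TRUE) {
  stopifnot(methods::is(motif, "MotifModel"))
  seqchr <- .seq_to_char(sequence)
  w <- motifWidth(motif)
  fwd <- .scan_strand(motif, seqchr)
  fwd$strand <- rep("+", nrow(fwd))
  out <- fwd
  if (bothStrands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seqchr)))
    rev <- .scan_strand(motif, rc)
    if (nrow(rev)) {
      L <- nchar(seqchr)
      rev$start <- L - (rev$start + w - 1L) + 1L
      rev$strand <- "-"
      out <- rbind(fwd, rev)
    }
  }
  out$end <- out$start + w - 1L
  out <- out[order(out$start, out$strand),
             c("start", "end", "strand", "match", "score", "rel_score")]
  rownames(out) <- NULL
  out
}
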