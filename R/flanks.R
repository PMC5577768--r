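#' Read gene models from a GFF3 annotation
#'
#' Imports gene features (1-based inclusive coordinates, converted by
#' rtracklayer into [GenomicRanges::GRanges]) and attaches a `gene_id`
#' metadata column taken from the `ID` or `Name` attribute. Malformed
#' coordinate pairs (end < start) are reported with their line number
#' before import.
#'
#' @param path GFF3 file path.
#' @param featureType feature type to keep (default `"gene"`).
#' @return a `GRanges` of gene models with a `gene_id` column; empty, with
#'   a warning, when the file has no features of the requested type.
#' @export
readAnnotation <- function(path, featureType = "gene") {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 5L) {
      s <- suppressWarnings(as.numeric(f[4L]))
      e <- suppressWarnings(as.numeric(f[5L]))
      if (!is.na(s) && !is.na(e) && e < s)
        stop(sprintf("end < start at line %d of %s", i, path))
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == featureType]
  if (!length(gr)) {
    warning("no '", featureType, "' features in ", path)
    mc <- S4Vectors::DataFrame(gene_id = character(0))
    gr2 <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr2) <- mc
    return(gr2)
  }
  id <- gr$ID
  if (is.null(id)) id <- gr$Name
  if (is.null(id)) id <- paste0(featureType, "_", seq_along(gr))
  id[is.na(id) | !nzchar(id)] <- paste0(featureType, "_",
                                        which(is.na(id) | !nzchar(id)))
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$gene_id <- as.character(id)
  out
}

.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("'genome' must be a DNAStringSet or a FASTA file path")
  if (is.null(names(genome))) stop("genome contigs must be named")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

.range_seqs <- function(genome, gr) {
  res <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    if (GenomicRanges::width(gr)[i] == 0L) return("")
    chr <- as.character(GenomicRanges::seqnames(gr))[i]
    s <- as.character(Biostrings::subseq(
      genome[[chr]], GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))
    if (as.character(GenomicRanges::strand(gr))[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1)))
  res
}

#' Extract strand-aware up- and downstream gene flanks
#'
#' For every gene, takes `flankLen` bases 5' of the gene start (upstream)
#' and 3' of the gene end (downstream), both in transcription orientation:
#' for a minus-strand gene the upstream flank lies after the gene end in
#' contig coordinates and both returned sequences are reverse-complemented
#' so they read 5' to 3' relative to the gene. Flanks are truncated at
#' contig edges and the realized length recorded.
#'
#' @param genes `GRanges` with a `gene_id` column (see [readAnnotation()]).
#' @param genome named [Biostrings::DNAStringSet] or FASTA path; must
#'   contain every contig the genes sit on.
#' @param flankLen flank length in bp (default 2000).
#' @return list with `upstream` and `downstream` (`DNAStringSet`s named by
#'   gene id, gene orientation) and `info`, a data.frame of contig
#'   coordinates (1-based), realized lengths and truncation flags.
#' @export
extractFlanks <- function(genes, genome, flankLen = 2000L) {
  stopifnot(methods::is(genes, "GRanges"))
  if (is.null(genes$gene_id)) stop("'genes' must carry a gene_id column")
  genome <- .as_genome(genome)
  contigs <- as.character(GenomicRanges::seqnames(genes))
  missing_ctg <- setdiff(unique(contigs), names(genome))
  if (length(missing_ctg))
    stop("contig(s) missing from genome: ", paste(missing_ctg, collapse = ", "))
  if (any(as.character(GenomicRanges::strand(genes)) == "*"))
    stop("every gene must have a defined strand (+ or -)")
  sl <- stats::setNames(Biostrings::width(genome), names(genome))
  gr <- genes
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- sl
  up <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(gr, flankLen, start = TRUE)))
  down <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(gr, flankLen, start = FALSE)))
  upSeq <- .range_seqs(genome, up)
  downSeq <- .range_seqs(genome, down)
  names(upSeq) <- names(downSeq) <- genes$gene_id
  info <- data.frame(
    gene_id = genes$gene_id,
    contig = contigs,
    strand = as.character(GenomicRanges::strand(genes)),
    upstream_start = GenomicRanges::start(up),
    upstream_end = GenomicRanges::end(up),
    upstream_length = GenomicRanges::width(up),
    upstream_truncated = GenomicRanges::width(up) < flankLen,
    downstream_start = GenomicRanges::start(down),
    downstream_end = GenomicRanges::end(down),
    downstream_length = GenomicRanges::width(down),
    downstream_truncated = GenomicRanges::width(down) < flankLen,
    stringsAsFactors = FALSE)
  list(upstream = upSeq, downstream = downSeq, info = info)
}

## Map a hit at `start` (1-based, on the gene-oriented flank sequence) back
## to contig coordinates. For minus-strand genes the flank sequence is the
## reverse complement of the contig segment, and hit strands flip.
.hit_to_contig <- function(start, w, geneStrand, hitStrand, fs, fe) {
  if (geneStrand == "+") {
    list(start = fs + start - 1L, end = fs + start + w - 2L,
         strand = hitStrand)
  } else {
    list(start = fe - (start + w - 1L) + 1L, end = fe - start + 1L,
         strand = if (hitStrand == "+") "-" else "+")
  }
}

#' Per-gene motif presence in 2-kb flanks
#'
#' Scans the up- and downstream flank of every gene for the motif and
#' tabulates presence per region, reproducing the presence/absence logic
#' used to ask which co-correlated transcripts carry an ARE near the gene.
#'
#' @inheritParams extractFlanks
#' @param motif a [MotifModel-class].
#' @param bothStrands scan both strands of each flank (default `TRUE`).
#' @return data.frame with one row per gene (`gene_id`, `upstream`,
#'   `downstream` presence flags, hit counts, and a `category` of
#'   `"both"`, `"either"` or `"none"`). Attributes: `hits`, a data.frame of
#'   individual hits with flank offsets and contig coordinates; `summary`,
#'   the named count of genes per category.
#' @seealso [exportHitsBed()]
#' @export
flankPresenceTable <- function(genes, genome, motif, flankLen = 2000L,
                               bothStrands = TRUE) {
  fl <- extractFlanks(genes, genome, flankLen)
  w <- motifWidth(motif)
  hit_rows <- list()
  n_up <- n_down <- integer(length(genes))
  for (i in seq_along(genes)) {
    gid <- fl$info$gene_id[i]
    for (region in c("upstream", "downstream")) {
      hits <- scanMotif(motif, fl[[region]][[i]], bothStrands = bothStrands)
      if (region == "upstream") n_up[i] <- nrow(hits)
      else n_down[i] <- nrow(hits)
      if (!nrow(hits)) next
      fs <- fl$info[[paste0(region, "_start")]][i]
      fe <- fl$info[[paste0(region, "_end")]][i]
      cc <- lapply(seq_len(nrow(hits)), function(j)
        .hit_to_contig(hits$start[j], w, fl$info$strand[i],
                       hits$strand[j], fs, fe))
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        gene_id = gid, region = region,
        offset = hits$start,
        contig = fl$info$contig[i],
        contig_start = vapply(cc, `[[`, integer(1), "start"),
        contig_end = vapply(cc, `[[`, integer(1), "end"),
        strand = vapply(cc, `[[`, character(1), "strand"),
        match = hits$match, score = hits$score,
        rel_score = hits$rel_score, stringsAsFactors = FALSE)
    }
  }
  up <- n_up > 0L
  down <- n_down > 0L
  category <- ifelse(up & down, "both", ifelse(up | down, "either", "none"))
  out <- data.frame(gene_id = fl$info$gene_id, upstream = up,
                    downstream = down, n_upstream = n_up,
                    n_downstream = n_down, category = category,
                    stringsAsFactors = FALSE)
  hits_df <- if (length(hit_rows)) do.call(rbind, hit_rows)
             else data.frame(gene_id = character(0), region = character(0),
                             offset = integer(0), contig = character(0),
                             contig_start = integer(0),
                             contig_end = integer(0), strand = character(0),
                             match = character(0), score = numeric(0),
                             rel_score = numeric(0))
  attr(out, "hits") <- hits_df
  attr(out, "summary") <- c(both = sum(category == "both"),
                            either = sum(category == "either"),
                            none = sum(category == "none"))
  out
}

#' Export motif hits as BED6
#'
#' Writes the hit table attached to a [flankPresenceTable()] result (or any
#' data.frame with the same columns) as BED6 in 0-based half-open contig
#' coordinates; the score column is the relative score scaled to 0-1000.
#'
#' @param hits data.frame with columns `contig`, `contig_start`,
#'   `contig_end`, `gene_id`, `region`, `strand`, `rel_score`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportHitsBed <- function(hits, path) {
  if (methods::is(hits, "data.frame") && !is.null(attr(hits, "hits")))
    hits <- attr(hits, "hits")
  if (!nrow(hits)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = hits$contig,
    ranges = IRanges::IRanges(start = hits$contig_start,
                              end = hits$contig_end),
    strand = hits$strand)
  names(gr) <- paste(hits$gene_id, hits$region, sep = "|")
  S4Vectors::mcols(gr)$score <- pmin(1000, pmax(0,
    round(hits$rel_score * 1000)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
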