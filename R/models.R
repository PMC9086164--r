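#' Transcript models
#'
#' A light container for gene structure: one row per transcript plus exon and
#' CDS interval tables, all in 1-based fully-closed genomic coordinates (the
#' GTF convention). CDS intervals include the stop codon, so the CDS of every
#' coding transcript starts with ATG, ends with a stop codon and has length
#' divisible by 3.
#'
#' @param transcripts data.frame with columns transcript_id, gene_id, chrom,
#'   strand, start, end, coding.
#' @param exons data.frame with columns transcript_id, chrom, strand, start, end.
#' @param cds data.frame with the same columns, possibly zero rows.
#'
#' @return An object of class `TranscriptModels`.
#' @export
transcript_models <- function(transcripts, exons, cds) {
  need_tx <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end", "coding")
  need_iv <- c("transcript_id", "chrom", "strand", "start", "end")
  stopifnot(all(need_tx %in% names(transcripts)),
            all(need_iv %in% names(exons)),
            all(need_iv %in% names(cds)))
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]
  m <- structure(list(transcripts = transcripts, exons = exons, cds = cds),
                 class = "TranscriptModels")
  validate_transcript_models(m)
  m
}

validate_transcript_models <- function(m) {
  for (tid in unique(m$exons$transcript_id)) {
    ex <- m$exons[m$exons$transcript_id == tid, ]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping or unsorted exons in transcript ", tid)
    cd <- m$cds[m$cds$transcript_id == tid, ]
    if (nrow(cd)) {
      inside <- vapply(seq_len(nrow(cd)), function(i)
        any(cd$start[i] >= ex$start & cd$end[i] <= ex$end), logical(1))
      if (!all(inside)) stop("CDS interval outside exons in transcript ", tid)
      if (sum(cd$end - cd$start + 1) %% 3 != 0)
        stop("CDS length not divisible by 3 in transcript ", tid)
    }
  }
  invisible(m)
}

#' @export
print.TranscriptModels <- function(x, ...) {
  cat("TranscriptModels:", nrow(x$transcripts), "transcripts (",
      sum(x$transcripts$coding), "coding ) on",
      length(unique(x$transcripts$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read transcript models from a GTF subset
#'
#' Expects gene/transcript/exon/CDS features with `gene_id` and
#' `transcript_id` attributes. A transcript is coding iff it has CDS rows.
#'
#' @param path Path to a GTF file.
#' @return A `TranscriptModels` object.
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(
    type = as.character(gr$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gr$gene_id),
    transcript_id = if (!is.null(gr$transcript_id)) as.character(gr$transcript_id) else NA_character_,
    stringsAsFactors = FALSE
  )
  tx <- df[df$type == "transcript", ]
  exons <- df[df$type == "exon", c("transcript_id", "chrom", "strand", "start", "end")]
  cds <- df[df$type == "CDS", c("transcript_id", "chrom", "strand", "start", "end")]
  transcripts <- data.frame(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    chrom = tx$chrom, strand = tx$strand, start = tx$start, end = tx$end,
    coding = tx$transcript_id %in% cds$transcript_id,
    stringsAsFactors = FALSE
  )
  transcript_models(transcripts, exons, cds)
}

#' Write transcript models as a GTF subset
#'
#' @param models A `TranscriptModels` object.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  tx <- models$transcripts
  rows <- character(0)
  attr_str <- function(gid, tid)
    paste0("gene_id \"", gid, "\"; transcript_id \"", tid, "\";")
  gtf_line <- function(chrom, src, type, start, end, strand, attrs)
    paste(chrom, src, type, start, end, ".", strand, ".", attrs, sep = "\t")
  for (g in unique(tx$gene_id)) {
    gtx <- tx[tx$gene_id == g, ]
    rows <- c(rows, gtf_line(gtx$chrom[1], "editscape", "gene",
                             min(gtx$start), max(gtx$end), gtx$strand[1],
                             paste0("gene_id \"", g, "\";")))
    for (i in seq_len(nrow(gtx))) {
      tid <- gtx$transcript_id[i]
      rows <- c(rows, gtf_line(gtx$chrom[i], "editscape", "transcript",
                               gtx$start[i], gtx$end[i], gtx$strand[i],
                               attr_str(g, tid)))
      ex <- models$exons[models$exons$transcript_id == tid, ]
      for (j in seq_len(nrow(ex)))
        rows <- c(rows, gtf_line(ex$chrom[j], "editscape", "exon",
                                 ex$start[j], ex$end[j], ex$strand[j],
                                 attr_str(g, tid)))
      cd <- models$cds[models$cds$transcript_id == tid, ]
      for (j in seq_len(nrow(cd)))
        rows <- c(rows, gtf_line(cd$chrom[j], "editscape", "CDS",
                                 cd$start[j], cd$end[j], cd$strand[j],
                                 attr_str(g, tid)))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

# Map transcript coordinates (1 = 5' end of the mature transcript) to genomic
# positions, given the transcript's exon intervals sorted by genomic start.
tx_to_genome <- function(txpos, starts, ends, strand) {
  w <- ends - starts + 1
  if (strand == "-") {
    ord <- rev(seq_along(w))
    starts <- starts[ord]; ends <- ends[ord]; w <- w[ord]
  }
  cw <- cumsum(w)
  idx <- findInterval(txpos - 1L, c(0L, cw), rightmost.closed = FALSE)
  off <- txpos - c(0L, cw)[idx]
  if (strand == "+") starts[idx] + off - 1L else ends[idx] - off + 1L
}

# Inverse of tx_to_genome for positions that fall inside an exon; NA otherwise.
genome_to_tx <- function(gpos, starts, ends, strand) {
  w <- ends - starts + 1
  cw_before <- c(0L, cumsum(w))[seq_along(w)]
  hit <- which(gpos >= starts & gpos <= ends)
  if (!length(hit)) return(NA_integer_)
  i <- hit[1]
  if (strand == "+") {
    cw_before[i] + (gpos - starts[i]) + 1L
  } else {
    total <- sum(w)
    plus_pos <- cw_before[i] + (gpos - starts[i]) + 1L
    total - plus_pos + 1L
  }
}

transcripts_granges <- function(models) {
  tx <- models$transcripts
  GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start, end = tx$end),
    strand = tx$strand,
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    coding = tx$coding
  )
}

#' Effective gene lengths
#'
#' Sum of exon lengths of the longest transcript of each gene, in bp; the
#' length convention used for TPM.
#'
#' @param models A `TranscriptModels` object.
#' @return Named numeric vector, one entry per gene.
#' @export
effective_gene_lengths <- function(models) {
  ex <- models$exons
  ex_len <- tapply(ex$end - ex$start + 1, ex$transcript_id, sum)
  tx <- models$transcripts
  tx_len <- ex_len[tx$transcript_id]
  out <- tapply(tx_len, tx$gene_id, max)
  setNames(as.numeric(out), names(out))
}
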