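## Minimal functional-consequence annotator for A-to-G edits against a
## transcript model, with VEP-style category names.

#' Consequence categories, most to least severe
#'
#' The fixed priority used to pick one call per site across overlapping
#' transcripts.
#' @export
CONSEQUENCE_SEVERITY <- c(
  "stop_lost", "missense_variant", "synonymous_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant",
  "non_coding_transcript_exon_variant", "intron_variant",
  "non_coding_transcript_intron_variant", "intergenic_variant")

sense_base_at <- function(reference, chrom, pos, strand) {
  b <- as.character(Biostrings::subseq(reference[[chrom]], pos, pos))
  if (strand == "-") comp_base(b) else b
}

# Classify one site against one transcript. Returns a list(category, codon
# fields) or NULL when the site misses the transcript span.
classify_in_transcript <- function(chrom, pos, tid, models, reference) {
  tx <- models$transcripts[models$transcripts$transcript_id == tid, ]
  if (tx$chrom != chrom || pos < tx$start || pos > tx$end) return(NULL)
  ex <- models$exons[models$exons$transcript_id == tid, ]
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (!in_exon) {
    cat <- if (tx$coding) "intron_variant" else "non_coding_transcript_intron_variant"
    return(list(category = cat, codon_ref = NA, codon_alt = NA,
                aa_ref = NA, aa_alt = NA))
  }
  if (!tx$coding)
    return(list(category = "non_coding_transcript_exon_variant",
                codon_ref = NA, codon_alt = NA, aa_ref = NA, aa_alt = NA))
  strand <- tx$strand
  txpos <- genome_to_tx(pos, ex$start, ex$end, strand)
  cd <- models$cds[models$cds$transcript_id == tid, ]
  cds_len <- sum(cd$end - cd$start + 1)
  cds_sense_start_g <- if (strand == "+") min(cd$start) else max(cd$end)
  cds_tx_start <- genome_to_tx(cds_sense_start_g, ex$start, ex$end, strand)
  cds_tx_end <- cds_tx_start + cds_len - 1L
  if (txpos < cds_tx_start)
    return(list(category = "5_prime_UTR_variant", codon_ref = NA,
                codon_alt = NA, aa_ref = NA, aa_alt = NA))
  if (txpos > cds_tx_end)
    return(list(category = "3_prime_UTR_variant", codon_ref = NA,
                codon_alt = NA, aa_ref = NA, aa_alt = NA))
  cds_pos <- txpos - cds_tx_start + 1L
  codon_idx <- (cds_pos - 1L) %/% 3L
  pos_in_codon <- (cds_pos - 1L) %% 3L + 1L
  codon_tx <- cds_tx_start + codon_idx * 3L + 0:2
  codon_g <- tx_to_genome(codon_tx, ex$start, ex$end, strand)
  codon_ref <- paste(vapply(codon_g, function(g)
    sense_base_at(reference, chrom, g, strand), character(1)), collapse = "")
  alt_chars <- strsplit(codon_ref, "")[[1]]
  alt_chars[pos_in_codon] <- "G"
  codon_alt <- paste(alt_chars, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[codon_ref]); aa_alt <- unname(gc[codon_alt])
  category <- if (identical(aa_ref, aa_alt)) "synonymous_variant"
    else if (identical(aa_ref, "*")) "stop_lost"
    else "missense_variant"
  list(category = category, codon_ref = codon_ref, codon_alt = codon_alt,
       aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Annotate sites with their functional consequence
#'
#' Locates each canonical A-to-G site in every overlapping transcript,
#' classifies it (UTR / CDS / intron / non-coding; in CDS the edited codon is
#' translated with the standard genetic code to call synonymous, missense or
#' stop_lost), and keeps the most severe call per site
#' ([CONSEQUENCE_SEVERITY]). Sites overlapping no transcript are
#' `intergenic_variant`. A site whose strand-adjusted reference base is not A
#' is flagged (`ref_mismatch`), not dropped.
#'
#' @param sites Canonical site data.frame (chrom, pos, strand).
#' @param models A `TranscriptModels`.
#' @param reference Named `DNAStringSet` covering the sites.
#' @return data.frame: chrom, pos, strand, category, gene_id, transcript_id,
#'   codon_ref, codon_alt, aa_ref, aa_alt, ref_mismatch.
#' @export
annotate_sites <- function(sites, models, reference) {
  if (!all(sites$chrom %in% names(reference)))
    stop("sites on chromosomes absent from the reference: ",
         paste(setdiff(unique(sites$chrom), names(reference)), collapse = ", "))
  n <- nrow(sites)
  if (n == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), category = character(0),
                      gene_id = character(0), transcript_id = character(0),
                      codon_ref = character(0), codon_alt = character(0),
                      aa_ref = character(0), aa_alt = character(0),
                      ref_mismatch = logical(0)))
  txgr <- transcripts_granges(models)
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  ov <- GenomicRanges::findOverlaps(gr, txgr, ignore.strand = TRUE)
  ov_by_site <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))

  out <- vector("list", n)
  for (i in seq_len(n)) {
    tids <- models$transcripts$transcript_id[ov_by_site[[as.character(i)]]]
    best <- NULL; best_tid <- NA_character_; best_gene <- NA_character_
    for (tid in tids) {
      cl <- classify_in_transcript(sites$chrom[i], sites$pos[i], tid,
                                   models, reference)
      if (is.null(cl)) next
      if (is.null(best) ||
          match(cl$category, CONSEQUENCE_SEVERITY) <
          match(best$category, CONSEQUENCE_SEVERITY)) {
        best <- cl; best_tid <- tid
        best_gene <- models$transcripts$gene_id[
          models$transcripts$transcript_id == tid]
      }
    }
    if (is.null(best))
      best <- list(category = "intergenic_variant", codon_ref = NA,
                   codon_alt = NA, aa_ref = NA, aa_alt = NA)
    mism <- sense_base_at(reference, sites$chrom[i], sites$pos[i],
                          sites$strand[i]) != "A"
    out[[i]] <- data.frame(
      chrom = sites$chrom[i], pos = sites$pos[i], strand = sites$strand[i],
      category = best$category, gene_id = best_gene,
      transcript_id = best_tid,
      codon_ref = as.character(best$codon_ref),
      codon_alt = as.character(best$codon_alt),
      aa_ref = as.character(best$aa_ref), aa_alt = as.character(best$aa_alt),
      ref_mismatch = mism, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Tabulate consequence categories
#'
#' @param calls Output of [annotate_sites()].
#' @return Named integer vector over the nine categories; sums to
#'   `nrow(calls)`.
#' @export
tabulate_categories <- function(calls) {
  tab <- table(factor(calls$category, levels = CONSEQUENCE_SEVERITY))
  setNames(as.integer(tab), names(tab))
}
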