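# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_chroms = 1L, chrom_length = 200000L, n_genes = 40L,
         n_sites = 300L, n_differential = 10L, n_cis = 3L,
         n_samples_per_group = 12L),
    list(...))
  do.call(sim_config, args)
}

# A small two-group dataset reused across test files.
small_sim <- function() {
  if (is.null(.fixtures$small)) .fixtures$small <- simulate_dataset(small_cfg())
  .fixtures$small
}

# A high-coverage variant where detection is essentially noiseless.
deep_sim <- function() {
  if (is.null(.fixtures$deep))
    .fixtures$deep <- simulate_dataset(small_cfg(coverage_mean = 300,
                                                 coverage_dispersion = 50))
  .fixtures$deep
}

# Hand-built toy genome and transcript model with known codon layout.
#
# chrom "t1", 400 bp, baseline all C.
# tx_plus ('+', coding): exons [11,70] and [121,180];
#   CDS = transcript positions 21..80 -> genomic [31,70] + [121,140].
#   codon 1 (tx 21-23, genomic 31-33) = ATG
#   codon 2 (tx 24-26, genomic 34-36) = AAA (Lys); edit at 35 -> AGA missense
#   codon 3 (tx 27-29, genomic 37-39) = CCA (Pro); edit at 39 -> CCG synonymous
#   codon 20 (tx 78-80, genomic 138-140) = TAG (stop); edit at 139 -> TGG stop_lost
#   5'UTR: genomic 15 (A); 3'UTR: genomic 160 (A); intron: genomic 100 (A)
# tx_nc ('+', non-coding): exons [211,240] and [261,290]; exon site 220 (A),
#   intron site 250 (A).
# intergenic: genomic 350 (A).
toy_genome <- function() {
  chars <- rep("C", 400)
  set_seq <- function(chars, at, s) { chars[at] <- strsplit(s, "")[[1]]; chars }
  chars <- set_seq(chars, 31:33, "ATG")
  chars <- set_seq(chars, 34:36, "AAA")
  chars <- set_seq(chars, 37:39, "CCA")
  chars <- set_seq(chars, 138:140, "TAG")
  chars[c(15, 100, 160, 220, 250, 350)] <- "A"
  reference <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(reference) <- "t1"

  transcripts <- data.frame(
    transcript_id = c("tp.1", "tn.1"), gene_id = c("TP", "TN"),
    chrom = "t1", strand = "+",
    start = c(11L, 211L), end = c(180L, 290L),
    coding = c(TRUE, FALSE), stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = c("tp.1", "tp.1", "tn.1", "tn.1"), chrom = "t1",
    strand = "+", start = c(11L, 121L, 211L, 261L),
    end = c(70L, 180L, 240L, 290L), stringsAsFactors = FALSE)
  cds <- data.frame(
    transcript_id = c("tp.1", "tp.1"), chrom = "t1", strand = "+",
    start = c(31L, 121L), end = c(70L, 140L), stringsAsFactors = FALSE)
  list(reference = reference,
       models = transcript_models(transcripts, exons, cds))
}

toy_site <- function(pos, strand = "+")
  data.frame(chrom = "t1", pos = pos, strand = strand,
             ref_base = "A", ed_base = "G", stringsAsFactors = FALSE)

# Reverse-complement a whole dataset: genome, models and site coordinates.
# Position p on a chromosome of length L maps to L - p + 1; strands flip.
revcomp_dataset <- function(reference, models, sites) {
  L <- setNames(Biostrings::width(reference), names(reference))
  rc_ref <- Biostrings::reverseComplement(reference)
  names(rc_ref) <- names(reference)
  flip_iv <- function(df) {
    l <- L[df$chrom]
    new_start <- l - df$end + 1L
    df$end <- as.integer(l - df$start + 1L)
    df$start <- as.integer(new_start)
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  tx <- flip_iv(models$transcripts)
  ex <- flip_iv(models$exons)
  cd <- flip_iv(models$cds)
  rc_sites <- sites
  rc_sites$pos <- as.integer(L[sites$chrom] - sites$pos + 1L)
  rc_sites$strand <- ifelse(sites$strand == "+", "-", "+")
  list(reference = rc_ref,
       models = transcript_models(tx, ex, cd),
       sites = rc_sites)
}

# Build a SiteCountMatrix directly from level/coverage specifications.
# NA cells become undercovered (2 reads), i.e. missing under the default
# coverage floor.
counts_from_levels <- function(levels_mat, coverage = 100L,
                               chrom = "chr1", strand = "+") {
  n <- nrow(levels_mat); s <- ncol(levels_mat)
  samples <- colnames(levels_mat)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(s))
  ed <- round(levels_mat * coverage)
  ref <- coverage - ed
  na <- is.na(levels_mat)
  ed[na] <- 0L; ref[na] <- 2L
  sites <- data.frame(chrom = chrom, pos = seq_len(n) * 100L, strand = strand,
                      ref_base = "A", ed_base = "G", stringsAsFactors = FALSE)
  site_count_matrix(sites, samples, ref, ed)
}
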