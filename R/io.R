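## Readers and writers for the pipeline's table dialects. Coordinates are
## 1-based and fully closed everywhere, matching GTF/VCF conventions.

#' Write one sample's site counts as TSV
#'
#' Columns: `chrom pos strand ref_base alt_base ref_count alt_count`.
#'
#' @param counts A `SiteCountMatrix`.
#' @param sample Sample identifier (must be a column of `counts`).
#' @param path Output path.
#' @export
write_site_counts_tsv <- function(counts, sample, path) {
  stopifnot(inherits(counts, "SiteCountMatrix"), sample %in% counts$samples)
  df <- data.frame(
    chrom = counts$sites$chrom, pos = counts$sites$pos,
    strand = counts$sites$strand, ref_base = counts$sites$ref_base,
    alt_base = counts$sites$ed_base,
    ref_count = counts$ref_counts[, sample],
    alt_count = counts$ed_counts[, sample],
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_one_counts_tsv <- function(path) {
  df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed count table ", path, ": ",
                                          conditionMessage(e)))
  need <- c("chrom", "pos", "strand", "ref_base", "alt_base",
            "ref_count", "alt_count")
  if (!all(need %in% names(df)))
    stop("count table ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!is.finite(df$pos) | df$pos < 1)
  if (length(bad))
    stop("count table ", path, ": positions must be >= 1 (1-based); ",
         "offending line(s): ", paste(bad + 1L, collapse = ", "))
  bad <- which(df$ref_count < 0 | df$alt_count < 0)
  if (length(bad))
    stop("count table ", path, ": negative counts at line(s): ",
         paste(bad + 1L, collapse = ", "))
  df
}

#' Read per-site base counts
#'
#' `format = "tsv"` accepts a directory containing `*.site_counts.tsv` files
#' (one per sample; the sample name is the file-name prefix) or a named
#' character vector of file paths. All files must list the same sites.
#' `format = "vcf"` accepts a multi-sample VCF with an `AD` FORMAT field;
#' records are canonicalized to A-to-G sites (strand from `models` when
#' given, otherwise implied by the substitution) and non-A-to-G records are
#' dropped.
#'
#' @param path Directory, file vector (tsv) or single file (vcf).
#' @param format `"tsv"` or `"vcf"`.
#' @param models Optional `TranscriptModels` for strand resolution (vcf).
#' @param allow_antisense Accept A-to-G edits antisense to an overlapping
#'   gene (vcf canonicalization policy).
#' @return A `SiteCountMatrix`.
#' @export
read_site_counts <- function(path, format = c("tsv", "vcf"), models = NULL,
                             allow_antisense = FALSE) {
  format <- match.arg(format)
  if (format == "vcf")
    return(read_counts_vcf(path, models = models,
                           allow_antisense = allow_antisense))
  if (length(path) == 1 && dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.site_counts\\.tsv$",
                             full.names = TRUE))
    if (!length(files)) stop("no *.site_counts.tsv files in ", path)
    names(files) <- sub("\\.site_counts\\.tsv$", "", basename(files))
    path <- files
  }
  if (is.null(names(path)))
    names(path) <- sub("\\.site_counts\\.tsv$", "", basename(path))
  tabs <- lapply(path, read_one_counts_tsv)
  key0 <- site_key(tabs[[1]])
  for (i in seq_along(tabs))
    if (!identical(site_key(tabs[[i]]), key0))
      stop("count tables disagree on the site list (", names(path)[i], ")")
  sites <- tabs[[1]][, c("chrom", "pos", "strand", "ref_base", "alt_base")]
  names(sites)[5] <- "ed_base"
  site_count_matrix(sites, names(path),
                    vapply(tabs, `[[`, numeric(nrow(sites)), "ref_count"),
                    vapply(tabs, `[[`, numeric(nrow(sites)), "alt_count"))
}

#' Write site counts as a minimal multi-sample VCF 4.2
#'
#' One record per site with genomic REF/ALT (A/G on '+', T/C on '-') and a
#' per-sample `AD` field holding "ref,alt" depths.
#'
#' @param counts A `SiteCountMatrix`.
#' @param path Output path.
#' @param chrom_lengths Optional named vector for `##contig` header lines.
#' @export
write_counts_vcf <- function(counts, path, chrom_lengths = NULL) {
  stopifnot(inherits(counts, "SiteCountMatrix"))
  s <- counts$sites
  ref <- ifelse(s$strand == "+", "A", "T")
  alt <- ifelse(s$strand == "+", "G", "C")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=editscape")
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  hdr <- c(hdr,
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths (ref,alt)\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", counts$samples), collapse = "\t"))
  ad <- matrix(paste0(counts$ref_counts, ",", counts$ed_counts),
               nrow(s), length(counts$samples))
  body <- apply(cbind(s$chrom, s$pos, ".", ref, alt, ".", "PASS", ".", "AD",
                      ad), 1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

read_counts_vcf <- function(path, models = NULL, allow_antisense = FALSE) {
  vcf <- VariantAnnotation::readVcf(path, genome = "editscape")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- vapply(seq_along(alt_list), function(i)
    as.character(alt_list[[i]][1]), character(1))
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt_chr, stringsAsFactors = FALSE)
  if (any(variants$pos < 1)) stop("VCF positions must be >= 1")
  can <- canonicalize_variants(variants, models = models,
                               allow_antisense = allow_antisense)
  ad <- VariantAnnotation::geno(vcf)$AD
  samples <- colnames(vcf)
  if (is.list(ad)) {
    ref_counts <- matrix(vapply(ad, function(x) as.numeric(x[1]), 0),
                         nrow(variants), length(samples))
    ed_counts <- matrix(vapply(ad, function(x) as.numeric(x[2]), 0),
                        nrow(variants), length(samples))
  } else {
    ref_counts <- ad[, , 1, drop = TRUE]
    ed_counts <- ad[, , 2, drop = TRUE]
  }
  keep <- can$index
  site_count_matrix(can$sites, samples,
                    ref_counts[keep, , drop = FALSE],
                    ed_counts[keep, , drop = FALSE])
}

#' Read a known-editing-site table
#'
#' TSV with columns `chrom pos ref ed strand` (a REDIportal-like catalogue).
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_known_sites <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "ed", "strand")
  if (!all(need %in% names(df)))
    stop("known-site table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Read a sample-metadata table
#'
#' TSV with columns `sample group`.
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("metadata must have columns sample, group")
  df
}

#' Read a gene-count table
#'
#' TSV with a `gene_id` column followed by one column per sample.
#'
#' @param path Path to the TSV.
#' @return Integer matrix, genes x samples.
#' @export
read_gene_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}
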