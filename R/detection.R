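## Editing-level quantification, variant canonicalization, the
## high-confidence filter, and per-group site accounting.

#' Editing level from base counts
#'
#' The editing level is ed/(ref + ed): the fraction of reads supporting the
#' edited base (G) among reads supporting either allele. When total A+G
#' coverage is below `min_coverage` the level is *missing* (`NA`), not zero —
#' an undercovered cell can neither satisfy nor fail a level threshold.
#'
#' @param ref_count,ed_count Non-negative integer vectors.
#' @param min_coverage Minimum A+G coverage for a defined level.
#' @return Numeric vector in \[0, 1\] with `NA` for missing cells.
#' @export
compute_editing_level <- function(ref_count, ed_count, min_coverage = 10L) {
  if (any(ref_count < 0, na.rm = TRUE) || any(ed_count < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  tot <- ref_count + ed_count
  ifelse(tot >= min_coverage & tot > 0, ed_count / tot, NA_real_)
}

#' Editing-level matrix from a count matrix
#'
#' @param counts A `SiteCountMatrix`.
#' @param min_coverage Coverage floor defining missingness.
#' @return An `EditingLevelMatrix`.
#' @export
editing_levels <- function(counts, min_coverage = 10L) {
  stopifnot(inherits(counts, "SiteCountMatrix"))
  lv <- matrix(compute_editing_level(as.vector(counts$ref_counts),
                                     as.vector(counts$ed_counts),
                                     min_coverage),
               nrow(counts$ref_counts), ncol(counts$ref_counts))
  editing_level_matrix(counts$sites, counts$samples, lv, min_coverage)
}

#' Canonicalize substitutions to A-to-G editing sites
#'
#' A-to-I editing is read as A-to-G on the edited strand; on the genomic
#' forward strand an edit in a '-'-strand gene appears as T-to-C. Each
#' single-nucleotide substitution is resolved against the strand of the
#' overlapping gene when `models` is given (falling back to `strand_hint`,
#' then to the strand implied by the substitution itself): A>G maps to '+',
#' T>C to '-', everything else is rejected. An A>G call inside a '-'-strand
#' gene (or T>C inside a '+' gene) is an *antisense* edit and is rejected
#' unless `allow_antisense = TRUE`.
#'
#' @param variants data.frame with columns chrom, pos, ref, alt.
#' @param models Optional `TranscriptModels` for gene-strand lookup.
#' @param strand_hint Optional per-variant strand ('+', '-' or NA).
#' @param allow_antisense Keep antisense A-to-G edits (canonical strand is
#'   then the substitution-implied one).
#' @return list with `sites` (canonical data.frame: chrom, pos, strand,
#'   ref_base = "A", ed_base = "G"), `rejected` (with a `reason` code), and
#'   `index` (row indices of accepted variants in the input).
#' @export
canonicalize_variants <- function(variants, models = NULL, strand_hint = NULL,
                                  allow_antisense = FALSE) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (any(nchar(variants$ref) != 1 | nchar(variants$alt) != 1) ||
      !all(variants$ref %in% DNA_BASES4) || !all(variants$alt %in% DNA_BASES4))
    stop("canonicalization requires single-nucleotide substitutions (ACGT)")
  n <- nrow(variants)
  implied <- rep(NA_character_, n)
  implied[variants$ref == "A" & variants$alt == "G"] <- "+"
  implied[variants$ref == "T" & variants$alt == "C"] <- "-"

  gene_strand <- rep(NA_character_, n)
  if (!is.null(models) && nrow(models$transcripts)) {
    gr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, variants$pos))
    hit <- GenomicRanges::findOverlaps(gr, transcripts_granges(models),
                                       select = "first")
    gene_strand[!is.na(hit)] <- models$transcripts$strand[hit[!is.na(hit)]]
  }
  resolved <- gene_strand
  if (!is.null(strand_hint))
    resolved[is.na(resolved)] <- strand_hint[is.na(resolved)]

  reason <- rep(NA_character_, n)
  reason[is.na(implied)] <- "not A-to-G under either strand"
  anti <- !is.na(implied) & !is.na(resolved) & implied != resolved
  if (!allow_antisense) reason[anti] <- "antisense A-to-G within a gene"
  accept <- is.na(reason)
  list(
    sites = data.frame(chrom = variants$chrom[accept],
                       pos = variants$pos[accept],
                       strand = implied[accept],
                       ref_base = "A", ed_base = "G",
                       stringsAsFactors = FALSE),
    rejected = cbind(variants[!accept, , drop = FALSE],
                     reason = reason[!accept]),
    index = which(accept))
}

#' Genomic (forward-strand) representation of canonical sites
#'
#' Inverse of canonicalization: a '+' site is A>G on the genome, a '-' site
#' is T>C.
#'
#' @param sites Canonical site data.frame (chrom, pos, strand).
#' @return data.frame chrom, pos, ref, alt.
#' @export
genomic_representation <- function(sites) {
  data.frame(chrom = sites$chrom, pos = sites$pos,
             ref = ifelse(sites$strand == "+", "A", "T"),
             alt = ifelse(sites$strand == "+", "G", "C"),
             stringsAsFactors = FALSE)
}

#' High-confidence editing-site filter
#'
#' A site is retained iff its editing level is at least `min_level` in at
#' least `min_samples` samples (missing cells cannot qualify), OR it matches
#' the known-site catalogue on (chrom, pos, strand) — position-only matching
#' with `match_strand = FALSE` for catalogues with unreliable strand.
#'
#' @param levels An `EditingLevelMatrix` of canonical sites.
#' @param known Known-site data.frame (chrom, pos, strand), or NULL.
#' @param min_level Level threshold (default 0.01, i.e. 1%).
#' @param min_samples Minimum samples at/above `min_level` (default 2).
#' @param match_strand Require strand agreement for the known branch.
#' @return list with `levels` (retained `EditingLevelMatrix`) and `log`
#'   (per-site decision record: n_at_level, known_match, branch one of
#'   "threshold", "known", "both", "removed").
#' @export
filter_high_confidence <- function(levels, known = NULL, min_level = 0.01,
                                   min_samples = 2L, match_strand = TRUE) {
  stopifnot(inherits(levels, "EditingLevelMatrix"))
  n_at <- rowSums(levels$levels >= min_level, na.rm = TRUE)
  pass_thr <- n_at >= min_samples
  if (!is.null(known) && nrow(known)) {
    kkey <- if (match_strand) paste(known$chrom, known$pos, known$strand)
            else paste(known$chrom, known$pos)
    skey <- if (match_strand)
      paste(levels$sites$chrom, levels$sites$pos, levels$sites$strand)
    else paste(levels$sites$chrom, levels$sites$pos)
    pass_known <- skey %in% kkey
  } else pass_known <- rep(FALSE, nrow(levels$sites))
  retained <- pass_thr | pass_known
  branch <- ifelse(pass_thr & pass_known, "both",
                   ifelse(pass_thr, "threshold",
                          ifelse(pass_known, "known", "removed")))
  log <- data.frame(levels$sites[, c("chrom", "pos", "strand")],
                    n_at_level = n_at, known_match = pass_known,
                    retained = retained, branch = branch,
                    stringsAsFactors = FALSE)
  list(levels = subset_levels(levels, retained), log = log)
}

#' Per-group site detection, edited-gene counts and Venn partition
#'
#' A site is "detected in group g" when at least `detect_min_samples` samples
#' of g have a defined level >= `min_level`. Retained sites are partitioned
#' into group-exclusive, shared and (possible only for sites retained purely
#' via the known-site branch) detected-in-neither buckets; the four counts
#' always sum to the retained total.
#'
#' @param levels Retained `EditingLevelMatrix`.
#' @param metadata data.frame sample, group (exactly two groups).
#' @param min_level Detection level threshold.
#' @param detect_min_samples Samples required per group.
#' @param gene_map Optional named character vector site-key -> gene_id for
#'   edited-gene counts.
#' @return list with `venn` (named counts: <g1>_exclusive, <g2>_exclusive,
#'   shared, neither), `detected` (site x group logical matrix),
#'   `per_group_sites`, `per_group_genes`, `per_sample` (sample, n_sites,
#'   n_genes).
#' @export
group_site_accounting <- function(levels, metadata, min_level = 0.01,
                                  detect_min_samples = 1L, gene_map = NULL) {
  stopifnot(inherits(levels, "EditingLevelMatrix"))
  groups <- sort(unique(metadata$group))
  if (length(groups) != 2) stop("exactly two groups required")
  for (g in groups)
    if (!sum(metadata$group == g)) stop("group ", g, " has zero samples")
  hit <- !is.na(levels$levels) & levels$levels >= min_level
  detected <- vapply(groups, function(g) {
    cols <- metadata$sample[metadata$group == g]
    rowSums(hit[, cols, drop = FALSE]) >= detect_min_samples
  }, logical(nrow(levels$sites)))
  if (is.null(dim(detected)))
    detected <- matrix(detected, nrow = 1, dimnames = list(NULL, groups))
  venn <- c(sum(detected[, 1] & !detected[, 2]),
            sum(detected[, 2] & !detected[, 1]),
            sum(detected[, 1] & detected[, 2]),
            sum(!detected[, 1] & !detected[, 2]))
  names(venn) <- c(paste0(groups, "_exclusive"), "shared", "neither")

  keys <- site_key(levels$sites)
  per_group_sites <- setNames(colSums(detected), groups)
  per_group_genes <- setNames(rep(NA_integer_, 2), groups)
  per_sample_genes <- rep(NA_integer_, length(levels$samples))
  if (!is.null(gene_map)) {
    gm <- gene_map[keys]
    per_group_genes <- vapply(groups, function(g)
      length(unique(stats::na.omit(gm[detected[, g]]))), integer(1))
    per_sample_genes <- vapply(seq_along(levels$samples), function(j)
      length(unique(stats::na.omit(gm[hit[, j]]))), integer(1))
  }
  per_sample <- data.frame(
    sample = levels$samples,
    group = metadata$group[match(levels$samples, metadata$sample)],
    n_sites = colSums(hit), n_genes = per_sample_genes,
    stringsAsFactors = FALSE)
  list(venn = venn, detected = detected,
       per_group_sites = per_group_sites, per_group_genes = per_group_genes,
       per_sample = per_sample)
}
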