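#' Per-site per-sample base-count matrix
#'
#' Holds reference-allele (A) and edited-allele (G) read counts for canonical
#' A-to-G sites across samples. Row order of the matrices follows `sites`.
#'
#' @param sites data.frame with columns chrom, pos (1-based), strand,
#'   ref_base, ed_base; one row per site.
#' @param samples Character vector of sample identifiers (column order).
#' @param ref_counts,ed_counts Integer matrices, sites x samples.
#'
#' @return An object of class `SiteCountMatrix`.
#' @export
site_count_matrix <- function(sites, samples, ref_counts, ed_counts) {
  stopifnot(all(c("chrom", "pos", "strand", "ref_base", "ed_base") %in% names(sites)))
  ref_counts <- as.matrix(ref_counts); ed_counts <- as.matrix(ed_counts)
  if (nrow(ref_counts) != nrow(sites) || nrow(ed_counts) != nrow(sites) ||
      ncol(ref_counts) != length(samples) || ncol(ed_counts) != length(samples))
    stop("count matrix dimensions do not match sites x samples")
  if (any(ref_counts < 0) || any(ed_counts < 0))
    stop("read counts must be non-negative")
  dimnames(ref_counts) <- dimnames(ed_counts) <- list(site_key(sites), samples)
  structure(list(sites = sites, samples = samples,
                 ref_counts = ref_counts, ed_counts = ed_counts),
            class = "SiteCountMatrix")
}

#' @export
print.SiteCountMatrix <- function(x, ...) {
  cat("SiteCountMatrix:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  invisible(x)
}

#' Unique site key
#'
#' `chrom:pos:strand` string used to align tables across pipeline stages.
#'
#' @param sites data.frame with chrom, pos, strand columns.
#' @return Character vector.
#' @export
site_key <- function(sites) paste(sites$chrom, sites$pos, sites$strand, sep = ":")

#' Per-site per-sample editing-level matrix
#'
#' Levels are edited/(reference + edited) read fractions in \[0, 1\]; a cell is
#' `NA` where total A+G coverage is below `min_coverage` (missing, not zero).
#'
#' @param sites Site table as in [site_count_matrix()].
#' @param samples Sample identifiers.
#' @param levels Numeric matrix with NA for missing cells.
#' @param min_coverage The coverage floor that defined missingness.
#'
#' @return An object of class `EditingLevelMatrix`.
#' @export
editing_level_matrix <- function(sites, samples, levels, min_coverage) {
  levels <- as.matrix(levels)
  if (nrow(levels) != nrow(sites) || ncol(levels) != length(samples))
    stop("level matrix dimensions do not match sites x samples")
  ok <- is.na(levels) | (levels >= 0 & levels <= 1)
  if (!all(ok)) stop("editing levels must lie in [0, 1] or be NA")
  dimnames(levels) <- list(site_key(sites), samples)
  structure(list(sites = sites, samples = samples, levels = levels,
                 min_coverage = as.integer(min_coverage)),
            class = "EditingLevelMatrix")
}

#' @export
print.EditingLevelMatrix <- function(x, ...) {
  cat("EditingLevelMatrix:", nrow(x$sites), "sites x", length(x$samples),
      "samples;", sum(is.na(x$levels)), "missing cells (min_coverage =",
      x$min_coverage, ")\n")
  invisible(x)
}

subset_levels <- function(levels, keep) {
  editing_level_matrix(levels$sites[keep, , drop = FALSE], levels$samples,
                       levels$levels[keep, , drop = FALSE], levels$min_coverage)
}
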