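## Nucleotide context around editing sites (+/- flank bp, strand-adjusted)
## and per-position enrichment against a background composition.

#' Extract strand-adjusted sequence contexts around sites
#'
#' Returns the (2*flank+1)-mer centered on each site, reverse-complemented
#' for '-'-strand sites so that "upstream" (-1, -2, ...) is always 5' of the
#' edited A on the edited strand. Sites too close to a contig end are dropped
#' with a warning.
#'
#' @param sites Canonical site data.frame (chrom, pos, strand).
#' @param reference Named `DNAStringSet`.
#' @param flank Bases on each side (default 6).
#' @return An object of class `ContextMatrix`: list with `counts` and `freqs`
#'   (4 x (2*flank+1) matrices, rows A/C/G/T, columns -flank..flank),
#'   `n_sites`, `flank`, `kmers` (per-site context strings) and `dropped`
#'   (site keys lost to contig ends).
#' @export
extract_contexts <- function(sites, reference, flank = 6L) {
  stopifnot(flank >= 1L)
  widths <- setNames(Biostrings::width(reference), names(reference))
  ok <- sites$pos - flank >= 1 & sites$pos + flank <= widths[sites$chrom]
  dropped <- site_key(sites)[!ok]
  if (length(dropped))
    warning(length(dropped), " site(s) within ", flank,
            " bp of a contig end dropped")
  sites <- sites[ok, , drop = FALSE]
  kmers <- character(nrow(sites))
  for (cn in unique(sites$chrom)) {
    idx <- which(sites$chrom == cn)
    v <- Biostrings::Views(reference[[cn]], start = sites$pos[idx] - flank,
                           end = sites$pos[idx] + flank)
    kmers[idx] <- as.character(v)
  }
  neg <- sites$strand == "-"
  if (any(neg))
    kmers[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(kmers[neg])))
  positions <- seq(-flank, flank)
  counts <- matrix(0L, 4, length(positions),
                   dimnames = list(DNA_BASES4, positions))
  if (nrow(sites)) {
    chm <- do.call(rbind, strsplit(kmers, ""))
    for (j in seq_along(positions))
      counts[, j] <- tabulate(factor(chm[, j], levels = DNA_BASES4), 4)
  }
  freqs <- if (nrow(sites)) counts / nrow(sites) else counts * NA_real_
  structure(list(counts = counts, freqs = freqs, n_sites = nrow(sites),
                 flank = flank, kmers = kmers, dropped = dropped),
            class = "ContextMatrix")
}

#' @export
print.ContextMatrix <- function(x, ...) {
  cat("ContextMatrix:", x$n_sites, "sites, positions -", x$flank, "..+",
      x$flank, "\n", sep = "")
  invisible(x)
}

#' Background base composition of a reference
#'
#' @param reference Named `DNAStringSet`.
#' @return Named integer vector of A/C/G/T counts.
#' @export
reference_base_counts <- function(reference) {
  af <- Biostrings::alphabetFrequency(reference)
  colSums(af[, DNA_BASES4, drop = FALSE])
}

#' Position-specific base enrichment around editing sites
#'
#' For every flank position p and base b, tests the observed count of b at p
#' against the background composition with a two-sided Fisher exact test on
#' the 2x2 table \[observed b, observed other; background b, background
#' other\], and reports the sample odds ratio. P-values are BH-adjusted
#' across all position x base cells (position 0 — the edited A itself — is
#' excluded). Cells with a zero margin get p = 1 and an undefined odds ratio,
#' flagged in `degenerate`.
#'
#' @param ctx A `ContextMatrix`.
#' @param background Named A/C/G/T vector of counts (e.g.
#'   [reference_base_counts()]) or frequencies summing to 1 (scaled to 1e6
#'   pseudo-counts), or a `DNAStringSet` whose composition is used.
#' @return data.frame: position, base, observed, expected, odds_ratio, p,
#'   padj, direction ("enriched"/"depleted"/"none"), degenerate.
#' @export
position_enrichment <- function(ctx, background) {
  stopifnot(inherits(ctx, "ContextMatrix"), ctx$n_sites >= 1)
  if (inherits(background, "DNAStringSet"))
    background <- reference_base_counts(background)
  background <- background[DNA_BASES4]
  if (any(is.na(background))) stop("background must cover A, C, G, T")
  if (abs(sum(background) - 1) < 1e-6)
    background <- round(background * 1e6)
  bg_tot <- sum(background)
  positions <- as.integer(colnames(ctx$counts))
  n <- ctx$n_sites
  rows <- list()
  for (p in positions[positions != 0]) {
    for (b in DNA_BASES4) {
      a <- ctx$counts[b, as.character(p)]
      cbg <- background[[b]]
      degenerate <- (a == 0 && cbg == 0) || (a == n && cbg == bg_tot)
      if (degenerate) {
        pval <- 1; or <- NA_real_
      } else {
        tab <- matrix(c(a, n - a, cbg, bg_tot - cbg), 2, byrow = TRUE)
        pval <- fisher.test(tab)$p.value
        or <- (a / (n - a)) / (cbg / (bg_tot - cbg))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, base = b, observed = a,
        expected = n * cbg / bg_tot, odds_ratio = or, p = pval,
        degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out$direction <- ifelse(is.na(out$odds_ratio), "none",
                          ifelse(out$odds_ratio > 1, "enriched",
                                 ifelse(out$odds_ratio < 1, "depleted", "none")))
  out[, c("position", "base", "observed", "expected", "odds_ratio",
          "p", "padj", "direction", "degenerate")]
}
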