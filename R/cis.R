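## Gene expression normalization (TPM) and cis-regulatory correlation of
## editing levels with host-gene expression.

#' Transcripts-per-million normalization
#'
#' Per sample: rate_g = count_g / length_g; TPM_g = rate_g / sum(rates) *
#' 1e6, so every sample with nonzero counts sums to exactly 1e6. Samples with
#' all-zero counts get NA and are listed in the `zero_samples` attribute.
#'
#' @param counts Integer matrix, genes x samples, rownames = gene ids.
#' @param lengths Named vector of effective gene lengths in bp
#'   (see [effective_gene_lengths()]).
#' @return Numeric matrix of TPM values with attribute `zero_samples`.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  len <- lengths[rownames(counts)]
  if (anyNA(len)) stop("missing effective lengths for: ",
                       paste(utils::head(rownames(counts)[is.na(len)]),
                             collapse = ", "))
  if (any(len <= 0)) stop("effective lengths must be positive")
  rate <- counts / len
  tot <- colSums(rate)
  zero <- tot == 0
  out <- sweep(rate, 2, ifelse(zero, NA, tot), "/") * 1e6
  attr(out, "zero_samples") <- colnames(counts)[zero]
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average ranks; p comes from the
#' two-sided t-approximation with n-2 degrees of freedom. Pairs with a
#' missing value are dropped. Fewer than `min_n` complete pairs, or zero
#' variance in either variable's ranks, yields NA.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_n Minimum complete pairs (default 4).
#' @return Named vector c(rho, p, n).
#' @export
spearman_cor <- function(x, y, min_n = 4L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < min_n || sd(x) == 0 || sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  c(rho = unname(ct$estimate), p = unname(ct$p.value), n = n)
}

#' Cis-regulatory scan: editing level vs host-gene expression
#'
#' For each site with a host gene present in the expression matrix, computes
#' the Spearman correlation between the site's editing levels and the gene's
#' expression across samples where both are defined. Sites passing
#' `p < p_cutoff` are cis candidates, split into positive and negative
#' directions; p-values are additionally BH-adjusted for reference.
#'
#' @param sites Site keys (`chrom:pos:strand`) to scan, or NULL for all sites
#'   in `levels`.
#' @param levels An `EditingLevelMatrix`.
#' @param expression Genes x samples matrix (e.g. [tpm()]); columns must
#'   cover `levels$samples`.
#' @param gene_map Named character vector: site key -> host gene id (NA for
#'   none), e.g. built from [annotate_sites()].
#' @param p_cutoff Significance cutoff (default 0.05).
#' @param min_n Minimum complete sample pairs per site.
#' @return list with `results` (site, gene, n, rho, p, padj, significant,
#'   direction) and `skipped` (site, reason).
#' @export
cis_scan <- function(sites = NULL, levels, expression, gene_map,
                     p_cutoff = 0.05, min_n = 4L) {
  stopifnot(inherits(levels, "EditingLevelMatrix"))
  keys <- site_key(levels$sites)
  if (is.null(sites)) sites <- keys
  idx <- match(sites, keys)
  if (anyNA(idx)) stop("unknown site keys in `sites`")
  rows <- list(); skipped <- list()
  skip <- function(s, why)
    skipped[[length(skipped) + 1L]] <<- data.frame(site = s, reason = why,
                                                   stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    i <- idx[k]; key <- keys[i]
    gene <- unname(gene_map[key])
    if (is.null(gene) || is.na(gene)) { skip(key, "no host gene"); next }
    if (!gene %in% rownames(expression)) {
      skip(key, "host gene absent from expression matrix"); next
    }
    y <- expression[gene, levels$samples]
    if (all(is.na(y)) || sd(y, na.rm = TRUE) == 0) {
      skip(key, "zero expression variance"); next
    }
    sc <- spearman_cor(levels$levels[i, ], y, min_n = min_n)
    if (is.na(sc[["rho"]])) {
      skip(key, "too few complete pairs or zero rank variance"); next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      site = key, gene = gene, n = sc[["n"]], rho = sc[["rho"]],
      p = sc[["p"]], stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = character(0), gene = character(0), n = integer(0),
               rho = numeric(0), p = numeric(0))
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(site = character(0), reason = character(0))
  if (nrow(results)) {
    results$padj <- p.adjust(results$p, method = "BH")
    results$significant <- results$p < p_cutoff
    results$direction <- ifelse(results$rho > 0, "positive", "negative")
  }
  list(results = results, skipped = skipped)
}
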