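## End-to-end orchestration: detect -> annotate -> context -> differential ->
## cis, with persisted stage tables and a summary report.

#' Default pipeline parameters
#'
#' @param ... Overrides for any parameter.
#' @return Named list of validated parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    min_coverage = 10L,      # A+G reads below which a level is missing
    min_level = 0.01,        # editing-level threshold of the filter (1%)
    min_samples = 2L,        # samples at/above min_level to retain a site
    match_strand = TRUE,     # known-site matching on (chrom, pos, strand)
    allow_antisense = FALSE,
    detect_min_samples = 1L, # per-group detection rule for the Venn split
    flank = 6L,              # context window half-width
    context_sites = "all",   # or "case_exclusive": sites for the motif scan
    alpha = 0.05,            # differential significance level (raw p)
    use_fdr = FALSE,
    min_per_group = 3L,
    max_missing = 0.5,       # PCA: drop sites with more missingness
    p_cutoff = 0.05,         # cis significance cutoff
    cis_sites = "significant", # or "genic": scan all retained genic sites
    min_n = 4L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  if (p$min_level <= 0 || p$min_level >= 1) stop("min_level must be in (0,1)")
  if (p$flank < 1) stop("flank must be >= 1")
  if (!p$context_sites %in% c("all", "case_exclusive"))
    stop("context_sites must be 'all' or 'case_exclusive'")
  if (!p$cis_sites %in% c("significant", "genic"))
    stop("cis_sites must be 'significant' or 'genic'")
  p
}

#' Run the full editing analysis on in-memory objects
#'
#' Stages: editing levels -> high-confidence filter -> consequence
#' annotation -> per-group accounting -> sequence context -> differential
#' scan -> PCA -> TPM -> cis scan. Every stage table is kept in the returned
#' report; [write_report()] persists them.
#'
#' @param counts A `SiteCountMatrix`.
#' @param models A `TranscriptModels`.
#' @param reference Named `DNAStringSet`.
#' @param known Known-site data.frame or NULL.
#' @param metadata data.frame sample, group.
#' @param gene_counts Genes x samples matrix.
#' @param params [pipeline_params()] list.
#' @return A list of class `EditingReport`.
#' @export
run_pipeline <- function(counts, models, reference, known, metadata,
                         gene_counts, params = pipeline_params()) {
  stages <- list()
  lv <- editing_levels(counts, params$min_coverage)
  filt <- filter_high_confidence(lv, known, params$min_level,
                                 params$min_samples, params$match_strand)
  retained <- filt$levels
  calls <- annotate_sites(retained$sites, models, reference)
  categories <- tabulate_categories(calls)
  gene_map <- setNames(calls$gene_id, site_key(calls))
  acct <- group_site_accounting(retained, metadata, params$min_level,
                                params$detect_min_samples, gene_map)

  groups <- sort(unique(metadata$group))
  ctx_idx <- if (params$context_sites == "case_exclusive")
    which(acct$detected[, 1] & !acct$detected[, 2]) else
      seq_len(nrow(retained$sites))
  context <- NULL; enrichment <- NULL
  if (length(ctx_idx) >= 1) {
    context <- extract_contexts(retained$sites[ctx_idx, , drop = FALSE],
                                reference, params$flank)
    if (context$n_sites >= 1)
      enrichment <- position_enrichment(context,
                                        reference_base_counts(reference))
  }

  diff <- differential_scan(retained, metadata, params$alpha,
                            params$min_per_group, params$use_fdr)
  pca <- NULL
  if (nrow(diff$significant) >= 2)
    pca <- tryCatch(pca_editing(retained, diff$significant$site,
                                params$max_missing),
                    error = function(e) NULL)

  expr <- tpm(gene_counts, effective_gene_lengths(models))
  cis_keys <- if (params$cis_sites == "significant") diff$significant$site
    else site_key(retained$sites)[!is.na(gene_map[site_key(retained$sites)])]
  cis <- cis_scan(cis_keys, retained, expr, gene_map,
                  params$p_cutoff, params$min_n)

  n_sig <- nrow(diff$significant)
  summary <- list(
    n_input_sites = nrow(counts$sites),
    n_retained_sites = nrow(retained$sites),
    n_edited_genes = length(unique(stats::na.omit(gene_map))),
    categories = as.list(categories),
    venn = as.list(acct$venn),
    per_group_sites = as.list(acct$per_group_sites),
    per_group_genes = as.list(acct$per_group_genes),
    n_differential = n_sig,
    n_up_in_case = sum(diff$significant$direction == "up_in_case"),
    n_down_in_case = sum(diff$significant$direction == "down_in_case"),
    n_differential_genes = length(unique(stats::na.omit(
      gene_map[diff$significant$site]))),
    pca_var_pct = if (!is.null(pca)) pca$var_pct[1:min(2, length(pca$var_pct))]
      else NULL,
    n_cis_tested = nrow(cis$results),
    n_cis_significant = if (nrow(cis$results)) sum(cis$results$significant)
      else 0L,
    n_cis_positive = if (nrow(cis$results))
      sum(cis$results$significant & cis$results$direction == "positive")
      else 0L,
    n_cis_negative = if (nrow(cis$results))
      sum(cis$results$significant & cis$results$direction == "negative")
      else 0L)

  structure(list(
    params = params, summary = summary, levels = lv, retained = retained,
    filter_log = filt$log, calls = calls, categories = categories,
    gene_map = gene_map, accounting = acct, context = context,
    enrichment = enrichment, differential = diff, pca = pca,
    expression = expr, cis = cis, groups = groups),
    class = "EditingReport")
}

#' @export
print.EditingReport <- function(x, ...) {
  s <- x$summary
  cat("EditingReport:", s$n_retained_sites, "retained sites in",
      s$n_edited_genes, "genes;", s$n_differential, "differential (",
      s$n_down_in_case, "down,", s$n_up_in_case, "up );",
      s$n_cis_significant, "cis-correlated\n")
  invisible(x)
}

#' Run the full pipeline from files
#'
#' @param config A list with input paths: `counts` (directory of per-sample
#'   TSVs, a vector of TSV paths, or a VCF), `format` ("tsv"/"vcf"),
#'   `reference` (FASTA), `annotation` (GTF), `known_sites`, `gene_counts`,
#'   `metadata`; optionally `out_dir` and `params` (a [pipeline_params()]
#'   list).
#' @return The `EditingReport`, invisibly when `out_dir` is set.
#' @export
run_all <- function(config) {
  need <- c("counts", "reference", "annotation", "gene_counts", "metadata")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config lacks: ", paste(miss, collapse = ", "))
  for (f in c(config$reference, config$annotation, config$gene_counts,
              config$metadata, config$known_sites))
    if (!file.exists(f) && !dir.exists(f)) stop("input not found: ", f)
  params <- config$params %||% pipeline_params()
  models <- read_transcript_models(config$annotation)
  reference <- Biostrings::readDNAStringSet(config$reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  counts <- read_site_counts(config$counts, config$format %||% "tsv",
                             models = models,
                             allow_antisense = params$allow_antisense)
  known <- if (!is.null(config$known_sites))
    read_known_sites(config$known_sites) else NULL
  metadata <- read_metadata(config$metadata)
  gene_counts <- read_gene_counts(config$gene_counts)
  report <- run_pipeline(counts, models, reference, known, metadata,
                         gene_counts, params)
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir)
    return(invisible(report))
  }
  report
}

#' Persist every stage table of a report
#'
#' Writes retained levels, the filter decision log, consequence calls,
#' context frequency matrix and enrichment table, differential results, PCA
#' scores, TPM matrix, cis results, and a `summary.json` echoing all
#' parameters.
#'
#' @param report An `EditingReport`.
#' @param out_dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list()
  lv <- data.frame(report$retained$sites,
                   report$retained$levels, check.names = FALSE)
  paths$levels <- wt(lv, "editing_levels.tsv")
  paths$filter_log <- wt(report$filter_log, "filter_log.tsv")
  paths$calls <- wt(report$calls, "consequences.tsv")
  paths$per_sample <- wt(report$accounting$per_sample, "per_sample_counts.tsv")
  if (!is.null(report$context)) {
    pfm <- data.frame(base = rownames(report$context$counts),
                      report$context$counts, check.names = FALSE)
    paths$pfm <- wt(pfm, "context_pfm.tsv")
  }
  if (!is.null(report$enrichment))
    paths$enrichment <- wt(report$enrichment, "context_enrichment.tsv")
  if (nrow(report$differential$results))
    paths$differential <- wt(report$differential$results, "differential.tsv")
  if (!is.null(report$pca)) {
    sc <- data.frame(sample = rownames(report$pca$scores),
                     report$pca$scores, check.names = FALSE)
    paths$pca <- wt(sc, "pca_scores.tsv")
  }
  expr <- data.frame(gene_id = rownames(report$expression),
                     report$expression, check.names = FALSE)
  paths$expression <- wt(expr, "tpm.tsv")
  if (nrow(report$cis$results))
    paths$cis <- wt(report$cis$results, "cis.tsv")
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(params = report$params,
                            summary = report$summary),
                       paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
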