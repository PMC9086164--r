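## Synthetic dataset generator: reference + gene models, planted A-to-G
## editing sites with nearest-neighbor motif structure, beta-binomial counts
## over negative-binomial coverage, and editing-coupled gene expression.

dss_to_chars <- function(reference)
  lapply(as.character(reference), function(s) strsplit(s, "")[[1]])

chars_to_dss <- function(chars)
  Biostrings::DNAStringSet(vapply(chars, paste, "", collapse = ""))

# Split a transcript of length tx_len into n_exons exon widths, each >= min_exon.
split_exon_widths <- function(tx_len, n_exons, min_exon = 30L) {
  while (n_exons > 1L && tx_len < n_exons * min_exon) n_exons <- n_exons - 1L
  rem <- tx_len - n_exons * min_exon
  extra <- if (n_exons == 1L) rem else
    as.vector(stats::rmultinom(1, rem, rep(1 / n_exons, n_exons)))
  min_exon + extra
}

#' Generate a random reference genome and gene annotation
#'
#' Emits one random nucleotide sequence per chromosome and a set of
#' non-overlapping single-transcript gene models. Every gene has >= 2 exons;
#' coding genes (the default; a `noncoding_prob` fraction is non-coding) carry
#' 5'/3' UTRs and a CDS that starts with ATG, ends with a stop codon and has
#' length divisible by 3 — the start and stop codons are written into the
#' reference so annotation and sequence always agree. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `reference` (a named
#'   [Biostrings::DNAStringSet]) and `models` (a `TranscriptModels`).
#' @export
generate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  chars <- lapply(seq_len(config$n_chroms), function(i)
    sample(DNA_BASES4, config$chrom_length, replace = TRUE))
  names(chars) <- chrom_names

  genes_per_chrom <- tabulate(rep(seq_len(config$n_chroms),
                                  length.out = config$n_genes),
                              nbins = config$n_chroms)
  tx_rows <- list(); exon_rows <- list(); cds_rows <- list()
  gid_n <- 0L
  for (ci in seq_len(config$n_chroms)) {
    cursor <- 1000L
    for (k in seq_len(genes_per_chrom[ci])) {
      gid_n <- gid_n + 1L
      gid <- sprintf("G%04d", gid_n)
      tid <- paste0(gid, ".t1")
      strand <- sample(STRANDS, 1)
      coding <- runif(1) >= config$noncoding_prob
      if (coding) {
        n_codons <- sample(60:250, 1)          # incl. start and stop codons
        cds_len <- 3L * n_codons
        u5 <- sample(30:150, 1); u3 <- sample(100:300, 1)
        tx_len <- u5 + cds_len + u3
      } else {
        u5 <- 0L; u3 <- 0L; cds_len <- 0L
        tx_len <- sample(400:1500, 1)
      }
      n_exons <- sample(2:5, 1)
      widths <- split_exon_widths(tx_len, n_exons)
      n_exons <- length(widths)
      introns <- sample(200:1500, n_exons - 1L, replace = TRUE)
      span <- sum(widths) + sum(introns)
      if (cursor + span + 1000L > config$chrom_length)
        stop("chromosome ", chrom_names[ci], " cannot host ",
             genes_per_chrom[ci], " genes of the requested sizes; ",
             "increase chrom_length or reduce n_genes")
      ex_start <- cursor + c(0L, cumsum(widths[-n_exons] + introns))
      ex_end <- ex_start + widths - 1L
      tx_rows[[gid]] <- data.frame(
        transcript_id = tid, gene_id = gid, chrom = chrom_names[ci],
        strand = strand, start = ex_start[1], end = ex_end[n_exons],
        coding = coding, stringsAsFactors = FALSE)
      exon_rows[[gid]] <- data.frame(
        transcript_id = tid, chrom = chrom_names[ci], strand = strand,
        start = ex_start, end = ex_end, stringsAsFactors = FALSE)
      if (coding) {
        # CDS occupies transcript positions u5+1 .. u5+cds_len
        cds_tx <- c(u5 + 1L, u5 + cds_len)
        gpos <- tx_to_genome(seq(cds_tx[1], cds_tx[2]), ex_start, ex_end, strand)
        gpos_sorted <- sort(gpos)
        brk <- c(0L, which(diff(gpos_sorted) > 1L), length(gpos_sorted))
        cds_iv <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(b)
          c(gpos_sorted[brk[b] + 1L], gpos_sorted[brk[b + 1L]])))
        cds_rows[[gid]] <- data.frame(
          transcript_id = tid, chrom = chrom_names[ci], strand = strand,
          start = cds_iv[, 1], end = cds_iv[, 2], stringsAsFactors = FALSE)
        # write start and stop codons (sense orientation)
        stop_codon <- sample(c("TAA", "TAG", "TGA"), 1)
        sense <- c("A", "T", "G", strsplit(stop_codon, "")[[1]])
        at_tx <- c(cds_tx[1] + 0:2, cds_tx[2] - 2:0)
        at_g <- tx_to_genome(at_tx, ex_start, ex_end, strand)
        written <- if (strand == "+") sense else comp_base(sense)
        chars[[ci]][at_g] <- written
      }
      cursor <- cursor + span + sample(500:1500, 1)
    }
  }
  transcripts <- do.call(rbind, tx_rows)
  exons <- do.call(rbind, exon_rows)
  cds <- if (length(cds_rows)) do.call(rbind, cds_rows) else
    data.frame(transcript_id = character(0), chrom = character(0),
               strand = character(0), start = integer(0), end = integer(0))
  if (is.null(transcripts))
    transcripts <- data.frame(transcript_id = character(0), gene_id = character(0),
                              chrom = character(0), strand = character(0),
                              start = integer(0), end = integer(0),
                              coding = logical(0))
  if (is.null(exons))
    exons <- data.frame(transcript_id = character(0), chrom = character(0),
                        strand = character(0), start = integer(0), end = integer(0))
  reference <- chars_to_dss(chars)
  names(reference) <- chrom_names
  list(reference = reference,
       models = transcript_models(transcripts, exons, cds))
}

# Genomic positions whose +/-1 neighborhood must stay untouched: the start and
# stop codons of every coding transcript.
protected_codon_positions <- function(models) {
  out <- lapply(split(models$cds, models$cds$transcript_id), function(cd) {
    if (!nrow(cd)) return(NULL)
    L <- sum(cd$end - cd$start + 1)
    gpos <- tx_to_genome(c(1:3, (L - 2):L), cd$start, cd$end, cd$strand[1])
    data.frame(chrom = cd$chrom[1], pos = gpos, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  if (is.null(df)) return(list())
  split(df$pos, df$chrom)
}

#' Plant editing sites with motif, differential and cis structure
#'
#' Selects `n_sites` positions whose strand-adjusted reference base is A
#' (gene strand where the position falls in a gene, '+' otherwise), at least
#' 7 bp apart and clear of CDS start/stop codons, then rewrites the
#' strand-adjusted -1/+1 neighbors so that G occurs there with the configured
#' probabilities. Baseline mean editing levels are drawn from
#' Beta(editing_alpha, editing_beta); `n_differential` sites get a case-group
#' mean of clamp(baseline + differential_shift, 0, 1); `n_cis` genic sites
#' (disjoint from the differential set) get a coupling sign. The true
#' functional category of every site is read off the final reference and
#' annotation.
#'
#' @param reference Named `DNAStringSet` from [generate_reference()].
#' @param models `TranscriptModels` from [generate_reference()].
#' @param config A [sim_config()] object.
#' @return A list with `truth` (class `SimTruth`, holding `site_table`) and
#'   `reference` (the rewritten `DNAStringSet`).
#' @export
plant_editing_sites <- function(reference, models, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  chrom_names <- names(reference)
  chars <- dss_to_chars(reference)
  L <- config$chrom_length
  txgr <- transcripts_granges(models)
  protected <- protected_codon_positions(models)
  forbidden <- lapply(chrom_names, function(cn) {
    p <- protected[[cn]]
    if (is.null(p)) integer(0) else unique(c(p - 1L, p, p + 1L))
  })
  names(forbidden) <- chrom_names

  occ <- lapply(chrom_names, function(cn) logical(L))
  names(occ) <- chrom_names
  acc_chrom <- character(0); acc_pos <- integer(0)
  acc_strand <- character(0); acc_gene <- character(0)
  # candidate positions target transcribed regions 90% of the time: editing
  # is observed in RNA-seq reads, so sites live mostly inside transcripts
  tx <- models$transcripts
  tx_w <- if (nrow(tx)) tx$end - tx$start + 1 else numeric(0)
  rounds <- 0L
  while (length(acc_pos) < config$n_sites && rounds < 40L) {
    rounds <- rounds + 1L
    m <- max(4L * (config$n_sites - length(acc_pos)), 1000L)
    ci <- sample.int(config$n_chroms, m, replace = TRUE)
    pos <- sample.int(L - 14L, m, replace = TRUE) + 7L
    if (nrow(tx)) {
      genic <- which(runif(m) < 0.9)
      ti <- sample.int(nrow(tx), length(genic), replace = TRUE, prob = tx_w)
      gpos <- tx$start[ti] + floor(runif(length(genic)) * tx_w[ti])
      okg <- gpos >= 8L & gpos <= L - 7L
      ci[genic[okg]] <- match(tx$chrom[ti], chrom_names)[okg]
      pos[genic[okg]] <- as.integer(gpos[okg])
    }
    gr <- GenomicRanges::GRanges(chrom_names[ci], IRanges::IRanges(pos, pos))
    hit <- GenomicRanges::findOverlaps(gr, txgr, select = "first")
    strand <- ifelse(is.na(hit), "+", models$transcripts$strand[hit])
    gene <- ifelse(is.na(hit), NA_character_, models$transcripts$gene_id[hit])
    for (i in seq_len(m)) {
      if (length(acc_pos) >= config$n_sites) break
      cn <- chrom_names[ci[i]]; p <- pos[i]
      need <- if (strand[i] == "+") "A" else "T"
      if (chars[[cn]][p] != need) next
      if (p %in% forbidden[[cn]]) next
      if (any(occ[[cn]][max(1L, p - 6L):min(L, p + 6L)])) next
      occ[[cn]][p] <- TRUE
      acc_chrom <- c(acc_chrom, cn); acc_pos <- c(acc_pos, p)
      acc_strand <- c(acc_strand, strand[i]); acc_gene <- c(acc_gene, gene[i])
    }
  }
  if (length(acc_pos) < config$n_sites)
    stop("could not find ", config$n_sites,
         " eligible A positions; reduce n_sites or enlarge the genome")

  ord <- order(match(acc_chrom, chrom_names), acc_pos)
  sites <- data.frame(
    site_id = sprintf("S%05d", seq_len(config$n_sites)),
    chrom = acc_chrom[ord], pos = acc_pos[ord], strand = acc_strand[ord],
    ref_base = "A", ed_base = "G", gene_id = acc_gene[ord],
    stringsAsFactors = FALSE)

  n <- config$n_sites
  idx_diff <- if (config$n_differential > 0) sample.int(n, config$n_differential) else integer(0)
  genic <- setdiff(which(!is.na(sites$gene_id)), idx_diff)
  if (length(genic) < config$n_cis)
    stop("not enough genic sites outside the differential set to host ",
         config$n_cis, " cis sites")
  idx_cis <- if (config$n_cis > 0) sample(genic, config$n_cis) else integer(0)

  baseline <- rbeta(n, config$editing_alpha, config$editing_beta)
  case_mean <- baseline
  case_mean[idx_diff] <- pmin(pmax(baseline[idx_diff] + config$differential_shift, 0), 1)
  cis_sign <- integer(n)
  cis_sign[idx_cis] <- sample(c(-1L, 1L), config$n_cis, replace = TRUE)
  is_known <- runif(n) < config$known_fraction

  # rewrite -1/+1 neighbors (strand-adjusted) to the configured G frequency
  draw_neighbor <- function(p_g) {
    g <- runif(n) < p_g
    out <- sample(c("A", "C", "T"), n, replace = TRUE)
    out[g] <- "G"
    out
  }
  sense_m1 <- draw_neighbor(config$motif_g_minus1_prob)
  sense_p1 <- draw_neighbor(config$motif_g_plus1_prob)
  for (i in seq_len(n)) {
    cn <- sites$chrom[i]
    if (sites$strand[i] == "+") {
      chars[[cn]][sites$pos[i] - 1L] <- sense_m1[i]
      chars[[cn]][sites$pos[i] + 1L] <- sense_p1[i]
    } else {
      chars[[cn]][sites$pos[i] + 1L] <- comp_base(sense_m1[i])
      chars[[cn]][sites$pos[i] - 1L] <- comp_base(sense_p1[i])
    }
  }
  new_reference <- chars_to_dss(chars)
  names(new_reference) <- chrom_names

  calls <- annotate_sites(sites, models, new_reference)
  ctx <- extract_contexts(sites, new_reference, flank = 6)
  site_table <- cbind(sites, data.frame(
    baseline_mean = baseline, case_mean = case_mean,
    is_differential = seq_len(n) %in% idx_diff,
    is_cis = seq_len(n) %in% idx_cis,
    cis_sign = cis_sign, is_known = is_known,
    category = calls$category, context13 = ctx$kmers,
    stringsAsFactors = FALSE))
  truth <- structure(list(site_table = site_table, phi = NULL),
                     class = "SimTruth")
  list(truth = truth, reference = new_reference)
}

#' Simulate base counts, gene expression and sample metadata
#'
#' For sample s and site j: coverage c_sj ~ NegBin(coverage_mean,
#' coverage_dispersion); the sample-level editing level phi_sj ~ Beta
#' re-parameterized around the site's group mean with concentration
#' `level_concentration`; edited reads g_sj ~ Binomial(c_sj, phi_sj); reference
#' reads = c_sj - g_sj. Gene counts are negative-binomial with log-mean
#' shifted by `cis_slope * sign * phi` at each gene's cis site.
#'
#' @param truth `SimTruth` from [plant_editing_sites()].
#' @param models `TranscriptModels`.
#' @param config A [sim_config()] object.
#' @return A list with `counts` (a `SiteCountMatrix`), `phi` (true per-sample
#'   levels, sites x samples), `gene_counts` (genes x samples integer matrix)
#'   and `metadata` (data.frame sample, group).
#' @export
simulate_counts <- function(truth, models, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  st <- truth$site_table
  n <- nrow(st)
  nspg <- config$n_samples_per_group
  samples <- c(sprintf("case_%02d", seq_len(nspg)),
               sprintf("control_%02d", seq_len(nspg)))
  groups <- rep(c("case", "control"), each = nspg)
  ns <- length(samples)

  mu <- matrix(0, n, ns)
  mu[, groups == "case"] <- st$case_mean
  mu[, groups == "control"] <- st$baseline_mean
  conc <- config$level_concentration
  phi <- matrix(0, n, ns)
  inner <- mu > 0 & mu < 1
  phi[inner] <- rbeta(sum(inner), mu[inner] * conc, (1 - mu[inner]) * conc)
  phi[mu >= 1] <- 1

  cov <- matrix(rnbinom(n * ns, mu = config$coverage_mean,
                        size = config$coverage_dispersion), n, ns)
  ed <- matrix(rbinom(n * ns, as.vector(cov), as.vector(phi)), n, ns)
  counts <- site_count_matrix(
    st[, c("chrom", "pos", "strand", "ref_base", "ed_base")],
    samples, cov - ed, ed)
  dimnames(phi) <- list(st$site_id, samples)

  gene_ids <- unique(models$transcripts$gene_id)
  base_mu <- rlnorm(length(gene_ids), config$expr_mean_log, config$expr_sd_log)
  gmu <- matrix(rep(base_mu, ns), length(gene_ids), ns)
  rownames(gmu) <- gene_ids
  for (j in which(st$is_cis)) {
    g <- st$gene_id[j]
    gmu[g, ] <- gmu[g, ] * exp(config$cis_slope * st$cis_sign[j] * phi[j, ])
  }
  gene_counts <- matrix(rnbinom(length(gmu), mu = as.vector(gmu),
                                size = config$expr_dispersion),
                        nrow(gmu), ns,
                        dimnames = list(gene_ids, samples))
  metadata <- data.frame(sample = samples, group = groups,
                         stringsAsFactors = FALSE)
  list(counts = counts, phi = phi, gene_counts = gene_counts,
       metadata = metadata)
}

#' Generate a complete synthetic editing dataset in memory
#'
#' Convenience wrapper chaining [generate_reference()],
#' [plant_editing_sites()] and [simulate_counts()].
#'
#' @param config A [sim_config()] object.
#' @return A list of class `EditingSim` with elements `config`, `reference`,
#'   `models`, `truth`, `counts`, `phi`, `gene_counts`, `gene_lengths`,
#'   `metadata`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genref <- generate_reference(config)
  planted <- plant_editing_sites(genref$reference, genref$models, config)
  sim <- simulate_counts(planted$truth, genref$models, config)
  truth <- planted$truth
  truth$phi <- sim$phi
  structure(list(
    config = config, reference = planted$reference, models = genref$models,
    truth = truth, counts = sim$counts, phi = sim$phi,
    gene_counts = sim$gene_counts,
    gene_lengths = effective_gene_lengths(genref$models),
    metadata = sim$metadata), class = "EditingSim")
}

#' @export
print.EditingSim <- function(x, ...) {
  cat("EditingSim:", nrow(x$truth$site_table), "planted sites,",
      length(x$metadata$sample), "samples, seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits reference FASTA (+ .fai index), GTF annotation, one site-count TSV
#' per sample plus an equivalent multi-sample VCF with AD fields, a known-site
#' table (the planted known sites plus decoy positions), gene counts,
#' metadata, and truth tables. All files are plain text and round-trip
#' through the package readers.
#'
#' @param sim An `EditingSim` from [simulate_dataset()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of the written paths.
#' @export
write_dataset <- function(sim, out_dir) {
  stopifnot(inherits(sim, "EditingSim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- list()

  paths$reference <- file.path(out_dir, "reference.fa")
  Biostrings::writeXStringSet(sim$reference, paths$reference)
  Rsamtools::indexFa(paths$reference)

  paths$annotation <- file.path(out_dir, "annotation.gtf")
  write_gtf(sim$models, paths$annotation)

  cdir <- file.path(out_dir, "counts")
  dir.create(cdir, showWarnings = FALSE)
  paths$counts <- vapply(sim$counts$samples, function(s) {
    p <- file.path(cdir, paste0(s, ".site_counts.tsv"))
    write_site_counts_tsv(sim$counts, s, p)
    p
  }, character(1))

  paths$vcf <- file.path(out_dir, "counts.vcf")
  write_counts_vcf(sim$counts, paths$vcf,
                   chrom_lengths = setNames(Biostrings::width(sim$reference),
                                            names(sim$reference)))

  st <- sim$truth$site_table
  known <- st[st$is_known, c("chrom", "pos", "strand"), drop = FALSE]
  known$ref <- rep("A", nrow(known)); known$ed <- rep("G", nrow(known))
  n_decoy <- round(sim$config$decoy_fraction / (1 - sim$config$decoy_fraction) *
                     max(nrow(known), 1))
  set.seed(sim$config$seed + 3L)
  decoys <- sample_decoy_sites(sim$reference, st, n_decoy)
  known_tab <- rbind(known[, c("chrom", "pos", "ref", "ed", "strand")],
                     decoys)
  known_tab <- known_tab[order(known_tab$chrom, known_tab$pos), ]
  paths$known_sites <- file.path(out_dir, "known_sites.tsv")
  write.table(known_tab, paths$known_sites, sep = "\t", quote = FALSE,
              row.names = FALSE)

  paths$gene_counts <- file.path(out_dir, "gene_counts.tsv")
  gc <- data.frame(gene_id = rownames(sim$gene_counts), sim$gene_counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(gc, paths$gene_counts, sep = "\t", quote = FALSE,
              row.names = FALSE)

  paths$metadata <- file.path(out_dir, "metadata.tsv")
  write.table(sim$metadata, paths$metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)

  paths$truth_sites <- file.path(out_dir, "truth_sites.tsv")
  write.table(st, paths$truth_sites, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$truth_levels <- file.path(out_dir, "truth_levels.tsv")
  tl <- data.frame(site_id = rownames(sim$phi), sim$phi,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tl, paths$truth_levels, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

# Decoy known-site entries: genomic A positions that were not planted.
sample_decoy_sites <- function(reference, site_table, n_decoy) {
  if (n_decoy <= 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), ed = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  chrom_names <- names(reference)
  planted <- paste(site_table$chrom, site_table$pos)
  out_chrom <- character(0); out_pos <- integer(0)
  tries <- 0L
  while (length(out_pos) < n_decoy && tries < 50L) {
    tries <- tries + 1L
    ci <- sample.int(length(chrom_names), n_decoy, replace = TRUE)
    L <- Biostrings::width(reference)[ci]
    pos <- vapply(L, function(l) sample.int(l - 14L, 1L) + 7L, integer(1))
    base <- vapply(seq_along(ci), function(i)
      as.character(Biostrings::subseq(reference[[ci[i]]], pos[i], pos[i])),
      character(1))
    ok <- base == "A" & !(paste(chrom_names[ci], pos) %in% planted) &
      !(paste(chrom_names[ci], pos) %in% paste(out_chrom, out_pos))
    out_chrom <- c(out_chrom, chrom_names[ci[ok]])
    out_pos <- c(out_pos, pos[ok])
  }
  k <- min(n_decoy, length(out_pos))
  data.frame(chrom = out_chrom[seq_len(k)], pos = out_pos[seq_len(k)],
             ref = "A", ed = "G", strand = "+", stringsAsFactors = FALSE)
}
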