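test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_sites = 10, n_differential = 8, n_cis = 4),
               "n_differential")
  expect_error(sim_config(known_fraction = 1.5), "probabilities")
  expect_error(sim_config(differential_shift = 1.2), "differential_shift")
  expect_error(sim_config(coverage_mean = -1), "coverage")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 60000L, n_genes = 8L,
                    n_sites = 40L, n_differential = 4L, n_cis = 2L,
                    n_samples_per_group = 3L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in c("reference.fa", "annotation.gtf", "counts.vcf",
              "known_sites.tsv", "gene_counts.tsv", "truth_sites.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
})

test_that("a zero-gene configuration still yields a valid empty annotation", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 10000L, n_genes = 0L,
                    n_sites = 0L, n_differential = 0L, n_cis = 0L)
  gr <- generate_reference(cfg)
  expect_equal(nrow(gr$models$transcripts), 0)
  expect_equal(sum(Biostrings::width(gr$reference)), 10000)
})

test_that("emitted CDS re-parsed from disk starts ATG, ends stop, length %% 3 == 0", {
  sim <- small_sim()
  d <- file.path(tempdir(), "cdscheck")
  write_dataset(sim, d)
  models <- read_transcript_models(file.path(d, "annotation.gtf"))
  ref <- Biostrings::readDNAStringSet(file.path(d, "reference.fa"))
  names(ref) <- sub("\\s.*$", "", names(ref))
  coding <- models$transcripts[models$transcripts$coding, ]
  expect_gt(nrow(coding), 5)
  for (tid in coding$transcript_id) {
    cd <- models$cds[models$cds$transcript_id == tid, ]
    w <- sum(cd$end - cd$start + 1)
    expect_equal(w %% 3, 0)
    strand <- cd$strand[1]
    pieces <- lapply(seq_len(nrow(cd)), function(i)
      as.character(Biostrings::subseq(ref[[cd$chrom[i]]], cd$start[i], cd$end[i])))
    cds_seq <- paste(pieces, collapse = "")
    if (strand == "-")
      cds_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_seq)))
    expect_equal(substr(cds_seq, 1, 3), "ATG")
    expect_true(substr(cds_seq, w - 2, w) %in% c("TAA", "TAG", "TGA"))
  }
})

test_that("planted truth is consistent with the emitted reference", {
  sim <- small_sim()
  st <- sim$truth$site_table
  # strand-adjusted reference base at every site is A
  base <- vapply(seq_len(nrow(st)), function(i) {
    b <- as.character(Biostrings::subseq(sim$reference[[st$chrom[i]]],
                                         st$pos[i], st$pos[i]))
    if (st$strand[i] == "-") chartr("ACGT", "TGCA", b) else b
  }, character(1))
  expect_true(all(base == "A"))
  # every recorded 13-mer matches an independent extraction from the FASTA
  ctx <- vapply(seq_len(nrow(st)), function(i) {
    s <- as.character(Biostrings::subseq(sim$reference[[st$chrom[i]]],
                                         st$pos[i] - 6, st$pos[i] + 6))
    if (st$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  expect_identical(ctx, st$context13)
})

test_that("degenerate motif and shift settings behave as configured", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 100000L, n_genes = 15L,
                    n_sites = 120L, n_differential = 10L, n_cis = 2L,
                    n_samples_per_group = 3L, motif_g_plus1_prob = 1,
                    differential_shift = 0)
  gr <- generate_reference(cfg)
  planted <- plant_editing_sites(gr$reference, gr$models, cfg)
  st <- planted$truth$site_table
  expect_true(all(substr(st$context13, 8, 8) == "G"))
  expect_equal(st$case_mean, st$baseline_mean)
})

test_that("the -1 G motif is depleted relative to background (binomial test)", {
  st <- small_sim()$truth$site_table     # motif_g_minus1_prob = 0.05
  k <- sum(substr(st$context13, 6, 6) == "G")
  bt <- binom.test(k, nrow(st), p = 0.25, alternative = "less")
  expect_lt(bt$p.value, 1e-6)
})

test_that("counts conserve coverage and levels concentrate at phi = 0.5 at deep coverage", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 80000L, n_genes = 10L,
                    n_sites = 60L, n_differential = 0L, n_cis = 0L,
                    n_samples_per_group = 4L, coverage_mean = 5000,
                    coverage_dispersion = 1000, editing_alpha = 1e6,
                    editing_beta = 1e6, level_concentration = 1e9)
  sim <- simulate_dataset(cfg)
  cov <- sim$counts$ref_counts + sim$counts$ed_counts
  expect_true(all(cov >= 0))
  lv <- sim$counts$ed_counts / cov
  # binomial SE at phi = 0.5 and the realized coverage; allow 4 SE
  se <- sqrt(0.25 / cov)
  expect_true(all(abs(lv - 0.5) < 4 * se + 1e-12))
})

test_that("mean baseline level is within 3 SE of the Beta prior mean", {
  cfg <- small_cfg(n_sites = 1000L)
  gr <- generate_reference(cfg)
  st <- plant_editing_sites(gr$reference, gr$models, cfg)$truth$site_table
  a <- cfg$editing_alpha; b <- cfg$editing_beta
  mu <- a / (a + b)
  se <- sqrt(a * b / ((a + b)^2 * (a + b + 1))) / sqrt(nrow(st))
  expect_lt(abs(mean(st$baseline_mean) - mu), 3 * se)
})

test_that("metadata mirrors the two-group study design", {
  md <- small_sim()$metadata
  expect_equal(nrow(md), 24)
  expect_equal(sort(unique(md$group)), c("case", "control"))
  expect_equal(unname(table(md$group)["case"]), 12, ignore_attr = TRUE)
})

test_that("with zero cis coupling, editing-expression correlation is null on average", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 300000L, n_genes = 60L,
                    n_sites = 400L, n_differential = 0L, n_cis = 20L,
                    n_samples_per_group = 12L, cis_slope = 0)
  sim <- simulate_dataset(cfg)
  st <- sim$truth$site_table
  expr <- tpm(sim$gene_counts, sim$gene_lengths)
  rhos <- vapply(which(st$is_cis), function(j)
    suppressWarnings(cor(sim$phi[j, ], expr[st$gene_id[j], ],
                         method = "spearman")), numeric(1))
  expect_lt(abs(mean(rhos)), 0.25)
})

test_that("written datasets round-trip through the package readers", {
  sim <- small_sim()
  d <- file.path(tempdir(), "roundtrip")
  paths <- write_dataset(sim, d)
  ct <- read_site_counts(file.path(d, "counts"), "tsv")
  expect_equal(ct$ref_counts, sim$counts$ref_counts, ignore_attr = TRUE)
  expect_equal(ct$ed_counts, sim$counts$ed_counts, ignore_attr = TRUE)
  expect_identical(site_key(ct$sites), site_key(sim$counts$sites))
  models <- read_transcript_models(paths$annotation)
  cv <- read_site_counts(paths$vcf, "vcf", models = models)
  # VCF and TSV routes agree downstream
  lt <- editing_levels(ct); lvcf <- editing_levels(cv)
  expect_identical(site_key(lt$sites), site_key(lvcf$sites))
  expect_equal(lt$levels, lvcf$levels, ignore_attr = TRUE)
})

test_that("known_fraction = 0 leaves only decoys in the known-site table", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 80000L, n_genes = 10L,
                    n_sites = 50L, n_differential = 0L, n_cis = 0L,
                    n_samples_per_group = 3L, known_fraction = 0,
                    decoy_fraction = 0.5)
  sim <- simulate_dataset(cfg)
  d <- file.path(tempdir(), "decoyonly")
  paths <- write_dataset(sim, d)
  known <- read_known_sites(paths$known_sites)
  planted <- paste(sim$truth$site_table$chrom, sim$truth$site_table$pos)
  expect_gt(nrow(known), 0)
  expect_false(any(paste(known$chrom, known$pos) %in% planted))
})
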