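test_that("contexts are strand-adjusted 13-mers with A fixed at position 0", {
  toy <- toy_genome()
  sites <- toy_site(c(100L, 160L))
  ctx <- extract_contexts(sites, toy$reference)
  expect_equal(ctx$n_sites, 2)
  expect_equal(colSums(ctx$counts), rep(2, 13), ignore_attr = TRUE)
  expect_equal(unname(ctx$freqs["A", "0"]), 1)
  expect_equal(colSums(ctx$freqs), rep(1, 13), ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("a '-' site's +1 base is the reverse complement of genomic pos-1", {
  ref <- Biostrings::DNAStringSet("ACGTACGTATGCATGCA")  # T at position 8
  names(ref) <- "c"
  site <- data.frame(chrom = "c", pos = 8L, strand = "-")  # sense base is A
  ctx <- extract_contexts(site, ref, flank = 2)
  genomic_m1 <- as.character(Biostrings::subseq(ref[[1]], 7, 7))   # "G"
  # reported context is revcomp of [6..10]; its +1 column is comp(genomic 7)
  expect_equal(substr(ctx$kmers, 4, 4), chartr("ACGT", "TGCA", genomic_m1))
  expect_equal(unname(ctx$freqs["A", "0"]), 1)
})

test_that("sites too close to a contig end are dropped with a warning", {
  ref <- Biostrings::DNAStringSet("AAAAAAAAAA")
  names(ref) <- "c"
  sites <- data.frame(chrom = "c", pos = c(2L, 5L), strand = "+")
  expect_warning(ctx <- extract_contexts(sites, ref, flank = 4), "dropped")
  expect_equal(ctx$n_sites, 1)
  expect_equal(ctx$dropped, "c:2:+")
})

test_that("Fisher p for table [[3,1],[1,3]] equals 34/70", {
  # a ContextMatrix whose +1/G cell yields exactly that 2x2 against a
  # 1-G / 3-other background
  kmers <- c("AAG", "AAG", "AAG", "AAA")
  sites <- data.frame(chrom = "c", pos = c(2L, 6L, 10L, 14L), strand = "+")
  ref <- Biostrings::DNAStringSet(paste(kmers, collapse = "A"))
  names(ref) <- "c"
  ctx <- extract_contexts(sites, ref, flank = 1)
  enr <- position_enrichment(ctx, c(A = 3, C = 0, G = 1, T = 0))
  cell <- enr[enr$position == 1 & enr$base == "G", ]
  expect_equal(cell$p, 34 / 70, tolerance = 1e-12)
  expect_equal(cell$p, oracle_fisher_p(3, 1, 1, 3), tolerance = 1e-12)
  expect_gt(cell$odds_ratio, 1)
})

test_that("Fisher p matches exhaustive enumeration for all small tables", {
  for (n in 2:12) {
    for (a in 0:n) for (cc in 0:n) {
      b <- n - a; d <- n - cc
      p_pkg <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
      expect_equal(p_pkg, oracle_fisher_p(a, b, cc, d), tolerance = 1e-9,
                   label = sprintf("table %d %d %d %d", a, b, cc, d))
    }
  }
})

test_that("an observed composition equal to background gives OR 1, p 1", {
  # 4 sites whose +1 base composition matches the background exactly
  kmers <- c("AAC", "AAC", "AAG", "AAT")
  ref <- Biostrings::DNAStringSet(paste(kmers, collapse = "A"))
  names(ref) <- "c"
  sites <- data.frame(chrom = "c", pos = c(2L, 6L, 10L, 14L), strand = "+")
  ctx <- extract_contexts(sites, ref, flank = 1)
  enr <- position_enrichment(ctx, c(A = 0, C = 2, G = 1, T = 1))
  p1 <- enr[enr$position == 1, ]
  expect_equal(p1$odds_ratio[p1$base == "C"], 1)
  expect_equal(p1$p[p1$base == "C"], 1)
  expect_equal(p1$odds_ratio[p1$base == "G"], 1)
  expect_equal(p1$p[p1$base == "T"], 1)
})

test_that("row swap inverts the odds ratio and preserves p", {
  kmers <- c(rep("AAG", 7), rep("AAT", 3))
  ref <- Biostrings::DNAStringSet(paste(kmers, collapse = "A"))
  names(ref) <- "c"
  sites <- data.frame(chrom = "c", pos = seq(2, by = 4, length.out = 10),
                      strand = "+")
  ctx <- extract_contexts(sites, ref, flank = 1)
  bg <- c(A = 0, C = 0, G = 2, T = 8)
  enr <- position_enrichment(ctx, bg)
  cell <- enr[enr$position == 1 & enr$base == "G", ]
  # swapped: background row as observed (2 G of 10), observed as background
  kmers2 <- c(rep("AAG", 2), rep("AAT", 8))
  ref2 <- Biostrings::DNAStringSet(paste(kmers2, collapse = "A"))
  names(ref2) <- "c"
  ctx2 <- extract_contexts(sites, ref2, flank = 1)
  enr2 <- position_enrichment(ctx2, c(A = 0, C = 0, G = 7, T = 3))
  cell2 <- enr2[enr2$position == 1 & enr2$base == "G", ]
  expect_equal(cell2$odds_ratio, 1 / cell$odds_ratio, tolerance = 1e-12)
  expect_equal(cell2$p, cell$p, tolerance = 1e-12)
})

test_that("planted motif directions are recovered at 500 sites", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 400000L, n_genes = 60L,
                    n_sites = 500L, n_differential = 0L, n_cis = 0L,
                    n_samples_per_group = 3L)
  gr <- generate_reference(cfg)
  planted <- plant_editing_sites(gr$reference, gr$models, cfg)
  st <- planted$truth$site_table
  ctx <- extract_contexts(st[, c("chrom", "pos", "strand")],
                          planted$reference)
  enr <- position_enrichment(ctx, reference_base_counts(planted$reference))
  m1 <- enr[enr$position == -1 & enr$base == "G", ]
  p1 <- enr[enr$position == 1 & enr$base == "G", ]
  expect_lt(m1$odds_ratio, 1); expect_lt(m1$p, 0.05)
  expect_equal(m1$direction, "depleted")
  expect_gt(p1$odds_ratio, 1); expect_lt(p1$p, 0.05)
  expect_equal(p1$direction, "enriched")
})
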