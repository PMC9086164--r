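test_that("editing level is ed/(ref+ed) with a coverage-defined missing state", {
  expect_equal(compute_editing_level(90, 10, 10), 0.10)
  expect_equal(compute_editing_level(99, 1, 10), 0.01)   # exactly at 1%
  expect_true(is.na(compute_editing_level(3, 1, 10)))
  expect_equal(compute_editing_level(c(90, 3), c(10, 1), 10),
               c(0.10, NA))
  expect_error(compute_editing_level(-1, 5), "non-negative")
})

test_that("canonicalization policy covers all substitutions and strands", {
  subs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  subs <- subs[subs$ref != subs$alt, ]
  for (gs in list(NULL, "+", "-")) {
    v <- data.frame(chrom = "chr1", pos = seq_len(nrow(subs)),
                    ref = subs$ref, alt = subs$alt, stringsAsFactors = FALSE)
    hint <- if (is.null(gs)) NULL else rep(gs, nrow(v))
    out <- canonicalize_variants(v, strand_hint = hint)
    is_ag <- subs$ref == "A" & subs$alt == "G"
    is_tc <- subs$ref == "T" & subs$alt == "C"
    expected_accept <- if (is.null(gs)) is_ag | is_tc
      else if (gs == "+") is_ag else is_tc
    expect_equal(sort(out$index), which(expected_accept))
    # rejected non-A-to-G substitutions carry the right reason
    rej <- out$rejected
    expect_true(all(rej$reason[!(rej$ref == "A" & rej$alt == "G") &
                               !(rej$ref == "T" & rej$alt == "C")] ==
                      "not A-to-G under either strand"))
    if (!is.null(gs)) {
      anti <- if (gs == "+") is_tc else is_ag
      expect_true(all(rej$reason[paste(rej$ref, rej$alt) %in%
                                   paste(subs$ref, subs$alt)[anti]] ==
                        "antisense A-to-G within a gene"))
    }
  }
})

test_that("gene strand wins and allow_antisense rescues antisense calls", {
  toy <- toy_genome()                     # both toy genes are '+'
  v <- data.frame(chrom = "t1", pos = c(35L, 100L), ref = c("T", "A"),
                  alt = c("C", "G"), stringsAsFactors = FALSE)
  out <- canonicalize_variants(v, models = toy$models)
  expect_equal(out$index, 2L)             # T>C inside a '+' gene is antisense
  expect_equal(out$rejected$reason, "antisense A-to-G within a gene")
  out2 <- canonicalize_variants(v, models = toy$models, allow_antisense = TRUE)
  expect_equal(out2$index, c(1L, 2L))
  expect_equal(out2$sites$strand, c("-", "+"))
  expect_error(canonicalize_variants(
    data.frame(chrom = "t1", pos = 1L, ref = "AT", alt = "G")), "single")
})

test_that("canonicalization is an involution through the genomic representation", {
  v <- data.frame(chrom = "chr9", pos = c(10L, 20L, 30L),
                  ref = c("A", "T", "T"), alt = c("G", "C", "C"),
                  stringsAsFactors = FALSE)
  c1 <- canonicalize_variants(v)$sites
  c2 <- canonicalize_variants(genomic_representation(c1))$sites
  expect_identical(c1, c2)
})

test_that("the high-confidence filter applies threshold-or-known retention", {
  lv <- rbind(c(0.02, 0.015, 0.0, NA),    # retained: 2 samples >= 1%
              c(0.02, 0.005, 0.0, 0.0),   # removed: only 1 sample >= 1%
              c(0.005, 0.005, NA, NA))    # retained only if known
  cm <- counts_from_levels(lv, coverage = 1000L)
  lev <- editing_levels(cm, min_coverage = 10)
  known <- data.frame(chrom = "chr1", pos = 300L, strand = "+",
                      stringsAsFactors = FALSE)
  out <- filter_high_confidence(lev, known)
  expect_equal(out$log$branch, c("threshold", "removed", "known"))
  expect_equal(nrow(out$levels$sites), 2)
  no_known <- filter_high_confidence(lev, NULL)
  expect_equal(no_known$log$retained, c(TRUE, FALSE, FALSE))
})

test_that("filter decisions match an exhaustive oracle on small matrices", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:5, 1); s <- sample(1:5, 1)
    lv <- matrix(sample(c(NA, 0, 0.005, 0.01, 0.02, 0.3), n * s, TRUE), n, s)
    cm <- counts_from_levels(lv, coverage = 1000L)
    lev <- editing_levels(cm, min_coverage = 10)
    is_known <- runif(n) < 0.3
    known <- if (any(is_known))
      data.frame(chrom = "chr1", pos = which(is_known) * 100L,
                 strand = "+", stringsAsFactors = FALSE) else NULL
    ml <- sample(c(0.01, 0.05), 1); ms <- sample(1:3, 1)
    got <- filter_high_confidence(lev, known, min_level = ml,
                                  min_samples = ms)$log$retained
    want <- vapply(seq_len(n), function(i)
      oracle_filter_decision(lev$levels[i, ], is_known[i], ml, ms),
      logical(1))
    expect_equal(got, want)
  }
})

test_that("filter is monotone in its thresholds and in the known table", {
  set.seed(7)
  lv <- matrix(runif(40 * 6, 0, 0.08), 40, 6)
  cm <- counts_from_levels(lv, coverage = 1000L)
  lev <- editing_levels(cm)
  n_ret <- function(ml, ms, known = NULL)
    nrow(filter_high_confidence(lev, known, ml, ms)$levels$sites)
  for (ml in c(0.005, 0.01, 0.02, 0.05))
    expect_gte(n_ret(ml, 2), n_ret(ml, 3))
  for (ms in 1:4)
    expect_gte(n_ret(0.01, ms), n_ret(0.02, ms))
  known1 <- data.frame(chrom = "chr1", pos = c(100L, 300L), strand = "+")
  known2 <- rbind(known1, data.frame(chrom = "chr1", pos = 500L, strand = "+"))
  expect_gte(n_ret(0.05, 3, known2), n_ret(0.05, 3, known1))
  expect_gte(n_ret(0.05, 3, known1), n_ret(0.05, 3, NULL))
})

test_that("per-group accounting partitions retained sites exactly", {
  sim <- small_sim()
  lev <- editing_levels(sim$counts)
  filt <- filter_high_confidence(lev, NULL)
  acct <- group_site_accounting(filt$levels, sim$metadata)
  expect_equal(sum(acct$venn), nrow(filt$levels$sites))
  expect_named(acct$venn, c("case_exclusive", "control_exclusive",
                            "shared", "neither"))
  expect_error(group_site_accounting(filt$levels,
                                     data.frame(sample = "x", group = "only")),
               "two groups")
})

test_that("case-only edited sites are detected as case-exclusive at depth", {
  ns <- 6
  lv <- rbind(matrix(c(rep(0.2, 10 * ns), rep(0, 10 * ns)), 10, 2 * ns),
              matrix(0.15, 5, 2 * ns))
  colnames(lv) <- c(sprintf("case_%02d", 1:ns), sprintf("control_%02d", 1:ns))
  cm <- counts_from_levels(lv, coverage = 500L)
  md <- data.frame(sample = colnames(lv),
                   group = rep(c("case", "control"), each = ns))
  lev <- editing_levels(cm)
  acct <- group_site_accounting(filter_high_confidence(lev, NULL)$levels, md)
  expect_equal(unname(acct$venn["case_exclusive"]), 10)
  expect_equal(unname(acct$venn["shared"]), 5)
  expect_equal(unname(acct$venn["control_exclusive"]), 0)
})

test_that("levels are in [0,1] and missingness follows the coverage floor", {
  sim <- small_sim()
  lev <- editing_levels(sim$counts, min_coverage = 10)
  cov <- sim$counts$ref_counts + sim$counts$ed_counts
  expect_identical(is.na(lev$levels), cov < 10)
  vals <- lev$levels[!is.na(lev$levels)]
  expect_true(all(vals >= 0 & vals <= 1))
})
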