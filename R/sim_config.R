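#' Configuration for the synthetic editing dataset generator
#'
#' Bundles every knob of the generator into a validated list. Defaults mirror
#' the two-group postmortem-brain study design the package targets (12 vs 12
#' samples) at desk scale (2 chromosomes x 1 Mb, 300 genes, 3000 sites, 40
#' differential sites, 6 cis-coupled sites).
#'
#' @param seed Integer seed; every random draw in the generator derives from it.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Number of non-overlapping gene models to place.
#' @param n_sites Number of editing sites to plant (strand-adjusted reference A).
#' @param n_differential Number of planted sites with a group effect.
#' @param n_cis Number of planted sites whose host-gene expression is coupled
#'   to the site's editing level. Disjoint from the differential set.
#' @param n_samples_per_group Samples per group ("case" and "control").
#' @param coverage_mean,coverage_dispersion Negative-binomial read coverage per
#'   site-sample cell: mean and size (smaller size = more overdispersion).
#' @param editing_alpha,editing_beta Beta prior of the baseline mean editing
#'   level across sites.
#' @param level_concentration Concentration of the per-sample Beta around the
#'   group mean level (larger = less sample-to-sample noise).
#' @param differential_shift Additive shift of the case-group mean editing
#'   level at differential sites, clamped to \[0, 1\]. Negative = lower in case.
#' @param cis_slope Coupling of host-gene log-expression to the editing level
#'   at cis sites (sign drawn per site).
#' @param expr_mean_log,expr_sd_log Lognormal parameters of baseline gene
#'   expression means.
#' @param expr_dispersion Negative-binomial size for gene counts.
#' @param motif_g_minus1_prob,motif_g_plus1_prob Probability that the
#'   strand-adjusted base immediately 5' (-1) / 3' (+1) of a planted site is G.
#' @param known_fraction Fraction of planted sites listed in the known-site
#'   catalogue.
#' @param decoy_fraction Fraction of the known-site table made of decoy
#'   (non-planted) positions.
#' @param noncoding_prob Probability a generated gene model is non-coding.
#'
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1000000L,
                       n_genes = 300L,
                       n_sites = 3000L,
                       n_differential = 40L,
                       n_cis = 6L,
                       n_samples_per_group = 12L,
                       coverage_mean = 50,
                       coverage_dispersion = 10,
                       editing_alpha = 1.5,
                       editing_beta = 6,
                       level_concentration = 30,
                       differential_shift = -0.15,
                       cis_slope = 3,
                       expr_mean_log = log(200),
                       expr_sd_log = 1,
                       expr_dispersion = 20,
                       motif_g_minus1_prob = 0.05,
                       motif_g_plus1_prob = 0.6,
                       known_fraction = 0.8,
                       decoy_fraction = 0.1,
                       noncoding_prob = 0.15) {
  config <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    n_sites = as.integer(n_sites), n_differential = as.integer(n_differential),
    n_cis = as.integer(n_cis),
    n_samples_per_group = as.integer(n_samples_per_group),
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    editing_alpha = editing_alpha, editing_beta = editing_beta,
    level_concentration = level_concentration,
    differential_shift = differential_shift, cis_slope = cis_slope,
    expr_mean_log = expr_mean_log, expr_sd_log = expr_sd_log,
    expr_dispersion = expr_dispersion,
    motif_g_minus1_prob = motif_g_minus1_prob,
    motif_g_plus1_prob = motif_g_plus1_prob,
    known_fraction = known_fraction, decoy_fraction = decoy_fraction,
    noncoding_prob = noncoding_prob
  )
  class(config) <- "SimConfig"
  validate_sim_config(config)
  config
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with(config, {
    if (n_chroms < 1L || chrom_length < 1000L)
      stop("need at least one chromosome of >= 1 kb")
    if (n_genes < 0L || n_sites < 0L)
      stop("n_genes and n_sites must be non-negative")
    if (n_differential + n_cis > n_sites)
      stop("n_differential + n_cis must not exceed n_sites")
    if (n_samples_per_group < 1L)
      stop("need at least one sample per group")
    if (coverage_mean <= 0 || coverage_dispersion <= 0)
      stop("coverage parameters must be positive")
    if (editing_alpha <= 0 || editing_beta <= 0 || level_concentration <= 0)
      stop("Beta parameters must be positive")
    if (abs(differential_shift) >= 1)
      stop("differential_shift must lie in (-1, 1)")
    probs <- c(motif_g_minus1_prob, motif_g_plus1_prob, known_fraction,
               decoy_fraction, noncoding_prob)
    if (any(probs < 0 | probs > 1))
      stop("probabilities must lie in [0, 1]")
  })
  invisible(config)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$n_chroms, "chrom x", x$chrom_length, "bp,",
      x$n_genes, "genes,", x$n_sites, "sites (",
      x$n_differential, "differential,", x$n_cis, "cis ),",
      2L * x$n_samples_per_group, "samples, seed", x$seed, "\n")
  invisible(x)
}
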