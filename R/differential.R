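## Differential editing between groups: per-site Kruskal-Wallis tests, BH
## adjustment, direction calls, and PCA over editing levels.

#' Kruskal-Wallis test on grouped values
#'
#' Rank-based k-sample test with average ranks for ties and the standard tie
#' correction; p from the chi-square upper tail with k-1 df. Missing values
#' are excluded. When all retained values are identical, H = 0 and p = 1.
#'
#' @param values Numeric vector (may contain NA).
#' @param groups Group labels, same length.
#' @return Named vector c(H, p).
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values)
  x <- values[ok]; g <- droplevels(factor(groups[ok]))
  if (nlevels(g) < 2) stop("need at least two groups with defined values")
  if (length(unique(x)) == 1) return(c(H = 0, p = 1))
  kt <- kruskal.test(x, g)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Per-site differential editing scan
#'
#' Runs the Kruskal-Wallis test per site on defined editing levels, skipping
#' sites with fewer than `min_per_group` defined values in any group.
#' P-values are BH-adjusted across tested sites; the significance rule is raw
#' p < alpha by default (`use_fdr = TRUE` switches to adjusted p). Direction
#' is the sign of (case mean - control mean) among significant sites.
#'
#' @param levels An `EditingLevelMatrix` (retained sites).
#' @param metadata data.frame sample, group (two groups).
#' @param alpha Significance level (default 0.05).
#' @param min_per_group Minimum defined values per group (default 3).
#' @param use_fdr Use BH-adjusted p for the significance call.
#' @param case_group Which group is "case" for direction naming; defaults to
#'   "case" if present, else the alphabetically first group.
#' @return list with `results` (per tested site: group n/mean/median, H, p,
#'   padj, significant, direction), `skipped` (site key + reason), and
#'   `significant` (the significant subset of `results`).
#' @export
differential_scan <- function(levels, metadata, alpha = 0.05,
                              min_per_group = 3L, use_fdr = FALSE,
                              case_group = NULL) {
  stopifnot(inherits(levels, "EditingLevelMatrix"))
  groups <- sort(unique(metadata$group))
  if (length(groups) != 2) stop("exactly two groups required")
  if (is.null(case_group))
    case_group <- if ("case" %in% groups) "case" else groups[1]
  ctrl_group <- setdiff(groups, case_group)
  gvec <- metadata$group[match(levels$samples, metadata$sample)]
  keys <- site_key(levels$sites)

  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(levels$sites))) {
    x <- levels$levels[i, ]
    n_case <- sum(!is.na(x[gvec == case_group]))
    n_ctrl <- sum(!is.na(x[gvec == ctrl_group]))
    if (n_case < min_per_group || n_ctrl < min_per_group) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        site = keys[i],
        reason = sprintf("fewer than %d defined values in a group",
                         min_per_group), stringsAsFactors = FALSE)
      next
    }
    kw <- kruskal_wallis(x, gvec)
    rows[[length(rows) + 1L]] <- data.frame(
      site = keys[i], chrom = levels$sites$chrom[i],
      pos = levels$sites$pos[i], strand = levels$sites$strand[i],
      n_case = n_case, n_control = n_ctrl,
      mean_case = mean(x[gvec == case_group], na.rm = TRUE),
      mean_control = mean(x[gvec == ctrl_group], na.rm = TRUE),
      median_case = median(x[gvec == case_group], na.rm = TRUE),
      median_control = median(x[gvec == ctrl_group], na.rm = TRUE),
      H = kw[["H"]], p = kw[["p"]], stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(site = character(0), reason = character(0))
  if (is.null(results))
    return(list(results = data.frame(), skipped = skipped,
                significant = data.frame()))
  results$padj <- p.adjust(results$p, method = "BH")
  results$significant <- if (use_fdr) results$padj < alpha else results$p < alpha
  delta <- results$mean_case - results$mean_control
  results$direction <- ifelse(!results$significant, "none",
                              ifelse(delta > 0, "up_in_case", "down_in_case"))
  list(results = results, skipped = skipped,
       significant = results[results$significant, , drop = FALSE])
}

#' PCA of samples over editing levels
#'
#' Sites with more than `max_missing` missing fraction are dropped; remaining
#' missing cells are imputed with the site mean; sites are centered (scaling
#' optional); samples are projected by eigendecomposition of their covariance.
#' Sign convention: within each PC the loading of largest magnitude is made
#' positive, so scores are reproducible run to run.
#'
#' @param levels An `EditingLevelMatrix`.
#' @param site_subset Optional site keys (`chrom:pos:strand`) or row indices.
#' @param max_missing Maximum tolerated per-site missing fraction.
#' @param scale. Scale sites to unit variance.
#' @return list of class `PcaResult`: `scores` (samples x PCs), `loadings`
#'   (sites x PCs), `var_pct` (percent variance per PC, sums to 100).
#' @export
pca_editing <- function(levels, site_subset = NULL, max_missing = 0.5,
                        scale. = FALSE) {
  stopifnot(inherits(levels, "EditingLevelMatrix"))
  X <- levels$levels
  if (!is.null(site_subset)) {
    idx <- if (is.character(site_subset))
      match(site_subset, site_key(levels$sites)) else site_subset
    if (anyNA(idx)) stop("site_subset contains unknown sites")
    X <- X[idx, , drop = FALSE]
  }
  miss <- rowMeans(is.na(X))
  X <- X[miss <= max_missing, , drop = FALSE]
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("need at least 2 sites and 2 samples after missing-value handling")
  for (i in which(rowSums(is.na(X)) > 0))
    X[i, is.na(X[i, ])] <- mean(X[i, ], na.rm = TRUE)
  if (scale.) X <- X[apply(X, 1, sd) > 0, , drop = FALSE]
  M <- t(X)                               # samples x sites
  if (sum(apply(M, 2, sd) > 0) == 0)
    stop("degenerate input: all sites have zero variance")
  pc <- prcomp(M, center = TRUE, scale. = scale.)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation, var_pct = var_pct),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PcaResult:", nrow(x$scores), "samples;",
      "PC1", sprintf("%.2f%%", x$var_pct[1]),
      if (length(x$var_pct) > 1) paste("PC2", sprintf("%.2f%%", x$var_pct[2])),
      "\n")
  invisible(x)
}
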