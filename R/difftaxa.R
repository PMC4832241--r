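#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact null distribution when the smaller group has at most 10 values and
#' the pooled values are tie-free; otherwise the normal approximation with
#' midranks, tie-corrected variance and continuity correction.
#'
#' @param a,b numeric vectors (non-empty).
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && min(length(a), length(b)) <= 10
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
  min(1, p)
}

#' Two-sided Fisher exact p-value for a prevalence contrast
#'
#' Tests the 2x2 presence/absence table of an OTU between two groups by
#' summing hypergeometric probabilities no greater than that of the observed
#' table.
#'
#' @param k_a,n_a present count and group size of the first group.
#' @param k_b,n_b present count and group size of the second group.
#' @return two-sided p-value.
#' @export
fisher_prevalence <- function(k_a, n_a, k_b, n_b) {
  if (n_a <= 0 || n_b <= 0) stop("group sizes must be positive")
  stopifnot(k_a >= 0, k_a <= n_a, k_b >= 0, k_b <= n_b)
  tab <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), nrow = 2)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Screen OTUs for abundance and prevalence differences within one site
#'
#' For every OTU detected in the site, compares relative abundances between
#' conditions with the Wilcoxon rank-sum test and prevalences (fraction of
#' samples with count > 0) with Fisher's exact test. An OTU is flagged when
#' either raw p-value falls below `alpha`; Benjamini-Hochberg adjusted
#' p-values are reported alongside but do not drive the flag.
#'
#' @param table an [otu_table()] (rarefied counts recommended so prevalence
#'   is depth-comparable).
#' @param meta a [sample_metadata()].
#' @param site `"tongue"` or `"saliva"`.
#' @param alpha significance level for flagging (default 0.05).
#' @return data.frame with one row per tested OTU: mean relative abundance
#'   and prevalence per condition, abundance and prevalence p- and q-values,
#'   direction, and `flagged`.
#' @export
differential_otus <- function(table, meta, site, alpha = 0.05) {
  stopifnot(inherits(table, "otu_table"), site %in% SITES)
  validate_metadata(table, meta)
  meta <- meta[meta$sample_id %in% colnames(table$counts), , drop = FALSE]
  sel <- meta[meta$site == site, , drop = FALSE]
  if (!all(CONDITIONS %in% sel$condition))
    stop("site must have samples in both conditions")
  ab <- relative_abundance(table)[, sel$sample_id, drop = FALSE]
  cnt <- table$counts[, sel$sample_id, drop = FALSE]
  is_h <- sel$condition == "healthy"
  n_h <- sum(is_h); n_d <- sum(!is_h)

  present <- rowSums(cnt) > 0
  if (any(!present))
    message(sprintf("%d OTU(s) absent in all %s samples; excluded",
                    sum(!present), site))
  ids <- rownames(cnt)[present]
  res <- lapply(ids, function(id) {
    x_h <- ab[id, is_h]; x_d <- ab[id, !is_h]
    k_h <- sum(cnt[id, is_h] > 0); k_d <- sum(cnt[id, !is_h] > 0)
    mean_h <- mean(x_h); mean_d <- mean(x_d)
    data.frame(otu_id = id, site = site,
               mean_ab_healthy = mean_h, mean_ab_halitosis = mean_d,
               prev_healthy = k_h / n_h, prev_halitosis = k_d / n_d,
               p_abundance = wilcoxon_rank_sum(x_h, x_d),
               p_prevalence = fisher_prevalence(k_h, n_h, k_d, n_d),
               direction = if (mean_d >= mean_h) "halitosis-enriched"
                           else "healthy-enriched",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_abundance <- stats::p.adjust(out$p_abundance, method = "BH")
  out$q_prevalence <- stats::p.adjust(out$p_prevalence, method = "BH")
  out$flagged <- out$p_abundance < alpha | out$p_prevalence < alpha
  out
}

#' First two principal-component scores of an abundance matrix
#'
#' PCA of the sample-by-OTU matrix after centering each OTU; typically run
#' on the OTUs flagged by [differential_otus()]. Deterministic up to the
#' sign of each axis.
#'
#' @param ab relative-abundance matrix (OTUs x samples) with >= 2 OTUs and
#'   >= 2 samples.
#' @return samples x 2 numeric score matrix (columns PC1, PC2).
#' @export
pca_scores <- function(ab) {
  ab <- as.matrix(ab)
  if (nrow(ab) < 2 || ncol(ab) < 2)
    stop("need at least 2 OTUs and 2 samples")
  pc <- stats::prcomp(t(ab), center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] <= 1e-12 * pc$sdev[1])
    stop("fewer than 2 non-degenerate dimensions")
  scores <- pc$x[, 1:2, drop = FALSE]
  colnames(scores) <- c("PC1", "PC2")
  scores
}
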