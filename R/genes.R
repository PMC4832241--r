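#' Exact two-library differential count test
#'
#' Conditional binomial test for one gene's counts in two pooled libraries
#' without replicates: given `n = k1 + k2`, under the null of equal relative
#' abundance `k1 ~ Binomial(n, N1 / (N1 + N2))`. The two-sided p-value sums
#' the probabilities of all outcomes no more likely than the observed one.
#'
#' @param k1,k2 gene counts in the two libraries.
#' @param N1,N2 total library sizes.
#' @return two-sided p-value in (0, 1].
#' @export
two_library_test <- function(k1, N1, k2, N2) {
  stopifnot(N1 > 0, N2 > 0, k1 >= 0, k2 >= 0)
  n <- k1 + k2
  if (n == 0) stop("k1 = k2 = 0: gene untestable")
  p0 <- N1 / (N1 + N2)
  probs <- stats::dbinom(0:n, n, p0)
  obs <- probs[k1 + 1L]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Pseudocount-adjusted relative abundance fold ratio
#'
#' `((k1 + pc) / N1) / ((k2 + pc) / N2)`. With the halitosis library first
#' this is the halitosis/healthy ratio used by the differential-gene and
#' pathway rules; the pseudocount keeps zero counts finite.
#'
#' @param k1,N1 numerator count and library size.
#' @param k2,N2 denominator count and library size.
#' @param pseudocount added to both counts (default 0.5).
#' @return positive fold ratio.
#' @export
fold_ratio <- function(k1, N1, k2, N2, pseudocount = 0.5) {
  stopifnot(N1 > 0, N2 > 0)
  ((k1 + pseudocount) / N1) / ((k2 + pseudocount) / N2)
}

#' Directional differential genes between two pooled libraries
#'
#' Flags genes whose halitosis/healthy fold ratio exceeds `fold_min` (or
#' falls below `1/fold_min`) with an exact two-library p-value below
#' `p_max`, and partitions them by direction. Genes with zero counts in
#' both libraries are skipped with a message.
#'
#' @param gt a [gene_table()].
#' @param fold_min fold-change threshold (default 5).
#' @param p_max p-value threshold (default 0.001).
#' @param pseudocount for [fold_ratio()].
#' @return list with `results` (per-gene data.frame), `halitosis_enriched`,
#'   `healthy_enriched` (gene-id vectors) and `summary`
#'   (see [directional_summary()]).
#' @export
differential_genes <- function(gt, fold_min = 5, p_max = 0.001,
                               pseudocount = 0.5) {
  stopifnot(inherits(gt, "gene_table"))
  k_h <- gt$counts[, "healthy"]
  k_d <- gt$counts[, "halitosis"]
  N_h <- gt$library_sizes[["healthy"]]
  N_d <- gt$library_sizes[["halitosis"]]
  testable <- (k_h + k_d) > 0
  if (any(!testable))
    message(sprintf("%d gene(s) with zero counts in both libraries skipped",
                    sum(!testable)))
  idx <- which(testable)
  fold <- fold_ratio(k_d[idx], N_d, k_h[idx], N_h, pseudocount = pseudocount)
  pval <- vapply(idx, function(i) two_library_test(k_d[i], N_d, k_h[i], N_h),
                 numeric(1))
  res <- data.frame(gene_id = rownames(gt$counts)[idx],
                    count_healthy = k_h[idx], count_halitosis = k_d[idx],
                    relab_healthy = k_h[idx] / N_h,
                    relab_halitosis = k_d[idx] / N_d,
                    fold = fold, p_value = pval,
                    row.names = NULL, stringsAsFactors = FALSE)
  res$direction <- ifelse(res$fold >= 1, "halitosis", "healthy")
  flag_up <- res$fold > fold_min & res$p_value < p_max
  flag_dn <- res$fold < 1 / fold_min & res$p_value < p_max
  up <- res$gene_id[flag_up]
  dn <- res$gene_id[flag_dn]
  list(results = res,
       halitosis_enriched = up,
       healthy_enriched = dn,
       summary = directional_summary(length(up), length(dn)))
}

#' Summarize a directional differential-gene split
#'
#' Reconstructs the total number of differential genes and the percentage
#' more abundant in each group from the two directional counts.
#'
#' @param n_halitosis genes more abundant in the halitosis library.
#' @param n_healthy genes more abundant in the healthy library.
#' @return list with `total`, `pct_halitosis`, `pct_healthy` (percentages).
#' @export
directional_summary <- function(n_halitosis, n_healthy) {
  total <- n_halitosis + n_healthy
  list(total = total,
       pct_halitosis = if (total > 0) 100 * n_halitosis / total else NA_real_,
       pct_healthy = if (total > 0) 100 * n_healthy / total else NA_real_)
}

#' Hypergeometric KO-category enrichment
#'
#' For each KO category with `m` members in the annotated population of
#' which `k` fall in the differential set (size `n`, population size `M`),
#' computes the upper-tail hypergeometric probability `P(X >= k)`.
#'
#' @param diff_genes character vector of differential gene ids (subset of
#'   `population`).
#' @param annotations an [annotation_maps()] with a `ko` map.
#' @param population character vector of background gene ids (default: all
#'   genes with any KO annotation).
#' @return data.frame per category: `category`, `m`, `k`, `p_value`, sorted
#'   by p-value.
#' @export
ko_enrichment <- function(diff_genes, annotations, population = NULL) {
  stopifnot(inherits(annotations, "annotation_maps"))
  ko <- annotations$ko
  if (is.null(ko)) stop("no KO map in annotations")
  if (is.null(population)) population <- unique(ko$gene_id)
  if (!length(population)) stop("empty annotation population")
  if (!all(diff_genes %in% population))
    stop("diff_genes must be a subset of the population")
  ko <- ko[ko$gene_id %in% population, , drop = FALSE]
  M <- length(population)
  n <- length(unique(diff_genes))
  cats <- unique(ko$category)
  rows <- lapply(cats, function(cat) {
    members <- unique(ko$gene_id[ko$category == cat])
    m <- length(members)
    k <- length(intersect(members, diff_genes))
    p <- stats::phyper(k - 1, m, M - m, n, lower.tail = FALSE)
    data.frame(category = cat, m = m, k = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$category), , drop = FALSE]
}

#' Hydrogen-sulphide pathway gene-family report
#'
#' For each gene family of the H2S metabolic map and each site, sums the
#' member genes' counts per library, forms the pseudocount-adjusted
#' halitosis/healthy relative-abundance ratio, and calls the family `up`
#' when the ratio exceeds `fold_min`, `down` below `1/fold_min`, `flat`
#' otherwise, or `absent` when the family has no member genes.
#'
#' @param tables named list of [gene_table()]s per site (`tongue`,
#'   `saliva`).
#' @param annotations an [annotation_maps()] with a `family` map.
#' @param fold_min fold threshold for calling a family (default 2).
#' @param pseudocount for the family-level ratio.
#' @return data.frame: `family`, `site`, `fold`, `status`.
#' @export
h2s_pathway_report <- function(tables, annotations, fold_min = 2,
                               pseudocount = 0.5) {
  stopifnot(inherits(annotations, "annotation_maps"))
  fam_map <- annotations$family
  if (is.null(fam_map)) stop("no pathway-family map in annotations")
  bad <- setdiff(unique(fam_map$family), h2s_families())
  if (length(bad)) stop("unknown family in map: ", paste(bad, collapse = ", "))
  rows <- list()
  for (site in names(tables)) {
    gt <- tables[[site]]
    stopifnot(inherits(gt, "gene_table"))
    N_h <- gt$library_sizes[["healthy"]]
    N_d <- gt$library_sizes[["halitosis"]]
    for (fam in h2s_families()) {
      members <- intersect(fam_map$gene_id[fam_map$family == fam],
                           rownames(gt$counts))
      if (!length(members)) {
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, site = site, fold = NA_real_, status = "absent",
          stringsAsFactors = FALSE)
        next
      }
      k_h <- sum(gt$counts[members, "healthy"])
      k_d <- sum(gt$counts[members, "halitosis"])
      fold <- fold_ratio(k_d, N_d, k_h, N_h, pseudocount = pseudocount)
      status <- if (fold > fold_min) "up"
                else if (fold < 1 / fold_min) "down"
                else "flat"
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, site = site, fold = fold, status = status,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Render an H2S pathway report as a compact text table
#'
#' One row per family with an up/down/flat glyph per site, tongue outside
#' and saliva inside brackets.
#'
#' @param report result of [h2s_pathway_report()].
#' @return character vector of lines (also printed invisibly).
#' @export
format_h2s_report <- function(report) {
  glyph <- c(up = "↑", down = "↓", flat = "-", absent = ".")
  fams <- unique(report$family)
  lines <- vapply(fams, function(fam) {
    tg <- report[report$family == fam & report$site == "tongue", ]
    sa <- report[report$family == fam & report$site == "saliva", ]
    g1 <- if (nrow(tg)) glyph[[tg$status]] else "?"
    g2 <- if (nrow(sa)) glyph[[sa$status]] else "?"
    sprintf("%-6s %s [%s]", fam, g1, g2)
  }, character(1))
  unname(lines)
}
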