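#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement so every retained
#' column sums exactly to `depth`; samples with fewer reads than `depth` are
#' dropped with a warning. A single subsample per sample is drawn, matching
#' the even-depth comparison of the diversity analysis.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample (default 7180, the even depth used
#'   for the richness comparison).
#' @param seed optional integer seed for reproducible subsampling.
#' @return a rarefied [otu_table()].
#' @export
rarefy <- function(table, depth = 7180, seed = NULL) {
  stopifnot(inherits(table, "otu_table"), depth > 0)
  run <- function() {
    m <- table$counts
    tot <- colSums(m)
    if (all(tot < depth))
      stop("rarefaction depth exceeds every sample's total")
    drop <- tot < depth
    if (any(drop))
      warning(sprintf("dropped %d sample(s) below depth %d: %s",
                      sum(drop), depth,
                      paste(colnames(m)[drop], collapse = ", ")))
    keep <- which(!drop)
    out <- matrix(0L, nrow(m), length(keep),
                  dimnames = list(rownames(m), colnames(m)[keep]))
    for (j in seq_along(keep)) {
      cnt <- m[, keep[j]]
      if (tot[keep[j]] == depth) {
        out[, j] <- cnt
      } else {
        reads <- rep.int(seq_along(cnt), cnt)
        pick <- sample(reads, depth)
        out[, j] <- tabulate(pick, nbins = length(cnt))
      }
    }
    otu_table(out, taxonomy = table$taxonomy)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Observed OTU richness of one sample
#' @param counts non-negative count vector.
#' @return integer number of OTUs with count > 0.
#' @export
observed_otus <- function(counts) {
  sum(counts > 0)
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + F1*(F1-1) / (2*(F2+1))` where `F1` and `F2` are the singleton
#' and doubleton counts. Always at least the observed richness.
#'
#' @param counts non-negative count vector for one sample.
#' @return numeric Chao1 estimate.
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all-zero sample: Chao1 undefined")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha diversity
#'
#' @param table an [otu_table()] (typically already rarefied).
#' @return data.frame with sample_id, observed_otus, chao1.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  m <- table$counts
  data.frame(sample_id = colnames(m),
             observed_otus = apply(m, 2L, observed_otus),
             chao1 = apply(m, 2L, chao1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Welch two-sample test for an alpha-diversity contrast
#'
#' Two-sided unequal-variance t-test. With zero variance in both groups the
#' p-value degenerates to 1 (equal means) or 0 (unequal means).
#'
#' @param values_a,values_b numeric vectors (>= 2 values each).
#' @return two-sided p-value.
#' @export
alpha_group_test <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0)
    return(if (mean(values_a) == mean(values_b)) 1 else 0)
  stats::t.test(values_a, values_b, var.equal = FALSE)$p.value
}

#' Normalized weighted UniFrac distance between two communities
#'
#' `D = sum_b l_b * |A_b - B_b| / sum_b l_b * (A_b + B_b)` where the sum runs
#' over branches of the rooted tree and `A_b`, `B_b` are the fractions of
#' each community descending from branch `b`. Bounded in [0,1]; 0 for
#' identical communities and 1 for phylogenetically disjoint ones.
#'
#' @param a,b named relative-abundance vectors over (a subset of) the tree's
#'   leaves, each summing to 1.
#' @param tree rooted `phylo` tree with branch lengths.
#' @return distance in [0,1].
#' @export
weighted_unifrac <- function(a, b, tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  for (v in list(a, b)) {
    if (is.null(names(v))) stop("abundance vectors must be named by OTU id")
    missing <- setdiff(names(v)[v > 0], tips)
    if (length(missing))
      stop("OTU absent from tree: ", paste(missing, collapse = ", "))
    if (abs(sum(v) - 1) > 1e-6) stop("abundances must sum to 1")
  }
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  accA <- accB <- numeric(n_node)
  accA[seq_len(n_tip)] <- ifelse(tips %in% names(a), a[tips], 0)
  accB[seq_len(n_tip)] <- ifelse(tips %in% names(b), b[tips], 0)
  tr <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    accA[par] <- accA[par] + accA[child]
    accB[par] <- accB[par] + accB[child]
  }
  childA <- accA[tr$edge[, 2L]]
  childB <- accB[tr$edge[, 2L]]
  num <- sum(tr$edge.length * abs(childA - childB))
  den <- sum(tr$edge.length * (childA + childB))
  if (den == 0) return(0)
  num / den
}

#' Pairwise weighted UniFrac distance matrix
#'
#' @param ab relative-abundance matrix (OTUs x samples), columns sum to 1.
#' @param tree rooted `phylo` tree covering the OTUs.
#' @return symmetric distance matrix with sample dimnames.
#' @export
unifrac_matrix <- function(ab, tree) {
  n <- ncol(ab)
  d <- matrix(0, n, n, dimnames = list(colnames(ab), colnames(ab)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- weighted_unifrac(ab[, i], ab[, j], tree)
    }
  }
  d
}

# Excoffier-style pseudo-F from squared distances for one grouping
.amova_f <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  k <- length(lev)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in lev) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  ms_among <- ss_among / (k - 1)
  ms_within <- ss_within / (n - k)
  if (ms_within == 0) return(Inf)
  ms_among / ms_within
}

#' Permutational analysis of molecular variance on a distance matrix
#'
#' Partitions the sum of squared pairwise distances into among- and
#' within-group components and assesses the pseudo-F statistic by random
#' relabelling of samples. The permutation p-value uses the add-one
#' estimator `(1 + #{F_perm >= F_obs}) / (n_perm + 1)`.
#'
#' @param dm symmetric distance matrix with sample dimnames.
#' @param grouping named character/factor mapping each sample to a group
#'   (>= 2 groups, each with >= 2 samples).
#' @param n_perm number of permutations.
#' @param seed optional seed.
#' @return list with `f` and `p_value`.
#' @export
amova <- function(dm, grouping, n_perm = 999, seed = NULL) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  samples <- rownames(dm)
  groups <- as.character(grouping[samples])
  if (anyNA(groups)) stop("grouping missing for some samples")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least two samples")
  d2 <- dm^2
  f_obs <- .amova_f(d2, groups)
  thr <- if (is.finite(f_obs)) f_obs - 1e-12 * max(1, abs(f_obs)) else Inf
  run <- function() {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (.amova_f(d2, sample(groups)) >= thr) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(f = f_obs, p_value = p)
}
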