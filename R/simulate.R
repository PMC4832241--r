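#' Build a simulation configuration
#'
#' Defines the study conditions emulated by the generator: ten subjects per
#' condition sampled at two oral sites (tongue coating, saliva) to a fixed
#' read depth, with a log-normal rank-abundance spectrum and optional planted
#' effects (extra richness in halitosis tongue coatings, fold-changes on
#' relative abundance, presence/absence shifts, correlated OTU pairs, and
#' gene-family fold changes for the pooled metagenomic libraries).
#'
#' Baseline OTU intensities are drawn once from a log-normal spectrum,
#' sorted in decreasing order and assigned to `OTU001..OTUn`, so low-numbered
#' OTUs are the abundant ones; planted effects can then target abundance
#' strata by id.
#'
#' @param n_subjects_per_condition subjects per group (study design: 10).
#' @param depth reads per sample (multinomial total).
#' @param n_otus number of baseline OTUs.
#' @param base_meanlog,base_sdlog log-normal parameters of the baseline
#'   rank-abundance spectrum.
#' @param subject_sdlog standard deviation of per-sample log-normal noise on
#'   OTU intensities.
#' @param richness_delta number of extra OTUs present only in halitosis
#'   tongue samples.
#' @param richness_relab typical relative abundance of each extra OTU.
#' @param differential_otus data.frame(otu_id, site, fold): multiplies the
#'   OTU's intensity by `fold` in halitosis samples of `site`.
#' @param prevalence_otus data.frame(otu_id, site, p_healthy, p_halitosis):
#'   per-sample presence probabilities in `site`.
#' @param correlated_pairs data.frame(site1, otu1, site2, otu2, rho): plants
#'   a shared latent log-normal factor so the Pearson correlation of the two
#'   members' relative abundances is approximately `rho` (subject-paired
#'   across sites).
#' @param gene list of gene-table settings: `n_genes`, `library_size`,
#'   `genes_per_family`, `n_ko`, `family_folds` (list per site of
#'   data.frame(family, fold)), `gene_folds` (list per site of
#'   data.frame(gene_id, fold)).
#' @param seed integer seed governing all randomness.
#' @return a validated `sim_config` list.
#' @export
simulate_config <- function(n_subjects_per_condition = 10,
                            depth = 10000,
                            n_otus = 200,
                            base_meanlog = 0,
                            base_sdlog = 2,
                            subject_sdlog = 0.7,
                            richness_delta = 0,
                            richness_relab = 5e-4,
                            differential_otus = NULL,
                            prevalence_otus = NULL,
                            correlated_pairs = NULL,
                            gene = list(),
                            seed = 1) {
  stopifnot(n_subjects_per_condition >= 2, depth > 0, n_otus >= 2,
            base_sdlog > 0, subject_sdlog > 0, richness_delta >= 0,
            richness_relab > 0)
  if (!is.null(differential_otus)) {
    stopifnot(all(c("otu_id", "site", "fold") %in% names(differential_otus)))
    if (any(differential_otus$fold <= 0)) stop("fold effects must be > 0")
    if (!all(differential_otus$site %in% SITES)) stop("bad site in differential_otus")
  }
  if (!is.null(prevalence_otus)) {
    stopifnot(all(c("otu_id", "site", "p_healthy", "p_halitosis") %in%
                    names(prevalence_otus)))
    pr <- c(prevalence_otus$p_healthy, prevalence_otus$p_halitosis)
    if (any(pr < 0 | pr > 1)) stop("presence probabilities must lie in [0,1]")
  }
  if (!is.null(correlated_pairs)) {
    stopifnot(all(c("site1", "otu1", "site2", "otu2", "rho") %in%
                    names(correlated_pairs)))
    if (any(abs(correlated_pairs$rho) >= 1)) stop("rho must lie in (-1,1)")
    if (!all(c(correlated_pairs$site1, correlated_pairs$site2) %in% SITES))
      stop("bad site in correlated_pairs")
  }
  gene_defaults <- list(n_genes = 20000, library_size = 1e6,
                        genes_per_family = 5, n_ko = 40,
                        family_folds = NULL, gene_folds = NULL)
  gene <- utils::modifyList(gene_defaults, gene)
  if (gene$n_genes < 17 * gene$genes_per_family)
    stop("n_genes too small for the pathway-family map")
  cfg <- list(n_subjects_per_condition = n_subjects_per_condition,
              depth = depth, n_otus = n_otus,
              base_meanlog = base_meanlog, base_sdlog = base_sdlog,
              subject_sdlog = subject_sdlog,
              richness_delta = richness_delta, richness_relab = richness_relab,
              differential_otus = differential_otus,
              prevalence_otus = prevalence_otus,
              correlated_pairs = correlated_pairs,
              gene = gene, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.sim_otu_ids <- function(n) sprintf("OTU%03d", seq_len(n))

# log-scale correlation giving Pearson correlation `rho` on the exp scale for
# a bivariate log-normal with common log-variance s2 (exact closed form)
.lognormal_rho_log <- function(rho, s2) {
  log(1 + rho * (exp(s2) - 1)) / s2
}

# Monte-Carlo calibration of the latent-factor loading for one correlated
# pair: finds the share a = lambda^2/s2 of log-variance carried by the
# shared factor so that the Pearson correlation of the two members'
# *relative* abundances (normalization noise included) hits |rho|.
# Tolerance |E[r] - rho| <= 0.05 for reachable targets; if compositional
# noise makes the target unreachable the maximum loading is used with a
# warning.
.calibrate_pair_lambda <- function(base, s2, otu1, otu2, rho,
                                   n_cal = 4000) {
  sdlog <- sqrt(s2)
  target <- abs(rho)
  z <- stats::rnorm(n_cal)
  e1 <- stats::rnorm(n_cal)
  e2 <- stats::rnorm(n_cal)
  rest_ids1 <- setdiff(names(base), otu1)
  rest_ids2 <- setdiff(names(base), otu2)
  rest1 <- colSums(base[rest_ids1] *
    exp(matrix(stats::rnorm(length(rest_ids1) * n_cal, 0, sdlog),
               length(rest_ids1), n_cal)))
  rest2 <- colSums(base[rest_ids2] *
    exp(matrix(stats::rnorm(length(rest_ids2) * n_cal, 0, sdlog),
               length(rest_ids2), n_cal)))
  # a <= 1: the shared factor takes a fraction a of the baseline
  # log-variance. a > 1: the shared factor replaces the residual entirely
  # and inflates the member's log-variance to a * s2 — needed when
  # compositional noise caps the reachable correlation below the target;
  # planting a strong correlation then also widens the pair's dispersion.
  r_of <- function(a) {
    resid <- sqrt(max(1 - a, 0))
    x1 <- base[[otu1]] * exp(sdlog * (sqrt(a) * z + resid * e1))
    x2 <- base[[otu2]] * exp(sdlog * (sqrt(a) * z + resid * e2))
    stats::cor(x1 / (x1 + rest1), x2 / (x2 + rest2))
  }
  grid <- c(seq(0, 0.95, by = 0.05), 0.99, 1.25, 1.5, 2, 3, 4, 6)
  r_grid <- cummax(vapply(grid, r_of, numeric(1)))
  if (max(r_grid) < target - 0.05) {
    warning(sprintf("correlation rho = %.2f for pair (%s, %s) unreachable; attenuated to %.2f",
                    rho, otu1, otu2, max(r_grid)))
    a <- grid[which.max(r_grid)]
  } else {
    a <- stats::approx(r_grid, grid, xout = min(target, max(r_grid)),
                       ties = "ordered")$y
  }
  sdlog * sqrt(a)
}

#' Simulate a two-condition, two-site OTU study
#'
#' Draws one tongue and one saliva sample per subject as
#' `multinomial(depth, p)` where `p` comes from subject-specific log-normal
#' intensities perturbed by the planted effects in the configuration.
#' Correlated pairs share a per-subject latent factor whose loading is
#' calibrated in closed form for the log-normal model. A random tree with
#' exponential branch lengths covers all OTUs. Identical seeds give
#' bit-identical outputs.
#'
#' @param config a [simulate_config()].
#' @return list with elements `table` ([otu_table()]), `metadata`
#'   ([sample_metadata()]), `tree` (ape phylo), `truth` (planted-effect
#'   ledger).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_study_impl(config))
}

.simulate_study_impl <- function(cfg) {
  n_s <- cfg$n_subjects_per_condition
  subjects <- c(sprintf("H%02d", seq_len(n_s)), sprintf("D%02d", seq_len(n_s)))
  condition_of <- setNames(rep(CONDITIONS, each = n_s), subjects)

  base_ids <- .sim_otu_ids(cfg$n_otus)
  extra_ids <- if (cfg$richness_delta > 0)
    sprintf("ROTU%03d", seq_len(cfg$richness_delta)) else character(0)
  all_ids <- c(base_ids, extra_ids)

  known <- function(df, cols) {
    ids <- unlist(df[cols], use.names = FALSE)
    bad <- setdiff(ids, all_ids)
    if (length(bad)) stop("config references unknown OTUs: ",
                          paste(unique(bad), collapse = ", "))
  }
  if (!is.null(cfg$differential_otus)) known(cfg$differential_otus, "otu_id")
  if (!is.null(cfg$prevalence_otus)) known(cfg$prevalence_otus, "otu_id")
  if (!is.null(cfg$correlated_pairs)) known(cfg$correlated_pairs, c("otu1", "otu2"))

  base <- sort(stats::rlnorm(cfg$n_otus, cfg$base_meanlog, cfg$base_sdlog),
               decreasing = TRUE)
  names(base) <- base_ids
  if (length(extra_ids)) {
    extra <- cfg$richness_relab * sum(base) *
      exp(stats::rnorm(length(extra_ids), 0, 0.5))
    names(extra) <- extra_ids
    base <- c(base, extra)
  }

  s2 <- cfg$subject_sdlog^2
  # latent factors: one standard normal per correlated pair per subject
  pairs <- cfg$correlated_pairs
  n_pairs <- if (is.null(pairs)) 0L else nrow(pairs)
  z <- if (n_pairs) matrix(stats::rnorm(n_pairs * length(subjects)),
                           n_pairs, length(subjects),
                           dimnames = list(NULL, subjects)) else NULL
  # loadings per (site, otu): possibly several pairs share a member
  loading_key <- function(site, otu) paste(site, otu, sep = ":")
  loadings <- list()
  if (n_pairs) {
    for (p in seq_len(n_pairs)) {
      lam <- .calibrate_pair_lambda(base, s2, pairs$otu1[p], pairs$otu2[p],
                                    pairs$rho[p])
      lam_m <- c(lam, sign(pairs$rho[p]) * lam)
      for (m in 1:2) {
        k <- loading_key(pairs[[paste0("site", m)]][p], pairs[[paste0("otu", m)]][p])
        loadings[[k]] <- rbind(loadings[[k]], c(pair = p, lambda = lam_m[m]))
      }
    }
  }

  sample_ids <- character(0)
  meta_rows <- list()
  counts <- matrix(0L, nrow = length(all_ids), ncol = 0,
                   dimnames = list(all_ids, NULL))

  for (subj in subjects) {
    cond <- condition_of[[subj]]
    for (site in SITES) {
      sid <- paste0(subj, "_", toupper(substr(site, 1, 1)))
      x <- base
      # site-restricted richness extras
      if (length(extra_ids) && !(cond == "halitosis" && site == "tongue"))
        x[extra_ids] <- 0
      # per-sample log-normal noise, with latent factors on pair members
      eps <- stats::rnorm(length(all_ids), 0, cfg$subject_sdlog)
      names(eps) <- all_ids
      if (n_pairs) {
        for (k in names(loadings)) {
          parts <- strsplit(k, ":", fixed = TRUE)[[1L]]
          if (parts[1L] != site) next
          ld <- loadings[[k]]
          lam2 <- sum(ld[, "lambda"]^2)
          shared <- sum(ld[, "lambda"] * z[ld[, "pair"], subj])
          if (nrow(ld) == 1L) {
            # calibrated single-pair loading; residual absorbs what is left
            # of the baseline log-variance (none if the loading exceeds it)
            eps[parts[2L]] <- shared + sqrt(max(s2 - lam2, 0)) * stats::rnorm(1)
          } else if (lam2 <= s2) {
            eps[parts[2L]] <- shared + sqrt(s2 - lam2) * stats::rnorm(1)
          } else {
            # one OTU in many pairs: rescale to keep the marginal variance
            # at s2; correlations attenuate
            raw <- shared + cfg$subject_sdlog * stats::rnorm(1)
            eps[parts[2L]] <- raw * cfg$subject_sdlog / sqrt(lam2 + s2)
          }
        }
      }
      x <- x * exp(eps)
      # planted fold effects on halitosis samples of the target site
      if (!is.null(cfg$differential_otus) && cond == "halitosis") {
        d <- cfg$differential_otus
        hit <- d$site == site
        if (any(hit)) x[d$otu_id[hit]] <- x[d$otu_id[hit]] * d$fold[hit]
      }
      # planted presence/absence
      if (!is.null(cfg$prevalence_otus)) {
        pv <- cfg$prevalence_otus
        hit <- which(pv$site == site)
        for (i in hit) {
          p_here <- if (cond == "healthy") pv$p_healthy[i] else pv$p_halitosis[i]
          if (stats::runif(1) > p_here) x[pv$otu_id[i]] <- 0
        }
      }
      if (sum(x) <= 0) stop("degenerate sample composition")
      cnt <- as.integer(stats::rmultinom(1, cfg$depth, x / sum(x)))
      counts <- cbind(counts, cnt)
      sample_ids <- c(sample_ids, sid)
      meta_rows[[sid]] <- data.frame(sample_id = sid, subject_id = subj,
                                     site = site, condition = cond,
                                     stringsAsFactors = FALSE)
    }
  }
  colnames(counts) <- sample_ids
  meta <- do.call(rbind, meta_rows)
  meta <- sample_metadata(meta$sample_id, meta$subject_id, meta$site,
                          meta$condition)

  tree <- ape::rtree(length(all_ids), tip.label = sample(all_ids),
                     br = function(n) stats::rexp(n, rate = 10))

  truth <- list(differential_otus = cfg$differential_otus,
                prevalence_otus = cfg$prevalence_otus,
                correlated_pairs = cfg$correlated_pairs,
                richness_otus = extra_ids)
  list(table = otu_table(counts), metadata = meta, tree = tree, truth = truth)
}

#' Simulate pooled two-library gene tables with annotations
#'
#' For each site, draws gene counts as `Poisson(library_size x relative
#' abundance)` per library, with the halitosis abundance equal to the healthy
#' abundance times any planted fold. The first block of genes carries the
#' hydrogen-sulphide pathway-family map; KO categories are assigned at
#' random. Planted family folds apply to all member genes of the family.
#'
#' @param config a [simulate_config()]; the `gene` element controls sizes and
#'   planted folds.
#' @return list with `tables` (per-site [gene_table()]), `annotations`
#'   ([annotation_maps()]), `truth` (planted fold ledger).
#' @export
simulate_gene_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, .simulate_genes_impl(config))
}

.simulate_genes_impl <- function(cfg) {
  g <- cfg$gene
  gene_ids <- sprintf("g%06d", seq_len(g$n_genes))
  fams <- h2s_families()
  fam_map <- data.frame(
    gene_id = gene_ids[seq_len(length(fams) * g$genes_per_family)],
    family = rep(fams, each = g$genes_per_family),
    stringsAsFactors = FALSE)
  ko_pool <- sprintf("K%02d", seq_len(g$n_ko))
  ko1 <- data.frame(gene_id = gene_ids, category = sample(ko_pool, g$n_genes,
                                                          replace = TRUE))
  second <- stats::runif(g$n_genes) < 0.1
  ko <- rbind(ko1, data.frame(gene_id = gene_ids[second],
                              category = sample(ko_pool, sum(second),
                                                replace = TRUE)))

  check_folds <- function(df, col) {
    if (is.null(df)) return(invisible(NULL))
    if (any(df$fold <= 0)) stop("planted gene folds must be > 0")
    bad <- setdiff(df[[col]], if (col == "family") fams else gene_ids)
    if (length(bad)) stop("unknown ", col, ": ", paste(bad, collapse = ", "))
  }

  N <- g$library_size
  if (length(N) == 1L) N <- c(healthy = N, halitosis = N)
  tables <- list()
  truth <- list()
  for (site in SITES) {
    relab <- stats::rlnorm(g$n_genes, 0, 1.5)
    relab <- relab / sum(relab)
    names(relab) <- gene_ids
    fold <- rep(1, g$n_genes)
    names(fold) <- gene_ids
    ff <- g$family_folds[[site]]
    check_folds(ff, "family")
    if (!is.null(ff)) {
      for (i in seq_len(nrow(ff))) {
        members <- fam_map$gene_id[fam_map$family == ff$family[i]]
        fold[members] <- ff$fold[i]
      }
    }
    gf <- g$gene_folds[[site]]
    check_folds(gf, "gene_id")
    if (!is.null(gf)) fold[gf$gene_id] <- gf$fold
    k_healthy <- stats::rpois(g$n_genes, N[["healthy"]] * relab)
    k_halitosis <- stats::rpois(g$n_genes, N[["halitosis"]] * relab * fold)
    counts <- cbind(healthy = k_healthy, halitosis = k_halitosis)
    rownames(counts) <- gene_ids
    lib <- pmax(N, colSums(counts))
    tables[[site]] <- gene_table(counts, library_sizes = lib)
    truth[[site]] <- list(family_folds = ff, gene_folds = gf)
  }
  ann <- annotation_maps(ko = ko, family = fam_map, genes = gene_ids)
  list(tables = tables, annotations = ann, truth = truth)
}
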