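#' Assemble and validate pipeline parameters
#'
#' Defaults mirror the study's analysis settings: rarefaction depth 7,180;
#' network thresholds |r| > 0.4, permutation P < 0.01, hub degree > 30;
#' core-microbiome prevalence 0.75 and abundance 0.01; gene rules 5-fold at
#' P < 0.001 and 2-fold for the H2S map; alpha 0.05.
#'
#' @param depth rarefaction depth.
#' @param alpha significance level for OTU screening and diversity tests.
#' @param r_min,p_max,net_perm,min_degree co-occurrence network settings.
#' @param amova_perm permutations for AMOVA.
#' @param prev_min,ab_min core-microbiome thresholds.
#' @param gene_fold_min,gene_p_max differential-gene thresholds.
#' @param h2s_fold_min pathway-family fold threshold.
#' @param seed global seed.
#' @return validated parameter list.
#' @export
pipeline_params <- function(depth = 7180, alpha = 0.05, r_min = 0.4,
                            p_max = 0.01, net_perm = 10000, min_degree = 30,
                            amova_perm = 999, prev_min = 0.75, ab_min = 0.01,
                            gene_fold_min = 5, gene_p_max = 0.001,
                            h2s_fold_min = 2, seed = 1) {
  p <- list(depth = depth, alpha = alpha, r_min = r_min, p_max = p_max,
            net_perm = net_perm, min_degree = min_degree,
            amova_perm = amova_perm, prev_min = prev_min, ab_min = ab_min,
            gene_fold_min = gene_fold_min, gene_p_max = gene_p_max,
            h2s_fold_min = h2s_fold_min, seed = as.integer(seed))
  probs <- c(alpha = alpha, p_max = p_max, gene_p_max = gene_p_max,
             prev_min = prev_min)
  if (any(probs <= 0 | probs >= 1))
    stop("probability thresholds must lie strictly in (0, 1)")
  pos <- c(depth, r_min, net_perm, min_degree, amova_perm, ab_min,
           gene_fold_min, h2s_fold_min)
  if (any(pos <= 0)) stop("all thresholds must be positive")
  p
}

#' Run the full halitosis microbiome analysis
#'
#' Executes rarefaction, alpha/beta diversity with AMOVA, per-site
#' differential OTU screening with PCA, per-condition co-occurrence
#' networks with edge classes and hubs, tiered core-microbiome
#' classification, per-site differential gene analysis with KO enrichment,
#' and the H2S pathway report. Identical inputs and seed give an identical
#' summary.
#'
#' @param study list with `table` ([otu_table()]), `metadata`
#'   ([sample_metadata()]), `tree` (phylo), e.g. from [simulate_study()].
#' @param genes optional list with `tables` (per-site [gene_table()]s) and
#'   `annotations` ([annotation_maps()]), e.g. from
#'   [simulate_gene_tables()].
#' @param params a [pipeline_params()] list.
#' @return list of stage results plus a `summary` list of headline numbers.
#' @export
run_pipeline <- function(study, genes = NULL, params = pipeline_params()) {
  stopifnot(inherits(study$table, "otu_table"))
  validate_metadata(study$table, study$metadata)
  rare <- rarefy(study$table, depth = params$depth, seed = params$seed)
  meta <- study$metadata[study$metadata$sample_id %in%
                           colnames(rare$counts), , drop = FALSE]

  alpha_df <- merge(alpha_diversity(rare), as.data.frame(meta),
                    by = "sample_id")
  alpha_tests <- list()
  for (site in SITES) {
    sub <- alpha_df[alpha_df$site == site, ]
    alpha_tests[[site]] <- list(
      observed = alpha_group_test(
        sub$observed_otus[sub$condition == "healthy"],
        sub$observed_otus[sub$condition == "halitosis"]),
      chao1 = alpha_group_test(
        sub$chao1[sub$condition == "healthy"],
        sub$chao1[sub$condition == "halitosis"]))
  }

  ab <- relative_abundance(rare)
  beta <- list()
  for (site in SITES) {
    ssel <- meta$sample_id[meta$site == site]
    dm <- unifrac_matrix(ab[, ssel, drop = FALSE], study$tree)
    grp <- setNames(meta$condition[match(ssel, meta$sample_id)], ssel)
    beta[[site]] <- amova(dm, grp, n_perm = params$amova_perm,
                          seed = params$seed)
  }

  difftaxa <- list(); pca <- list()
  for (site in SITES) {
    res <- differential_otus(rare, meta, site, alpha = params$alpha)
    difftaxa[[site]] <- res
    flagged <- res$otu_id[res$flagged]
    ssel <- meta$sample_id[meta$site == site]
    if (length(flagged) >= 2)
      pca[[site]] <- pca_scores(ab[flagged, ssel, drop = FALSE])
  }

  networks <- list()
  for (cond in CONDITIONS) {
    vec <- site_otu_vectors(rare, meta, cond)
    networks[[cond]] <- build_network(vec, condition = cond,
                                      r_min = params$r_min,
                                      p_max = params$p_max,
                                      n_perm = params$net_perm,
                                      seed = params$seed)
  }

  core <- core_microbiome(rare, meta, prev_min = params$prev_min,
                          ab_min = params$ab_min)

  gene_res <- NULL
  if (!is.null(genes)) {
    gene_res <- list(diff = list(), enrichment = list())
    for (site in names(genes$tables)) {
      dg <- differential_genes(genes$tables[[site]],
                               fold_min = params$gene_fold_min,
                               p_max = params$gene_p_max)
      gene_res$diff[[site]] <- dg
      flagged <- c(dg$halitosis_enriched, dg$healthy_enriched)
      pop <- unique(genes$annotations$ko$gene_id)
      flagged <- intersect(flagged, pop)
      gene_res$enrichment[[site]] <-
        ko_enrichment(flagged, genes$annotations, population = pop)
    }
    gene_res$h2s <- h2s_pathway_report(genes$tables, genes$annotations,
                                       fold_min = params$h2s_fold_min)
  }

  summary <- list(
    n_samples = ncol(rare$counts),
    alpha_p = alpha_tests,
    amova_p = lapply(beta, `[[`, "p_value"),
    n_flagged_otus = lapply(difftaxa, function(d) sum(d$flagged)),
    network = lapply(networks, function(n) list(
      nodes = nrow(n$nodes), edges = nrow(n$edges),
      classes = as.list(classify_edges(n)),
      hubs = nrow(hub_nodes(n, params$min_degree)))),
    core_labels = as.list(table(core$label)),
    genes = if (!is.null(gene_res))
      lapply(gene_res$diff, `[[`, "summary"))

  list(rarefied = rare, alpha = alpha_df, alpha_tests = alpha_tests,
       beta = beta, difftaxa = difftaxa, pca = pca, networks = networks,
       core = core, genes = gene_res, params = params, summary = summary)
}

#' Write a pipeline summary as JSON
#' @param result a [run_pipeline()] result.
#' @param path output JSON path.
#' @export
write_summary <- function(result, path) {
  jsonlite::write_json(result$summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
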