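#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort that stands in for the study's
# sequencing data: 10 healthy + 10 halitosis children, tongue coating and
# saliva per child, plus pooled two-library gene tables per site. Plants
# the effects the later stages are meant to recover: extra richness in
# halitosis tongue coatings, fold-shifted and presence-shifted OTUs, a
# cross-site correlated OTU pair, and the H2S gene-family pattern.

suppressPackageStartupMessages(library(halimicro))

seed <- 2026
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

up_fams <- c("cbs", "aspB", "yhdR", "sseA", "glpE")
plant_genes <- data.frame(family = c(up_fams, "cysM"),
                          fold = c(rep(3, 5), 1 / 3))

cfg <- simulate_config(
  seed = seed,
  n_otus = 150, depth = 10000,
  richness_delta = 50, richness_relab = 1e-3,
  differential_otus = data.frame(
    otu_id = c("OTU020", "OTU035", "OTU050", "OTU080"),
    site = c("tongue", "tongue", "saliva", "tongue"),
    fold = c(8, 4, 6, 5)),
  prevalence_otus = data.frame(
    otu_id = c("OTU090", "OTU095"), site = c("tongue", "saliva"),
    p_healthy = c(0.15, 0.2), p_halitosis = c(1.0, 1.0)),
  correlated_pairs = data.frame(
    site1 = "tongue", otu1 = "OTU010", site2 = "saliva", otu2 = "OTU012",
    rho = 0.9),
  gene = list(n_genes = 5000, library_size = 2e6,
              family_folds = list(tongue = plant_genes,
                                  saliva = plant_genes),
              # strong folds outside the H2S families drive the >5-fold
              # differential-gene stage and KO enrichment
              gene_folds = list(
                tongue = data.frame(
                  gene_id = sprintf("g%06d", 101:160),
                  fold = rep(c(8, 1 / 8), 30)),
                saliva = data.frame(
                  gene_id = sprintf("g%06d", 201:240),
                  fold = rep(c(10, 1 / 10), 20)))))

st <- simulate_study(cfg)
gn <- simulate_gene_tables(cfg)

write_otu_table(st$table, file.path(out, "otu_table.tsv"))
write_metadata(st$metadata, file.path(out, "metadata.tsv"))
write_tree(st$tree, file.path(out, "tree.nwk"))
for (site in c("tongue", "saliva"))
  write_gene_table(gn$tables[[site]],
                   file.path(out, paste0("genes_", site, ".tsv")))
write.table(gn$annotations$ko, file.path(out, "gene_ko.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(gn$annotations$family, file.path(out, "gene_families.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(seed = seed,
       library_sizes = lapply(gn$tables, function(t)
         as.list(t$library_sizes)),
       truth = list(study = st$truth, genes = gn$truth)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("cohort: %d OTUs x %d samples at depth %d\n",
            nrow(st$table$counts), ncol(st$table$counts), cfg$depth))
cat(sprintf("planted: %d differential OTUs, %d prevalence OTUs, 1 correlated pair, %d extra richness OTUs\n",
            nrow(cfg$differential_otus), nrow(cfg$prevalence_otus),
            cfg$richness_delta))
cat(sprintf("gene tables: %d genes per site, %d H2S families planted\n",
            cfg$gene$n_genes, nrow(plant_genes)))
cat("wrote", out, "\n")
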