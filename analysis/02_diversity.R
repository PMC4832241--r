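#!/usr/bin/env Rscript
# Stage 2: alpha diversity (observed OTUs, Chao1) at even depth, and
# weighted UniFrac beta diversity with permutational AMOVA per site.
# Expectation from the planted richness: halitosis tongue coatings richer
# than healthy ones; no beta-diversity separation was planted.

suppressPackageStartupMessages(library(halimicro))

seed <- 2026
tab <- read_otu_table("results/data/otu_table.tsv")
meta <- read_metadata("results/data/metadata.tsv")
tree <- read_tree("results/data/tree.nwk")

rare <- rarefy(tab, depth = 7180, seed = seed)
adiv <- merge(alpha_diversity(rare), as.data.frame(meta), by = "sample_id")
write.table(adiv, "results/alpha_diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("alpha diversity at depth 7180:\n")
for (site in c("tongue", "saliva")) {
  sub <- adiv[adiv$site == site, ]
  oh <- sub$observed_otus[sub$condition == "healthy"]
  od <- sub$observed_otus[sub$condition == "halitosis"]
  ch <- sub$chao1[sub$condition == "healthy"]
  cd <- sub$chao1[sub$condition == "halitosis"]
  cat(sprintf("  %s: observed %0.1f vs %0.1f (p=%.3g); chao1 %0.1f vs %0.1f (p=%.3g)\n",
              site, mean(oh), mean(od), alpha_group_test(oh, od),
              mean(ch), mean(cd), alpha_group_test(ch, cd)))
}

ab <- relative_abundance(rare)
for (site in c("tongue", "saliva")) {
  sel <- meta$sample_id[meta$site == site &
                          meta$sample_id %in% colnames(ab)]
  dm <- unifrac_matrix(ab[, sel, drop = FALSE], tree)
  write.table(dm, sprintf("results/unifrac_%s.tsv", site), sep = "\t",
              quote = FALSE, col.names = NA)
  grp <- setNames(meta$condition[match(sel, meta$sample_id)], sel)
  res <- amova(dm, grp, n_perm = 999, seed = seed)
  cat(sprintf("  %s weighted UniFrac AMOVA: F=%.3f, p=%.3f\n",
              site, res$f, res$p_value))
}
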