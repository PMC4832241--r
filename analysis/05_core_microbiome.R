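#!/usr/bin/env Rscript
# Stage 5: tiered core-microbiome classification of tongue-coating OTUs
# (prevalence > 75% in both / one condition; tiers by full prevalence and
# 1% mean relative abundance).

suppressPackageStartupMessages(library(halimicro))

tab <- read_otu_table("results/data/otu_table.tsv")
meta <- read_metadata("results/data/metadata.tsv")

core <- core_microbiome(tab, meta, prev_min = 0.75, ab_min = 0.01)
write.table(core, "results/core_microbiome.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

counts <- table(core$label)
cat("tongue-coating core classification:\n")
for (lab in names(counts))
  cat(sprintf("  %-22s %d\n", lab, counts[[lab]]))
tiers <- table(core$label[core$tier %in% 1:3], core$tier[core$tier %in% 1:3])
if (length(tiers)) {
  cat("tiers (rows = label, cols = tier):\n")
  print(tiers)
}
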