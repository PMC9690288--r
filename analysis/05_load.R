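#!/usr/bin/env Rscript
# Zygosity-stratified mutational-load proportions per impact category.

source("analysis/00_config.R")

scaffolds <- read.table(file.path(SIM_DIR, "scaffolds.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
layout <- genome_layout(scaffolds, masked = read_bed(file.path(SIM_DIR, "mask.bed")))
mat <- read_vcf(file.path(SIM_DIR, "cohort.filtered.vcf"), layout)
impact <- read_impact_table(file.path(SIM_DIR, "impact.tsv"))
metadata <- read_metadata(file.path(SIM_DIR, "metadata.tsv"))

lp <- load_proportions(mat, impact)
lp$population <- metadata$population[match(lp$individual, metadata$sample)]

message("population means of load proportions:")
agg <- aggregate(cbind(p_hom, p_het) ~ population + category, lp, mean)
for (i in seq_len(nrow(agg))) {
  message(sprintf("  %-8s %-8s hom %.5f  het %.5f", agg$population[i],
                  agg$category[i], agg$p_hom[i], agg$p_het[i]))
}

write.table(lp, file.path(RESULTS_DIR, "load_proportions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", RESULTS_DIR, "/load_proportions.tsv")
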