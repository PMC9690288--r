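#!/usr/bin/env Rscript
# Read the serialized cohort back through the standard-format readers and
# apply the site/genotype quality filters.

source("analysis/00_config.R")

scaffolds <- read.table(file.path(SIM_DIR, "scaffolds.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
layout <- genome_layout(scaffolds, masked = read_bed(file.path(SIM_DIR, "mask.bed")))
metadata <- read_metadata(file.path(SIM_DIR, "metadata.tsv"))
mat <- read_vcf(file.path(SIM_DIR, "cohort.vcf"), layout)
message("read ", n_sites(mat), " sites x ", length(mat$samples), " samples")

fs <- filter_sites(mat, layout, metadata)
message("retained ", n_sites(fs$matrix), " sites; removals by rule:")
for (i in seq_len(nrow(fs$report))) {
  message(sprintf("  %-22s %d", fs$report$rule[i], fs$report$n_sites[i]))
}

write_vcf(fs$matrix, file.path(SIM_DIR, "cohort.filtered.vcf"), layout)
write.table(fs$report, file.path(RESULTS_DIR, "filter_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", SIM_DIR, "/cohort.filtered.vcf and ",
        RESULTS_DIR, "/filter_report.tsv")
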