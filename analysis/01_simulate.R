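#!/usr/bin/env Rscript
# Generate the synthetic cohort and serialize it in the standard formats
# (VCF + mask BED + metadata TSV + impact TSV + truth JSON), so the rest of
# the workflow consumes files exactly as a real study would.

source("analysis/00_config.R")
dir.create(SIM_DIR, showWarnings = FALSE, recursive = TRUE)

layout <- analysis_layout()
cfg <- analysis_config(layout)
message("simulating cohort (seed ", SEED, ") on ",
        round(analyzable_length(layout) / 1e6), " Mb analyzable genome...")
sim <- simulate_cohort(cfg)
message("  ", n_sites(sim$matrix), " sites x ",
        length(sim$matrix$samples), " individuals; ",
        nrow(sim$impact), " impact-annotated sites")

write_vcf(sim$matrix, file.path(SIM_DIR, "cohort.vcf"), layout)
write_bed(layout$masked, file.path(SIM_DIR, "mask.bed"))
write.table(sim$metadata, file.path(SIM_DIR, "metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$impact, file.path(SIM_DIR, "impact.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(layout$scaffolds, file.path(SIM_DIR, "scaffolds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(individuals = lapply(sim$truth$individuals, function(i) {
    list(population = i$population, froh = as.list(i$froh),
         theta_bg = i$theta_bg, f_load = i$f_load, tracts = i$tracts)
  }),
  epsilon = sim$truth$epsilon, depth_mean = sim$truth$depth_mean,
  analyzable_bp = sim$truth$analyzable_bp, seed = sim$truth$seed),
  file.path(SIM_DIR, "truth.json"), auto_unbox = TRUE, digits = NA)

message("wrote ", SIM_DIR, "/{cohort.vcf, mask.bed, metadata.tsv, impact.tsv, scaffolds.tsv, truth.json}")
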