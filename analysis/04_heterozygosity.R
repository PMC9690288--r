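#!/usr/bin/env Rscript
# Genome-wide heterozygosity per kb and maximum-likelihood (theta, epsilon)
# from simulated read profiles.

source("analysis/00_config.R")

scaffolds <- read.table(file.path(SIM_DIR, "scaffolds.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
layout <- genome_layout(scaffolds, masked = read_bed(file.path(SIM_DIR, "mask.bed")))
mat <- read_vcf(file.path(SIM_DIR, "cohort.filtered.vcf"), layout)
truth <- jsonlite::read_json(file.path(SIM_DIR, "truth.json"),
                             simplifyVector = TRUE)

# heterozygous segregating sites per kb of analyzable genome
het <- het_per_kb(mat, callable_bp = analyzable_length(layout))
message("het/kb by individual:")
for (i in seq_len(nrow(het))) {
  message(sprintf("  %-12s %.3f", het$individual[i], het$het_per_kb[i]))
}

message("estimating (theta, epsilon) from read profiles (depth ",
        truth$depth_mean, "x, epsilon ", truth$epsilon, ")...")
set.seed(SEED + 1)
profiles <- simulate_read_profiles(mat, truth$depth_mean, truth$epsilon)
est <- estimate_theta_all(profiles)
est$theta_truth <- vapply(truth$individuals[est$individual],
                          function(i) i$theta_bg, numeric(1))
message(sprintf("  mean epsilon-hat %.4f (true %.3f); theta-hat tracks theta_bg x (1 - F): r = %.3f",
                mean(est$epsilon), truth$epsilon,
                stats::cor(est$theta, est$theta_truth)))

out <- merge(het, est, by = "individual")
write.table(out, file.path(RESULTS_DIR, "heterozygosity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", RESULTS_DIR, "/heterozygosity.tsv")
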