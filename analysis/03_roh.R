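#!/usr/bin/env Rscript
# Call runs of homozygosity, decompose F_ROH into coalescence-age bins and
# compare the recovered inbreeding against the planted truth.

source("analysis/00_config.R")

scaffolds <- read.table(file.path(SIM_DIR, "scaffolds.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
layout <- genome_layout(scaffolds, masked = read_bed(file.path(SIM_DIR, "mask.bed")))
mat <- read_vcf(file.path(SIM_DIR, "cohort.filtered.vcf"), layout)
truth <- jsonlite::read_json(file.path(SIM_DIR, "truth.json"),
                             simplifyVector = TRUE)

message("calling ROH (200-SNP windows, het max 3, hit threshold 5%)...")
segs <- call_roh_all(mat)
segs <- annotate_segment_ages(segs)
fr <- froh(segs, layout, individuals = mat$samples)

longest <- segs[which.max(segs$length_mb), ]
message(sprintf("  %d segments; longest %.1f Mb in %s (g ~ %.1f generations)",
                nrow(segs), longest$length_mb, longest$individual,
                longest$g))

tru <- t(vapply(truth$individuals[mat$samples],
                function(i) unlist(i$froh), numeric(3)))
message("mean |recovered - planted| per bin: ",
        paste(sprintf("%s %.4f", colnames(tru),
                      colMeans(abs(as.matrix(fr[, c("froh_historical",
                                                    "froh_intermediate",
                                                    "froh_recent")]) - tru))),
              collapse = ", "))

write.table(segs, file.path(RESULTS_DIR, "roh_segments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fr, file.path(RESULTS_DIR, "froh.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", RESULTS_DIR, "/roh_segments.tsv and ",
        RESULTS_DIR, "/froh.tsv")
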