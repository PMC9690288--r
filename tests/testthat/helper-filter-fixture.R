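# Build the 10-site fixture used throughout: 2 low-QV sites, 1 SNP within
# 5 bp of an indel, 1 site on a 20 kb scaffold, 1 site depth-violating in
# one sample, 5 clean sites.
fixture_matrix <- function() {
  sites <- data.frame(
    scaffold = c(rep("big", 9), "tiny"),
    pos = c(1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000, 9000, 500),
    ref = "A", alt = "G",
    qual = c(29, 10, rep(60, 8)),          # sites 1-2 fail quality
    stringsAsFactors = FALSE)
  calls <- matrix(0L, 10, 2)
  depth <- matrix(24L, 10, 2)
  depth[4, 2] <- 60L                        # site 4: > 2 x 24 in sample b
  genotype_matrix(sites, calls, depth, c("a", "b"),
                  indels = data.frame(scaffold = "big", pos = 3004))
  # site 3 at pos 3000 is 4 bp from the indel anchor -> removed
}

fixture_layout <- function() genome_layout(c(big = 1e6, tiny = 2e4))

fixture_metadata <- function() {
  data.frame(sample = c("a", "b"), population = "p", year = 2019,
             mean_coverage = 24)
}
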