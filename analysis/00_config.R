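# Shared configuration for the analysis workflow: a desk-scale synthetic
# cohort emulating the contrast between a small, fragmented, recently
# inbred population ("fenno") and a large, well-connected one ("siberia").
# Sourced by the numbered scripts; nothing here runs the pipeline.

library(erodescan)

RESULTS_DIR <- "results"
SIM_DIR <- file.path(RESULTS_DIR, "sim")
SEED <- 2043

# 6 x 25 Mb scaffolds (150 Mb), one hard-masked block and one scaffold
# below the 25 kb analysis threshold, so the site filter has work to do.
analysis_layout <- function() {
  genome_layout(
    c(scaf1 = 25e6, scaf2 = 25e6, scaf3 = 25e6, scaf4 = 25e6,
      scaf5 = 25e6, scaf6 = 25e6, tiny1 = 2e4),
    masked = intervals("scaf1", 10e6, 11e6)
  )
}

# Inbred population: F_ROH 0.25 total with a 40% recent share; outbred:
# historical inbreeding only, lower deleterious-variant inbreeding.
analysis_config <- function(layout = analysis_layout()) {
  sim_config(
    layout,
    populations = list(
      fenno = pop_spec(n = 6, theta_bg = 0.17,
                       froh_targets = c(historical = 0.10,
                                        intermediate = 0.05,
                                        recent = 0.10),
                       f_load = 0.25),
      siberia = pop_spec(n = 6, theta_bg = 0.22,
                         froh_targets = c(historical = 0.04,
                                          intermediate = 0,
                                          recent = 0),
                         f_load = 0.02)
    ),
    # structured sites carry *all* between-population covariance in this
    # generator (background sites are exchangeable across individuals), so
    # their share must be large enough for a 12-sample PCA to resolve the
    # split; real data spreads this signal over every site via LD.
    n_struct_sites = 10000, struct_fst = 0.15,
    seed = SEED
  )
}
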