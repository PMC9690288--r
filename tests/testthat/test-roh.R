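test_that("hit fractions are 1 on all-hom and 0 on all-het scaffolds", {
  p <- roh_params()
  expect_equal(window_hit_fractions(rep(0L, 300), p), rep(1, 300))
  expect_equal(window_hit_fractions(rep(1L, 300), p), rep(0, 300))
  # short scaffolds fall back to one truncated window
  expect_equal(window_hit_fractions(rep(0L, 50), p), rep(1, 50))
  expect_equal(window_hit_fractions(c(rep(0L, 46), rep(1L, 4)), p), rep(0, 50))
})

test_that("hit fractions equal brute-force window enumeration on random vectors", {
  p <- roh_params(window_snp = 20, window_het_max = 2, window_missing_max = 2)
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(c(5, 15, 30, 120, 500), 1)
    calls <- sample(c(0L, 1L, 2L, NA), n, TRUE, prob = c(0.6, 0.2, 0.15, 0.05))
    expect_equal(window_hit_fractions(calls, p),
                 oracle_window_fracs(calls, p))
  }
  # default window size too
  p200 <- roh_params()
  calls <- sample(c(0L, 1L, 2L, NA), 450, TRUE, prob = c(0.8, 0.1, 0.05, 0.05))
  expect_equal(window_hit_fractions(calls, p200),
               oracle_window_fracs(calls, p200))
})

test_that("a clean homozygous stretch is called as a single segment", {
  # 200 hom SNPs spanning ~150 kb at 750 bp spacing: every rule passes
  m <- toy_matrix(list(a = rep(0L, 200)), spacing = 750)
  segs <- call_roh(m$sites, m$calls[, 1], roh_params(), "a")
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 200)
  expect_equal(segs$length_bp, 199 * 750 + 1)
  # all-het scaffold yields nothing
  m <- toy_matrix(list(a = rep(1L, 400)))
  expect_equal(nrow(call_roh(m$sites, m$calls[, 1])), 0)
})

test_that("segments match the direct-scan reference on fuzzed genotype vectors", {
  # smaller windows to exercise every rule on short vectors
  p <- roh_params(window_snp = 25, window_het_max = 2, window_missing_max = 2,
                  seg_min_snp = 20, seg_min_kb = 10, density_kb_per_snp = 5,
                  gap_max_kb = 50)
  set.seed(404)
  for (rep in 1:60) {
    n <- sample(50:600, 1)
    # hom background with planted het clusters and occasional large gaps
    calls <- rep(0L, n)
    n_clust <- sample(0:5, 1)
    for (k in seq_len(n_clust)) {
      at <- sample(n, 1)
      calls[at:min(n, at + sample(1:20, 1))] <- 1L
    }
    calls[sample(n, round(0.05 * n))] <- NA
    calls[sample(n, round(0.1 * n))] <- 2L
    gaps <- sample(c(500, 1000, 2000), n, TRUE)
    gaps[sample(n, sample(0:3, 1))] <- 60000  # exceed gap_max_kb = 50
    sites <- data.frame(scaffold = "s1", pos = cumsum(gaps), ref = "A",
                        alt = "G", qual = 60)
    got <- call_roh(sites, calls, p, "x")
    ref <- oracle_call_roh(sites, calls, p)
    expect_equal(got[c("scaffold", "start", "end", "n_snps", "length_bp")],
                 ref, ignore_attr = TRUE)
  }
})

test_that("the caller is invariant under hom allele swaps and monotone in het flips", {
  p <- roh_params(window_snp = 25, window_het_max = 2, window_missing_max = 2,
                  seg_min_snp = 20, seg_min_kb = 10, density_kb_per_snp = 5)
  set.seed(505)
  for (rep in 1:10) {
    n <- 400
    calls <- sample(c(0L, 1L, 2L), n, TRUE, prob = c(0.75, 0.05, 0.2))
    sites <- data.frame(scaffold = "s1", pos = seq(1, by = 700, length.out = n),
                        ref = "A", alt = "G", qual = 60)
    base <- call_roh(sites, calls, p)
    # swap HOM_REF <-> HOM_ALT at a random subset
    swapped <- calls
    at <- sample(n, n %/% 3)
    swapped[at] <- ifelse(swapped[at] == 0L, 2L,
                          ifelse(swapped[at] == 2L, 0L, swapped[at]))
    expect_equal(call_roh(sites, swapped, p), base)
    # flipping hom -> het never increases total ROH length
    flipped <- calls
    hom_at <- which(flipped != 1L)
    flipped[sample(hom_at, 5)] <- 1L
    expect_lte(sum(call_roh(sites, flipped, p)$length_bp),
               sum(base$length_bp))
  }
})

test_that("segment length maps to generations via g = 100/(2rL)", {
  expect_equal(age_of_length(0.1, 0.6), 100 / (2 * 0.6 * 0.1))
  expect_equal(round(age_of_length(0.1, 0.6) / 50) * 50, 850)
  expect_equal(round(age_of_length(8, 0.6) / 5) * 5, 10)
  expect_equal(round(age_of_length(2, 0.6), 1), 41.7)
  # algebraic identity: 2rL = 100 -> one generation
  expect_equal(age_of_length(50, 1), 1)
  expect_equal(age_of_length(100 / (2 * 0.37), 0.37), 1)
  expect_error(age_of_length(0), "positive")
  expect_error(age_of_length(1, -1), "positive")
})

test_that("bin edges correspond to the conventional generation labels", {
  bins <- roh_age_bins()
  g_edges <- age_of_length(bins$min_mb, 0.6)
  expect_equal(round(g_edges[1]), 833)   # rounded to 850 in common usage
  expect_equal(round(g_edges[2], 1), 41.7)
  expect_equal(round(g_edges[3], 1), 10.4)
})

test_that("froh partitions segment mass into age bins that sum exactly to the total", {
  layout <- toy_layout(len = 2e8)
  segs <- data.frame(
    individual = "a", scaffold = "s1",
    start = c(0, 1e6, 10e6, 30e6),
    end = c(0.5e6, 4e6, 15e6, 80e6),
    n_snps = c(500, 3000, 5000, 50000),
    length_bp = c(0.5e6, 3e6, 5e6, 50e6))
  fr <- froh(segs, layout)
  expect_equal(fr$froh_historical, 0.5e6 / 2e8)
  expect_equal(fr$froh_intermediate, 8e6 / 2e8)
  expect_equal(fr$froh_recent, 50e6 / 2e8)
  expect_identical(fr$froh_total,
                   fr$froh_historical + fr$froh_intermediate + fr$froh_recent)
  # one 50 Mb segment on a 200 Mb analyzable layout
  fr1 <- froh(segs[4, ], layout)
  expect_equal(fr1$froh_total, 0.25)
  expect_equal(fr1$froh_recent, 0.25)
  # no segments at all
  fr0 <- froh(segs[0, ], layout, individuals = "a")
  expect_equal(fr0$froh_total, 0)
  expect_equal(fr0$n_segments, 0)
})

test_that("planted tracts are recovered with window-scale boundary error", {
  layout <- toy_layout(len = 2.5e7, n_scaffolds = 4)
  cfg <- sim_config(layout, populations = list(p = pop_spec(
    n = 1, froh_targets = c(historical = 0, intermediate = 0.06,
                            recent = 0.12))),
    load_sites = c(LOW = 0, MODERATE = 0, HIGH = 0), seed = 17)
  sim <- simulate_cohort(cfg)
  segs <- call_roh_all(sim$matrix)
  tracts <- sim$truth$individuals[[1]]$tracts
  # every planted tract has a recovered segment within one window span
  # (200 SNPs ~ 200 kb at 1 kb spacing) plus one inter-SNP gap per boundary
  tol <- 200 * 1000 + 1000
  for (i in seq_len(nrow(tracts))) {
    hit <- segs[segs$scaffold == tracts$scaffold[i] &
                  segs$end > tracts$start[i] &
                  segs$start < tracts$end[i], ]
    expect_equal(nrow(hit), 1)
    expect_lt(abs(hit$start - tracts$start[i]), tol)
    expect_lt(abs(hit$end - tracts$end[i]), tol)
  }
})

test_that("segment ages annotate bins consistently with froh", {
  segs <- data.frame(individual = "a", scaffold = "s1",
                     start = c(0, 1e6), end = c(0.05e6, 4e6),
                     n_snps = c(50, 3000), length_bp = c(0.05e6, 3e6))
  ann <- annotate_segment_ages(segs)
  expect_true(is.na(ann$age_bin[1]))  # below the smallest bin edge
  expect_equal(ann$age_bin[2], "intermediate")
  expect_equal(ann$g[2], 100 / (2 * 0.6 * 3))
})
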