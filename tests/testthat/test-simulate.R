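test_that("tract length draws follow the exponential law with mean 100/(2rg)", {
  set.seed(99)
  draws <- draw_tract_lengths(1e4, g = 10, r = 0.6)
  mu <- 100 / (2 * 0.6 * 10)  # 8.33 Mb
  se <- mu / sqrt(1e4)        # exponential sd = mean
  expect_lt(abs(mean(draws) - mu), 3 * se)
  # truncation respects the requested range
  tr <- draw_tract_lengths(1000, g = 21, r = 0.6, min_mb = 2, max_mb = 8)
  expect_true(all(tr > 2 & tr <= 8))
})

test_that("planted tracts hit their per-bin targets, avoid masked regions and never overlap", {
  layout <- toy_layout(len = 2e7, n_scaffolds = 5,
                       masked = intervals("s1", 5e6, 1e7))
  set.seed(5)
  targets <- c(historical = 0.08, intermediate = 0.05, recent = 0.10)
  tr <- plant_roh(layout, targets)
  an <- analyzable_length(layout)
  for (b in names(targets)) {
    planted <- sum(tr$end[tr$bin == b] - tr$start[tr$bin == b])
    expect_lt(abs(planted / an - targets[[b]]) / targets[[b]], 0.10 + 1e-9)
  }
  expect_equal(nrow(intervals_intersect(tr, intervals("s1", 5e6, 1e7))), 0)
  # pairwise disjoint: union length equals summed lengths
  expect_equal(intervals_total_length(tr[c("scaffold", "start", "end")]),
               sum(tr$end - tr$start))

  expect_equal(nrow(plant_roh(layout, c(historical = 0, intermediate = 0,
                                        recent = 0))), 0)
  expect_error(plant_roh(layout, c(historical = 0.5, intermediate = 0.3,
                                   recent = 0.2)), "90%")
  # a target below the bin's minimum tract length cannot be met
  expect_error(plant_roh(layout, c(historical = 0, intermediate = 0,
                                   recent = 0.001)), "infeasible")
})

test_that("zero heterozygosity, no tracts and no deleterious sites give an all-hom-ref matrix", {
  layout <- toy_layout(len = 1e6)
  cfg <- sim_config(layout, populations = list(p = pop_spec(
    n = 2, theta_bg = 0,
    froh_targets = c(historical = 0, intermediate = 0, recent = 0))),
    load_sites = c(LOW = 0, MODERATE = 0, HIGH = 0), seed = 4)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$matrix$calls == 0L))
  expect_equal(nrow(sim$impact), 0)
})

test_that("the same seed reproduces the cohort bit-exactly", {
  layout <- toy_layout(len = 2e6)
  cfg <- sim_config(layout, populations = list(p = pop_spec(
    n = 2, froh_targets = c(historical = 0.05, intermediate = 0,
                            recent = 0))),
    n_struct_sites = 50, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$matrix$calls, b$matrix$calls)
  expect_identical(a$matrix$sites, b$matrix$sites)
  expect_identical(a$matrix$depth, b$matrix$depth)
  expect_identical(a$impact, b$impact)
  expect_identical(a$truth$individuals[[1]]$tracts,
                   b$truth$individuals[[1]]$tracts)
})

test_that("truth per-bin F equals planted tract arithmetic exactly", {
  layout <- toy_layout(len = 2e7, n_scaffolds = 5)
  cfg <- sim_config(layout, populations = list(p = pop_spec(n = 2)),
                    load_sites = c(LOW = 0, MODERATE = 0, HIGH = 0),
                    seed = 21)
  sim <- simulate_cohort(cfg)
  an <- analyzable_length(layout)
  for (ind in sim$truth$individuals) {
    planted <- vapply(c("historical", "intermediate", "recent"), function(b) {
      sum(ind$tracts$end[ind$tracts$bin == b] -
            ind$tracts$start[ind$tracts$bin == b])
    }, numeric(1))
    expect_identical(unname(ind$froh), unname(planted / an))
  }
})

test_that("deleterious genotype frequencies follow the inbreeding model", {
  layout <- toy_layout(len = 2e7)
  f <- 0.3; p <- 0.1
  cfg <- sim_config(layout, populations = list(p = pop_spec(
    n = 1, theta_bg = 0, f_load = f,
    froh_targets = c(historical = 0, intermediate = 0, recent = 0))),
    load_sites = c(LOW = 0, MODERATE = 10000, HIGH = 0),
    load_alt_freq = c(LOW = 0.3, MODERATE = p, HIGH = 0.05), seed = 8)
  sim <- simulate_cohort(cfg)
  key <- paste(sim$impact$scaffold, sim$impact$pos)
  g <- sim$matrix$calls[match(key, paste(sim$matrix$sites$scaffold,
                                         sim$matrix$sites$pos)), 1]
  n <- length(g)
  p_het <- 2 * p * (1 - p) * (1 - f)    # 0.126
  se <- sqrt(p_het * (1 - p_het) / n)
  expect_lt(abs(mean(g == 1L) - p_het), 3 * se)
  # chi-squared goodness of fit against the full three-class model
  probs <- c(hom_ref = (1 - p)^2 + f * p * (1 - p),
             het = p_het,
             hom_alt = p^2 + f * p * (1 - p))
  obs <- c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("read profiles follow the per-genotype error model", {
  set.seed(31)
  hom <- toy_matrix(list(a = rep(0L, 2000)))
  pr <- simulate_read_profiles(hom, depth_mean = 20, epsilon = 0)
  expect_true(all(pr$alt == 0))
  expect_true(all(pr$ref[hom$calls == 0L] >= 0))

  het <- toy_matrix(list(a = rep(1L, 5000)))
  pr <- simulate_read_profiles(het, depth_mean = 20, epsilon = 0)
  frac_alt <- sum(pr$alt) / sum(pr$ref + pr$alt)
  expect_lt(abs(frac_alt - 0.5), 3 * 0.5 / sqrt(sum(pr$ref + pr$alt)))

  # hom sites with epsilon = 0.01: mismatch fraction ~ 0.01 over ~1e5 reads
  hom <- toy_matrix(list(a = rep(2L, 5000)))
  pr <- simulate_read_profiles(hom, depth_mean = 20, epsilon = 0.01)
  n_reads <- sum(pr$ref + pr$alt)
  mismatch <- sum(pr$ref) / n_reads
  expect_lt(abs(mismatch - 0.01), 3 * sqrt(0.01 * 0.99 / n_reads))

  # missing genotypes yield zero-depth profiles
  mis <- toy_matrix(list(a = c(NA, 0L, NA)))
  pr <- simulate_read_profiles(mis, depth_mean = 20, epsilon = 0)
  expect_equal(unname((pr$ref + pr$alt)[c(1, 3), 1]), c(0L, 0L))
})

test_that("background heterozygosity scales linearly with theta_bg", {
  layout <- toy_layout(len = 5e6)
  hets <- vapply(c(0.05, 0.1, 0.2), function(th) {
    cfg <- sim_config(layout, populations = list(p = pop_spec(
      n = 1, theta_bg = th,
      froh_targets = c(historical = 0, intermediate = 0, recent = 0))),
      load_sites = c(LOW = 0, MODERATE = 0, HIGH = 0), seed = 14)
    sim <- simulate_cohort(cfg)
    mean(sim$matrix$calls == 1L)
  }, numeric(1))
  expect_lt(max(abs(hets / c(0.05, 0.1, 0.2) - 1)), 0.1)
})
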