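test_that("the GRM matches a direct double-loop computation on a toy matrix", {
  set.seed(9)
  d <- matrix(sample(0:2, 40, TRUE), 8, 5,
              dimnames = list(NULL, paste0("i", 1:5)))
  p <- rowMeans(d) / 2
  keep <- p > 0 & p < 1
  dk <- d[keep, , drop = FALSE]; pk <- p[keep]
  n <- ncol(d)
  ref <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    ref[i, j] <- mean((dk[, i] - 2 * pk) * (dk[, j] - 2 * pk) /
                        (2 * pk * (1 - pk)))
  }
  grm <- standardized_grm(d)
  expect_equal(unname(grm), ref, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(grm, t(grm))
  expect_equal(attr(grm, "n_snps"), sum(keep))
  expect_error(standardized_grm(matrix(2L, 3, 4)), "polymorphic")
  expect_error(standardized_grm(rbind(d, 0L), drop_monomorphic = FALSE),
               "monomorphic")
})

test_that("identical individuals get identical GRM rows and PCA coordinates", {
  set.seed(10)
  d <- matrix(sample(0:2, 60, TRUE), 20, 3)
  d <- cbind(d, d[, 3])  # duplicate individual
  colnames(d) <- paste0("i", 1:4)
  grm <- standardized_grm(d)
  expect_equal(grm[3, ], grm[4, ], ignore_attr = TRUE)
  pc <- pca_grm(grm, 2)
  expect_equal(pc$coords[3, ], pc$coords[4, ], ignore_attr = TRUE)
})

test_that("GRM diagonal averages about 1 under Hardy-Weinberg genotypes", {
  set.seed(12)
  m <- 5000; n <- 12
  p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(m * n, 2, p), m, n)
  grm <- standardized_grm(d)
  expect_lt(abs(mean(diag(grm)) - 1), 0.05)
})

test_that("PCA eigenpairs match the dense solver and variance fractions are normalized", {
  set.seed(13)
  a <- matrix(rnorm(100), 10)
  s <- crossprod(a) / 10
  pc <- pca_grm(s, 3)
  eig <- eigen(s, symmetric = TRUE)
  for (k in 1:3) {
    expect_equal(abs(pc$coords[, k]),
                 abs(eig$vectors[, k] * sqrt(eig$values[k])),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
  expect_equal(sum(pc$eigenvalues[pc$eigenvalues > 0] /
                     sum(pc$eigenvalues[pc$eigenvalues > 0])), 1)
  expect_true(all(diff(pc$var_explained) <= 0))
  # rank-deficient matrix truncates with a warning
  low <- tcrossprod(rnorm(4))
  expect_warning(pc1 <- pca_grm(low, 3), "rank")
  expect_equal(ncol(pc1$coords), 1)
})

test_that("PC1 separates simulated populations with planted allele-frequency divergence", {
  layout <- toy_layout(len = 2e6)
  ok <- logical(10)
  for (s in 1:10) {
    cfg <- sim_config(layout, populations = list(
      A = pop_spec(n = 6, theta_bg = 0.1,
                   froh_targets = c(historical = 0, intermediate = 0,
                                    recent = 0)),
      B = pop_spec(n = 6, theta_bg = 0.1,
                   froh_targets = c(historical = 0, intermediate = 0,
                                    recent = 0))),
      load_sites = c(LOW = 0, MODERATE = 0, HIGH = 0),
      n_struct_sites = 1000, struct_fst = 0.15, seed = 300 + s)
    sim <- simulate_cohort(cfg)
    pc <- pca_grm(standardized_grm(sim$matrix), 2)
    pop <- sim$metadata$population
    x <- pc$coords[, 1]
    # positive silhouette on axis 1: within-group spread below group gap
    gap <- abs(mean(x[pop == "A"]) - mean(x[pop == "B"]))
    spread <- max(stats::sd(x[pop == "A"]), stats::sd(x[pop == "B"]))
    ok[s] <- gap > spread
  }
  expect_gte(sum(ok), 9)
})

test_that("Kruskal-Wallis matches the worked rank example and degenerate input", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  expect_equal(kw$df, 1)
  same <- kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  expect_error(kruskal_wallis(1:3, c("a", "a", "a")), "two non-empty")
})

test_that("Dunn z values match the rank formula oracle and identical groups give z = 0", {
  set.seed(14)
  for (rep in 1:10) {
    values <- c(rnorm(8), rnorm(6, 1), sample(1:4, 7, TRUE))  # with ties
    groups <- rep(c("a", "b", "c"), c(8, 6, 7))
    dn <- dunn_posthoc(values, groups)
    for (j in seq_len(nrow(dn))) {
      expect_equal(dn$z[j],
                   oracle_dunn_z(values, groups, dn$group1[j], dn$group2[j]),
                   tolerance = 1e-12)
    }
    # adjusted p monotone in raw p within the family
    ord <- order(dn$p)
    expect_true(all(diff(dn$p_adj[ord]) >= -1e-12))
    expect_true(all(dn$p_adj >= dn$p - 1e-12))
  }
  two <- dunn_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(two$z, 0)
  expect_equal(two$p, 1)
})

test_that("group comparisons join metrics to metadata labels", {
  df <- data.frame(individual = paste0("i", 1:9),
                   froh_total = c(0.3, 0.25, 0.35, 0.05, 0.04, 0.06,
                                  0.1, 0.12, 0.09))
  md <- data.frame(sample = paste0("i", 1:9),
                   population = rep(c("fenno", "siberia", "kola"), each = 3))
  res <- compare_groups(df, "froh_total", md)
  expect_equal(res$kw$df, 2)
  expect_equal(nrow(res$pairwise), 3)
  expect_error(compare_groups(df, "froh_total", md[1:3, ]), "missing")
})
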