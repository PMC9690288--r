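#' Genome-wide heterozygosity per kb
#'
#' Counts heterozygous calls per individual and divides by the callable
#' length in kb. Callable length is an input (it depends on upstream
#' filtering, not on the genotype matrix itself); pass the number of
#' callable sites when heterozygosity per callable site is wanted instead.
#'
#' @param x A (filtered) [genotype_matrix()].
#' @param callable_bp Callable length in bp: a single value or a vector
#'   named by / aligned with samples. Must be positive.
#' @return Data frame per individual: `n_het`, `callable_bp`, `het_per_kb`.
#' @export
het_per_kb <- function(x, callable_bp) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (any(callable_bp <= 0)) {
    stop("callable length must be positive", call. = FALSE)
  }
  callable_bp <- rep_len(callable_bp, length(x$samples))
  n_het <- colSums(x$calls == GT_HET, na.rm = TRUE)
  data.frame(individual = x$samples,
             n_het = as.integer(n_het),
             callable_bp = callable_bp,
             het_per_kb = 1000 * n_het / callable_bp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-allele site log-likelihood for (theta, epsilon)
#'
#' Mixture likelihood of a read profile at one site: with probability
#' `1 - theta` the site is homozygous (each of the n reads errs
#' independently with probability `epsilon`; the homozygous allele identity
#' is chosen to maximize the likelihood), and with probability `theta`
#' heterozygous (each read drawn from either allele 50:50; in the two-allele
#' model an error flips between them, so supporting counts are
#' Binomial(n, 1/2)). A zero-depth profile contributes 0 (uninformative).
#' This is a deliberate two-allele reduction of the full four-nucleotide
#' profile likelihood used by mlRho-style estimators.
#'
#' @param ref,alt Non-negative read counts for the two observed alleles
#'   (vectorized).
#' @param theta Per-site heterozygosity probability, in [0, 1].
#' @param epsilon Per-read error probability, in [0, 0.5).
#' @return Vector of per-site log-likelihoods (finite).
#' @export
#' @examples
#' site_loglik(10, 0, theta = 0, epsilon = 0)  # log(1) = 0
#' site_loglik(5, 5, theta = 1, epsilon = 0)   # log dbinom(5, 10, 0.5)
site_loglik <- function(ref, alt, theta, epsilon) {
  if (theta < 0 || theta > 1 || epsilon < 0 || epsilon >= 0.5) {
    stop("theta must lie in [0,1] and epsilon in [0, 0.5)", call. = FALSE)
  }
  if (any(ref < 0) || any(alt < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  n <- ref + alt
  p_hom <- pmax(dbinom(alt, n, epsilon), dbinom(ref, n, epsilon))
  p_het <- dbinom(alt, n, 0.5)
  ll <- log((1 - theta) * p_hom + theta * p_het)
  ll[n == 0] <- 0
  ll
}

# Collapse profiles to unique (ref, alt) pairs with multiplicities, for fast
# repeated likelihood evaluation over a parameter grid.
profile_weights <- function(ref, alt) {
  keep <- (ref + alt) > 0
  if (!any(keep)) {
    return(list(ref = numeric(), alt = numeric(), w = numeric(),
                n_sites = 0L))
  }
  key <- paste(ref[keep], alt[keep])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  list(ref = as.numeric(parts[, 1]), alt = as.numeric(parts[, 2]),
       w = as.numeric(tab), n_sites = sum(keep))
}

#' Maximum-likelihood (theta, epsilon) from read profiles
#'
#' Maximizes the summed [site_loglik()] over per-site heterozygosity theta
#' and sequencing error epsilon: a coarse log-spaced grid scan followed by
#' Nelder-Mead refinement on the log scale. Deterministic given the inputs
#' (fixed grid, fixed start). Under the infinite-sites model theta
#' approximates the population-scaled mutation rate 4 Ne mu.
#'
#' @param ref,alt Read-count vectors over sites (one individual).
#' @param theta_bounds,epsilon_bounds Search bounds (epsilon upper bound
#'   must stay below 0.5).
#' @param grid_n Grid points per axis for the coarse scan.
#' @return List of class `theta_estimate`: `theta`, `epsilon`, `loglik`,
#'   `n_sites` (informative, depth > 0).
#' @export
estimate_theta <- function(ref, alt,
                           theta_bounds = c(1e-6, 0.99),
                           epsilon_bounds = c(1e-7, 0.49),
                           grid_n = 50) {
  pw <- profile_weights(ref, alt)
  if (pw$n_sites == 0) {
    stop("all profiles have zero depth; nothing to estimate", call. = FALSE)
  }
  obj <- function(theta, eps) {
    sum(pw$w * site_loglik(pw$ref, pw$alt, theta, eps))
  }
  theta_grid <- exp(seq(log(theta_bounds[1]), log(theta_bounds[2]),
                        length.out = grid_n))
  eps_grid <- exp(seq(log(epsilon_bounds[1]), log(epsilon_bounds[2]),
                      length.out = grid_n))
  best <- c(-Inf, theta_grid[1], eps_grid[1])
  for (eps in eps_grid) {
    p_hom <- pmax(dbinom(pw$alt, pw$ref + pw$alt, eps),
                  dbinom(pw$ref, pw$ref + pw$alt, eps))
    p_het <- dbinom(pw$alt, pw$ref + pw$alt, 0.5)
    for (theta in theta_grid) {
      ll <- sum(pw$w * log((1 - theta) * p_hom + theta * p_het))
      if (ll > best[1]) best <- c(ll, theta, eps)
    }
  }
  clamp <- function(v, b) pmin(pmax(v, b[1]), b[2])
  neg <- function(par) {
    -obj(clamp(exp(par[1]), theta_bounds), clamp(exp(par[2]), epsilon_bounds))
  }
  fit <- optim(log(c(best[2], best[3])), neg, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  theta_hat <- clamp(exp(fit$par[1]), theta_bounds)
  eps_hat <- clamp(exp(fit$par[2]), epsilon_bounds)
  structure(list(theta = theta_hat, epsilon = eps_hat,
                 loglik = -fit$value, n_sites = pw$n_sites),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("theta_estimate: theta = %.5g, epsilon = %.5g (logL = %.2f over %d informative sites)\n",
              x$theta, x$epsilon, x$loglik, x$n_sites))
  invisible(x)
}

#' Estimate (theta, epsilon) for every sample from profile matrices
#'
#' @param profiles List with `ref` and `alt` matrices (sites x samples), as
#'   from [simulate_read_profiles()].
#' @param ... Passed to [estimate_theta()].
#' @return Data frame per individual: `theta`, `epsilon`, `loglik`,
#'   `n_sites`.
#' @export
estimate_theta_all <- function(profiles, ...) {
  samples <- colnames(profiles$ref)
  rows <- lapply(seq_along(samples), function(k) {
    est <- estimate_theta(profiles$ref[, k], profiles$alt[, k], ...)
    data.frame(individual = samples[k], theta = est$theta,
               epsilon = est$epsilon, loglik = est$loglik,
               n_sites = est$n_sites, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
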