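# Independent brute-force references used to validate the fast
# implementations. Deliberately written as plain loops over definitions.

# Per-base boolean-array union length of an interval set (single scaffold
# sets of modest size only).
bitmap_total_length <- function(iv) {
  total <- 0
  for (sc in unique(iv$scaffold)) {
    rows <- iv[iv$scaffold == sc, , drop = FALSE]
    hi <- max(rows$end)
    cov <- logical(hi)
    for (i in seq_len(nrow(rows))) {
      cov[(rows$start[i] + 1):rows$end[i]] <- TRUE
    }
    total <- total + sum(cov)
  }
  total
}

bitmap_cover <- function(iv, hi) {
  cov <- logical(hi)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i]) cov[(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  cov
}

# O(n*w) enumeration of every window for the per-SNP hit fractions.
oracle_window_fracs <- function(calls, params) {
  n <- length(calls)
  if (n == 0) return(numeric())
  w <- params$window_snp
  is_hom_window <- function(idx) {
    sum(calls[idx] == 1, na.rm = TRUE) <= params$window_het_max &&
      sum(is.na(calls[idx])) <= params$window_missing_max
  }
  if (n < w) {
    return(rep(as.numeric(is_hom_window(seq_len(n))), n))
  }
  hom <- vapply(seq_len(n - w + 1),
                function(s) is_hom_window(s:(s + w - 1)), logical(1))
  vapply(seq_len(n), function(j) {
    wins <- max(1, j - w + 1):min(n - w + 1, j)
    mean(hom[wins])
  }, numeric(1))
}

# Direct-scan ROH reference: thresholded SNPs -> runs -> gap split ->
# retention rules, all as explicit loops.
oracle_call_roh <- function(sites, calls, params) {
  segs <- list()
  for (sc in unique(sites$scaffold)) {
    idx <- which(sites$scaffold == sc)
    pos <- sites$pos[idx]
    frac <- oracle_window_fracs(calls[idx], params)
    member <- frac >= params$hit_threshold
    i <- 1
    n <- length(member)
    while (i <= n) {
      if (!member[i]) { i <- i + 1; next }
      j <- i
      while (j < n && member[j + 1]) j <- j + 1
      # split run i..j at big gaps
      run <- pos[i:j]
      piece <- c(run[1])
      flush <- function(piece) {
        m <- length(piece)
        len <- piece[m] - (piece[1] - 1)
        if (m >= params$seg_min_snp && len >= params$seg_min_kb * 1000 &&
            m / (len / 1000) >= 1 / params$density_kb_per_snp) {
          segs[[length(segs) + 1]] <<- data.frame(
            scaffold = sc, start = piece[1] - 1, end = piece[m],
            n_snps = m, length_bp = len, stringsAsFactors = FALSE)
        }
      }
      for (k in seq_along(run)[-1]) {
        if (run[k] - run[k - 1] > params$gap_max_kb * 1000) {
          flush(piece)
          piece <- c(run[k])
        } else {
          piece <- c(piece, run[k])
        }
      }
      flush(piece)
      i <- j + 1
    }
  }
  if (length(segs) == 0) {
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      length_bp = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, segs)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive two-allele profile likelihood: enumerate the latent genotype
# and every per-read outcome (allele origin x error) for depths <= 8.
oracle_site_lik <- function(ref, alt, theta, epsilon) {
  n <- ref + alt
  if (n == 0) return(1)
  # hom: reads err independently; maximize over which allele is true
  p_hom_given <- function(n_err) {
    choose(n, n_err) * epsilon^n_err * (1 - epsilon)^(n - n_err)
  }
  p_hom <- max(p_hom_given(alt), p_hom_given(ref))
  # het: each read picks an allele 1/2, then flips with prob epsilon;
  # enumerate origin/error combinations per read -> P(read = alt) = 1/2
  p_read_alt <- 0.5 * (1 - epsilon) + 0.5 * epsilon
  p_het <- choose(n, alt) * p_read_alt^alt * (1 - p_read_alt)^(n - alt)
  (1 - theta) * p_hom + theta * p_het
}

# Dunn z statistic recomputed directly from the rank formula.
oracle_dunn_z <- function(values, groups, g1, g2) {
  rk <- rank(values)
  n_tot <- length(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  s2 <- n_tot * (n_tot + 1) / 12 - tie_term
  m1 <- mean(rk[groups == g1]); m2 <- mean(rk[groups == g2])
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
}

# Small genotype-matrix builder: one scaffold, evenly spaced sites.
toy_matrix <- function(calls_by_sample, spacing = 1000, scaffold = "s1",
                       qual = 60, depth = 20, start_pos = 1) {
  calls <- do.call(cbind, calls_by_sample)
  n <- nrow(calls)
  sites <- data.frame(scaffold = scaffold,
                      pos = seq(start_pos, by = spacing, length.out = n),
                      ref = "A", alt = "G", qual = qual,
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, calls,
                  matrix(depth, n, ncol(calls)),
                  names(calls_by_sample))
}

toy_layout <- function(len = 1e7, n_scaffolds = 1, min_scaffold_bp = 25000,
                       masked = intervals()) {
  genome_layout(setNames(rep(len, n_scaffolds),
                         paste0("s", seq_len(n_scaffolds))),
                masked = masked, min_scaffold_bp = min_scaffold_bp)
}
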