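#' Variance-standardized genomic relationship matrix
#'
#' Per site, the alt-allele dosage d in \{0, 1, 2\} is standardized to
#' (d - 2p)/sqrt(2p(1-p)) with p the sample alt-allele frequency; the GRM is
#' the average over sites of the outer products of the standardized dosage
#' vectors. Monomorphic sites carry no information and are excluded (by
#' default silently; with `drop_monomorphic = FALSE` their presence is an
#' error, for callers that guarantee pre-exclusion).
#'
#' @param x A [genotype_matrix()], or an integer dosage matrix
#'   (sites x samples). Missing genotypes are not supported; filter first.
#' @param drop_monomorphic Drop sites with sample frequency 0 or 1.
#' @return Symmetric n x n matrix with an `n_snps` attribute.
#' @export
standardized_grm <- function(x, drop_monomorphic = TRUE) {
  d <- if (inherits(x, "genotype_matrix")) x$calls else as.matrix(x)
  if (anyNA(d)) {
    stop("dosage matrix contains missing genotypes; filter first",
         call. = FALSE)
  }
  p <- rowMeans(d) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    if (!drop_monomorphic) {
      stop("monomorphic sites must be excluded before GRM computation",
           call. = FALSE)
    }
    d <- d[!mono, , drop = FALSE]
    p <- p[!mono]
  }
  m <- nrow(d)
  if (m == 0) stop("no polymorphic sites", call. = FALSE)
  z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  grm <- crossprod(z) / m
  dimnames(grm) <- list(colnames(d), colnames(d))
  attr(grm, "n_snps") <- m
  grm
}

#' PCA of a relationship matrix
#'
#' Eigendecomposition of the (symmetric) GRM. Individual coordinates are
#' eigenvector times sqrt(eigenvalue); variance-explained fractions are each
#' eigenvalue over the sum of all positive eigenvalues.
#'
#' @param grm Symmetric relationship matrix from [standardized_grm()].
#' @param k Number of axes to return (truncated to the number of positive
#'   eigenvalues, with a warning).
#' @return List of class `grm_pca`: `coords` (n x k), `var_explained`
#'   (length k), `eigenvalues` (all), `n_snps`.
#' @export
pca_grm <- function(grm, k = 2) {
  stopifnot(is.matrix(grm), nrow(grm) == ncol(grm))
  eig <- eigen(grm, symmetric = TRUE)
  pos <- eig$values > .Machine$double.eps * max(abs(eig$values)) * nrow(grm)
  rank <- sum(pos)
  if (k > rank) {
    warning("requested ", k, " axes but rank is ", rank, "; truncating")
    k <- rank
  }
  lambda <- eig$values[seq_len(k)]
  coords <- sweep(eig$vectors[, seq_len(k), drop = FALSE], 2,
                  sqrt(pmax(lambda, 0)), `*`)
  rownames(coords) <- rownames(grm)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coords = coords,
                 var_explained = lambda / sum(eig$values[pos]),
                 eigenvalues = eig$values,
                 n_snps = attr(grm, "n_snps")),
            class = "grm_pca")
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper over [stats::kruskal.test()] returning the tie-corrected H
#' statistic, degrees of freedom and chi-squared p value in a tidy row.
#' When all observations are identical, H = 0 and p = 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (>= 2 non-empty groups).
#' @return Data frame with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2 || any(table(groups) == 0)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  if (length(unique(values)) == 1) {
    return(data.frame(H = 0, df = nlevels(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  data.frame(H = unname(kt$statistic), df = unname(kt$parameter),
             p = kt$p.value)
}

#' Dunn's post hoc pairwise comparisons
#'
#' Rank-based z tests between all group pairs following a Kruskal-Wallis
#' test, with mid-ranks for ties and the tie-corrected variance
#' N(N+1)/12 - sum(t^3 - t) / (12(N-1)). Two-sided p values are adjusted
#' for multiplicity (Holm by default).
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (>= 2 non-empty groups).
#' @param method Adjustment method passed to [stats::p.adjust()].
#' @return Data frame per pair: `group1`, `group2`, `z`, `p`, `p_adj`,
#'   `method`.
#' @export
dunn_posthoc <- function(values, groups, method = "holm") {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2 || any(table(groups) == 0)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  n_tot <- length(values)
  rk <- rank(values)  # mid-ranks
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  var_base <- n_tot * (n_tot + 1) / 12 - tie_term
  mean_rank <- tapply(rk, groups, mean)
  n_g <- table(groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2)
  z <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(var_base * (1 / n_g[[a]] + 1 / n_g[[b]]))
    if (se == 0) return(0)
    (mean_rank[[a]] - mean_rank[[b]]) / se
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = p.adjust(p, method = method), method = method,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Group comparison of a per-individual metric
#'
#' Convenience wrapper running [kruskal_wallis()] and [dunn_posthoc()] on a
#' per-individual metric table joined to a metadata grouping (two-level
#' region contrasts and per-subpopulation contrasts alike).
#'
#' @param df Data frame with an `individual` column and the metric.
#' @param metric Name of the metric column.
#' @param metadata Data frame with `sample` and the grouping column.
#' @param group Name of the grouping column in `metadata`.
#' @param method Multiplicity adjustment for the pairwise table.
#' @return List with `kw` (H/df/p) and `pairwise` (Dunn table).
#' @export
compare_groups <- function(df, metric, metadata, group = "population",
                           method = "holm") {
  idx <- match(df$individual, metadata$sample)
  if (anyNA(idx)) {
    stop("individuals missing from metadata: ",
         paste(df$individual[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  g <- metadata[[group]][idx]
  list(kw = kruskal_wallis(df[[metric]], g),
       pairwise = dunn_posthoc(df[[metric]], g, method = method))
}
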