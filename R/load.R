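#' Zygosity-stratified mutational-load proportions
#'
#' For each individual, counts homozygous-alternate and heterozygous
#' genotypes at impact-annotated sites per category and divides each count
#' by the total number of alleles: 2 x (annotated sites genotyped in that
#' individual, pooled across categories). The alternate allele is treated as
#' the deleterious/derived allele (annotations are alt-specific); no
#' ancestral-state inference is attempted. The shared pooled denominator
#' keeps hom and het proportions comparable across categories and
#' individuals, and is recorded in the output.
#'
#' @param x A (filtered) [genotype_matrix()].
#' @param impact Annotation data frame with `scaffold`, `pos`, `category`
#'   (see [read_impact_table()]).
#' @return Data frame per individual x category: `n_hom`, `n_het`,
#'   `denominator` (total alleles), `p_hom`, `p_het`.
#' @export
#' @examples
#' # 2 hom-alt + 1 het LoF among 10 annotated sites: denominator 20,
#' # hom proportion 0.10, het proportion 0.05
load_proportions <- function(x, impact) {
  stopifnot(inherits(x, "genotype_matrix"))
  bad <- setdiff(unique(impact$category), impact_categories())
  if (length(bad) > 0) {
    stop("unknown impact categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  key_sites <- paste(x$sites$scaffold, x$sites$pos)
  key_impact <- paste(impact$scaffold, impact$pos)
  idx <- match(key_impact, key_sites)
  present <- !is.na(idx)
  if (!any(present)) {
    stop("no annotated site overlaps the genotype matrix", call. = FALSE)
  }
  idx <- idx[present]
  cat_site <- impact$category[present]

  rows <- lapply(x$samples, function(s) {
    g <- x$calls[idx, s]
    genotyped <- !is.na(g)
    denom <- 2 * sum(genotyped)
    per_cat <- lapply(impact_categories(), function(cc) {
      sel <- genotyped & cat_site == cc
      n_hom <- sum(g[sel] == GT_HOM_ALT)
      n_het <- sum(g[sel] == GT_HET)
      data.frame(individual = s, category = cc,
                 n_hom = n_hom, n_het = n_het, denominator = denom,
                 p_hom = if (denom > 0) n_hom / denom else NA_real_,
                 p_het = if (denom > 0) n_het / denom else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_cat)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
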