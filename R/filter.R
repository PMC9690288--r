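#' Site filtering parameters
#'
#' Quality rules applied to a genotype matrix before analysis: minimum site
#' quality QV 30; exclusion of SNPs within 5 bp of an indel anchor
#' position; per-sample depth between one third and twice that sample's
#' mean coverage; removal of masked regions and scaffolds below 25 kb; and
#' (by default) retention only of sites genotyped in every individual.
#'
#' @param min_qv Minimum site quality.
#' @param indel_exclusion_radius SNPs at distance <= this many bp from an
#'   indel anchor are removed.
#' @param depth_min_factor Lower depth bound as a fraction of the sample's
#'   mean coverage.
#' @param depth_max_factor Upper depth bound as a multiple of the sample's
#'   mean coverage.
#' @param min_scaffold_bp Minimum scaffold length kept.
#' @param require_complete_genotyping Drop sites with any missing call.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_qv = 30, indel_exclusion_radius = 5,
                          depth_min_factor = 1 / 3, depth_max_factor = 2,
                          min_scaffold_bp = 25000,
                          require_complete_genotyping = TRUE) {
  stopifnot(min_qv >= 0, indel_exclusion_radius >= 0,
            depth_min_factor > 0, depth_max_factor > depth_min_factor)
  structure(list(min_qv = min_qv,
                 indel_exclusion_radius = indel_exclusion_radius,
                 depth_min_factor = depth_min_factor,
                 depth_max_factor = depth_max_factor,
                 min_scaffold_bp = min_scaffold_bp,
                 require_complete_genotyping = require_complete_genotyping),
            class = "filter_params")
}

#' Per-sample depth thresholds
#'
#' The depth window for a sample is (mean/3, 2 x mean): genotypes below one
#' third or above twice the sample's mean coverage are unreliable (repeat
#' collapse, structural variation) and are excluded.
#'
#' @param mean_coverage Mean fold coverage of the sample (> 0).
#' @return Numeric vector `c(min, max)`.
#' @export
#' @examples
#' depth_thresholds(26.68)  # ~8.89x and ~53.36x
depth_thresholds <- function(mean_coverage) {
  if (any(mean_coverage <= 0)) {
    stop("mean coverage must be positive", call. = FALSE)
  }
  c(min = mean_coverage / 3, max = 2 * mean_coverage)
}

#' Filter a genotype matrix by site and genotype quality
#'
#' Applies the rules of [filter_params()] with first-failing-rule
#' attribution, in the fixed order: scaffold/mask, site quality, indel
#' proximity, per-sample depth, completeness. A site failing several rules
#' is counted once, under the first. Depth thresholds are per sample, from
#' that sample's `mean_coverage` in `metadata`.
#'
#' @param x A [genotype_matrix()] (its indel registry feeds the proximity
#'   rule).
#' @param layout A [genome_layout()]; `params$min_scaffold_bp` overrides the
#'   layout's own minimum for the scaffold-size rule.
#' @param metadata Data frame with `sample` and `mean_coverage` covering
#'   every sample in `x` (see [check_samples()]).
#' @param params A [filter_params()].
#' @return List with `matrix` (the retained sites) and `report` (data frame
#'   of per-rule removal counts plus retained; counts sum to the input site
#'   count).
#' @export
filter_sites <- function(x, layout, metadata, params = filter_params()) {
  stopifnot(inherits(x, "genotype_matrix"),
            inherits(layout, "genome_layout"),
            inherits(params, "filter_params"))
  md <- check_samples(x, metadata)
  n <- n_sites(x)
  # first-failing-rule attribution: 0 = retained
  fail <- integer(n)
  rule_names <- c("scaffold_or_mask", "quality", "indel_proximity",
                  "depth", "incomplete_genotyping")

  # rule 1: analyzable scaffolds and mask
  sc_len <- layout$scaffolds$length[match(x$sites$scaffold,
                                          layout$scaffolds$name)]
  off <- is.na(sc_len) | sc_len < params$min_scaffold_bp
  masked <- positions_in_intervals(x$sites$scaffold, x$sites$pos,
                                   layout$masked)
  fail[fail == 0L & (off | masked)] <- 1L

  # rule 2: site quality (missing QV treated as failing)
  low_q <- is.na(x$sites$qual) | x$sites$qual < params$min_qv
  fail[fail == 0L & low_q] <- 2L

  # rule 3: proximity to indel anchors
  if (nrow(x$indels) > 0 && params$indel_exclusion_radius >= 0) {
    near <- logical(n)
    for (sc in unique(x$indels$scaffold)) {
      ip <- sort(x$indels$pos[x$indels$scaffold == sc])
      sel <- which(x$sites$scaffold == sc)
      if (length(sel) == 0) next
      j <- findInterval(x$sites$pos[sel], ip)
      d_left <- ifelse(j >= 1, x$sites$pos[sel] - ip[pmax(j, 1)], Inf)
      d_right <- ifelse(j < length(ip),
                        ip[pmin(j + 1, length(ip))] - x$sites$pos[sel], Inf)
      near[sel] <- pmin(d_left, d_right) <= params$indel_exclusion_radius
    }
    fail[fail == 0L & near] <- 3L
  }

  # rule 4: per-sample depth window
  depth_ok <- matrix(TRUE, n, length(x$samples))
  for (k in seq_along(x$samples)) {
    dmin <- params$depth_min_factor * md$mean_coverage[k]
    dmax <- params$depth_max_factor * md$mean_coverage[k]
    depth_ok[, k] <- x$depth[, k] >= dmin & x$depth[, k] <= dmax
  }
  fail[fail == 0L & !apply(depth_ok, 1, all)] <- 4L

  # rule 5: complete genotyping
  if (params$require_complete_genotyping && n > 0) {
    incomplete <- rowSums(is.na(x$calls)) > 0
    fail[fail == 0L & incomplete] <- 5L
  }

  retained <- fail == 0L
  report <- data.frame(
    rule = c(rule_names, "retained"),
    n_sites = c(vapply(seq_along(rule_names),
                       function(k) sum(fail == k), numeric(1)),
                sum(retained)),
    stringsAsFactors = FALSE
  )
  list(matrix = subset_sites(x, retained), report = report)
}
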