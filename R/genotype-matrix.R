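#' Genotype matrix
#'
#' Per-individual, per-site diploid genotype calls with positions, site
#' quality and per-genotype read depth. Calls are coded `0` (hom ref), `1`
#' (het), `2` (hom alt), `NA` (missing); see [genotype_codes()]. Indel
#' positions are carried separately so the site filter can apply the
#' indel-proximity rule; indels never enter the call matrix.
#'
#' @param sites Data frame with columns `scaffold`, `pos` (1-based bp),
#'   `ref`, `alt`, `qual` (site quality QV, >= 0). Positions must be
#'   strictly increasing within scaffold.
#' @param calls Integer matrix, sites x samples, values in \{0, 1, 2, NA\}.
#' @param depth Integer matrix, sites x samples, non-negative.
#' @param samples Character vector of individual identifiers (columns).
#' @param indels Data frame with columns `scaffold`, `pos` (1-based anchor
#'   positions of indel records), may be empty.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, calls, depth, samples,
                            indels = data.frame(scaffold = character(),
                                                pos = numeric())) {
  stopifnot(is.data.frame(sites),
            all(c("scaffold", "pos", "ref", "alt", "qual") %in% names(sites)))
  calls <- as.matrix(calls)
  depth <- as.matrix(depth)
  storage.mode(calls) <- "integer"
  storage.mode(depth) <- "integer"
  samples <- as.character(samples)
  if (nrow(calls) != nrow(sites) || nrow(depth) != nrow(sites) ||
      ncol(calls) != length(samples) || ncol(depth) != length(samples)) {
    stop("calls/depth dimensions must be n_sites x n_samples", call. = FALSE)
  }
  if (anyDuplicated(samples)) stop("sample ids must be unique", call. = FALSE)
  bad <- !is.na(calls) & !(calls %in% c(0L, 1L, 2L))
  if (any(bad)) stop("calls must be 0/1/2/NA", call. = FALSE)
  if (any(depth < 0, na.rm = TRUE)) {
    stop("depth must be non-negative", call. = FALSE)
  }
  if (any(!is.na(sites$qual) & sites$qual < 0)) {
    stop("site quality must be >= 0", call. = FALSE)
  }
  ord_ok <- tapply(sites$pos, sites$scaffold,
                   function(p) all(diff(p) > 0))
  if (nrow(sites) > 0 && !all(unlist(ord_ok))) {
    stop("positions must be strictly increasing within scaffold",
         call. = FALSE)
  }
  rownames(calls) <- rownames(depth) <- NULL
  colnames(calls) <- colnames(depth) <- samples
  sites$scaffold <- as.character(sites$scaffold)
  structure(list(sites = sites, calls = calls, depth = depth,
                 samples = samples, indels = indels),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples on %d scaffolds (%d indel positions registered)\n",
              n_sites(x), length(x$samples),
              length(unique(x$sites$scaffold)), nrow(x$indels)))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @return `n_sites()`: number of SNP sites.
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a genotype matrix by site index
#'
#' @param x A [genotype_matrix()].
#' @param i Logical or integer site index.
#' @return A `genotype_matrix` with the selected sites (indel registry and
#'   samples unchanged).
#' @export
subset_sites <- function(x, i) {
  stopifnot(inherits(x, "genotype_matrix"))
  genotype_matrix(x$sites[i, , drop = FALSE],
                  x$calls[i, , drop = FALSE],
                  x$depth[i, , drop = FALSE],
                  x$samples, x$indels)
}
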