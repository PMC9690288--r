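#' Genome layout: scaffolds, lengths and masked regions
#'
#' The coordinate frame for all analyses. Holds the scaffold table, the
#' masked intervals (hard-masked repeats, X-linked scaffolds, mitogenome)
#' and the minimum scaffold size retained for analysis (scaffolds below
#' `min_scaffold_bp` are dropped from the analyzable genome; 25 kb by
#' default).
#'
#' @param scaffolds Data frame with columns `name` and `length` (bp), or a
#'   named numeric vector of scaffold lengths.
#' @param masked Interval data frame (see [intervals()]) of masked regions,
#'   0-based half-open. Must lie within their scaffolds.
#' @param min_scaffold_bp Minimum scaffold length (bp) retained for
#'   analysis.
#' @return An object of class `genome_layout`.
#' @export
#' @examples
#' gl <- genome_layout(c(s1 = 1e6, s2 = 2e4),
#'                     masked = intervals("s1", 0, 1e4))
#' analyzable_length(gl)  # s2 dropped (< 25 kb), s1 minus mask
genome_layout <- function(scaffolds, masked = intervals(),
                          min_scaffold_bp = 25000) {
  if (!is.data.frame(scaffolds)) {
    scaffolds <- data.frame(name = names(scaffolds),
                            length = as.numeric(scaffolds),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "length") %in% names(scaffolds)))
  scaffolds$name <- as.character(scaffolds$name)
  scaffolds$length <- as.numeric(scaffolds$length)
  if (anyDuplicated(scaffolds$name)) {
    stop("scaffold names must be unique", call. = FALSE)
  }
  if (any(scaffolds$length <= 0)) {
    stop("scaffold lengths must be positive", call. = FALSE)
  }
  validate_intervals(masked)
  if (nrow(masked) > 0) {
    idx <- match(masked$scaffold, scaffolds$name)
    if (anyNA(idx)) {
      stop("masked interval on unknown scaffold: ",
           paste(unique(masked$scaffold[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    if (any(masked$start < 0) ||
        any(masked$end > scaffolds$length[idx])) {
      stop("masked interval extends outside its scaffold", call. = FALSE)
    }
    masked <- intervals_merge(masked)
  }
  structure(list(scaffolds = scaffolds, masked = masked,
                 min_scaffold_bp = min_scaffold_bp),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d scaffolds, %.3f Mb total, %.3f Mb analyzable (min scaffold %d bp, %d masked intervals)\n",
              nrow(x$scaffolds), sum(x$scaffolds$length) / 1e6,
              analyzable_length(x) / 1e6, as.integer(x$min_scaffold_bp),
              nrow(x$masked)))
  invisible(x)
}

#' @rdname genome_layout
#' @param layout A `genome_layout`.
#' @return `analyzable_scaffolds()`: the scaffold table restricted to
#'   scaffolds of at least `min_scaffold_bp`.
#' @export
analyzable_scaffolds <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  layout$scaffolds[layout$scaffolds$length >= layout$min_scaffold_bp, ,
                   drop = FALSE]
}

#' @rdname genome_layout
#' @return `analyzable_intervals()`: unmasked intervals on analyzable
#'   scaffolds (0-based half-open).
#' @export
analyzable_intervals <- function(layout) {
  sc <- analyzable_scaffolds(layout)
  if (nrow(sc) == 0) return(intervals())
  full <- intervals(sc$name, 0, sc$length)
  intervals_subtract(full, layout$masked)
}

#' @rdname genome_layout
#' @return `analyzable_length()`: total analyzable base pairs (scaffolds of
#'   at least `min_scaffold_bp`, minus masked overlap). Must be positive for
#'   a usable layout.
#' @export
analyzable_length <- function(layout) {
  intervals_total_length(analyzable_intervals(layout))
}
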