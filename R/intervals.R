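#' Interval sets
#'
#' Interval sets are plain data frames with columns `scaffold` (character),
#' `start` and `end` (numeric, 0-based half-open, `start < end`). They are
#' the internal currency for masks, planted tracts and ROH segments. The
#' algebra (merge, intersect, subtract, total length) is delegated to
#' GenomicRanges; these helpers convert between the package's 0-based
#' half-open convention and the 1-based closed convention of `GRanges` in
#' one place so no other code performs coordinate shifts.
#'
#' @param scaffold Character vector of scaffold names.
#' @param start,end Numeric vectors, 0-based half-open.
#' @return `intervals()` returns a normalized interval data frame.
#' @export
#' @examples
#' intervals(c("s1", "s1"), c(0, 5), c(10, 20))
intervals <- function(scaffold = character(), start = numeric(),
                      end = numeric()) {
  df <- data.frame(scaffold = as.character(scaffold),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("scaffold", "start", "end") %in% names(df)))
  if (nrow(df) > 0 && any(df$end <= df$start)) {
    stop("interval end must exceed start (0-based half-open)", call. = FALSE)
  }
  invisible(df)
}

# 0-based half-open -> GRanges (1-based closed)
iv_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

# GRanges -> 0-based half-open data frame
gr_to_iv <- function(gr) {
  data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' @rdname intervals
#' @param df,a,b Interval data frames.
#' @return `intervals_merge()` a sorted, merged (disjoint) interval set.
#' @export
intervals_merge <- function(df) {
  validate_intervals(df)
  if (nrow(df) == 0) return(intervals())
  gr_to_iv(GenomicRanges::reduce(GenomicRanges::sort(iv_to_gr(df))))
}

#' @rdname intervals
#' @return `intervals_intersect()` the intersection of two interval sets.
#' @export
intervals_intersect <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(intervals())
  gr_to_iv(GenomicRanges::intersect(iv_to_gr(a), iv_to_gr(b)))
}

#' @rdname intervals
#' @return `intervals_subtract()` bases of `a` not covered by `b`.
#' @export
intervals_subtract <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0) return(intervals())
  if (nrow(b) == 0) return(intervals_merge(a))
  gr_to_iv(GenomicRanges::setdiff(iv_to_gr(a), iv_to_gr(b)))
}

#' @rdname intervals
#' @return `intervals_total_length()` total covered base pairs (overlaps
#'   counted once).
#' @export
intervals_total_length <- function(df) {
  m <- intervals_merge(df)
  sum(m$end - m$start)
}
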