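#' Arctic fox study cohort table
#'
#' The sampling summary for the 43-genome arctic fox cohort (country, sample
#' area, sampling years, tissue and method, number of individuals, and how
#' many of those were newly sequenced), shipped as a package data file. The
#' deposited sequence data itself (ENA PRJEB55788) is not required by any
#' function; this table supports cohort bookkeeping only.
#'
#' @return `cohort_table()`: data frame with one row per sample area.
#' @export
#' @examples
#' cohort_size()  # 43
cohort_table <- function() {
  path <- system.file("extdata", "cohort_table.tsv", package = "erodescan",
                      mustWork = TRUE)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname cohort_table
#' @return `cohort_size()`: total number of genomes across all sample areas.
#' @export
cohort_size <- function() sum(cohort_table()$n)
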