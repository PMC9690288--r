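#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) and retains biallelic SNP records
#' with their GT and DP fields. Indel records (any allele longer than one
#' base, or the `*` spanning-deletion allele) are not genotyped but their
#' anchor positions are registered on the returned object so the
#' indel-proximity filter can use them. Multiallelic SNP records are
#' dropped. Records on scaffolds absent from `layout` are dropped, with a
#' message giving the count.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param layout A [genome_layout()]; records are restricted to its
#'   scaffolds.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (nrow(fix) == 0) {
    return(genotype_matrix(
      data.frame(scaffold = character(), pos = numeric(),
                 ref = character(), alt = character(), qual = numeric()),
      matrix(integer(), 0, length(samples)),
      matrix(integer(), 0, length(samples)),
      samples))
  }
  on_layout <- fix$CHROM %in% layout$scaffolds$name
  n_off <- sum(!on_layout)
  if (n_off > 0) {
    message(sprintf("read_vcf: dropped %d record(s) on scaffolds absent from layout", n_off))
  }

  alt <- fix$ALT
  ref <- fix$REF
  alt_alleles <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  is_indel <- mapply(function(r, aa) {
    nchar(r) != 1L || any(nchar(aa) != 1L) || any(aa == "*")
  }, ref, alt_alleles, USE.NAMES = FALSE)
  is_snp <- !is_indel & !grepl(",", alt, fixed = TRUE) &
    !is.na(alt) & alt != "." & alt != ref

  keep <- on_layout & is_snp
  indel_rows <- on_layout & is_indel
  indels <- data.frame(scaffold = fix$CHROM[indel_rows],
                       pos = as.numeric(fix$POS[indel_rows]),
                       stringsAsFactors = FALSE)

  sites <- data.frame(
    scaffold = fix$CHROM[keep],
    pos = as.numeric(fix$POS[keep]),
    ref = ref[keep],
    alt = alt[keep],
    qual = suppressWarnings(as.numeric(fix$QUAL[keep])),
    stringsAsFactors = FALSE
  )

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt))
  gtn <- gsub("|", "/", gt, fixed = TRUE)
  calls[gtn %in% c("0/0")] <- GT_HOM_REF
  calls[gtn %in% c("0/1", "1/0")] <- GT_HET
  calls[gtn %in% c("1/1")] <- GT_HOM_ALT
  dp[is.na(dp)] <- 0
  genotype_matrix(sites, calls, dp, samples, indels)
}

gt_string <- function(call, depth) {
  g <- rep("./.", length(call))
  g[!is.na(call) & call == GT_HOM_REF] <- "0/0"
  g[!is.na(call) & call == GT_HET] <- "0/1"
  g[!is.na(call) & call == GT_HOM_ALT] <- "1/1"
  paste0(g, ":", depth)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Serializes SNP sites with `GT:DP` genotype fields; registered indel
#' positions are written as placeholder deletion records (`REF = "NN"`,
#' `ALT = "N"`, genotypes missing) so that [read_vcf()] composed with
#' `write_vcf()` is the identity on calls, depths, positions and the indel
#' registry. Output is plain text (uncompressed).
#'
#' @param x A [genotype_matrix()].
#' @param path Output path.
#' @param layout Optional [genome_layout()]; when given, `##contig` header
#'   lines are emitted and records are sorted in its scaffold order.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, layout = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=erodescan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  )
  if (!is.null(layout)) {
    header <- append(header, sprintf("##contig=<ID=%s,length=%d>",
                                     layout$scaffolds$name,
                                     as.integer(layout$scaffolds$length)),
                     after = 2L)
  }
  writeLines(header, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", x$samples), collapse = "\t"), con)

  n_snp <- n_sites(x)
  n_ind <- nrow(x$indels)
  if (n_snp + n_ind == 0) return(invisible(path))

  geno_snp <- if (n_snp > 0) {
    vapply(seq_len(n_snp), function(i) {
      paste(gt_string(x$calls[i, ], x$depth[i, ]), collapse = "\t")
    }, character(1))
  } else character()
  missing_geno <- paste(rep("./.:0", length(x$samples)), collapse = "\t")

  rec <- data.frame(
    scaffold = c(x$sites$scaffold, x$indels$scaffold),
    pos = c(x$sites$pos, x$indels$pos),
    ref = c(x$sites$ref, rep("NN", n_ind)),
    alt = c(x$sites$alt, rep("N", n_ind)),
    qual = c(ifelse(is.na(x$sites$qual), ".",
                    format(x$sites$qual, trim = TRUE, scientific = FALSE)),
             rep(".", n_ind)),
    geno = c(geno_snp, rep(missing_geno, n_ind)),
    stringsAsFactors = FALSE
  )
  scaff_order <- if (!is.null(layout)) layout$scaffolds$name else
    unique(rec$scaffold)
  rec <- rec[order(match(rec$scaffold, scaff_order), rec$pos), , drop = FALSE]
  lines <- paste(rec$scaffold, format(rec$pos, trim = TRUE, scientific = FALSE),
                 ".", rec$ref, rec$alt, rec$qual, ".", ".", "GT:DP",
                 rec$geno, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read and write BED3 interval files
#'
#' BED files are 0-based half-open, matching the package's internal interval
#' convention, so no coordinate shift is applied. Intervals are normalized
#' (sorted, merged) on read.
#'
#' @param path Path to a 3-column BED file.
#' @return `read_bed()`: a merged interval data frame (see [intervals()]).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(intervals())
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("scaffold", "start", "end"),
                   colClasses = c("character", "numeric", "numeric"))
  if (any(df$end <= df$start)) {
    stop("malformed BED: end <= start at line ",
         which(df$end <= df$start)[1], call. = FALSE)
  }
  intervals_merge(df)
}

#' @rdname read_bed
#' @param df Interval data frame.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  write.table(format(df, trim = TRUE, scientific = FALSE), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated table with one row per individual: columns `sample`,
#' `population`, `year` and `mean_coverage` (fold coverage, > 0).
#'
#' @param path Path to the TSV file.
#' @return Data frame of metadata.
#' @export
read_metadata <- function(path) {
  md <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("sample", "population", "mean_coverage")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(md$mean_coverage <= 0)) {
    stop("mean_coverage must be positive", call. = FALSE)
  }
  md
}

#' Check that metadata covers every sample in a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param metadata Data frame from [read_metadata()].
#' @return `metadata` reordered to the matrix's sample order, invisibly
#'   usable downstream. Errors if any sample lacks exactly one row.
#' @export
check_samples <- function(x, metadata) {
  stopifnot(inherits(x, "genotype_matrix"))
  idx <- match(x$samples, metadata$sample)
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         paste(x$samples[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(metadata$sample)) {
    stop("duplicated sample ids in metadata", call. = FALSE)
  }
  metadata[idx, , drop = FALSE]
}

#' Read a variant impact annotation table
#'
#' Tab-separated table with columns `scaffold`, `pos`, `ref`, `alt`,
#' `category`; categories must be `LOW` (synonymous), `MODERATE` (missense)
#' or `HIGH` (loss of function), matching a flattened snpEff/VEP export.
#'
#' @param path Path to the TSV file.
#' @return Data frame of annotated sites.
#' @export
read_impact_table <- function(path) {
  it <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("scaffold", "pos", "category")
  if (!all(need %in% names(it))) {
    stop("impact table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(it$category), impact_categories())
  if (length(bad) > 0) {
    stop("unknown impact categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  it
}

#' @rdname read_impact_table
#' @return `impact_categories()`: the three recognized categories, ordered
#'   by increasing predicted severity.
#' @export
impact_categories <- function() c("LOW", "MODERATE", "HIGH")
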