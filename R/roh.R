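#' ROH calling parameters
#'
#' Sliding-window run-of-homozygosity parameters, matching the conventional
#' whole-genome scan settings for resequencing data: 200-SNP windows with at
#' most 3 heterozygous and 5 missing calls, a SNP belongs to a homozygous
#' run when at least 5% of the windows containing it are homozygous, and a
#' run is reported as a ROH when it has at least 100 SNPs, spans at least
#' 100 kb, has at least one SNP per 50 kb, and contains no inter-SNP gap
#' above 1000 kb.
#'
#' @param window_snp Window size, SNPs.
#' @param window_het_max Maximum heterozygous calls per homozygous window.
#' @param window_missing_max Maximum missing calls per homozygous window.
#' @param hit_threshold Minimum fraction of containing windows that must be
#'   homozygous for a SNP to join a run, in (0, 1].
#' @param seg_min_snp Minimum SNPs per reported segment.
#' @param seg_min_kb Minimum segment span, kb.
#' @param density_kb_per_snp Maximum kb per SNP in a reported segment.
#' @param gap_max_kb Maximum gap between neighbouring member SNPs, kb.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 200, window_het_max = 3,
                       window_missing_max = 5, hit_threshold = 0.05,
                       seg_min_snp = 100, seg_min_kb = 100,
                       density_kb_per_snp = 50, gap_max_kb = 1000) {
  stopifnot(window_snp >= 1, window_het_max >= 0, window_missing_max >= 0,
            hit_threshold > 0, hit_threshold <= 1, seg_min_snp >= 1,
            seg_min_kb > 0, density_kb_per_snp > 0, gap_max_kb > 0)
  structure(list(window_snp = as.integer(window_snp),
                 window_het_max = as.integer(window_het_max),
                 window_missing_max = as.integer(window_missing_max),
                 hit_threshold = hit_threshold,
                 seg_min_snp = as.integer(seg_min_snp),
                 seg_min_kb = seg_min_kb,
                 density_kb_per_snp = density_kb_per_snp,
                 gap_max_kb = gap_max_kb),
            class = "roh_params")
}

#' Coalescence-age model for ROH lengths
#'
#' A ROH of length L Mb is dated to g = 100/(2 r L) generations before
#' present. With the silver fox recombination rate r = 0.6 cM/Mb, the bin
#' edges 0.1 / 2 / 8 Mb correspond to roughly 833 / 42 / 10 generations
#' (conventionally rounded to 850 / 45 / 10): ROH longer than 100 kb trace
#' to historical ancestors, 2-8 Mb to an intermediate period, and > 8 Mb to
#' recent inbreeding.
#'
#' @param r Recombination rate, cM per Mb.
#' @param generation_time Generation time in years (for converting g to
#'   calendar time; not used in the decomposition itself).
#' @return `age_model()`: a list with `r`, `generation_time` and the bin
#'   table from [roh_age_bins()].
#' @export
age_model <- function(r = 0.6, generation_time = 2) {
  stopifnot(r > 0, generation_time > 0)
  structure(list(r = r, generation_time = generation_time,
                 bins = roh_age_bins()),
            class = "age_model")
}

#' @rdname age_model
#' @return `roh_age_bins()`: data frame of bins (`historical` 0.1-2 Mb,
#'   `intermediate` 2-8 Mb, `recent` > 8 Mb), half-open on the left:
#'   a segment of length L falls in bin k when min_mb < L <= max_mb.
#' @export
roh_age_bins <- function() {
  data.frame(bin = c("historical", "intermediate", "recent"),
             min_mb = c(0.1, 2, 8), max_mb = c(2, 8, Inf),
             stringsAsFactors = FALSE)
}

#' Generations to the common ancestor of a ROH
#'
#' g = 100/(2 r L): the expected number of generations back to the common
#' ancestor of the two haplotypes forming a run of homozygosity of length
#' L Mb, given recombination rate r cM/Mb.
#'
#' @param length_mb ROH length, Mb (> 0).
#' @param r Recombination rate, cM/Mb (> 0).
#' @return Generations (numeric, vectorized over `length_mb`).
#' @export
#' @examples
#' age_of_length(0.1)  # ~833 generations, conventionally rounded to 850
#' age_of_length(8)    # ~10.4 generations
age_of_length <- function(length_mb, r = 0.6) {
  if (any(length_mb <= 0) || r <= 0) {
    stop("length and recombination rate must be positive", call. = FALSE)
  }
  100 / (2 * r * length_mb)
}

#' Per-SNP homozygous-window hit fractions
#'
#' Slides a `window_snp`-wide window over one scaffold's ordered genotype
#' calls; a window is homozygous when it contains at most `window_het_max`
#' heterozygous and `window_missing_max` missing calls. Each SNP's hit
#' fraction is the proportion of windows containing it (only windows fully
#' inside the scaffold's SNP list) that are homozygous. Scaffolds with fewer
#' SNPs than the window size are evaluated against a single truncated window
#' covering all their SNPs.
#'
#' @param calls Integer genotype vector for one scaffold (ordered by
#'   position): 0/1/2/NA as in [genotype_codes()].
#' @param params A [roh_params()].
#' @return Numeric vector of per-SNP hit fractions in [0, 1].
#' @export
window_hit_fractions <- function(calls, params = roh_params()) {
  n <- length(calls)
  if (n == 0) return(numeric())
  w <- params$window_snp
  het <- as.integer(!is.na(calls) & calls == GT_HET)
  mis <- as.integer(is.na(calls))
  if (n < w) {
    ok <- sum(het) <= params$window_het_max &&
      sum(mis) <= params$window_missing_max
    return(rep(as.numeric(ok), n))
  }
  # window i covers SNPs i..i+w-1, i = 1..n-w+1
  ch <- c(0, cumsum(het))
  cm <- c(0, cumsum(mis))
  starts <- seq_len(n - w + 1)
  hom <- (ch[starts + w] - ch[starts]) <= params$window_het_max &
    (cm[starts + w] - cm[starts]) <= params$window_missing_max
  # SNP j is in windows max(1, j-w+1) .. min(n-w+1, j)
  chom <- c(0, cumsum(as.numeric(hom)))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(n - w + 1L, j)
  (chom[hi + 1] - chom[lo]) / (hi - lo + 1)
}

# Retention rules applied to a candidate run of member SNPs.
segment_passes <- function(pos, params) {
  n <- length(pos)
  # half-open [pos1 - 1, posn): spans both end SNPs
  len_bp <- pos[n] - (pos[1] - 1)
  n >= params$seg_min_snp &&
    len_bp >= params$seg_min_kb * 1000 &&
    n / (len_bp / 1000) >= 1 / params$density_kb_per_snp
}

#' Call runs of homozygosity for one individual
#'
#' Computes per-SNP hit fractions per scaffold ([window_hit_fractions()]),
#' takes maximal runs of consecutive SNPs with hit fraction at least
#' `hit_threshold`, splits runs at inter-SNP gaps above `gap_max_kb`, and
#' retains segments satisfying the minimum SNP count, minimum span and
#' minimum SNP density rules. Segment extent is first to last member SNP
#' (reported 0-based half-open, so `length = end - start` covers both end
#' SNPs).
#'
#' @param sites Data frame with `scaffold` and `pos` (1-based), ordered.
#' @param calls Integer genotype vector aligned with `sites`.
#' @param params A [roh_params()].
#' @param individual Identifier recorded on the output rows.
#' @return Data frame of segments: `individual`, `scaffold`, `start`, `end`
#'   (0-based half-open), `n_snps`, `length_bp`; non-overlapping and sorted.
#' @export
call_roh <- function(sites, calls, params = roh_params(),
                     individual = NA_character_) {
  stopifnot(length(calls) == nrow(sites))
  out <- list()
  for (sc in unique(sites$scaffold)) {
    idx <- which(sites$scaffold == sc)
    pos <- sites$pos[idx]
    frac <- window_hit_fractions(calls[idx], params)
    in_run <- frac >= params$hit_threshold
    if (!any(in_run)) next
    r <- rle(in_run)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      run_pos <- pos[starts[k]:ends[k]]
      # split at gaps > gap_max_kb between neighbouring member SNPs
      gap_break <- which(diff(run_pos) > params$gap_max_kb * 1000)
      piece_start <- c(1, gap_break + 1)
      piece_end <- c(gap_break, length(run_pos))
      for (p in seq_along(piece_start)) {
        pp <- run_pos[piece_start[p]:piece_end[p]]
        if (segment_passes(pp, params)) {
          out[[length(out) + 1]] <- data.frame(
            individual = individual, scaffold = sc,
            start = pp[1] - 1, end = pp[length(pp)],
            n_snps = length(pp),
            length_bp = pp[length(pp)] - (pp[1] - 1),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(individual = character(), scaffold = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call ROH for every individual in a genotype matrix
#'
#' @param x A (filtered) [genotype_matrix()].
#' @param params A [roh_params()].
#' @return Data frame of segments across individuals (see [call_roh()]).
#' @export
call_roh_all <- function(x, params = roh_params()) {
  stopifnot(inherits(x, "genotype_matrix"))
  segs <- lapply(x$samples, function(s) {
    call_roh(x$sites, x$calls[, s], params, individual = s)
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient F_ROH with age decomposition
#'
#' F_ROH is the fraction of the analyzable genome covered by ROH. Segments
#' are partitioned by length into the coalescence-age bins of
#' [roh_age_bins()] via g = 100/(2 r L); per-bin fractions sum exactly to
#' the total.
#'
#' @param segments Segment data frame from [call_roh_all()] (or
#'   [call_roh()]; an `individual` column is required).
#' @param layout A [genome_layout()] (denominator = analyzable length).
#' @param model An [age_model()].
#' @param individuals Individuals to report (default: those present in
#'   `segments`); pass the full sample list to include zero rows.
#' @return Data frame per individual: `froh_total`, `froh_historical`,
#'   `froh_intermediate`, `froh_recent`, `n_segments`, `denominator_bp`.
#' @export
froh <- function(segments, layout, model = age_model(),
                 individuals = NULL) {
  stopifnot(inherits(layout, "genome_layout"), inherits(model, "age_model"))
  denom <- analyzable_length(layout)
  if (denom <= 0) stop("layout has no analyzable sequence", call. = FALSE)
  if (is.null(individuals)) individuals <- unique(segments$individual)
  bins <- model$bins
  rows <- lapply(individuals, function(ind) {
    seg <- segments[segments$individual == ind, , drop = FALSE]
    len_mb <- seg$length_bp / 1e6
    binned <- vapply(seq_len(nrow(bins)), function(k) {
      sum(seg$length_bp[len_mb > bins$min_mb[k] & len_mb <= bins$max_mb[k]])
    }, numeric(1))
    data.frame(individual = ind,
               froh_total = sum(binned) / denom,
               froh_historical = binned[1] / denom,
               froh_intermediate = binned[2] / denom,
               froh_recent = binned[3] / denom,
               n_segments = nrow(seg),
               denominator_bp = denom,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate segments with coalescence age
#'
#' Adds the age bin and the point age g = 100/(2 r L) of each segment.
#'
#' @param segments Segment data frame from [call_roh_all()].
#' @param model An [age_model()].
#' @return `segments` with `length_mb`, `age_bin` and `g` columns; segments
#'   no longer than the smallest bin edge get `age_bin = NA`.
#' @export
annotate_segment_ages <- function(segments, model = age_model()) {
  bins <- model$bins
  len_mb <- segments$length_bp / 1e6
  bin <- rep(NA_character_, nrow(segments))
  for (k in seq_len(nrow(bins))) {
    bin[len_mb > bins$min_mb[k] & len_mb <= bins$max_mb[k]] <- bins$bin[k]
  }
  segments$length_mb <- len_mb
  segments$age_bin <- bin
  segments$g <- age_of_length(len_mb, model$r)
  segments
}
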