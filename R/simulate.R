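#' Simulation configuration
#'
#' Describes a synthetic cohort: the genome layout, one or more populations
#' (each with its own inbreeding profile), the site-spacing model, the read
#' model and the deleterious-variant model. All randomness downstream flows
#' from `seed`, so identical configurations give bit-identical cohorts.
#'
#' Defaults emulate the study conditions the package is aimed at: a mean
#' inter-SNP spacing of 1 kb (the order of magnitude of a few million
#' segregating sites on a ~2 Gb canid genome), per-site background
#' heterozygosity `theta_bg = 0.2` at segregating sites (~0.2 het/kb),
#' read depth 24x, sequencing error 1%, silver-fox recombination rate
#' 0.6 cM/Mb, and coalescence-age bins represented by the age of each bin's
#' geometric-mean length (186 / 21 generations for the historical and
#' intermediate bins; 10 generations, the bin-edge age, for the open-ended
#' recent bin), so planted tracts spread across their bin rather than
#' piling up at its lower edge.
#'
#' @param layout A [genome_layout()].
#' @param populations Named list of population specs from [pop_spec()].
#' @param spacing_mean Mean inter-SNP distance, bp (geometric gaps).
#' @param bin_ages Representative tract ages (generations) for the
#'   historical / intermediate / recent bins, used to draw tract lengths.
#' @param r Recombination rate, cM per Mb.
#' @param load_sites Named integer vector: deleterious site counts per
#'   impact category (`LOW`, `MODERATE`, `HIGH`).
#' @param load_alt_freq Named numeric vector: alt (deleterious) allele
#'   frequency per category, each in (0, 1).
#' @param n_struct_sites Number of neutral sites with population-specific
#'   allele frequencies (Balding-Nichols model), giving PCA-visible
#'   structure. 0 disables.
#' @param struct_fst Divergence parameter of the Balding-Nichols draw.
#' @param depth_mean Mean read depth (Poisson lambda), fold coverage.
#' @param epsilon Per-read sequencing error probability, in [0, 0.5).
#' @param tract_alt_freq Probability that a site inside a planted tract is
#'   homozygous for the alternate rather than the reference allele.
#' @param min_tract_gap Minimum separation (bp) enforced between planted
#'   tracts, keeping their boundaries identifiable.
#' @param site_qual Site quality (QV) written for every simulated site.
#' @param seed Integer seed for all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(layout,
                       populations = list(popA = pop_spec(n = 5)),
                       spacing_mean = 1000,
                       bin_ages = c(historical = 186, intermediate = 21,
                                    recent = 10),
                       r = 0.6,
                       load_sites = c(LOW = 4000, MODERATE = 2000,
                                      HIGH = 800),
                       load_alt_freq = c(LOW = 0.3, MODERATE = 0.1,
                                         HIGH = 0.05),
                       n_struct_sites = 0,
                       struct_fst = 0.1,
                       depth_mean = 24,
                       epsilon = 0.01,
                       tract_alt_freq = 0.5,
                       min_tract_gap = 50000,
                       site_qual = 60,
                       seed = 1) {
  stopifnot(inherits(layout, "genome_layout"),
            length(populations) >= 1,
            !is.null(names(populations)),
            spacing_mean >= 1, r > 0, depth_mean > 0,
            epsilon >= 0, epsilon < 0.5,
            all(load_alt_freq > 0), all(load_alt_freq < 1),
            all(names(load_sites) %in% impact_categories()))
  for (p in populations) {
    stopifnot(inherits(p, "pop_spec"))
    if (sum(p$froh_targets) > 1) {
      stop("per-bin F targets must sum to <= 1", call. = FALSE)
    }
    if (p$theta_bg < 0 || p$theta_bg >= 1) {
      stop("theta_bg must lie in [0, 1)", call. = FALSE)
    }
  }
  structure(list(layout = layout, populations = populations,
                 spacing_mean = spacing_mean, bin_ages = bin_ages, r = r,
                 load_sites = load_sites, load_alt_freq = load_alt_freq,
                 n_struct_sites = n_struct_sites, struct_fst = struct_fst,
                 depth_mean = depth_mean, epsilon = epsilon,
                 tract_alt_freq = tract_alt_freq,
                 min_tract_gap = min_tract_gap, site_qual = site_qual,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param n Number of individuals in the population.
#' @param theta_bg Background per-site heterozygosity probability at
#'   segregating sites, in [0, 1).
#' @param froh_targets Named fractions of the analyzable genome to plant as
#'   identity-by-descent tracts per age bin (`historical`, `intermediate`,
#'   `recent`); must sum to <= 1 and to <= 0.9 for feasible placement.
#' @param f_load Inbreeding coefficient governing genotype frequencies at
#'   deleterious sites: P(hom alt) = p^2 + F p(1-p), P(het) = 2p(1-p)(1-F).
#' @param tract_het_noise Per-site probability of a heterozygous call inside
#'   a planted tract (0 = perfectly homozygous tracts; use small values to
#'   stress the window het tolerance).
#' @param year Sampling year recorded in the metadata.
#' @return `pop_spec()`: a list of class `pop_spec`.
#' @export
pop_spec <- function(n,
                     theta_bg = 0.2,
                     froh_targets = c(historical = 0.10,
                                      intermediate = 0.05, recent = 0.10),
                     f_load = 0.2,
                     tract_het_noise = 0,
                     year = 2019) {
  stopifnot(n >= 1, f_load >= 0, f_load <= 1,
            tract_het_noise >= 0, tract_het_noise < 1)
  froh_targets <- froh_targets[c("historical", "intermediate", "recent")]
  if (anyNA(froh_targets)) {
    stop("froh_targets must name historical, intermediate and recent",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), theta_bg = theta_bg,
                 froh_targets = froh_targets, f_load = f_load,
                 tract_het_noise = tract_het_noise, year = year),
            class = "pop_spec")
}

#' Expected tract length for a coalescence age
#'
#' Inverts the age mapping g = 100/(2 r L): a tract coalescing g
#' generations back has expected length 100/(2 r g) Mb.
#'
#' @param g Age in generations.
#' @param r Recombination rate, cM/Mb.
#' @return Expected length, Mb.
#' @export
expected_tract_length_mb <- function(g, r = 0.6) {
  stopifnot(all(g > 0), r > 0)
  100 / (2 * r * g)
}

#' Draw identity-by-descent tract lengths
#'
#' Tract lengths for a bin of representative age `g` are exponential with
#' mean 100/(2 r g) Mb (the standard coalescent expectation), optionally
#' truncated to the bin's length range by inverse-CDF sampling.
#'
#' @param n Number of draws.
#' @param g Representative age, generations.
#' @param r Recombination rate, cM/Mb.
#' @param min_mb,max_mb Truncation bounds, Mb (default untruncated).
#' @return Numeric vector of lengths in Mb.
#' @export
draw_tract_lengths <- function(n, g, r = 0.6, min_mb = 0, max_mb = Inf) {
  stopifnot(n >= 0, g > 0, r > 0, min_mb >= 0, max_mb > min_mb)
  mean_mb <- expected_tract_length_mb(g, r)
  if (n == 0) return(numeric())
  # inverse CDF of the exponential restricted to (min_mb, max_mb]
  flo <- 1 - exp(-min_mb / mean_mb)
  fhi <- 1 - exp(-max_mb / mean_mb)
  u <- flo + runif(n) * (fhi - flo)
  -mean_mb * log(1 - u)
}

# Draw lengths for one bin until the planted total lies within +/-10%
# relative of target_bp. Draws exceeding the band are re-drawn; infeasible
# combinations (e.g. a target smaller than the bin's minimum tract) error.
draw_bin_lengths <- function(target_bp, g, r, min_mb, max_mb,
                             max_attempts = 10000) {
  if (target_bp <= 0) return(numeric())
  lo <- 0.9 * target_bp
  hi <- 1.1 * target_bp
  if (min_mb * 1e6 > hi) {
    stop(sprintf("infeasible bin target: %.0f bp but minimum tract is %.0f bp",
                 target_bp, min_mb * 1e6), call. = FALSE)
  }
  # a draw sequence can dead-end (remaining gap below the bin's minimum
  # tract length), so stalled sequences are discarded and re-drawn whole
  for (restart in seq_len(max_attempts %/% 50)) {
    lens <- numeric()
    total <- 0
    rejects <- 0
    while (total < lo && rejects <= 50) {
      len <- round(draw_tract_lengths(1, g, r, min_mb, max_mb) * 1e6)
      if (total + len <= hi) {
        lens <- c(lens, len)
        total <- total + len
      } else {
        rejects <- rejects + 1
      }
    }
    if (total >= lo) return(lens)
  }
  stop("could not reach bin target within tolerance; target likely infeasible",
       call. = FALSE)
}

#' Plant identity-by-descent tracts of known age class
#'
#' Draws tract lengths per age bin (exponential with mean 100/(2 r g) Mb,
#' truncated to the bin's length range), re-drawing until each bin's planted
#' total is within 10% relative of its target fraction of the analyzable
#' genome, then places all tracts uniformly at random on unmasked analyzable
#' sequence without overlap and with at least `min_gap_bp` separation.
#'
#' @param layout A [genome_layout()].
#' @param targets Named fractions (`historical`, `intermediate`, `recent`)
#'   of the analyzable genome; must total <= 0.9.
#' @param ages Representative ages per bin, generations.
#' @param r Recombination rate, cM/Mb.
#' @param min_gap_bp Minimum separation between placed tracts, bp.
#' @param bins Age-bin table from [roh_age_bins()].
#' @param max_restarts Placement restarts before giving up.
#' @return Interval data frame with columns `scaffold`, `start`, `end`
#'   (0-based half-open) and `bin`.
#' @export
plant_roh <- function(layout, targets,
                      ages = c(historical = 186, intermediate = 21,
                               recent = 10),
                      r = 0.6, min_gap_bp = 50000,
                      bins = roh_age_bins(), max_restarts = 20) {
  stopifnot(inherits(layout, "genome_layout"))
  targets <- targets[bins$bin]
  targets[is.na(targets)] <- 0
  an_len <- analyzable_length(layout)
  if (an_len <= 0) stop("layout has no analyzable sequence", call. = FALSE)
  if (sum(targets) > 0.9) {
    stop("total tract targets exceed 90% of the analyzable genome",
         call. = FALSE)
  }
  free0 <- analyzable_intervals(layout)

  for (restart in seq_len(max_restarts)) {
    lens <- list()
    for (k in seq_len(nrow(bins))) {
      lens[[bins$bin[k]]] <- draw_bin_lengths(
        targets[[bins$bin[k]]] * an_len, ages[[bins$bin[k]]], r,
        bins$min_mb[k], bins$max_mb[k])
    }
    tl <- data.frame(
      bin = rep(names(lens), lengths(lens)),
      len = unlist(lens, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    if (nrow(tl) == 0) {
      return(data.frame(scaffold = character(), start = numeric(),
                        end = numeric(), bin = character(),
                        stringsAsFactors = FALSE))
    }
    tl <- tl[order(-tl$len), , drop = FALSE]  # longest first
    free <- free0
    placed <- vector("list", nrow(tl))
    ok <- TRUE
    for (i in seq_len(nrow(tl))) {
      len <- tl$len[i]
      widths <- free$end - free$start
      fits <- which(widths >= len)
      if (length(fits) == 0) { ok <- FALSE; break }
      slack <- widths[fits] - len + 1
      j <- fits[sample.int(length(fits), 1, prob = slack)]
      offset <- floor(runif(1) * (widths[j] - len + 1))
      start <- free$start[j] + offset
      placed[[i]] <- data.frame(scaffold = free$scaffold[j], start = start,
                                end = start + len, bin = tl$bin[i],
                                stringsAsFactors = FALSE)
      # split the chosen free slot around the tract plus its buffer
      b_lo <- max(free$start[j], start - min_gap_bp)
      b_hi <- min(free$end[j], start + len + min_gap_bp)
      pieces <- data.frame(
        scaffold = free$scaffold[j],
        start = c(free$start[j], b_hi),
        end = c(b_lo, free$end[j]),
        stringsAsFactors = FALSE)
      pieces <- pieces[pieces$end > pieces$start, , drop = FALSE]
      free <- rbind(free[-j, , drop = FALSE], pieces)
    }
    if (ok) {
      out <- do.call(rbind, placed)
      out <- out[order(out$scaffold, out$start), , drop = FALSE]
      rownames(out) <- NULL
      return(out)
    }
  }
  stop("could not place tracts after ", max_restarts,
       " restarts; targets likely infeasible on this layout", call. = FALSE)
}

# Sample n distinct 1-based positions uniformly over an interval set.
sample_positions <- function(iv, n) {
  if (n == 0) {
    return(data.frame(scaffold = character(), pos = numeric(),
                      stringsAsFactors = FALSE))
  }
  widths <- iv$end - iv$start
  total <- sum(widths)
  stopifnot(total >= n)
  cw <- cumsum(widths)
  pick <- function(m) {
    u <- floor(runif(m) * total)
    j <- findInterval(u, c(0, cw), rightmost.closed = TRUE)
    pos0 <- iv$start[j] + (u - c(0, cw)[j])
    data.frame(scaffold = iv$scaffold[j], pos = pos0 + 1,
               stringsAsFactors = FALSE)
  }
  out <- unique(pick(n))
  while (nrow(out) < n) {
    out <- unique(rbind(out, pick(n - nrow(out))))
  }
  out[seq_len(n), , drop = FALSE]
}

# TRUE for sites falling inside an interval set (pos is 1-based).
positions_in_intervals <- function(scaffold, pos, iv) {
  inside <- logical(length(pos))
  if (nrow(iv) == 0 || length(pos) == 0) return(inside)
  for (sc in unique(iv$scaffold)) {
    rows <- iv$scaffold == sc
    st <- sort(iv$start[rows])
    en <- iv$end[rows][order(iv$start[rows])]
    sel <- which(scaffold == sc)
    if (length(sel) == 0) next
    p0 <- pos[sel] - 1
    j <- findInterval(p0, st)
    inside[sel] <- j > 0 & p0 < en[pmax(j, 1)]
  }
  inside
}

rand_alleles <- function(n) {
  nt <- c("A", "C", "G", "T")
  ref <- nt[sample.int(4, n, replace = TRUE)]
  shift <- sample.int(3, n, replace = TRUE)
  alt <- nt[(match(ref, nt) - 1 + shift) %% 4 + 1]
  cbind(ref, alt)
}

# Genotypes at deleterious/structured sites under an inbreeding coefficient:
# P(hom alt) = p^2 + F p q, P(het) = 2 p q (1 - F), rest hom ref.
rgeno_f <- function(n, p, f) {
  q <- 1 - p
  p_hom <- p^2 + f * p * q
  p_het <- 2 * p * q * (1 - f)
  u <- runif(n)
  ifelse(u < p_hom, GT_HOM_ALT, ifelse(u < p_hom + p_het, GT_HET, GT_HOM_REF))
}

#' Simulate a multi-population cohort with planted ROH and a truth ledger
#'
#' Places segregating sites along the analyzable genome with geometric
#' inter-site gaps, plants per-individual identity-by-descent tracts per age
#' bin ([plant_roh()]), fills background genotypes (heterozygous with
#' probability `theta_bg` outside tracts; homozygous inside), adds
#' optional population-structured neutral sites and impact-annotated
#' deleterious sites whose genotype frequencies follow each population's
#' inbreeding coefficient, and records everything planted in a truth
#' ledger. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` ([genotype_matrix()]), `impact`
#'   (annotation data frame), `metadata` (per-sample data frame), and
#'   `truth` (per-individual planted tracts and per-bin F, plus the
#'   generating parameters).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- config$layout
  an_iv <- analyzable_intervals(layout)
  an_len <- analyzable_length(layout)
  if (an_len <= 0) stop("layout has no analyzable sequence", call. = FALSE)

  # -- background segregating sites: geometric gaps, outside the mask
  bg <- lapply(seq_len(nrow(an_iv)), function(i) {
    width <- an_iv$end[i] - an_iv$start[i]
    n_exp <- ceiling(width / config$spacing_mean * 1.25) + 10
    gaps <- rgeom(n_exp, 1 / config$spacing_mean) + 1
    pos0 <- an_iv$start[i] + cumsum(gaps) - 1
    pos0 <- pos0[pos0 < an_iv$end[i]]
    data.frame(scaffold = an_iv$scaffold[i], pos = pos0 + 1,
               stringsAsFactors = FALSE)
  })
  bg <- do.call(rbind, bg)
  bg$kind <- "background"

  # -- structured neutral sites (Balding-Nichols per-population frequencies)
  npop <- length(config$populations)
  struct <- sample_positions(an_iv, config$n_struct_sites)
  struct_freq <- NULL
  if (config$n_struct_sites > 0) {
    struct$kind <- "struct"
    p_anc <- runif(config$n_struct_sites, 0.05, 0.95)
    fst <- config$struct_fst
    shape <- (1 - fst) / fst
    struct_freq <- vapply(seq_len(npop), function(k) {
      pmin(pmax(rbeta(config$n_struct_sites, p_anc * shape,
                      (1 - p_anc) * shape), 0.01), 0.99)
    }, numeric(config$n_struct_sites))
    colnames(struct_freq) <- names(config$populations)
  }

  # -- deleterious sites per impact category
  cats <- rep(names(config$load_sites), config$load_sites)
  del <- sample_positions(an_iv, length(cats))
  if (length(cats) > 0) {
    del$kind <- "deleterious"
    del$category <- cats
  }

  sites <- rbind(bg[c("scaffold", "pos", "kind")],
                 if (nrow(struct) > 0) struct[c("scaffold", "pos", "kind")],
                 if (nrow(del) > 0) del[c("scaffold", "pos", "kind")])
  sites$category <- NA_character_
  if (nrow(del) > 0) {
    sites$category[sites$kind == "deleterious"] <- del$category
  }
  # collisions between site classes are rare; keep first occurrence
  dup <- duplicated(sites[c("scaffold", "pos")])
  keep_struct <- !dup[sites$kind == "struct"]
  sites <- sites[!dup, , drop = FALSE]
  if (!is.null(struct_freq)) {
    struct_freq <- struct_freq[keep_struct, , drop = FALSE]
  }
  scaff_order <- match(sites$scaffold, layout$scaffolds$name)
  ord <- order(scaff_order, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  n_site <- nrow(sites)
  is_bg <- sites$kind == "background"
  is_struct <- sites$kind == "struct"
  is_del <- sites$kind == "deleterious"
  struct_rows <- which(is_struct)
  # struct_freq rows follow the original struct order; map to sorted order
  if (!is.null(struct_freq)) {
    key_struct <- paste(struct$scaffold[keep_struct],
                        struct$pos[keep_struct])
    struct_freq <- struct_freq[match(paste(sites$scaffold[struct_rows],
                                           sites$pos[struct_rows]),
                                     key_struct), , drop = FALSE]
  }

  samples <- character()
  pops <- character()
  years <- numeric()
  calls <- NULL
  truth_ind <- list()
  bins <- roh_age_bins()

  for (k in seq_along(config$populations)) {
    pspec <- config$populations[[k]]
    pname <- names(config$populations)[k]
    for (i in seq_len(pspec$n)) {
      id <- sprintf("%s_%02d", pname, i)
      tracts <- plant_roh(layout, pspec$froh_targets, config$bin_ages,
                          config$r, config$min_tract_gap, bins)
      g <- rep(GT_HOM_REF, n_site)
      in_tract <- positions_in_intervals(sites$scaffold, sites$pos, tracts)
      # background model outside tracts
      out_bg <- is_bg & !in_tract
      g[out_bg] <- ifelse(runif(sum(out_bg)) < pspec$theta_bg,
                          GT_HET, GT_HOM_REF)
      # inside tracts: homozygous, allele picked by tract_alt_freq,
      # with optional het noise
      in_rows <- which(in_tract & is_bg)
      if (length(in_rows) > 0) {
        g[in_rows] <- ifelse(runif(length(in_rows)) < config$tract_alt_freq,
                             GT_HOM_ALT, GT_HOM_REF)
        if (pspec$tract_het_noise > 0) {
          noisy <- runif(length(in_rows)) < pspec$tract_het_noise
          g[in_rows[noisy]] <- GT_HET
        }
      }
      # structured and deleterious sites follow their marginal models
      # outside tracts; inside a planted tract identity-by-descent forces
      # homozygosity, with the allele picked by its frequency
      if (length(struct_rows) > 0) {
        pf <- struct_freq[, pname]
        dose <- rbinom(length(struct_rows), 2, pf)
        inside <- in_tract[struct_rows]
        dose[inside] <- 2L * (runif(sum(inside)) < pf[inside])
        g[struct_rows] <- dose
      }
      if (any(is_del)) {
        p <- config$load_alt_freq[sites$category[is_del]]
        gd <- rgeno_f(sum(is_del), p, pspec$f_load)
        inside <- in_tract[is_del]
        gd[inside] <- ifelse(runif(sum(inside)) < p[inside],
                             GT_HOM_ALT, GT_HOM_REF)
        g[is_del] <- gd
      }
      calls <- cbind(calls, g)
      samples <- c(samples, id)
      pops <- c(pops, pname)
      years <- c(years, pspec$year)
      planted_bp <- vapply(bins$bin, function(b) {
        sum(tracts$end[tracts$bin == b] - tracts$start[tracts$bin == b])
      }, numeric(1))
      truth_ind[[id]] <- list(tracts = tracts,
                              froh = planted_bp / an_len,
                              population = pname,
                              theta_bg = pspec$theta_bg,
                              f_load = pspec$f_load)
    }
  }
  colnames(calls) <- samples

  alleles <- rand_alleles(n_site)
  depth <- matrix(rpois(n_site * length(samples), config$depth_mean),
                  n_site, length(samples))
  site_df <- data.frame(scaffold = sites$scaffold, pos = sites$pos,
                        ref = alleles[, 1], alt = alleles[, 2],
                        qual = config$site_qual, stringsAsFactors = FALSE)
  mat <- genotype_matrix(site_df, calls, depth, samples)

  impact <- data.frame(scaffold = sites$scaffold[is_del],
                       pos = sites$pos[is_del],
                       ref = alleles[is_del, 1],
                       alt = alleles[is_del, 2],
                       category = sites$category[is_del],
                       stringsAsFactors = FALSE)
  metadata <- data.frame(sample = samples, population = pops, year = years,
                         mean_coverage = config$depth_mean,
                         stringsAsFactors = FALSE)
  truth <- list(individuals = truth_ind, epsilon = config$epsilon,
                depth_mean = config$depth_mean, r = config$r,
                bin_ages = config$bin_ages, analyzable_bp = an_len,
                seed = config$seed)
  list(matrix = mat, impact = impact, metadata = metadata, truth = truth)
}

#' @rdname simulate_cohort
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$populations) != 1) {
    stop("simulate_population expects a single-population config; use simulate_cohort",
         call. = FALSE)
  }
  simulate_cohort(config)
}

#' Simulate per-site read profiles
#'
#' Generates mlRho-style two-allele read profiles for every
#' individual-by-site cell: depth is Poisson(`depth_mean`); for homozygous
#' genotypes each read reports the true allele with probability
#' `1 - epsilon`; for heterozygotes each read picks one of the two alleles
#' 50:50 (in the two-allele model a sequencing error flips between them, so
#' the supporting-read count is Binomial(depth, 1/2)). Missing genotypes get
#' depth 0.
#'
#' @param x A [genotype_matrix()].
#' @param depth_mean Mean depth (Poisson lambda).
#' @param epsilon Per-read error probability, in [0, 0.5).
#' @return List of two integer matrices `ref` and `alt` (sites x samples)
#'   of reads supporting the reference and alternate allele.
#' @export
simulate_read_profiles <- function(x, depth_mean, epsilon) {
  stopifnot(inherits(x, "genotype_matrix"), depth_mean > 0,
            epsilon >= 0, epsilon < 0.5)
  n <- n_sites(x) * length(x$samples)
  depth <- matrix(rpois(n, depth_mean), n_sites(x), length(x$samples))
  depth[is.na(x$calls)] <- 0L
  alt <- matrix(0L, n_sites(x), length(x$samples))
  hom_ref <- !is.na(x$calls) & x$calls == GT_HOM_REF
  hom_alt <- !is.na(x$calls) & x$calls == GT_HOM_ALT
  het <- !is.na(x$calls) & x$calls == GT_HET
  alt[hom_ref] <- rbinom(sum(hom_ref), depth[hom_ref], epsilon)
  alt[hom_alt] <- depth[hom_alt] - rbinom(sum(hom_alt), depth[hom_alt],
                                          epsilon)
  alt[het] <- rbinom(sum(het), depth[het], 0.5)
  ref <- depth - alt
  dimnames(ref) <- dimnames(alt) <- list(NULL, x$samples)
  list(ref = ref, alt = alt)
}
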