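---
title: "Methods: quantifying genome erosion from resequencing genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying genome erosion from resequencing genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erodescan)
```

erodescan quantifies genome erosion — inbreeding, loss of heterozygosity and
the zygosity state of deleterious variation — in small, fragmented
populations from multi-sample genotype data, the situation typified by the
endangered Fennoscandian arctic fox relative to the large, well-connected
Siberian population. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic cohort generator does
and does not emulate.

## Coordinate frame and filtering

All internal intervals are 0-based half-open; VCF positions (1-based) and
BED intervals are converted only at the I/O boundary. A `genome_layout`
holds scaffold lengths, masked intervals (hard-masked repeats, X-linked
scaffolds, mitogenome) and the minimum scaffold size (default 25 kb);
the *analyzable length* — scaffolds at or above that size minus masked
overlap — is the denominator of every genome-proportion statistic.

`filter_sites()` applies, in a fixed order with first-failing-rule
attribution: scaffold-size/mask exclusion; minimum site quality (QV 30);
exclusion of SNPs within 5 bp of an indel anchor position (indel extent is
not modelled; the VCF POS anchors the rule, which keeps "within 5 bp"
well-defined); a per-sample depth window of one third to twice *that
sample's* mean coverage (genotypes outside it are dominated by mapping
artefacts near structural variation and collapsed repeats); and, by
default, complete genotyping across individuals. First-failure attribution
makes the removal report deterministic and conserves counts: attributed
removals plus retained sites always equal the input. Filtering is
idempotent, and relaxing any single threshold can only grow the retained
set — both properties are enforced by tests.

## Runs of homozygosity and the age decomposition

ROH are called per individual with a sliding-window scan: windows of 200
consecutive SNPs are *homozygous* when they contain at most 3 heterozygous
and at most 5 missing calls; a SNP joins a homozygous run when at least 5%
of the windows containing it are homozygous; runs are split at inter-SNP
gaps above 1000 kb; and a run is reported when it has ≥ 100 SNPs, spans
≥ 100 kb, and averages at least one SNP per 50 kb. The missing-call
tolerance (5) is a parameter the window rule needs but that is rarely
stated; it is exposed on `roh_params()` and kept conservative. Two edge
conventions had to be fixed: scaffolds with fewer SNPs than the window size
are evaluated against a single truncated window covering all their SNPs
(rather than being silently skipped), and a segment's extent is the first
to last member SNP, stored half-open so `length = end - start` covers both
end SNPs. The density rule is evaluated on the final segment as
`n_snps / length_kb >= 1/50`. There is no per-segment heterozygosity cap:
only the per-window rule is stated by the scan's definition, and adding
unstated rules would silently change results.

The fast implementation (cumulative sums over window flags) is verified
segment-for-segment against a brute-force direct scan that enumerates every
window, on hundreds of fuzzed genotype vectors. Two structural properties
are also enforced: calls are invariant under swapping the two homozygous
codes at any subset of sites, and flipping any homozygous call to
heterozygous never increases total ROH length.

A ROH of length $L$ Mb is dated to

$$g = \frac{100}{2 r L}$$

generations before present, with $r$ the recombination rate in cM/Mb
(default 0.6, the silver fox rate, appropriate for fox-like life
histories). The bin edges 0.1 / 2 / 8 Mb map to $g \approx 833$, $41.7$ and
$10.4$ generations — conventionally rounded to 850, 45 and 10. $F_{ROH}$ is
the summed ROH length over the analyzable length, and the per-bin fractions
(historical 0.1–2 Mb, intermediate 2–8 Mb, recent > 8 Mb, half-open on the
left) partition it exactly. Lengths are physical (Mb), not genetic map
length, so individual segment ages carry a large variance; the
decomposition is a binning device, not a per-segment clock. A generation
time of 2 years converts $g$ to calendar time when needed; nothing in the
decomposition uses it.

## Heterozygosity and the (theta, epsilon) likelihood

Genome-wide heterozygosity is reported two ways, because studies do both:
as heterozygous calls per kb of callable sequence (`het_per_kb()`; the
callable length is an explicit input since it depends on upstream
filtering), and as a maximum-likelihood estimate of the per-site
heterozygosity probability $\theta$ — the infinite-sites approximation to
the population-scaled mutation rate $4 N_e \mu$ — jointly with the
per-read error rate $\epsilon$ from read profiles, in the spirit of
mlRho-style estimators. The site likelihood is a deliberate two-allele
reduction of the four-nucleotide profile likelihood:

$$L(\theta, \epsilon) = (1 - \theta)\,
  \max_a \binom{n}{k_a} \epsilon^{k_a} (1-\epsilon)^{n-k_a}
  + \theta \binom{n}{k} 2^{-n},$$

where the homozygous term errs each read independently (maximized over
which of the two observed alleles is the true one) and the heterozygous
term draws each read from either allele 50:50 — in a two-allele world a
sequencing error flips between them, so the heterozygous term does not
depend on $\epsilon$. This keeps the $(\theta, \epsilon)$ identifiability
structure ($\epsilon$ is identified by low-level mismatches at homozygous
sites, $\theta$ by balanced profiles) at a fraction of the bookkeeping; it
is a simplification, not a reimplementation of mlRho. The likelihood is
validated against exhaustive enumeration over the latent genotype and
per-read outcomes at depths ≤ 8. Optimization is deterministic: profiles
are collapsed to unique (ref, alt) pairs with multiplicities, a 50×50
log-spaced grid is scanned, and Nelder–Mead refines from the grid optimum
on the log scale. Zero-depth profiles contribute nothing; mapping-quality
filters are assumed applied upstream of the profiles.

## Mutational load

Impact annotations (LOW = synonymous, MODERATE = missense, HIGH = loss of
function) are consumed as a table keyed by site; running the annotation is
out of scope. For each individual, homozygous-alternate and heterozygous
counts per category are divided by the *total number of alleles*, read as
2 × (annotated sites genotyped in that individual, pooled across
categories). The pooled denominator is one defensible reading of "total
alleles" — it keeps hom and het proportions on a common scale across
categories and individuals — and it is recorded in every output row so the
convention is auditable. The alternate allele is treated as the
deleterious/derived allele; no ancestral-state inference is attempted.
Bookkeeping obeys $2 n_{hom} + n_{het} \le$ denominator, with equality
exactly when no annotated genotype is homozygous reference.

## Population structure and group tests

Structure uses the variance-standardized genomic relationship matrix:
dosages $d \in \{0,1,2\}$ standardized to $(d - 2\hat p)/\sqrt{2 \hat p (1
- \hat p)}$ with $\hat p$ the sample alternate-allele frequency,
monomorphic sites excluded, averaged over sites; PCA is the
eigendecomposition, with coordinates scaled by the square root of the
eigenvalue and variance fractions normalized over all positive eigenvalues
(whether published percentages normalize over all or top-K eigenvalues is
usually unstated; all-positive is used here). No LD pruning is applied —
a fidelity choice, since the scan method itself states none. Note that in
strongly inbred cohorts the GRM diagonal (≈ 1 + F) is itself an erosion
signal, and when within-individual inbreeding exceeds between-population
drift the leading axes track individual inbreeding rather than the
population split — the shipped workflow illustrates exactly this regime,
while the population-separation property is tested on tract-free cohorts
where drift carries the signal.

Group differences in any per-individual metric use Kruskal–Wallis (via
`stats::kruskal.test`, tie-corrected) with Dunn's rank-based z tests for
pairwise follow-up, implemented in-package with mid-ranks and the
tie-corrected variance, and Holm adjustment by default (the conservative
standard when the upstream analysis names no method); the method name is
recorded in the output. Dunn z values are tested against a direct
recomputation from the rank formula, and the Kruskal–Wallis wrapper holds
its nominal type-I error within [0.04, 0.06] over $10^4$ null replicates.

## The synthetic cohort generator

Every stage needs a recovery test, so the package ships a generator that
plants what the pipeline is supposed to find and writes a truth ledger
(`simulate_cohort()`). What it emulates:

- **Sites.** Segregating sites with geometric inter-site gaps (mean 1 kb —
  the order of magnitude of a few million cohort SNPs on a ~2 Gb canid
  genome), on unmasked, analyzable sequence.
- **Background heterozygosity.** Outside planted tracts an individual is
  heterozygous at each site with probability `theta_bg` (default 0.2 per
  segregating site, ≈ 0.2 het/kb at the default spacing — fox-like rather
  than outbred-mammal-like). `theta_bg` is the simulated primitive; $N_e$
  and $\mu$ are not modelled separately.
- **Planted IBD tracts.** Per-bin target fractions of the analyzable
  genome; tract lengths are exponential with mean $100/(2 r g)$ Mb — the
  standard coalescent expectation for IBD segments of age $g$ — truncated
  to the bin's length range, re-drawn until each bin's planted total is
  within ±10% of target, and placed uniformly without overlap, avoiding
  masked sequence, with a 50 kb minimum separation so recovered segments
  are never merged across tract boundaries. The *representative age* of a
  bin is the age of the bin's geometric-mean length (186 and 21 generations
  for the historical and intermediate bins; the bin-edge age 10 for the
  open-ended recent bin). Using the bins' edge ages instead would
  concentrate all historical tracts at the very bottom of the 0.1–2 Mb
  bin — an unrepresentative reading of bins that are merely *labelled* by
  their edge ages. Tracts are perfectly homozygous by default;
  `tract_het_noise` plants heterozygous calls inside tracts to stress the
  3-het window tolerance.
- **Deleterious and structured sites.** Impact-annotated sites get
  genotypes from an inbreeding model, $P(\text{hom alt}) = p^2 + F p q$,
  $P(\text{het}) = 2 p q (1 - F)$; structured neutral sites get
  Balding–Nichols population frequencies for PCA-visible divergence.
  Inside a planted tract, identity by descent overrides both marginal
  models: every site class is homozygous there, with the allele picked by
  its frequency. (The marginal F-model therefore holds exactly only in
  configurations without tracts, which is how its goodness of fit is
  tested.)
- **Reads.** Depth is Poisson (default mean 24); homozygous sites err
  per read with probability $\epsilon$ (default 0.01); heterozygous sites
  yield Binomial(depth, ½) supporting counts.

All randomness flows from one seed; identical configurations are
bit-identical. The truth ledger records each individual's tracts, exact
per-bin planted F (tract arithmetic over the analyzable length), and the
generating parameters.

What the generator does **not** emulate: linkage disequilibrium beyond the
planted tracts, a realistic site-frequency spectrum, mapping artefacts,
genotyping error outside the read-profile layer, pedigree structure, or
coalescent variation in tract age within a bin. Passing recovery tests
therefore demonstrates that the pipeline finds what its models define,
under its own assumptions — not that those models capture every property
of real resequencing data.

## Problem sizes, tolerances and degenerate inputs

The shipped analysis workflow (`analysis/01...06`) runs a 12-individual,
two-population cohort on a 150 Mb, 7-scaffold layout (~160k sites) — large
enough that every ROH bin is feasible (a bin's target fraction must be
achievable with tracts no shorter than the bin minimum, to within the ±10%
planting band) and every qualitative contrast is resolvable, small enough
to run in about a minute. Recovery tests use one individual on a 200 Mb
layout over 20 seeds (per-bin recovered/planted ratio within ±15% on
average across seeds; single seeds can leak one tract across a bin edge
when its recovered length crosses 2 or 8 Mb, a boundary effect of order
one window span that the tract-level recovery test bounds explicitly), and
$(\theta, \epsilon)$ recovery uses $10^5$ profile sites over 10 seeds
(±25% relative). Degenerate inputs fail loudly rather than silently: zero
analyzable length, infeasible planting targets, all-zero-depth profiles,
empty annotation overlap, monomorphic-only dosage matrices and empty
groups are all errors with specific messages.
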