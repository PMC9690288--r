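# erodescan

Genome erosion scans from resequencing genotypes: runs of homozygosity,
inbreeding age decomposition and mutational load.

Small, fragmented populations — the endangered Fennoscandian arctic fox
relative to the large, connected Siberian population is the motivating case
— erode genetically: inbreeding accumulates, heterozygosity falls, and
recessive deleterious variants are increasingly exposed in homozygous
state. `erodescan` quantifies this erosion from a multi-sample VCF (GT and
per-genotype DP), a genome layout, a mask BED and a variant-impact table.
It is aimed at conservation genomicists comparing inbreeding histories and
mutational load across populations or subpopulations.

## What it computes

- **Site filtering** — minimum site quality QV ≥ 30, exclusion of SNPs
  within 5 bp of indels, per-sample depth in (mean/3, 2·mean), removal of
  masked regions and scaffolds < 25 kb, complete genotyping; with a
  per-rule removal report (`filter_sites()`).
- **Runs of homozygosity** — sliding-window caller (200-SNP windows, ≤ 3
  het; a SNP joins a run when ≥ 5% of its windows are homozygous; segments
  need ≥ 100 SNPs, ≥ 100 kb, ≥ 1 SNP / 50 kb, gaps ≤ 1000 kb), verified
  against a brute-force direct scan (`call_roh_all()`).
- **F_ROH and its age decomposition** — the fraction of the analyzable
  genome in ROH, partitioned by segment length into coalescence-age bins
  via

      g = 100 / (2 r L)

  (g generations to the common ancestor, L the ROH length in Mb, r the
  recombination rate in cM/Mb; r = 0.6, the silver fox rate, by default).
  Bin edges 0.1 / 2 / 8 Mb ≈ 850 / 45 / 10 generations (`froh()`,
  `age_of_length()`).
- **Heterozygosity** — het calls per callable kb (`het_per_kb()`) and a
  deterministic maximum-likelihood estimate of per-site heterozygosity θ
  (≈ 4·Ne·µ under infinite sites) jointly with sequencing error ε from
  two-allele read profiles (`estimate_theta()`).
- **Mutational load** — per-individual homozygous and heterozygous variant
  proportions per impact category (LOW/synonymous, MODERATE/missense,
  HIGH/LoF), over a pooled total-allele denominator
  (`load_proportions()`).
- **Structure and group tests** — variance-standardized genomic
  relationship matrix with PCA (`standardized_grm()`, `pca_grm()`);
  Kruskal–Wallis with Dunn post hoc pairwise tests, Holm-adjusted
  (`kruskal_wallis()`, `dunn_posthoc()`, `compare_groups()`).
- **A synthetic cohort generator** — plants identity-by-descent tracts of
  known age class (exponential lengths with mean 100/(2rg) Mb), background
  heterozygosity θ_bg, impact-annotated sites under an inbreeding
  coefficient, Balding–Nichols population structure and Poisson read
  profiles, with a truth ledger, so every stage has a recovery test
  (`simulate_cohort()`, `plant_roh()`, `simulate_read_profiles()`).

## Worked example: the analysis workflow

The numbered scripts under `analysis/` run a complete desk-scale study on a
synthetic 12-genome, two-population cohort (150 Mb layout, ~166k sites):
an inbred "fenno" population (planted F_ROH 0.25, 40% of it recent) against
an outbred "siberia" population (historical inbreeding only):

```sh
Rscript analysis/01_simulate.R        # cohort -> VCF/BED/TSV/truth JSON
Rscript analysis/02_filter.R          # site filters + removal report
Rscript analysis/03_roh.R             # ROH segments, F_ROH per age bin
Rscript analysis/04_heterozygosity.R  # het/kb, ML (theta, epsilon)
Rscript analysis/05_load.R            # load proportions per impact class
Rscript analysis/06_structure_stats.R # GRM/PCA + Kruskal-Wallis/Dunn
```

Output (abridged) from a run of scripts 03–06:

```
calling ROH (200-SNP windows, het max 3, hit threshold 5%)...
  220 segments; longest 16.1 Mb in fenno_04 (g ~ 5.2 generations)
mean |recovered - planted| per bin: historical 0.0014, intermediate 0.0002, recent 0.0001

het/kb by individual:
  fenno_01     0.155   ...   siberia_06   0.243
  mean epsilon-hat 0.0100 (true 0.010); theta-hat tracks theta_bg x (1 - F): r = 0.999

population means of load proportions:
  fenno    HIGH     hom 0.00131  het 0.00300
  siberia  HIGH     hom 0.00023  het 0.00487

  mean GRM diagonal: fenno 1.577, siberia 0.929
  froh_total   H =  8.308 (df 1), p = 0.003948
  froh_recent  H =  9.466 (df 1), p = 0.002093
```

Reading the numbers: the caller recovers the planted per-bin inbreeding to
a few parts per thousand of the genome; the longest recovered ROH (16.1 Mb)
dates to ~5 generations — very recent close inbreeding; the inbred
population carries *more homozygous* and *fewer heterozygous*
loss-of-function variants than the outbred one (the unmasking signature of
inbreeding); its elevated GRM diagonal (≈ 1 + F) shows the same erosion
from the relatedness side; and the rank tests resolve every contrast at
n = 6 + 6. Tables land under `results/`.

The methods vignette (`vignettes/genome-erosion-methods.Rmd`) documents the
models, parameter defaults, numerical choices and the generator's limits.

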