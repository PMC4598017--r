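---
title: "Contrasting adaptive MHC and neutral microsatellite structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrasting adaptive MHC and neutral microsatellite structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcpopgen)
```

## The scientific question

Balancing selection at immune loci — heterozygote advantage or negative
frequency-dependent selection at the MHC's peptide-binding region — is
expected to *homogenize* allele frequencies among populations: rare alleles
are protected from loss by drift, so differentiation at the selected locus
stays below what gene flow and drift alone would produce. Neutral markers
(microsatellites) record only gene flow and drift. Contrasting the two
marker classes across the same individuals therefore separates selection
from demography: weak MHC structure against strong, distance-driven
microsatellite structure is the signature of broad-scale balancing
selection; the opposite contrast would point at local adaptation.

`mhcpopgen` implements this comparative workflow end to end for the common
survey design: a short MHC class II DRB exon 2 amplicon (185 bp by default)
genotyped by pooled tagged amplicon sequencing, where 2-5 alleles
co-amplify per individual from an unknown (at least
`ceiling(5 / 2) = 3`) number of unresolvable loci, alongside a panel of
diploid microsatellites.

## Amplicon genotyping model

Raw reads carry a forward MID tag + forward primer, the insert, and the
reverse complements of the reverse primer and reverse MID.
`demultiplex()` requires *exact* tag and primer matches, inserts free of
ambiguity codes, and the exact expected insert length. Exactness is a
deliberate choice: MID schemes are designed with large pairwise tag
distances precisely so that a read either matches perfectly or is noise,
and an exact contract is fully auditable (each discarded read logs the one
rule that rejected it).

Allele calling is threshold- and rule-based, not clustering-based. The
central statistic is the **maximum per-amplicon frequency (MPAF)** of a
variant: the largest share the variant attains of any single individual's
retained reads. True alleles must reach appreciable within-individual
frequency in at least one carrier; PCR and sequencing artifacts rarely do.
`classify_variants()` applies a deterministic ladder:

1. variants below an MPAF floor (default 0.001) are discarded outright
   (`BELOW_FLOOR` — the label is ours; some name is needed for this
   mandatory outcome);
2. variants at or above the true-allele threshold (default 0.04) with a
   clean reading frame and either two independent carriers or confirmation
   in a replicated sample are promoted to `TRUE_ALLELE`; previously
   characterized alleles can be supplied as a whitelist baseline;
3. everything else is triaged in a fixed order chosen to be maximally
   conservative toward calling artifacts: 1-2 bp shadows of a co-occurring
   true allele first (the dominant PCR/sequencing error class), then stop
   codons, then frameshifts, then single-carrier variants, then variants
   that fail replicate verification; survivors are `CANDIDATE`s reported
   for manual review but excluded from genotypes.

"1-2 bp difference" is implemented as Hamming distance at most 2, which is
exact here because indel-bearing reads can never pass the length filter.
The `FRAMESHIFT` label is retained for completeness even though the length
filter makes it nearly unreachable under defaults.

Genotypes are then called per individual (`call_genotypes()`): individuals
under the depth threshold (default 150 retained reads) are discarded as
unreliable, and the allele set is the true-allele variants at or above the
MPAF threshold *within that individual*. The MPAF denominator is the
individual's total retained reads, including reads later attributed to
artifacts; the alternative (post-filter denominators) changes MPAF by at
most a few percent and would make the statistic depend on its own output.

A known limitation, visible in the synthetic data: individuals far below
the depth threshold still contribute MPAF denominators, so a one-error
read in a 10-read amplicon can push an artifact over the 4% threshold.
Such spurious promotions never reach called genotypes (their within-
individual share in any *called* individual is far below threshold), but
they do inflate the `TRUE_ALLELE` list in classification output; the
replicate-verification and whitelist mechanisms both suppress them.

## Population statistics

* **Heterozygosities** use the small-sample-unbiased gene diversity
  `(2n/(2n-1)) (1 - sum p^2)`, appropriate for the 13-56 individuals per
  region this design targets.
* **Rarefied allelic richness** is exact hypergeometric rarefaction,
  `sum_i [1 - C(N - N_i, g) / C(N, g)]`, with `g` defaulting to the
  smallest non-missing gene-copy count over population-locus combinations.
* **Nucleotide diversity** weights haplotype p-distances by carrier-count
  frequencies with the `n/(n-1)` small-sample factor.
* **AMOVA** is the one-level Excoffier decomposition of squared distances
  among sampled units. The marker classes differ only in their unit
  definitions: for the MHC, each individual contributes one unit per
  allele carried (allele *carriages*), with Jukes-Cantor distances between
  allele sequences — the natural frequency-weighted haplotype analysis when
  alleles cannot be assigned to loci; for microsatellites, units are gene
  copies with 0/1 allele-identity distances, components accumulated over
  loci; binary-encoded data use individuals with Jaccard distances.
  Permutation tests shuffle units (whole individuals, for multilocus
  genotypes) among populations, with `(b+1)/(m+1)` smoothing. If a pair of
  populations carries no molecular variance at all, Phi is reported as 0
  (no differentiation) rather than 0/0.
* **Jost's D** uses the k-population estimator with nearly unbiased
  heterozygosities (`sum n_i (n_i - 1) / (n (n - 1))` in place of
  `sum p^2`), which partitions diversity into independent within- and
  between-population components — more informative than fixation indices
  when within-population diversity is high, as at the MHC.
* **MHC-specific diversity** uses allele-frequency-free measures (the
  distinct-set genotype counts `GT`/`P_GT` and the individual
  allele-diversity index `A = |set| / max |set|`) because carriage counts
  are not genotype frequencies. Relative allele frequencies divide carrier
  counts by total carriage per population (the denominator choice is
  isolated in `relative_allele_frequencies()`).

## Multivariate co-structure

Both markers are binary-encoded (each allele a dominant presence/absence
locus) to put a multi-locus amplicon and co-dominant microsatellites on the
same footing. From there: Jaccard S3 similarity, the Euclidean-embeddable
`sqrt(1 - s)` transform, principal coordinates (Lingoes correction by
default — the standard bridge from a non-Euclidean distance to a PCA-like
space), and between-class analysis with populations as groups.

Co-inertia between the two between-class analyses is computed on the
**population-centroid tables** (weighted by sample size), and the RV
permutation test shuffles population rows. We initially implemented the
test at individual rows and found it structurally anticonservative: any two
tables that each carry some within-population block structure — even when
the two markers' structures are statistically independent — beat an
individual-permutation null, because permuting individuals destroys the
grouping itself rather than the markers' *agreement*. At the population
level the test asks the intended question (do the two markers place
populations similarly?) and is correctly calibrated under independence.
Individual projections onto the co-inertia axes are still reported for
plotting. Axes are sign-fixed (largest loading positive) for
reproducibility.

## Isolation by distance

Geographic distances are great-circle (haversine, Earth radius 6371 km),
natural-log transformed for linearity; the log base is immaterial to a
correlation statistic. `mantel()` correlates upper triangles with a
one-sided (positive-association) permutation test by default, matching the
isolation-by-distance hypothesis; `partial_mantel()` correlates residuals
given a covariate matrix and permutes the residual matrix of the focal
marker. Raw differentiation values are used (no `F/(1-F)` linearization);
geographically detached reference populations can be excluded via the
`exclude` argument rather than being hard-coded.

## Selection statistics

`ng86_dnds()` is the classical codon-counting estimator: per-position
synonymous site fractions (mutations to stops count as nonsynonymous),
differences averaged with equal weight over all shortest mutational
pathways excluding those through stop codons, Jukes-Cantor correction, and
a one-sided Z-test of `dN > dS` with a seeded codon-bootstrap standard
error. Pairs at mismatch saturation (p >= 0.75) are excluded with a
warning. `lrt()` performs the chi-square likelihood-ratio arithmetic
between externally fitted nested codon models; maximum-likelihood fitting
of the site models themselves is deliberately out of scope — the package
consumes `(label, lnL, k)` records.

## The synthetic-data generator

`sim_config()` defaults encode the emulated study: 9 populations of
13-56 individuals (269 total), a 10-allele pool for a 185-bp amplicon read
in frame offset 2 (61 codons; the fragment's true frame is configurable),
genotype-size weights 0.267/0.304/0.399/0.030 for 2/3/4/5 alleles,
11 microsatellite loci with 8 alleles each, and a read model with mean
depth 1412 at negative-binomial dispersion ~1.04 (variance matching a
reported SD of roughly the mean), 0.001/bp substitution errors, 2%
chimeras, 1% random noise reads, and log-normal amplification bias
(SD 0.3).

Design choices worth knowing:

* **F-model**: population frequencies are
  `Dirichlet(base (1 - F) / F)`, so the expected fixation index equals the
  target `F`; recovery is within a few thousandths at 9 x 50 individuals.
* **Allelic series**: pool alleles derive from one ancestral sequence by
  3-10 substitutions. Independent random sequences would differ at ~75% of
  sites — past Jukes-Cantor saturation and nothing like a real allelic
  series; the chosen divergence lands per-population nucleotide diversity
  near 0.04-0.05, as observed for such amplicons.
* **Isolation by distance** is induced by drifting the base frequencies
  along the (geographically ordered) population chain, with per-step
  intensity `ibd_slope x log(km)`. The default microsatellite slope of
  0.005 per log-km adds a few percent of extra divergence across the chain
  — enough for a clear Mantel signal without driving terminal populations
  toward fixation. The MHC slope defaults to 0 (homogenized).
* **Artifacts**: chimeras are single-crossover hybrids of two of the
  individual's own alleles; noise variants are uniform-random sequences.
  MHC genotypes are allele sets without locus structure, because loci are
  unresolvable by design; no coalescent genealogy, quality scores, or
  homopolymer-specific error model is simulated — passing tests therefore
  say nothing about quality-dependent filtering on real data.
* The default MID scheme (14 forward x 8 reverse 10-bp tags, pairwise
  Hamming distance >= 5) covers up to 112 individuals in one pooled run.

All generation is bit-reproducible from the single config seed; each stage
derives its own stream so stages can be rerun in isolation.

## Numerical and testing choices

Permutation p-values are one-sided with `(b+1)/(m+1)` smoothing
throughout. Brute-force oracles (direct sums-of-squares AMOVA, exhaustive
rarefaction enumeration, one-step codon enumeration, triangle
correlations) back the unit tests at 1e-8 tolerances. The acceptance-style
property checks run at deliberately scaled problem sizes — 9 x 50
individuals for fixation-index recovery (20 seeds per level), 100
individuals at mean depth 500 for genotype recovery (5 seeds), and 9 x 20
for the structure-contrast checks (20 seeds, 99-199 permutations) — sizes
at which the checked contrasts are already stable.

The pipeline orchestrator (`validate_config()`, `run_pipeline()`) is the
package's operational interface: a single YAML document, stage-derived
seeds, content-hashed artifacts in a `MANIFEST.json`, and a `summary.json`
holding the headline marker contrast (AMOVA components, mean pairwise
differentiation, the Mantel pair, RV, the diversity correlation, dN/dS and
any configured LRTs).

## Known limitations

* Tag/primer matching has no mismatch tolerance; reads with sequencing
  errors inside tags or primers are discarded, not rescued.
* MPAF-based classification degrades for amplicons far below the depth
  threshold (see above); depth-based discarding is the backstop.
* Population-level co-inertia with few populations has limited permutation
  resolution (9 rows give at most 9! distinct relabelings — ample for
  p = 0.05, but not for much smaller p).
* The Mantel family tests linear association of distances; strongly
  non-linear distance-decay would call for other tools.
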