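# mhcpopgen

Comparative population genetics of adaptive and neutral markers: does the
spatial structure of a highly polymorphic immune gene track demography, or
has selection decoupled it?

Under balancing selection (heterozygote advantage, negative
frequency-dependent selection on the MHC peptide-binding region),
population differentiation at the selected locus is expected to be *weaker*
than at neutral loci: Φ<sub>ST</sub>(MHC) ≪ F<sub>ST</sub>(microsatellites),
no isolation by distance at the MHC while the neutral markers show it
(Mantel r > 0, p < 0.05), and no significant global co-structure between
the two markers (RV test). `mhcpopgen` implements the full workflow that
measures this contrast for the common wildlife-survey design — a short MHC
class II DRB exon 2 amplicon (2–5 co-amplifying alleles per individual
from ≥ ⌈5/2⌉ = 3 unresolvable loci) genotyped by pooled tagged amplicon
sequencing, alongside a diploid microsatellite panel:

* **Amplicon genotyper** — exact MID/primer demultiplexing with a discard
  log, variant tabulation with the maximum per-amplicon frequency (MPAF),
  a deterministic multi-step artifact ladder (1–2 bp shadows, stop codons,
  frameshifts, singletons, replicate verification), depth-thresholded
  genotype calls and replicate concordance.
* **Population statistics** — unbiased heterozygosities, hypergeometric
  rarefied allelic richness, nucleotide diversity, one-level AMOVA
  (Φ<sub>ST</sub> on Jukes–Cantor-distanced allele carriages for the MHC;
  multilocus allele-identity F<sub>ST</sub> on gene copies for
  microsatellites; Jaccard mode for binary encodings), Jost's D, MHC-like
  genotype diversity, the individual allele-diversity index
  (A = |set|/max, i.e. 0.4–1 when the maximum is 5 alleles), and dominant
  binary encoding.
* **Multivariate co-structure** — Jaccard S3 distances, principal
  coordinates (Lingoes), between-class analysis, and population-level
  co-inertia with the RV permutation test.
* **Isolation by distance** — log-km haversine distances, simple and
  partial Mantel tests, Pearson diversity correlation.
* **Selection statistics** — Nei–Gojobori (1986) dN/dS with a codon-
  bootstrap Z-test, and likelihood-ratio arithmetic
  (2ΔlnL ~ χ²<sub>Δk</sub>) for externally fitted nested codon models.
* **Synthetic-data generator** — a seeded, ground-truthed simulator of the
  whole study (Dirichlet F-model with E[F<sub>ST</sub>] = F,
  isolation-by-distance gradients, overdispersed read depths, point
  errors, chimeras, noise reads, amplification bias), so every stage is
  testable end to end without any external data.
* **Pipeline** — `validate_config()` + `run_pipeline()` drive all stages
  from one YAML document into a hashed artifact manifest and a
  `summary.json` with the headline marker contrast.

## Worked example

Simulate a nine-population survey (12 individuals each) with homogenized
MHC (F = 0.01) and isolation-by-distance microsatellites (F = 0.10), push
the reads through the genotyper, and measure the contrast:

```r
library(mhcpopgen)

cfg   <- sim_config(samples_per_population = 12,
                    read_model = list(mean_depth = 400, depth_dispersion = 5),
                    seed = 42)
pool  <- build_allele_pool(cfg)
truth <- simulate_genotypes(pool, cfg)
reads <- simulate_reads(truth, cfg)

dm    <- demultiplex(reads$reads, reads$scheme, cfg$amplicon_length)
vt    <- tabulate_variants(dm)
cls   <- classify_variants(vt, frame_offset = cfg$frame_offset,
                           known_alleles = pool)
calls <- call_genotypes(vt, cls,
                        populations = setNames(truth$mhc$population,
                                               truth$mhc$individual))
calls
#> MHC genotype calls: 108 individuals (98 called, 10 discarded for low depth)
#>   alleles per called individual: 2-5 (implied minimum loci: 3)

called <- calls[calls$status == "CALLED" & calls$n_alleles >= 2, ]
mhc    <- mhc_genotypes(called$individual, called$population, called$allele_set)

amova(mhc, allele_seqs = pool, n_perm = 999, seed = 1)
#>   Phi_ST = 0.0029, p = 0.249 (999 permutations)
amova(truth$msat, n_perm = 999, seed = 1)
#>   Phi_ST = 0.1461, p = 0.001 (999 permutations)

geo <- geographic_log_distance(truth$coordinates)
mantel(pairwise_differentiation(truth$msat, "fst", n_perm = 0)$stat, geo,
       n_perm = 999, seed = 1)
#> Simple Mantel test: r = 0.581, p = 0.002 (999 permutations, greater)
mantel(pairwise_differentiation(mhc, "phist", allele_seqs = pool,
                                n_perm = 0)$stat, geo, n_perm = 999, seed = 1)
#> Simple Mantel test: r = 0.212, p = 0.092 (999 permutations, greater)

be <- binary_encode(mhc, truth$msat)
bx <- between_class_analysis(principal_coordinates(jaccard_s3_distance(be$mhc)),
                             be$populations)
by <- between_class_analysis(principal_coordinates(jaccard_s3_distance(be$msat)),
                             be$populations)
coinertia(bx, by, n_perm = 999, seed = 1)
#> Co-inertia analysis: 8 axes, RV = 0.7063, p = 0.706 (999 permutations)

lrt(model_fit("M1a", -527.69, 2), model_fit("M2a", -516.17, 4))
#> LRT M1a vs M2a: 2*dlnL = 23.04, df = 2, p = 9.93e-06
```

Reading the numbers: the neutral marker is strongly structured
(F<sub>ST</sub> = 0.146, p = 0.001) with clear isolation by distance
(r = 0.58, p = 0.002), while the adaptive marker is essentially
unstructured (Φ<sub>ST</sub> = 0.003, n.s.; Mantel n.s.) and the global
marker co-structure is non-significant (RV p = 0.71) — the balancing-
selection signature the package is designed to detect, here recovered
from its own simulated ground truth. (`ng86_dnds(codon_alignment(pool,
frame_offset = 2))` runs on the same pool, but the generator places
mutations without selection, so its Z statistic just fluctuates around 0
from pool to pool.)

`run_pipeline(list(seed = 1, simulation = list(samples_per_population = 8)),
"out")` performs all of the above (plus diversity reports, Jost's D and
partial Mantel tests) in one call and writes `out/summary.json` and a
hashed `MANIFEST.json`.

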