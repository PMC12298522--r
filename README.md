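# strainmarker

Strain-level identity matters wherever a specific bacterial strain — not
just its species — carries the validated effect: probiotic quality
control, regulatory compliance, tracking a production strain through a
multi-strain product. Near-identical strains of *Bifidobacterium animalis*
subsp. *lactis* differ by only a handful of nucleotides across ~1.94 Mb,
so strain-specific detection comes down to finding single-nucleotide
positions where the target strain differs from **every** other genome in a
panel, and then building a TaqMan qPCR assay on one of them.

`strainmarker` implements that whole workflow as a tested R package:

1. **Pairwise whole-genome alignment**, written from scratch in the
   classical anchor-based style: maximal unique matches (MUMs) found with
   a suffix array + LCP scan, chained by a weighted
   longest-increasing-subsequence, inter-anchor gaps closed by affine-gap
   global alignment, and blocks reduced to a one-to-one tiling so each
   reference and query region is used at most once.
2. **SNP extraction** from the alignment blocks, with isolation (`buff`)
   and edge-distance (`dist`) annotations for each call.
3. **Marker intersection**: positions where *every* comparator genome is
   both aligned and variant. An unaligned position is "unknown", never
   "different", so assembly gaps cannot fake strain specificity. A flank
   k-mer uniqueness test (default k = 61) stands in for the "single-copy"
   requirement.
4. **Assay design**: exhaustive primer/probe enumeration under TaqMan
   constraints with SantaLucia nearest-neighbor melting temperatures, and
   in-silico PCR to screen specificity across the panel (the assay passes
   only if the target yields exactly one perfectly probed product and
   every non-target fails to amplify or mismatches the probe at the SNP).
5. **qPCR quantification mathematics**: standard curves (ordinary least
   squares of Cq on log10 quantity), amplification efficiency
   E(%) = (10^(−1/slope) − 1) × 100, the strict Cq < 35 positivity rule,
   detection limits as the monotone positivity frontier, replicate
   SD/RSD statistics, and viable-count content
   M = 10^x · (A + B)/A · C in CFU/g.
6. **A synthetic-data generator** that plants private SNPs, shared SNPs,
   indels and a duplicated segment with known truth, so the entire
   pipeline is testable end-to-end without downloading a single genome.

## Worked example

```r
library(strainmarker)

# a 30 kb panel: target + 3 comparators with 5 planted private SNPs
panel <- default_panel(seed = 7, genome_length = 30000L, n_strains = 3L)
res   <- discover_markers(panel$target, panel$comparators)
res$markers[, c("ref_pos", "ref_allele", "alt_alleles",
                "buff_min", "dist_min", "flank_unique")]
#>   ref_pos ref_allele alt_alleles buff_min dist_min flank_unique
#> 1    4500          T       A,A,A     1083     2920         TRUE
#> 2   22500          C       A,A,A      929     8099         TRUE
#> 3    9000          T       A,A,A      298     7420         TRUE
#> 4   13500          T       A,A,A      137    11920         TRUE
#> 5   18000          C       A,A,A      122    12599         TRUE
```

Every reported position is variant in all three comparators
(`alt_alleles`, one per comparator), isolated from other variants by at
least `buff_min` bp, and flanked by a genome-unique 61-mer. Designing and
screening an assay on the top marker:

```r
designs <- enumerate_assays(panel$target, res$markers$ref_pos[1])
designs[1, c("fwd", "rev", "probe", "probe_tm", "amplicon_length")]
#>                  fwd                rev                   probe probe_tm amplicon_length
#> 1 GCACGAGAGCGTCTCGGG CCGACGTCAGACCACCCC CGCACCACTTCCAGTAAGTCACT 58.70252              96

specificity_screen(as.list(designs[1, ]),
                   c(list(panel$target), unname(panel$comparators)),
                   "target")$pass
#> [1] TRUE
```

Quantification from a simulated dilution ladder and three sample
replicates (25 g sample in 225 mL, dilution 10×):

```r
cv <- fit_standard_curve(simulate_cq(standard_curve(-3.347, 44.17),
                                     3:8, reps = 3, noise_sd = 0.15, seed = 8))
cv
#> <standard_curve> Cq = -3.3452 * x + 44.1158  (R2 = 0.9994, efficiency = 99.04%)
quantify_sample(cv, c(20.70, 20.75, 20.80), A = 25, B = 225, C = 10)$log10_M
#> [1] 8.98
```

A `strainmarker` command-line script (installed under `exec/`) exposes the
same steps as `simulate`, `align`, `call-snps`, `find-markers`,
`design-assay` and `quantify` subcommands.

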