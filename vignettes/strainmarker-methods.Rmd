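---
title: "Methods: strain-private SNP discovery and qPCR quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-private SNP discovery and qPCR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainmarker)
```

# The problem

A strain-specific qPCR assay rests on a single-nucleotide position where
the target strain's allele differs from every other genome in a
comparison panel, located in single-copy sequence so that one genome
equivalent contributes exactly one template copy. `strainmarker` covers
the computational path from a panel of assemblies to such a marker, the
TaqMan assay built on it, and the quantification mathematics applied to
the resulting Cq measurements. This vignette records the models,
parameter choices and numerical conventions, and what the synthetic
test bed does and does not demonstrate.

Throughout the package, coordinates are 0-based half-open; conversion to
the 1-based inclusive conventions of GFF3, SNP reports and VCF happens
only at format boundaries. IUPAC ambiguity codes other than N are mapped
to N on input (with a count), and N is excluded from anchoring and SNP
calling, so ambiguous assembly positions can never become markers.

# Pairwise alignment

The aligner follows the classical anchor-based design.

**Anchoring.** A maximal unique match (MUM) is an exact match that
occurs exactly once in the reference and once in the query and can be
extended in neither direction. MUMs are found on a suffix array of the
concatenated, integer-coded sequences with an LCP scan: a pair of
adjacent suffixes from different sequences whose common prefix is
strictly longer than both neighbouring LCPs is unique in both sequences;
a preceding-character check enforces left-maximality. Every N receives a
unique integer code, so N matches nothing (not even another N) and
anchors split at ambiguous positions. Both query strands are searched;
minus-strand anchors carry query coordinates on the reverse-complemented
query, and SNP reports convert back to forward-strand query positions.
The default minimum anchor length is 20 bp. An O(n²) brute-force
enumerator over all substring pairs lives in the test suite as an
independent oracle; the suffix-array implementation is required to agree
with it exactly on randomized inputs.

**Chaining.** Per strand, anchors are chained by a weighted
longest-increasing-subsequence on total anchored length. Two anchors may
be linked when reference and query starts both strictly increase, each
inter-anchor gap is at most `max_gap` (default 90 bp) and the diagonal
drift is at most `max_gap`. Chains are extracted greedily by score;
chains with under `min_cluster` (default 65 bp) anchored sequence are
dropped. The defaults mirror the published defaults of classical
anchor-chain aligners in spirit; they are configurable because the
appropriate values depend on panel divergence.

**Gap closure.** Gaps between consecutive anchors are aligned globally
with affine gap scores (match +1, mismatch −1, gap open −5, gap extend
−1; configurable). A gap whose reference/query length difference exceeds
`band` (default 200 bp) is left unaligned and splits the chain into
separate blocks — closing such a gap would manufacture alignment columns
through what is structurally an insertion or deletion too large to
trust. Each block carries an explicit edit transcript over
M/X/I/D whose consumption invariants are asserted after construction.

**One-to-one filtering.** Blocks are retained greedily by
score = transcript length × identity, subject to overlapping no retained
block on either the reference or the query axis, with deterministic
(ref_start, qry_start) tie-breaks. This is the "1-to-1" filtering mode
of delta-filter-style tools: it is what prevents a duplicated query
segment from contributing two alignments to one reference locus.

# SNP calling and marker intersection

One SNP call is emitted per mismatch column whose two bases are both
unambiguous; indel columns are never calls but do reset the isolation
distance. Each call carries `buff` (alignment columns to the nearest
other variant column or block edge) and `dist` (columns to the nearest
block edge), mirroring the BUFF/DIST columns of classical SNP
extractors, so downstream filters can demand isolated, internal SNPs
(defaults: `buff` ≥ 20, `dist` ≥ 100).

A position is a marker candidate only if **every** comparator (i) covers
it with an aligned query base — M or X column; a base deleted from the
query does not cover — and (ii) carries a variant call there.
Comparators are not required to agree on the alternative allele: what
makes the marker usable is that the target allele is unique, not that
the others coincide (`require_consistent_alt` enables the stricter
reading). Coverage is computed from the retained one-to-one blocks, so
"missing" never counts as "different".

The "single-copy" requirement is approximated computationally: the
k-mer window centred on the marker (k = 61 by default — long enough that
a random 100 kb–2 Mb genome essentially never repeats it, short enough
to stay within a conserved locus) must occur exactly once in the target
genome, counting forward and reverse-complement occurrences together.
Gene containment from a GFF3 annotation is an optional additional
filter, optional because marker discovery must work on unannotated
assemblies. Ranking is deterministic: flank-unique first, then
descending isolation, then position.

A multi-copy locus is usually lost earlier than the flank filter: a
duplicated segment has no unique anchors, so it drops out of the
one-to-one alignment and fails the coverage requirement. The
`explain_position()` classifier therefore tests flank uniqueness before
coverage, labelling any repeat-flanked position "multi-copy" whichever
mechanism removed it — the label describes the cause, not the code path.

# Assay design

Melting temperatures use the unified SantaLucia nearest-neighbor
parameter set with initiation terms, the entropic salt correction
0.368 (N−1) ln[Na+], and Tm = ΔH / (ΔS + R ln(C/4)) − 273.15 for
non-self-complementary oligos. Defaults: total strand concentration
250 nM (hence C/4), 50 mM monovalent salt. The test suite pins this
implementation against an independent nearest-neighbor implementation to
within 0.005 °C on a fixed oligo set, including the strain-assay
primers and probe.

Designs are enumerated exhaustively within constraint windows: primer
length 18–25, probe length 13–25, amplicon 50–150 bp, primer Tm 54–62 °C,
probe Tm 58–63 °C, GC fraction 0.30–0.80, no G/C run above 4, probe not
starting with G (a 5′ G quenches the reporter), probe strictly between
the primers and covering the SNP. The probe Tm window is a **proxy**: a
minor-groove-binder modification raises the effective probe Tm
substantially and is not modeled thermodynamically, so the window
describes the unmodified oligo. Ranking is by distance of the probe Tm
from the window centre, then amplicon length, then position —
deterministic, but note that SNP centrality within the probe is not a
ranking key; designs with the SNP near a probe end rank equally.

In-silico PCR reports a product wherever the forward primer matches the
plus strand and the reverse primer the minus strand, facing each other,
each within a per-primer mismatch allowance (default 2) and an exact 3′
seed (default 3 bases — polymerase extension is far more sensitive to 3′
mismatches than internal ones), product length capped at 2 kb. The
specificity screen passes an assay only if the target yields exactly one
product with a perfect probe match and every non-target yields no
product or mismatches the probe at the SNP offset. Treating a single
probe mismatch as full discrimination is a deliberate simplification of
hydrolysis-probe chemistry; real assays discriminate by Cq shift, not
absolutely, which is why the screen's verdict carries its rationale.

# Quantification mathematics

Standard curves regress Cq on log10 quantity (Cq as the response,
matching how dilution ladders are plotted), replicates entering
individually. Efficiency is E(%) = (10^(−1/slope) − 1) × 100; a slope of
−1/log10(2) ≈ −3.32 is exactly 100%. R² is computed from the residual
and total sums of squares directly.

Positivity is strictly Cq < 35 with missing/undetermined Cq negative;
the threshold is configurable. The detection limit is the monotone
positivity frontier: the smallest level whose replicates, and those of
every larger level, are all positive. When a fully positive level sits
below a level with dropouts the frontier stays at the conservative
(larger) level and a warning is raised — an isolated dropout means the
assay is not reliable at that dilution.

For passage/repeatability statistics, the reported SD is the sample
standard deviation (n−1) of the **group means** (e.g. per-generation
means), with the RSD computed on unrounded intermediates; the pooled
within-group SD is also returned because the two answer different
questions (drift across groups vs noise within a run), and the raw-value
SD is deliberately not the headline number.

Content in CFU/g is M = 10^x · (A + B)/A · C, with x the curve-inverted
log10 density (CFU/mL) of the measured suspension, A the sample mass
(g), B the diluent volume (mL) and C the dilution factor. Equating
genome copies of a single-copy marker gene with CFU is an assumption —
it ignores dead cells and free DNA — and every quantification result
carries an explicit flag saying so.

# The synthetic test bed

`simulate_genome()` draws i.i.d. bases at a requested GC content.
`build_panel()` derives comparators from a common ancestor by planting:
private SNPs (applied to every comparator, so the target allele is
private), shared SNPs (a proper subset of comparators), per-comparator
indels, a duplicated segment copied into every genome, and random
per-comparator background substitutions at 1e-3 per bp, emulating the
~99.9% identity of a real within-subspecies panel. Background edits are
kept at least 100 bp from planted sites so that the planted truth is
exactly what the selection criteria should return — the generator
emulates markers inside conserved loci, which is precisely the situation
a usable marker occupies. Desk-scale defaults are 100 kb genomes and
5 comparators (seconds per pairwise alignment); `default_panel()` also
plants the three canonical confounders (shared / deleted-in-one /
duplicated) whose exclusion the end-to-end tests verify reason by
reason. Cq tables are simulated as cq = intercept + slope·x + N(0, σ)
with σ = 0.15 cycles by default. All generators are pure functions of
their seed and restore the caller's RNG state.

What the generator does **not** emulate — and therefore what passing
tests do not demonstrate about real data: assembly errors and contig
fragmentation, genome rearrangements beyond the planted edits,
compositional structure (real genomes are not i.i.d.), mobile elements
and large repeat families, and any wet-lab effect other than Gaussian
Cq noise (no inhibition, no plateau effects, no inter-platform bias).
The acceptance of the pipeline on synthetic panels shows the logic is
correct under its stated model, not that the model captures every real
assembly.

# Degenerate inputs and numerical conventions

Empty anchor sets yield empty alignments, not errors; a single-x
standard curve is an error (slope undefined); a single replicate group
flags `sd_undefined` rather than fabricating an SD; an all-negative
positivity ladder reports an undefined detection limit. All rankings and
filters carry explicit deterministic tie-breaks, so identical inputs
give byte-identical outputs everywhere, including across the CLI.

Problem sizes used by the shipped tests and the acceptance script —
oracle comparisons on ≤300 bp pairs, panels of 20–100 kb with 2–5
comparators, 500 seeded curve-recovery trials — were chosen as the
smallest sizes at which every mechanism under test (repeat suppression,
chain splitting, coverage loss, frontier ties) actually occurs.
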