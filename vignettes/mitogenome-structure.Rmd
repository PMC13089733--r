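---
title: "Methods: structural characterization of annotated mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural characterization of annotated mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

`mitochar` characterizes the structure of annotated circular mitochondrial
genomes: feature geometry, base-compositional strand asymmetry, codon
usage under the echinoderm/flatworm mitochondrial code, population
diversity indices, and comparative gene order. This vignette is the
package's account of the underlying definitions, the conventions chosen
where published practice is ambiguous, and what the synthetic-data
generators do and do not emulate.

## Coordinates and the central container

Everything is 1-based and inclusive, the convention of GenBank feature
tables and published mitogenome annotation tables. A `Mitogenome` holds an
identifier, total length, circularity flag, optional sequence and an
ordered feature table. Feature names need not be unique (holothurian
mitogenomes carry tRNA paralogs, and published tables sometimes repeat a
label); identity is the pair (name, start). A feature with `end < start`
wraps the origin and is legal only on circular records, with length
`(L − start + 1) + end`.

Half-open, 0-based coordinates are used internally for slicing but never
appear in any file the package reads or writes.

## Geometry: spacers, overlaps, and the overlap typology

For consecutive features (by start), the signed gap is

```
gap = start(next) − end(prev) − 1
```

positive values are intergenic spacers, negative values overlaps, zero
means abutting genes. This formula is fixed by reproducing the printed
spacer/overlap column of the packaged *H. atra* table (9 between `cox1`
and `trnR`, −7 between `atp8` and `atp6`).

Two deliberate exclusions:

* the **origin-spanning pair** (last feature back to the first) is not a
  spacer; its size is reported separately as the unannotated wraparound
  (151 bp in the fixture, the putative control region). Counting it as a
  spacer would inflate the spacer count to 19; published counts treat the
  control region as its own entity.
* **nested features** (fully contained in their predecessor) have no
  defined adjacent-pair gap; the pair is skipped with a warning rather
  than assigned a fabricated depth.

Overlaps are classified by a fixed priority, because the published
categories overlap logically (an opposite-strand overlap may also touch a
stop codon):

1. `opposite_strand` — the features sit on different strands;
2. `stop_codon` — the overlapped interval is entirely contained in the
   upstream PCG's (≤ 3 bp) stop codon, the signature of TA(A)-termination
   sharing;
3. `pcg_pcg` — both features protein-coding;
4. `other`.

Under this priority the 2 bp `cox3`/`trnS2` overlap is type 1 (the two
genes face each other) even though it also coincides with `cox3`'s stop
codon, and the 7 bp `atp8`/`atp6` overlap is type 3 because it extends
beyond `atp8`'s 3 bp stop. With the packaged table this yields 3
opposite-strand overlaps, 1 PCG–PCG, 3 other, and none in the pure
stop-codon class — the published narrative names all four types, but its
stop-codon example is the same `cox3` junction the priority rule assigns
to type 1, and its PCG–PCG sentence names `atp6`/`cox3` where the
coordinates show `atp8`/`atp6` (+2 between `atp6` and `cox3`). The
implementation follows the coordinates.

The identity
`Σ lengths + Σ spacers − Σ |overlaps| + wraparound = genome length`
holds for records without nested features and is asserted in the tests.

## Strand-asymmetry (skew) statistics

```
AT-skew = (A − T) / (A + T)          GC-skew = (G − C) / (G + C)
```

Both are dimensionless, bounded in [−1, 1], scale-invariant (counts and
percentages give the same value), antisymmetric, and sign-flipped by
reverse complementation. A zero denominator yields an undefined value
(`NaN`), never 0 — a sequence with no A or T has no AT-skew.

Per-feature composition is computed on the **plus-strand slice** of the
feature's range regardless of feature strand. This matches published
per-gene composition tables: the sole minus-strand PCG (`nad6`) shows
sign-inverted skews relative to the other PCGs, which is exactly what
plus-strand slicing produces. Coding-strand composition is available
behind `coding_strand = TRUE`.

Report precisions follow the published table: percentages at 1 decimal,
skews at 3. When skews are recomputed from *printed* percentages (inputs
already rounded to 1 decimal), the third decimal can shift; the package's
acceptance tests use a |Δ| ≤ 0.0015 envelope, widened to 0.003 only for
rows whose G+C denominator is small enough that half-a-decimal rounding of
the inputs alone implies a larger shift (analytically: |Δ| can reach
0.1/(G+C)). N bases are excluded from all denominators; a feature over 10%
N triggers a warning.

## Codon usage under translation table 9

The genetic code is hard-coded as the standard table plus the documented
per-table substitutions; table 9 (echinoderm/flatworm mitochondrial)
differs from the standard code by AAA→Asn, AGA/AGG→Ser, TGA→Trp, leaving
ATA as Ile (unlike the vertebrate and invertebrate mitochondrial tables 2
and 5, which are also supported, as is the standard code). Stops under
table 9 are exactly TAA and TAG; there are 62 sense codons. The test suite
verifies all 64 codon assignments against the independently maintained
Biostrings reference for every supported table.

Codon extraction takes the coding strand (reverse complement for minus
features), splits into triplets from the feature's first position, and
audits the ends: the first codon against the code's start codons, the
terminus against its stops. A trailing 1–2 bp remainder is an **incomplete
stop** (`T` or `TA`, completed to TAA by polyadenylation in vivo) and is
returned as a fragment, never counted as a codon. Internal stops raise a
warning with codon positions.

Counting conventions (the CodonW conventions):

* complete terminal stop codons are excluded from counts and RSCU;
* incomplete terminal fragments are excluded and logged (`T--` style) in
  the start/stop audit;
* N-containing codons are skipped with a tally.

RSCU for codon *c* in a synonymous family of size *n*:
`RSCU(c) = count(c) / (family total / n)`. Families are full synonymous
families under the code in use — serine is 8-fold under table 9 (TCN +
AGA/AGG/AGT/AGC), leucine 6-fold; sub-family display labels ("Ser1",
"Leu1") are presentation metadata only. Family RSCU values sum to the
family size whenever the family is observed; unobserved families are
undefined (`NA`), never 0. Amino-acid percentages pool all PCGs jointly
(the per-gene-averaged alternative was considered and rejected: pooling is
what a single genome-wide codon tally measures; a flag-level alternative
can be added without changing the container).

## Diversity indices

Given an alignment (n ≥ 2), **complete deletion** removes every column
containing a gap or ambiguous base before analysis — the default of
classical population-genetics software; pairwise deletion is available by
flag. On the filtered matrix:

* *H* — number of exactly-identical row classes;
* *Hd* — Nei's unbiased haplotype diversity `n/(n−1) · (1 − Σ pᵢ²)`;
  the n/(n−1) correction matches the software the published analysis
  names;
* *S* — columns with ≥ 2 states;
* *k* — mean pairwise Hamming distance over all C(n,2) pairs, computed
  from per-column state counts (`Σ_sites [C(n,2) − Σ_b C(n_b,2)] / C(n,2)`,
  algebraically identical to the pairwise double loop but O(nL)); the
  tests verify it against a literal O(n²L) double loop;
* *Pi = k/L*, and the within-group mean p-distance equals *Pi* under these
  definitions — consistent with the published table, where the
  within-group distances equal the rounded nucleotide diversities.

Report precisions follow the published table (Hd and k at 3 decimals, Pi
at 4). The published 16S/COI index values themselves are not
desk-reproducible — the 30 specimen sequences were not deposited — so the
package's verification is exact parameter recovery on synthetic alignments
with closed-form truth (below), including a spec with n = 30, haplotype
partition (27, 1, 1, 1) and 3 singleton mutations, the structure of the
published 16S result (H = 4, S = 3).

## Gene-order comparison

Orders are modelled as **signed circular** sequences: a gene order and its
mirrored reading (the circle traversed backwards with all orientations
flipped) are one arrangement, which is required for strand-annotated
orders to compare correctly. Canonicalization rotates `cox1` — the anchor
conserved across the group — to the front, flipping the reading first if
the anchor is on the minus strand; it is idempotent, and a missing or
duplicated anchor is an error with an explicit override argument.

Adjacencies are oriented neighbor pairs normalized so that an adjacency
and its reverse complement coincide; the **breakpoint distance** is the
number of adjacencies of one order absent from the other. On equal gene
content it is symmetric, zero exactly for identical arrangements, and
satisfies the triangle inequality — verified exhaustively over all 384
signed circular orders of 5 genes. Content mismatches restrict both orders
to the shared genes with a warning (duplicated tRNAs and control regions
are the usual offenders); disjoint contents are an error.

Event classification is a deliberately **single-event heuristic**, applied
in order: single-gene translocation (removing one gene from both orders
makes them identical — tested under rotation-only equivalence, which
separates a true segment inversion from a one-gene move), segment
inversion (reversing one contiguous segment with flipped orientations),
contiguous multi-gene shift. Anything needing more than one event reports
`unclassified` with the breakpoint count rather than guessing a history;
no attempt is made at minimal reversal/DCJ distances. Every emitted event
carries replay parameters, and `applyEvent()` reproduces the target order
— asserted for all three kinds in the tests.

Cross-database gene naming is handled by an editable harmonization table
(`inst/extdata/gene_name_map.tsv`) mapping e.g. MITOS anticodon-suffixed
tRNA names and `COI`/`16S` spellings onto the controlled vocabulary.

## The synthetic-data generators

Both generators are driven by one integer seed with separate derived
streams (adding a call to one never perturbs the other), and both save and
restore the session RNG state.

**Genomes.** A `genomeSpec` fixes the gene order, per-feature lengths,
signed gap plan, wraparound size, composition weights and per-PCG stop
plan. Coordinates follow the gap plan; overlaps are realized by coordinate
arithmetic alone — the downstream feature simply starts inside the
upstream one, as in real records — not by duplicating sequence. PCGs are
written on their coding strand as ATG + random sense codons + the planned
stop, with the length modulo 3 encoding a complete (0) or incomplete
(`T` = 1, `TA` = 2) stop. Because a later feature can overwrite an earlier
one's bases at an overlap, start codons and stops are re-imposed after
assembly, and a repair pass removes any collateral in-frame stop by
mutating a non-forced base (plans that cannot be repaired are rejected).
All truth tables — the exact gap vector, per-feature base counts, per-PCG
codon lists and peptides — are computed from the final assembled sequence
by plain string slicing, an independent code path from the Biostrings-based
analysis functions they verify. `hatraLikeGenomeSpec()` copies the
packaged annotation's order, lengths, gaps and stop plan (with the default
weights set to the published whole-genome base percentages), so the
simulated genome reproduces the published architecture counts by
construction while carrying random sequence.

The generator emulates annotation *geometry* and composition, not
biology: no substitution model, no rate heterogeneity, no realistic codon
bias beyond the base weights, no tRNA secondary structure. Passing tests
therefore demonstrate that the analysis code measures what the annotation
says — not that it would annotate raw sequence correctly (annotation
inference is out of scope).

**Haplotype alignments.** A `haplotypeSpec` fixes n, L, a haplotype
partition of n and a mutation plan (default: one substitution per
non-reference class; automatic plans are infinite-sites, so S equals the
number of planted substitutions; recurrent hits can be enabled for stress
tests). The reference row is drawn uniformly, replicated per class, and
substitutions are planted. Truth is closed-form: H from distinct mutation
signatures, Hd from the class sizes, S from per-site state counts, k by
direct enumeration over class pairs (`Σ sizeᵢ·sizeⱼ·Hamming(repᵢ, repⱼ) /
C(n,2)`), Pi = k/L — all integer arithmetic, no sampling error. The model
is star-shaped (every haplotype differs from the reference, not from each
other, unless plans overlap); it does not emulate recombination,
sequencing error, gaps or coalescent genealogies.

## Problem sizes and runtime choices

The test suite and acceptance script run on one CPU in well under a
minute each with the sizes chosen here: the 37-feature fixture for all
geometry checks; 15.8 kb synthetic genomes; 200 seeded haplotype specs
(n ≤ 30, L ≤ 300) each verified against the O(n²L) brute-force oracle;
exhaustive 5-gene enumeration (384 orders) for the breakpoint metric
axioms. These sizes already exercise every code path exactly (the
diversity truths are closed-form, so larger n adds no information), which
is why larger simulations are not used.

## Known limitations

* GenBank parsing covers the flat-file subset annotated mitogenomes use
  (LOCUS, gene/CDS/tRNA/rRNA features, `complement`, a single
  origin-spanning `join`); it is not a general GenBank reader, and GFF3 is
  not supported.
* The published per-gene A+T% column duplicates T% for PCG rows; the
  package always reports true A+T and treats that column as a printing
  anomaly.
* The packaged annotation preserves a published inconsistency — the
  feature labelled `trnL` at 13,133 bp carries an isoleucine anticodon
  (GAU) — and surfaces it as a validation warning rather than renaming the
  gene.
* Event classification is single-event; composite rearrangement histories
  are reported as `unclassified`, by design.
* Whole-genome claims that require the deposited sequence (observed codon
  count of 61, Leu most abundant at 16.58%) are not asserted offline; the
  codon machinery is instead verified on synthetic genomes with exact
  truth.
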