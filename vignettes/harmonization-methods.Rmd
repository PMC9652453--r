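---
title: "Harmonizing single-cell read structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing single-cell read structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scunify)
```

## The harmonization model

UMI-based single-cell RNA-seq chemistries all carry the same information —
a cell barcode, a unique molecular identifier (UMI) and a cDNA fragment —
but distribute it differently across the read pair. `scunify` describes
each chemistry declaratively as an ordered list of *segments*: a source
read (R1, R2, I1 or I2), a 0-based offset, a length in bp, and a role
(`barcode`, `umi` or `linker`). Everything else follows mechanically from
that description:

1. **Extraction.** Barcode segments are concatenated in declaration order;
   linker-role segments are skipped. Chemistries whose two barcode halves
   do not reach the declared total (the inDrops family: 8 + 8 observed bp
   against a 19 bp barcode) have the configured `linker_fill` bases
   inserted after the first segment, reflecting the variable-length first
   half being padded by constant linker sequence. Chemistries that place
   the UMI first, or that put all elements in R2 with the cDNA in R1, need
   no special code: the segment offsets and the `elements_in_r2` flag
   encode it.
2. **Canonicalization.** The extracted barcode is mapped into the 16 bp
   space (next section), the UMI is right-padded to the canonical UMI
   length, and the cDNA passes through byte-for-byte — the package never
   trims or edits biological sequence. Output files follow the
   `<sample>_S1_L00<lane>_R1_001.fastq.gz` convention so standard
   quantification pipelines accept them directly.

The registry ships 40 presets as plain-text config files
(`system.file("extdata", "chemistries", package = "scunify")`). For most
platforms only the total barcode and UMI lengths are public; those presets
use a single contiguous barcode block followed (or preceded) by the UMI.
Exact segment offsets and linker sequences of the multi-segment platforms
(inDrops, SPLiT-Seq, SureCell) are proprietary or vary by kit revision, so
the bundled layouts use documented placeholder offsets and a placeholder
linker; a custom config file overrides any of it. This affects only where
bases sit inside the raw read, never the lengths that downstream tools see.

## Barcode recoding to 16 bp

The canonical barcode width is 16 bp. Three regimes:

* **Exactly 16 bp** — identity.
* **Shorter** — right-padded with the fixed prefix of
  `ACGTACGTACGTACGT`. The same pad is applied to reads and to the
  whitelist, so a read matches the native whitelist *iff* its canonical
  form matches the recoded whitelist. The pad is constant (not read-
  dependent), so padded barcodes remain pairwise distinct.
* **Longer** (18–40 bp platforms) — no truncation could be injective, so
  barcodes are recoded through a bijective surrogate table: the whitelist
  is sorted lexicographically and the i-th barcode receives the i-th
  16-mer in lexicographic order (base-4 encoding of its rank). The table
  is reproducible without a seed, is written alongside every output
  (`*_whitelist_16bp.txt.translation.tsv`), and inverts exactly. A read
  barcode absent from the whitelist maps to the sentinel
  `NNNNNNNNNNNNNNNN`; since `N` is disallowed in whitelists, such reads can
  never be mistaken for valid cells. Distinct off-whitelist barcodes
  therefore collapse — acceptable because they are unusable as cells
  either way, but worth knowing if you tally off-list reads per barcode.

Surrogate recoding is this package's own mechanism for fitting oversized
barcodes into a 16 bp pipeline; it makes no claim about how any particular
commercial pipeline handles them.

## Canonical UMI length

The canonical UMI length is `max(12, native UMI length)`: 12 bp — the
longest UMI among the droplet chemistries the canonical layout targets —
for every bundled preset except ICELL8 v3, whose 14 bp UMI would lose two
bases under a fixed 12. A fixed-12 design was considered and rejected
because truncation breaks exact UMI recovery and can merge molecules.
Shorter UMIs are right-padded with `A` (quality `I`); padding cannot merge
distinct UMIs because it is constant.

Chemistries without a UMI (`umi_length` "none") receive a deterministic
pseudo-UMI: the read's within-run ordinal in base-4 (A=0, C=1, G=2, T=3)
over 12 positions. No two reads of a run share a pseudo-UMI, so nothing
collapses during deduplication and downstream "UMI counts" are **read
counts** for these platforms. This is stated in the transform
documentation because it changes the interpretation of the counts.

## Paired quality filtering

`filter_pairs()` keeps or drops whole pairs on Read-2 quality only,
preserving order and lockstep, because R2 carries the cDNA whose quality
determines mappability while R1 carries only structured bases that are
never aligned. The statistic is deliberately simple and exposed: mean
Phred ≥ threshold (default), min Phred ≥ threshold, or fraction of bases
below threshold ≤ `max_fraction`. The default threshold of 20 (99% per-base
accuracy) is a conventional choice, not a calibrated one; raising the
threshold is monotone (never keeps more pairs), which the test suite
asserts as a property.

## Counting rule

A tagged alignment record contributes to the gene-barcode matrix iff it is
mapped, primary, reported with exactly one alignment, gene-assigned, and
its 16 bp barcode is on the whitelist. The count for a (gene, barcode)
pair is the number of **distinct UMIs** among contributing records.
Multi-mapping reads are discarded entirely rather than fractionally
assigned: this is the conservative convention of droplet pipelines, and it
makes counts reproducible without an assignment heuristic. No UMI error
collapsing (Hamming/directional networks) is performed — exact-string
deduplication is the rule, and barcode error correction is likewise out of
scope. "Assigned" means mapped + unique + gene-tagged; the per-barcode
invariant `umi_count ≤ reads_assigned ≤ reads_mapped ≤ reads_total` is
enforced by construction and tested.

## Comparing two gene-barcode matrices

Two GBMs rarely share exact label sets. `harmonize()` applies two rules:
barcodes are restricted to the intersection (a cell must be called in both
outputs to be comparable), while genes are extended to the union with
zero-filled rows (a gene missed by one pipeline is evidence, not missing
data). The scatter set then takes one point per (gene, cell) pair unless
both counts are zero — both-zero pairs carry no information and would
inflate the correlation, while a pair with up to `genes × cells` points
(1000 for 10 cells × 100 genes) remains when nothing is both-zero.
Pearson correlation is computed on raw counts (the matrices being compared
are raw pipeline outputs; normalization would entangle the comparison with
a normalization choice). Zero-variance or sub-2-point sets yield `NA` with
a warning, never a silent 0.

Cluster agreement uses the Adjusted Rand Index in the Hubert–Arabie form,
computed from the label contingency table; the degenerate case where the
maximum index equals its expectation (both partitions trivial) is defined
as 1. Clustering itself is not reimplemented — any external tool's labels
enter as a two-column table — because the defined computation here is the
comparison, not the clustering.

## What the synthetic generator emulates — and what it does not

`simulate_reads()` builds reads that are exactly faithful to a config's
segment geometry: barcode parts at their offsets, constant linker bases,
UMI placement, role inversion, index files for dual-index chemistries, an
optional unstructured tail on the barcode read, and uniform-random
transcripts as cDNA. Substitution errors are injected at a flat per-base
rate into the cDNA (optionally into barcodes, for negative tests). One
seed governs every draw, and the manifest records the realized reads, so
round-trip tests assert exact equality rather than distributional
closeness.

It does **not** emulate: quality-score-dependent error profiles, indels,
adapter read-through, PCR amplification bias, UMI collision statistics of
real libraries, ambient RNA, or empty droplets. Passing round-trip tests
therefore demonstrates that the structural transformation is lossless and
correct, not that downstream biology is robust to real sequencing noise.
Similarly, `simulate_tagged_alignments()` plants mapping/multi-mapping/
assignment outcomes per read with known realized tallies; it validates the
counting rule, not an aligner.

## Numerical and interface choices

* Segment offsets are 0-based internally; lengths are bp.
* All barcode sorting uses radix order (byte-wise), making surrogate
  tables and file outputs locale-independent.
* Permutation whitelists are generated in lexicographic order; lists
  longer than 4^10 are streamed in fixed-prefix chunks rather than
  materialized.
* Phred qualities are Phred+33; pad bases receive quality `I` (Phred 40).
* Empty inputs are valid everywhere (empty FASTQ in → valid empty FASTQ
  out); desynchronized pairs and malformed whitelists are fatal with the
  offending record identified.
* The `"10x"` alias resolves by observed R1 length (≥ 28 bp implies the
  16 + 12 layout, otherwise 16 + 10); explicit version tokens always win.
* The test suite and acceptance script run at deliberately small problem
  sizes — 5 cells × 20 reads per chemistry for round trips, 100 random
  streams of 80 records for the counting oracle, 10 × 100 matrices for the
  comparison — chosen so the full suite exercises every chemistry and
  every code path in well under a minute of compute while keeping every
  assertion exact.

## Known limitations

* Dual-index presets require I1/I2 files to be present but do not fold
  index bases into the cell barcode, because published per-platform index
  lengths are not available; custom configs may declare I1/I2 barcode
  segments, which are appended after read-derived segments (R1, then I1,
  then I2) and counted in the declared total.
* Whitelist matching is exact; no 1-mismatch barcode rescue.
* 5′ chemistries are not modelled beyond what the segment grammar can
  express.
* Bundled multi-segment layouts use placeholder offsets and linkers (see
  above); for real data from those platforms, supply a config file with
  the kit's actual geometry.
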