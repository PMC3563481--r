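---
title: "Two-step target-region mapping with read-backmapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step target-region mapping with read-backmapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Capture enrichment concentrates sequencing on selected target regions,
and the natural shortcut is to map the reads only against those regions.
The shortcut has a specific failure mode. Enrichment is a hybridisation
process: any genomic fragment sufficiently similar to a probe is pulled
down, including fragments from paralogs and segmental duplications of
the targets. When the mapping reference contains only the target copy,
reads from the off-target homolog have no correct placement; the aligner
puts them on the in-target copy as the best available hit ("force
mapping"). At every position where the two copies differ, the pileup
then shows a mixture of the reference base (from true-locus reads) and
the homolog's base (from force-mapped reads) — typically near 50/50,
which is indistinguishable from a genuine heterozygous SNP at the
calling stage.

`backmapr` implements the two-step remedy: call candidates quickly
against the compact target-region (TR) reference, then *backmap only the
reads covering those candidates* to the whole genome, drop every read
that maps better or equally well somewhere else, and re-type each
candidate from the reads that remain uniquely mapped over it. The
expensive whole-genome alignment is paid only for the tiny fraction of
reads that touch a candidate site.

# The TR reference

Targets are padded on both sides, merged where the padded intervals
overlap or abut, and concatenated into a single sequence with a run of
`spacer_len` `N` bases between blocks. A transform table records, for
each block, its TR start/end, chromosome and genome start; liftover in
both directions is exact and O(log n) via sorted-boundary search, and a
TR position inside a spacer raises a dedicated error class — an
alignment there should be impossible.

Parameter choices:

* **Padding** (`pad`, bases): default 50, the conventional exome
  padding. A value of read length − 1 (49 for 50-mers) is the minimal
  padding that keeps every read overlapping a target by at least one
  base mappable; both are exposed through the same argument.
* **Spacer length** (`spacer_len`, bases): default 50, chosen to be at
  least the read length. Because a read base aligned against `N` counts
  as a mismatch, a read would need more than `max_mismatches` bases
  hanging into the spacer to cross a junction, which the budget forbids;
  the pipeline warns when reads are longer than the spacer.
* **CCDS ingest**: exome-style target lists in the CCDS flat format are
  converted to BED-style intervals on ingest (inclusive coordinates to
  half-open, one interval per exon sub-span, duplicates retained for the
  later merge). Records are kept when their status is `Public` — the
  release status that marks agreed, current models — with a flag to
  disable the filter; unparseable location fields are skipped and
  counted in a warning.

All coordinates are 0-based half-open internally; VCF output is 1-based
on write. A single convention end to end removes the classic source of
off-by-one liftover bugs.

# The aligner

The built-in aligner is a deterministic, exhaustive, ungapped k-mismatch
mapper: every placement of the read (both strands, all sequences, fully
inside the reference) with at most `max_mismatches` Hamming mismatches
is considered, and all placements achieving the minimum mismatch count
are reported, each annotated with `n_best_hits`, the count of equal-best
placements. "Unique" downstream means `n_best_hits == 1`. `N` never
matches anything, including `N`.

Candidates are found by exact-match seeding with `max_mismatches + 1`
disjoint seeds per read, which is exhaustive by pigeonhole: a placement
with at most k mismatches must contain a mismatch-free seed. Candidate
offsets are then verified by vectorised Hamming counting. Reads too
short for informative seeds (seed length < 4) fall back to a C-level
exhaustive scan. A classic seed-and-extend index with a fixed 12-mer
seed was considered and rejected: with a budget of 5 mismatches on
50-mers it is not exhaustive, and exactness is what makes the
equal-best-hit semantics (and the brute-force oracle tests) meaningful.

Design decisions worth stating:

* **Ungapped only.** The method evaluates SNPs; indel handling would
  complicate the equal-best comparison that the cleanup step depends on
  without serving the mechanism being modelled.
* **Mismatch counts, not quality-weighted scores**, decide "better or
  equally well". Production aligners weight by base quality; the
  comparator here is the read's whole-length Hamming distance, which
  keeps the uniqueness decision exact and reproducible.
* **Pairing** prefers proper pairs (opposite strands, forward mate
  leftmost, outer insert within `insert_range`, default 100–400 bp for
  200 ± 20 bp inserts) minimising total mismatches, but a mate's
  placement never changes a read's own `n_best_hits`.
* **Duplicates** are flagged per placement signature
  `(reference, strand, position, mate position)`, keeping the
  fewest-mismatch record with read-identifier order as the tie-break —
  the standard start-coordinate definition of PCR duplicates.
* External aligners interoperate via SAM: the `NM` tag carries mismatch
  counts, and mapping quality 0 is interpreted as non-unique when
  `n_best_hits` is unavailable.

# Genotyping

The caller is deliberately count-based. For a pileup column of depth d:

* d < `min_depth` (default 8, the conventional minimum depth for SNP
  detection): no-call, reason `low_depth`.
* majority base fraction strictly greater than `hom_fraction` (default
  0.80): homozygous for the majority base. The strictness matters at the
  boundary — 8 of 10 reads is *not* homozygous.
* otherwise heterozygous for the top two bases, provided the minor
  allele has at least `min_minor_reads` reads (default 2) and, by
  default, at least one read on each strand; a third allele reaching
  `min_minor_reads` makes the column tri-allelic and the call ambiguous.
* ties are broken in lexicographic base order, making calls invariant
  under read reordering.

`min_minor_reads` exists because the bare "more than 80% → homozygous,
otherwise heterozygous" rule would let a single erroneous read at depth
8 produce a heterozygous call. Overlapping mates are counted as two
independent observations — the simplest contract, stated and covered by
a test. Base qualities are ignored by the core rule (the synthetic reads
carry flat qualities); a minimum-quality ingest filter would sit in
front of the pileup, not inside the rule.

# The backmapping stage

Only heterozygous candidates trigger read extraction by default:
force-mapped mixtures present as heterozygous, while homozygous
non-reference calls are overwhelmingly genuine; `include_hom = TRUE`
extends extraction to them. Extraction takes every read *covering* a
selected candidate (each read once, mates included even if unmapped).
Covering, not just alternate-allele-supporting, is essential: re-typing
from the alternate-supporting reads alone would bias every surviving
candidate toward homozygous-alternate. The call records carry both sets.

After whole-genome remapping and duplicate removal, a read survives for
a candidate iff its single best placement covers the candidate's lifted
position. Re-typing runs the identical genotype rule on the surviving
reads. Verdicts separate the two elimination mechanisms: a candidate
that re-types homozygous-reference was a force-mapping artifact
(`hom_reference`), while one whose surviving depth falls below
`min_depth` is `low_depth_after_backmap` — its reads were ambiguous
rather than contradictory. Eliminated candidates are preserved in a
separate VCF with `FILTER=backmap_removed` because some of them are real
variants in homologous regions (see Limitations).

The older probe screen (`probe_backmap`: map the candidate's reference
k-mer, default the site ± 25 bases, to the genome and flag multi-locus
placements) is provided as a fast pre-filter but never eliminates
anything on its own: a probe can be unique — because a divergence site
falls inside its window — while the individual 50 bp reads over the
site are not. The test suite constructs exactly this case.

# QC metrics

* **On-target %**: fraction of mapped, non-duplicate reads whose span
  overlaps any target by ≥ 1 base.
* **ADoC**: mean depth over target bases.
* **Completeness**: fraction of target bases at or above each threshold
  in {1, 2, 5, 8, 15, 20, 30}; non-increasing by construction.
* **Enrichment factor**: (on-target read fraction) / (target length /
  genome size). This is the standard dimensionless fold-enrichment — it
  is 1 for uniform unenriched coverage (a property the suite verifies
  across 20 seeded simulations) — and is the package's own definition,
  documented as such.
* **Coverage AUC**: the exact Mann–Whitney formulation
  P(d_on > d_off) + ½ P(d_on = d_off) over per-base depths, computed
  from ranks, not a trapezoid approximation; invariant under monotone
  transforms of depth.
* **Strand bias**: |forward fraction − 0.5| × 2 as a percentage, so 0%
  is balanced and 100% is single-stranded.
* **Genotype concordance**: over sites called non-reference in both
  sets, the fraction with identical unordered genotypes; the discordant
  list supports replicate-based filtering.
* **Variant-set overlap**: Venn region counts over (chrom, pos, alt)
  keys for 2–3 sets; pairwise overlap is reported with both the
  min-set-size and the union denominator, since "percent overlap" is
  ambiguous between the two.

# The synthetic-data generator

The generator exists so that every stage, including the failure
mechanism, is testable from code alone. It emulates:

* a small multi-chromosome genome with an optional paralog: a donor span
  copied to a destination locus with i.i.d. per-base divergence, every
  divergence position recorded;
* planted heterozygous/homozygous SNPs realised as two haplotypes,
  avoiding divergence positions and each other;
* paired-end FR reads with normal insert sizes, uniform haplotype and
  strand choice, i.i.d. substitution errors, enriched coverage on
  capture intervals over a uniform background, and optional exact-copy
  duplicates;
* co-capture: the capture set may include the off-target paralog span,
  emulating cross-hybridisation — this is what makes force-mapped
  coverage appear at realistic depth.

Canonical scenarios (fixed seeds, overridable): `CLEAN` (60 kb, 8 kb
targets, no paralogy, 15 het + 10 hom, 30×), `PARALOG95` (200 kb, 5 kb
duplicated span at 95% identity co-captured, 20 het + 10 hom, 30×),
`IDENTICAL_DUP` (divergence 0 — every duplicated-span read has two
equal-best placements), `LOWDEPTH` (the 8× calling boundary). Defaults
follow the regime the method is meant for: 50 bp paired reads,
200 ± 20 bp inserts, 1% error, 30× on-target with background at
on-target/100. The problem sizes keep a full pipeline run in tens of
seconds while leaving hundreds of divergence sites in the paralog
scenario — enough to measure elimination fractions meaningfully.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: indels and structural variation (the aligner
is ungapped by design), base-quality profiles and quality-dependent
errors, PCR duplicates beyond exact copies, barcode chemistry
(replicates are emulated as independent seed-varied read sets from the
same haplotypes), and per-position capture-efficiency bias. The last one
matters for interpretation: real replicate coverage tracks correlate
strongly because they share probe-affinity structure, while two
independent simulations here share none, so their correlation is near
zero — the correlation-matrix code is therefore verified against the
closed-form Pearson computation and affine invariance, not against a
target correlation value.

# Numerical and determinism choices

Everything is deterministic: generator outputs are byte-identical under
a fixed (seed, parameters) pair; mapping, dedup, calling and re-typing
contain no randomness and fixed tie-breaks (reference order, position,
strand, lexicographic bases, read identifiers), so identical inputs give
byte-identical SAM and VCF. Degenerate inputs have defined behaviour:
empty read sets and empty target sets abort with clear errors; zero
depth makes strand bias missing, not 0; zero-variance coverage tracks
make the corresponding correlation missing, not 0; candidates with no
recorded reads are eliminated with reason `no_reads`.

# Limitations

* A true variant inside a (near-)identical duplication loses its reads
  to the uniqueness filter and is eliminated with
  `low_depth_after_backmap` — the price of the method; such variants are
  recoverable only from the removed-variants VCF. The `IDENTICAL_DUP`
  scenario demonstrates the extreme case, and at 95% identity a planted
  SNP sitting in a locally divergence-poor stretch can still be lost.
* The count-based rule mis-types zygosity when the sampled allele
  fraction crosses 80% by chance (binomial tail at moderate depth);
  both analysis modes are affected identically.
* Ungapped alignment: indels near a candidate shift mismatch counts and
  can perturb uniqueness decisions; indel calling is out of scope.
* TR-mode enrichment metrics are computed on alignments lifted from TR
  to genome coordinates, clipping the few bases of spacer overhang; the
  whole-genome mode's metrics are the reference QC numbers.
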