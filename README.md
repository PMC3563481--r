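# backmapr

Targeted-enrichment (capture) sequencing buys depth on the regions you
care about, but analysing it conventionally means mapping every read to
the whole genome — slow — while mapping only against the captured
regions is fast but dangerous: reads whose true locus lies *outside* the
target have nowhere correct to go, get **force-mapped** onto homologous
in-target sequence, and show up as spurious heterozygous SNPs at every
position where the two loci differ.

`backmapr` implements the two-step strategy that keeps the speed without
the artifacts, for anyone analysing capture panels or exomes (or
studying the force-mapping failure mode itself):

1. **Target-region (TR) mapping.** Targets are padded by one read
   length, merged, and concatenated into a single reference with runs of
   50 `N` between blocks (so no read can align across a junction); an
   exact transform table lifts coordinates back to the genome. Reads are
   mapped to this small reference and variants are typed from
   strand-aware pileups.
2. **Read-backmapping.** Only the reads covering candidate SNPs (plus
   their mates) are remapped to the whole genome. A read that maps
   better *or equally well* somewhere else is discarded everywhere, and
   each candidate is re-typed from the reads that remain uniquely mapped
   over its lifted position. Candidates that re-type homozygous
   reference, or fall below the depth threshold, are eliminated as
   force-mapping artifacts.

Genotypes use a count-based rule: a site with depth ≥ 8 is homozygous
for the majority base when its fraction is strictly greater than 80%,
otherwise heterozygous for the top two bases provided the minor allele
has ≥ 2 reads on both strands; anything else is a no-call with a reason
code.

The package also provides the capture QC metrics used to validate an
enrichment experiment — on-target read percentage, average depth of
coverage (ADoC), completeness at depth thresholds, enrichment factor
EF = (on-target read fraction)/(target share of the genome), the exact
rank-statistic coverage ROC AUC = P(d_on > d_off) + ½·P(d_on = d_off),
per-target strand bias, replicate coverage correlation, genotype
concordance and Venn-style variant-set overlap — plus a fully
deterministic synthetic-data generator whose paralogous decoy loci
reproduce the force-mapping mechanism, so the whole pipeline is testable
without any external data.

## Worked example

The `PARALOG95` scenario is a 200 kb two-chromosome genome in which a
5 kb in-target span is duplicated at 95% identity to an off-target locus
that is co-captured (as a real homolog would hybridise to the same
probes), with 30 planted SNPs, 30× on-target coverage and 1% read error:

```r
library(backmapr)

sc  <- synth_scenario("PARALOG95")
run <- run_tr_backmap(sc$genome, sc$targets, sc$reads$pairs)
run
#> backmapr tr_backmap run: 6840 read pairs, 30 final variant call(s)
#> read-backmapping report: 254 candidate variant(s); 20 retained,
#>   1 genotype changed, 233 eliminated (91.7%)

nrow(run$initial_calls)
#> [1] 263
```

TR-only calling yields 263 variants: the 30 planted SNPs plus 233
heterozygous false positives sitting exactly on the divergence positions
of the duplicated span. Backmapping the covering reads to the whole
genome relocates the paralog's reads to their true locus, every
divergence-site candidate re-types homozygous-reference and is
eliminated, and the final call set equals the planted truth:

```r
truth_key <- paste(sc$truth_variants$chrom, sc$truth_variants$pos)
final_key <- paste(run$final_calls$ref, run$final_calls$pos)
setequal(final_key, truth_key)
#> [1] TRUE
```

The per-variant verdicts, read accounting and elimination fraction are
in `run$report`; capture QC is in `run$enrichment`:

```r
run$enrichment
#> enrichment summary: 100.0% reads on target, ADoC 39.1x, EF 13.3, AUC 1.000
#> completeness: 1x 100.0%, 2x 100.0%, 5x 100.0%, 8x 100.0%, 15x 99.9%,
#>   20x 98.4%, 30x 70.0%
```

(The ADoC exceeds the nominal 30× inside the duplicated span because the
co-captured homolog's reads force-map there — visible enrichment QC is
exactly how such loci betray themselves.)

A command-line dispatcher wraps the same functions:

```sh
exec/backmapr simulate  --scenario PARALOG95 --out sim/
exec/backmapr build-ref --genome sim/genome.fa --targets sim/targets.bed --out ref/
exec/backmapr run --genome sim/genome.fa --targets sim/targets.bed \
    --fq1 sim/reads_1.fastq --fq2 sim/reads_2.fastq --mode both --out run/
exec/backmapr compare --vcf-a run/tr_backmap/final.vcf --vcf-b run/wg/final.vcf
```

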