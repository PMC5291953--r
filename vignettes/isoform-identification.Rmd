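---
title: "Identifying full-length mRNA isoforms from UMI-tagged single-cell long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying full-length mRNA isoforms from UMI-tagged single-cell long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscope)
```

## The problem

Short-read single-cell RNA-seq counts molecules but rarely resolves which
*isoform* of a gene each molecule represents. Long-read (circular
consensus) sequencing of full-length, UMI-tagged cDNA can, in principle,
read each molecule end to end — but the raw reads are messy in specific,
well-characterized ways:

* each molecule is wrapped in a grammar of adapters: a 16 bp sample
  barcode, the Illumina adapter `AATGATACGGCGACCACCGAT`, a 6 bp unique
  molecular identifier (UMI), a template-switch `GGG`, the cDNA itself,
  a poly-A tail, and the reverse complements of adapter and barcode —
  read in either orientation ("case 1" or its reverse complement,
  "case 2");
* during library circularization, several molecules can be ligated end
  to end, so one sequencing read may contain 2–4 complete cDNAs
  (concatemers) that must be split at internal adapter pairs;
* PCR emits each UMI-tagged molecule a variable number of times;
* reverse transcription and degradation truncate molecules from the 5'
  end, and alignment places ends and splice junctions with a small
  (~1 bp at junctions, ~5 bp at ends) uncertainty.

`isoscope` implements the full path from raw reads to isoform-level
statistics, plus a synthetic read generator that emulates every one of
these effects with known ground truth, so each stage can be validated
exactly.

## Pipeline model

**Extraction.** Adapters are matched by Hamming distance with at most 2
substitutions; circular-consensus reads are substitution-dominated, so
indel-aware matching is deliberately not used — it would also make the
2-mismatch rule ambiguous. A read is split into subreads wherever a
barcode reverse-complement match is immediately followed by a forward
barcode match (the boundary between two ligated molecules). A subread is
valid when exactly one sample barcode is present with its reverse
complement, the barcode is adjacent (±10 bp) to the Illumina adapter,
and a homopolymer tail of ≥10 A (case 1, before the reverse-complement
adapter) or ≥10 T (case 2, after the forward adapter) is found. Case-2
subreads are reverse complemented into transcript orientation and
re-parsed, which reduces both cases to one code path. The UMI is the 6
bases after the adapter; the template is trimmed of adapters, UMI, the
maximal G-run (≤5 nt; the template-switch signature's length is not
fixed in practice, so the trim is greedy but capped) and the poly-A
tail. Templates containing both an A-run and a T-run of ≥10 are dropped
as PCR artifacts. Every rejection carries an enumerated reason that is
tallied in the run manifest.

**Assembly.** Spliced alignments arrive as BED12 (one record per read,
blocks = exons); read ids appearing more than once are discarded as
non-unique alignments. Alignment blocks separated by gaps of <40 bp are
fused — spliced aligners fragment alignments with small spurious gaps,
and true introns are larger. Reads are assigned to the unique gene whose
annotated span (same strand) holds the majority of their aligned bases;
reads touching zero or several genes are set aside. Reads sharing a
(cell barcode, gene, UMI) key are collapsed into one consensus
transcript: identical block lists deduplicate; reads differing only in
their 5'-most position that share the same first 8 template bases take
the most 5' position (the discrepancy is then alignment-induced, not
biological); otherwise each coordinate takes the group median, with the
lower of the two central values for even groups so coordinates stay
integral and deterministic. Groups whose reads disagree on the exon
count first vote on the structure (majority, ties towards more exons).
The gene is part of the UMI key deliberately: with 4⁶ = 4096 UMIs,
collisions within a cell are certain at realistic molecule counts, and
the gene guard confines them to same-gene collisions, which the
majority/median rules then resolve.

**Isoform definition.** All transcript 5' ends of a gene (per anchor
first exon) are clustered by single linkage: two ends within 5 bp are
the same start site, and the cluster's range extends transitively —
a cluster can therefore be wider than 5 bp, which is intended; cluster
widths are reported for QC rather than capped. 3' ends are treated
symmetrically. Isoforms are then called at three strictness levels:

* **full** — same 5' cluster, identical junction chain, same 3' cluster;
* **conservative** — only transcripts that carry a poly-A tail *and*
  cover the annotated first exon (full-length molecules); junction
  coordinates differing by ≤1 bp are not distinct;
* **cassette** — same set of annotated exons, ends and junction
  micro-positions ignored.

For the conservative level, all junction coordinates observed in a gene
are pooled and clustered by single linkage at 1 bp, and each chain maps
to its sequence of junction clusters. Pooling across exon structures
means a junction shared by several structures is supported by all of
them. This was a genuinely open design point: a greedy,
support-ordered merge of chains within ±1 bp was considered and
rejected, because ±1 bp tolerance is non-transitive — a representative
chain at +1 never merges with a chain at −1 unless the 0 chain is
present, so greedy merging is not invariant under the very jitter the
tolerance exists to absorb. Transitive clustering of pooled positions
is, and it mirrors how end positions are clustered. The practical
consequence shows in the noise-robustness check below.

**Full-length filter.** A transcript covers the first exon when its
5'-most block overlaps the annotated first exon and starts within its
bounds, with a 5 bp upstream tolerance matching the end-placement
uncertainty; without that tolerance, genuine full-length molecules with
−1..−5 bp end noise would be discarded. 5'-truncation products that
start in exon 2 or later are always removed.

**Statistics.** For every gene and exon structure with ≥2 transcripts,
offsets from the (lower) median are computed at the 5' position, each
junction start and end, and the 3' position; the same computation over
raw reads of one UMI group quantifies pure technical variability. ERCC
spike-ins (92 species, 255–2007 bp, exactly known ends; one species
with inconsistent reference 3' ends is excluded throughout) calibrate
absolute end accuracy. Event counting classifies isoform diversity
into alternative TSS, TTS, exon-position and cassette events, each
counted beyond the first variant in its context; position events use
the same 1 bp tolerance as conservative isoforms, for consistency.
Exon co-inclusion is tested with a two-sided Fisher exact test over
transcripts whose span covers both exon loci (otherwise absence is
unobservable). Sites are labelled coding when they fall inside the
gene's CCDS-style coding intervals (ends inclusive); transcript ends
labelled coding are excluded as presumed artifacts. Coding and
non-coding junction variability are compared with a two-sided Wilcoxon
test — rank-sum by default, since the two site classes are independent
sets; a signed-rank form on per-gene mean absolute offsets is exposed
for matched comparisons, as the pairing unit behind the published use
of the signed-rank form on such data is ambiguous.

## The synthetic data generator

The generator is a first-class module, not a test fixture: it defines
the conditions every claim in this package is validated under.

* Gene models: 50 genes by default, 4–8 exons of 100–300 bp, introns
  200–1000 bp, on one simulated chromosome with random sequence; the
  CDS excludes 150 exonic bp at each transcript end so coding and
  non-coding junction classes both occur.
* Isoforms: 3 structures per gene (all exons; drop exon 2; drop exon 3)
  with sampling weights 0.5/0.3/0.2, so the major isoform carries about
  half of gene expression; optional alternative TSS/TTS sites spaced
  25 bp inside the first/last exon.
* Molecules: drawn per cell with a uniform random 6 bp UMI; with
  probability 0.7 a molecule is 5'-truncated to a random position in
  exon 2 or later (3' end intact), reflecting that in real single-cell
  data most 5' ends do not reach the annotated start. ERCC molecules
  are never truncated.
* Reads: each molecule is emitted a geometric (≥1, mean 1.6) number of
  times, so ~60% of UMIs are singletons; ends get uniform offsets on
  {−e..e} (defaults up to 5 bp), junction coordinates uniform offsets
  on {−j..j} (default 1 bp), independent per read; the poly-A tail is
  30 nt (threshold for detection is 10, the margin avoids boundary
  flakiness); a third of records are 2–4-mer concatemers (uniform
  arity — only the "three or more adapters" detection class is
  characterized in real data, not the arity distribution); each
  segment is rendered in case-1 or case-2 orientation with equal
  probability.
* Barcodes: six fixed 16-mers with pairwise Hamming distance ≥5
  (including reverse complements and adapter windows), so 2-mismatch
  demultiplexing is unambiguous by construction.

A fixed seed makes all outputs — FASTQ, BED12, GTF, truth tables —
byte-identical across runs. The generator writes the observed (noisy)
alignment BED12 the pipeline consumes, standing in for the spliced
aligner, and a noise-free truth BED12 per molecule; spliced alignment
itself is out of scope.

What the generator does *not* emulate: indel-dominated raw PacBio error
profiles (inputs are circular-consensus reads), quality-value
structure, chimeras other than end-to-end ligation, fragmentary
adapters, or expression-dependent gene weights. Passing tests therefore
demonstrate correctness of the grammar handling, consensus, clustering
and statistics under realistic geometry and noise — not robustness to
raw-read error modes the pipeline never sees.

## Numerical choices and degenerate inputs

* Medians use the lower-median convention throughout (even-sized
  groups take the lower central value): integral, deterministic, and
  biased towards the 5'/inner value rather than fabricating half-base
  coordinates.
* Single-linkage clustering on a line is computed by sorting unique
  positions and splitting where consecutive gaps exceed the link
  distance — exactly the connected components of the |a−b| ≤ d graph,
  verified against a brute-force union-find oracle.
* "Within 5 bp" and "1 bp difference" are inclusive (|a−b| ≤ 5 links;
  |a−b| ≤ 1 collapses); both boundaries are pinned by tests (5 links,
  6 does not; 1 collapses, 2 does not; gap 39 merges, 40 does not;
  2 adapter mismatches found, 3 lost).
* Ties in modal/representative selection resolve lexicographically;
  isoform results are invariant to transcript input order.
* Degenerate statistics are defined, not errors: empty or one-sided
  contingency tables give p = 1, all-zero offset comparisons give
  p = 1 (flagged by the degenerate count columns), singleton offset
  contexts are excluded and counted.
* Transcript ends overhanging the annotation by ≤5 bp are clamped into
  [0, 1] for relative-position summaries; larger overhangs give NA.

## Problem sizes

Unit tests run on small simulations (≤10 genes, ≤500 molecules). The
acceptance-style checks use the scale the method is specified at: 500
molecules across 3 barcodes with 30% concatemers for the grammar
round-trip (recovery ≥99.5% with exact barcode and UMI), and 50 genes ×
3 isoforms × ~2000 molecules for isoform recovery — exact
precision/recall 1.0 at zero noise, and ≥95% of genes with the exact
conservative isoform count under ±1 bp junction and ±4 bp end noise.
These sizes keep the full suite to a few minutes on one core.

## Known limitations

* Adapter matching is substitution-only; a read with an indel inside an
  adapter can fail demultiplexing. Real circular-consensus data makes
  this rare; raw subreads would not.
* Spurious 2-mismatch barcode look-alikes inside a template reject the
  read as a barcode conflict (the "no other barcode in between" rule is
  applied literally); at random-sequence rates this loses well under
  0.5% of molecules.
* Genes are assumed non-overlapping on a strand; reads overlapping two
  annotated spans are unassigned rather than arbitrated.
* The conservative tolerance absorbs ±1 bp jitter only when the true
  junction value is observed at least once in the gene (it bridges −1
  and +1); a gene observed solely at the two extremes keeps two
  isoforms. With pooled junction clustering this needs every structure
  sharing the junction to miss the true value simultaneously, which at
  realistic coverage is negligible.
* Intron-retention-like transcripts (a block spanning a full annotated
  intron, e.g. after gap-fusion of a short intron) are not separately
  flagged; they surface as distinct cassette structures.
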