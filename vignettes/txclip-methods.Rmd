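---
title: "Transcript-aware CLIP-seq site processing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript-aware CLIP-seq site processing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txclip)
```

## Why transcript context

CLIP-seq peak callers place RBP binding sites on the genome, but for
proteins that bind mature (spliced) RNA the biologically meaningful
coordinate system is the transcript. Two artefacts follow from ignoring
this. First, a binding site spanning an exon–exon junction appears in
genomic coordinates as two separate peaks at the adjacent exon ends; we
call these *pair sites*. Second, the common practice of extending sites
with flanking genomic sequence — for motif searches or to build training
sets for site-prediction models — pulls in intronic bases that are absent
from the RNA the protein actually bound. txclip implements the site
algebra, coordinate mapping, context extraction and motif scanning needed
to quantify and correct both artefacts.

## Isoform selection

Mapping a genomic site into "the" transcript requires choosing one isoform
per gene. `select_most_prominent()` applies a hierarchical filter over
Ensembl-style annotation: only transcripts in the GENCODE basic set that
carry an APPRIS label *and* a transcript support level are eligible;
candidates are ranked by APPRIS label first (principal1 best), TSL second
(1 best). Genes with no eligible isoform are dropped entirely rather than
falling back to weaker evidence — exon coordinates from poorly supported
isoforms would contaminate every downstream overlap statistic.

Two ordering details are our own choices, since the label hierarchy alone
does not totalise the order: `alternative1`/`alternative2` APPRIS labels
are accepted but rank below all `principal` labels, and remaining ties are
broken by longer spliced length, then lexicographic transcript id. The
last two rules carry no biological meaning; they exist solely to make the
selection deterministic and order-invariant.

The GTF reader is implemented in the package rather than delegated to a
generic importer because Ensembl encodes APPRIS and basic membership as
*repeated* `tag` attributes on one line; importers that map attributes to
one column per key keep only a single `tag` value and silently lose the
information the hierarchy needs. The reader also reports malformed input
by line number and accepts both the `transcript_support_level` and `tsl`
attribute spellings, with a literal `"NA"` treated as missing.

## Coordinate mapping

Internally all intervals are GenomicRanges/IRanges objects, i.e. 1-based
closed coordinates — the convention of the R/Bioconductor interval stack
this package is built on. BED input and output are converted at the file
boundary (BED is 0-based half-open), exactly as the standard importers do.

Transcript coordinates run 5'→3' along the mature mRNA: position 1 is the
transcript 5' end, so on a minus-strand model the genomic *end* of an
exonic interval maps to the smallest transcript coordinate. This is the
natural orientation for motif work, where patterns are defined on the RNA.

`genome_to_transcript()` maps the exonic bases of a genomic interval to
their (always contiguous) spliced image. Intervals that partially overlap
introns are *reported* with their exonic fraction rather than silently
clipped — the ≥90 % overlap policy belongs to the caller, and different
callers legitimately want different policies. `transcript_to_genome()` is
the exact inverse: an interval crossing k junctions yields k+1 genomic
blocks separated by whole introns, writable as BED12. Sites overlapping
exons of several retained isoforms are assigned to the isoform with the
largest exon overlap, ties broken by transcript id.

## Site algebra and thresholds

All numeric parameters live in one `thresholds()` record:

| parameter | default | meaning |
|---|---|---|
| `min_lfc` | 1 | minimum log2 fold change after replicate merging |
| `max_len` | ∞ (80 for context sets) | maximum site length, nt |
| `max_pvalue` | off (0.01 for context sets) | maximum site p-value |
| `exon_overlap_frac` | 0.90 | exonic-site overlap fraction |
| `border_dist` | 50 | near-border distance, nt (inclusive) |
| `pair_dist` | 10 | pair-site border distance, nt (strict `<`) |
| `merge_dist` | 10 | merge sites with gap `<` this, nt |
| `ext` | 80 | context extension per side (window 2·80+1 = 161 nt) |

Replicate merging keeps, within every component of transitively
overlapping same-strand sites, only the site with the highest LFC — with
its own coordinates, not the union span, since a merged span would mix
evidence from sites that were never jointly observed. Nearby-site merging
uses the same winner rule over components formed by gaps strictly smaller
than `merge_dist`; book-ended sites (gap 0) overlap by zero bases and are
therefore merged by `merge_nearby()` but not by `merge_replicates()`,
which requires ≥1 nt of true overlap. Both operations are idempotent and
order-invariant, which the test suite asserts by property.

The exonic overlap fraction uses the *site* length as denominator
(fraction-of-query semantics, as in `intersectBed -f`), computed against
the reduced exon union of the selected isoforms only, strand-matched
(strand `"."` sites match both strands). Border distances are measured
from each site end to the matching border of its containing exon, oriented
5'→3' along the transcript; a site is near-border when the minimum over
its two ends is ≤ `border_dist`. Pair detection requires, strictly below
`pair_dist`, the 3'-end distance of the upstream site at exon *i* and the
5'-end distance of the downstream site at exon *i*+1 of the same model;
each site joins at most one pair, assigned greedily by junction and then
by summed LFC. Sites classified exonic at fractional overlap may overhang
an exon edge by up to 10 % of their length; for border statistics such
ends are clipped to the exon union first (`clip = TRUE`), since an
overhanging end is by construction at distance 0 from the border.

## Context extraction

A site is reduced to its center base: the middle base for odd lengths,
and for even lengths the more 5'-ward of the two central bases — a
convention chosen so that reverse-complementing the input flips the choice
consistently; the paper-level procedure does not specify it. The center is
then extended ±`ext` nt either on the genome (`extract_genomic_context()`,
reverse-complemented for minus-strand sites so sequences always read
5'→3') or in spliced coordinates (`extract_transcript_context()`, reading
through junctions). Transcript windows truncate at transcript ends;
genomic windows only at chromosome ends. Truncated sequences are kept and
reported with their lost lengths (`up_truncated`, `dn_truncated`) rather
than re-padded or dropped — full extension at transcript ends is only
possible in genomic context, and that asymmetry is part of what the
genomic/transcript comparison is about. FASTA output encodes site id,
space, window, viewpoint position and truncation in the header; genomic
`N`s propagate into contexts untouched.

## Motif scanning

Motif definitions cover plain IUPAC strings (RNA `U` normalised to `T` at
parse time), bounded spacers `N{a-b}` and repeats `[XY]k` — enough to
express both single-element motifs like the PUM2 PRE (`UGUANAUA`) and
multi-domain compound motifs like the IGF2BP3 motif
(`GGC-N{15-25}-CA-N{7-20}-CA-N{15-25}-GGC-N{2-8}-[CA]4`).

The scanner reports **one hit per start position**: a start with several
feasible gap assignments would otherwise inflate positional hit counts,
and counts are the quantity being compared between context sets. Among
feasible assignments the minimal-total-gap one (ties resolved smallest
gap first from the left) defines the reported match. The test suite pins
the scanner, on hundreds of random instances, to an independent oracle
that exhaustively enumerates every gap combination. A masked base (`N` in
the sequence) matches only motif `N`, never a concrete IUPAC code, to
avoid phantom hits in masked regions. Hits are deduplicated on (space,
target, strand, start, end, motif): identical positions reached from
overlapping context windows count once. Transcript-space hits map back to
the genome via `transcript_to_genome()`; a hit is *split* when it maps to
two or more blocks. Frequencies between context sets are compared as
hits per nt of total context length, with the percent change
100·(d_t/d_g − 1); scanning happens on the sense strand only, because
context sequences are already strand-resolved.

## Negative sampling

`sample_negatives()` draws classifier-training negatives uniformly from
the gene spans (first to last exon of the selected isoform) of genes
covered by at least one positive, excluding — base-exactly and
strand-blind — every position that would make a negative overlap any
positive site. Negatives default to 161 nt so they match positive context
windows without further extension, inherit the strand of their gene, and
are kept mutually non-overlapping (our choice; duplicate or overlapping
negatives would be near-duplicate training examples). Sampling only
genomic space mirrors how such negative sets are built for this assay.
When fewer than `n` eligible positions exist the available ones are
returned with a warning and an `exhausted` flag. Determinism under a fixed
seed is part of the contract and is tested byte-for-byte.

## The synthetic fixture

`make_fixture()` is first-class, tested code, not a test utility: it
generates a toy genome (i.i.d. uniform bases over up to three
chromosomes), an Ensembl-style GTF with APPRIS/TSL/basic labels including
decoy isoforms with strictly worse labels and one gene that must be
excluded, BED peak sites planted per category (deep exonic, near-border,
pair, intronic, transcript-end), and motif instances written into the
genome at chosen spliced positions — including instances straddling
junctions, whose image is split across the flanking exon ends. Every
planted object is recorded in truth tables, and identical seeds give
byte-identical files.

The generator makes specific guarantees so that planted truth equals
pipeline output exactly: gene 1 is single-exon and roughly 40 % of genes
are minus-strand (to exercise orientation code); exon lengths start at
140 nt so a deep site fits with both ends > 50 nt from the borders; deep
sites additionally keep their ±80 nt window inside the transcript; each
exon border hosts at most one planted site, and near-border distances are
drawn from [10, 50] so they can never form accidental pairs (which need
< 10 nt). Junction-split motif instances are placed so that each genomic
run is shorter than the motif's minimal match length, so no complete match
can sit on one side of the junction; chance matches that the uniform
background produces inside a genomic context window are removed by
rotating the unprotected (non-planted) bases of the accidental hit, which
never touches planted instances. What the fixture deliberately does not
emulate: read-level signal, crosslink-induced truncations, non-uniform
base composition, overlapping genes, and alternative isoform expression —
so green tests demonstrate algorithmic correctness on planted structure,
not performance on real eCLIP data, whose headline percentages depend on
specific ENCODE datasets and annotation releases and are out of scope
here.

## Numerical and edge-case conventions

* Inclusive bounds for all filter thresholds ("maximum length 80" keeps
  length 80); strict `<` only where stated (pair distance, merge gap).
* "Merging nearby sites" uses *gap < merge_dist*; a gap of exactly
  `merge_dist` keeps both sites.
* Even-length centering breaks ties toward 5'.
* The top ratio-histogram bin [75, 100] is right-closed so a ratio of
  exactly 1 is counted.
* Zero-variance inputs to the ratio correlation, empty exonic sets, and
  zero genomic motif hits yield flagged `NA`s, not errors.
* `sample_negatives()` and `make_fixture()` take explicit seeds; all other
  functions are deterministic.

## Problem sizes used in the checks

The bundled verification runs use fixtures of 10–50 genes (three
chromosomes, genomes of tens of kilobases), 1,000-interval round-trip and
overlap-oracle checks, and 200 random motif-scanner instances against the
exhaustive oracle — sizes at which planted truth is exactly recoverable
and every check runs in seconds, chosen as the package's own test design.
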