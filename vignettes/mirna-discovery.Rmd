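---
title: "Small-RNA miRNA discovery and two-library differential analysis with miRvine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-RNA miRNA discovery and two-library differential analysis with miRvine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRvine)
```

## The analysis

miRvine implements the classical desk analysis of a two-condition plant
small-RNA sequencing experiment — one library from hormone-treated tissue
and one from a control — in which the questions are: which miRNAs are
present, which of them are novel to the species, and which respond to the
treatment. The package is organised as one function per analytical step,
with numbered driver scripts under `analysis/` that run the steps in
order on a synthetic study and write their tables under `results/`.

The stages are:

1. **Preprocessing.** 3' adapter removal (left-most seed match of the
   adapter prefix, seed ≥ 8 nt, ≤ 1 mismatch by default), removal of
   reads outside 18–30 nt, of reads containing N, and of polyA-dominated
   reads (≥ 80% A by default), then collapsing of identical reads into
   unique *tags* with multiplicities. "Unique" (distinct tags) and
   "redundant" (read-weighted) views are both first-class, since the two
   weightings answer different questions about a library.
2. **Profiling.** Length distribution and first-nucleotide bias per
   length. In healthy plant libraries the length histogram peaks at 21 nt
   (miRNA-sized) and 24 nt (heterochromatic siRNA-sized) and miRNA-sized
   tags show an excess of 5' uridine, so these two profiles are the
   standard first sanity check.
3. **Annotation.** Each tag receives exactly one category by a fixed
   priority: known miRNA > rRNA > tRNA > snRNA > snoRNA > repeat > exon
   (sense, then antisense) > intron (sense, then antisense) >
   unannotated. Structural-RNA-first is the standard convention; the
   priority makes the breakdown a true partition, which the tests
   enforce. Class membership is exact substring matching against class
   reference sequences (either strand); a separate, deliberately
   non-exclusive "maps to genome" tally is reported alongside, because a
   tag can both map and be, say, ribosomal.
4. **Known-miRNA matching.** Tags are compared to a mature reference
   (miRBase-style) by ungapped alignment over all offsets up to ±4 nt.
   The cost of an offset is the mismatch count inside the overlap plus
   the unaligned overhang of the shorter sequence; hits with cost ≤ 3 are
   accepted, ties broken by cost, then |offset|, then reference
   identifier. Counting overhangs keeps the 0–3 budget meaningful while
   still letting length-variant isomiRs (20–23-nt members of one family)
   match. Each tag's abundance is attributed to its single best
   reference, never double-counted.
5. **Novel discovery.** Unannotated tags of mature length are mapped
   exactly to the genome (both strands). Around each locus two windows
   are extracted (default 150-nt flank on the long side, 20 nt on the
   short side), and candidate precursors are folded and evaluated. Each
   distinct locus of a multi-locus tag yields its own candidate, with
   abundance shared, not multiplied; tags mapping to more than 5 loci are
   set aside as repeat-derived.
6. **Differential classification.** Counts are normalized to
   reads-per-million (NC), and each mature is classified by its two NCs:
   detected only in the treatment (▲), only in the control (▼), in
   neither (●), or, when present in both, up (↑) if the treatment/control
   ratio is ≥ 1.5, down (↓) if ≤ 1/1.5, unchanged (●) otherwise.
7. **Target prediction and cleavage validation.** Each mature is scanned
   against a transcript set by exhaustive ungapped antisense windows with
   a mismatch budget of 3, G:U wobbles counting 0.5. RACE-derived
   cleavage coordinates are validated by computing which miRNA position
   pairs the observed 5' end of the downstream fragment; positions 9–11
   support slicing.

## Secondary-structure folding

The folding engine maximizes the number of base pairs (Watson–Crick plus
G:U) under the no-pseudoknot constraint with a minimum hairpin loop of
3 nt — a Nussinov-style dynamic program, written in C++ for speed and
verified in the test suite against an independent pure-R interval
recursion for every sequence up to 30 nt, and against full structure
enumeration on tiny inputs. The traceback is deterministic: within any
interval the leftmost base pairs the smallest admissible partner.

Maximum pairing is a counting objective, not a free-energy model, and it
has a characteristic artifact: on long windows it happily pairs mature
bases with distant background, and near the terminal loop it squeezes in
an extra pair by shifting the register. Two design choices absorb this:

- **Boundary refinement.** Rather than folding the full flank window
  once, the discovery step folds a ladder of sub-windows anchored at the
  mature (long side from 40 nt — the tightest loop-plus-star span — up to
  the flank, in 15-nt steps) and accepts the first that passes. Small
  windows are dominated by the hairpin's own pairing, so the planted
  structure wins whenever it exists.
- **Duplex-chain evaluation.** The hairpin check does not require every
  paired mature base to be consistent. It finds the longest chain of
  mature pairs that lie on one side, run antiparallel, and whose
  mature-side gaps and star-side jumps stay within the bulge limit
  (3 nt); pairs outside the chain count as mismatches. Acceptance then
  requires ≥ 16 chained pairs and ≤ 4 mismatching mature bases, the
  mature entirely on one arm, operationalizing the community annotation
  criteria for plant miRNAs (near-complete mature/star pairing, no large
  bulges, both arms of one foldback).

The predicted star is anchored at the loop-distal mature end — its
partner projection is the stable one — with the mature's length and the
canonical 2-nt 3' overhang shift. Star detection then looks for a
sequenced tag equal to the prediction within ±2 nt end shifts, since real
(and simulated) star reads have ragged ends. An energy-based folding
backend could be swapped in behind the same `fold()` contract without
touching the evaluation logic.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| adapter seed / mismatches | 8 nt / 1 | typical small-RNA trimming stringency |
| tag length range | 18–30 nt | the gel-excised small-RNA size window |
| polyA threshold | ≥ 80% A | drops oligo-A artifacts without touching A-rich miRNAs |
| known-match budget | 3 | the conserved-miRNA matching rule (0–3 mismatches) |
| known-match shift | ±4 nt | spans the isomiR end-variation seen within families |
| min paired mature bases | 16 of 21 | near-complete duplex pairing |
| max duplex mismatches / bulge | 4 / 3 nt | community hairpin-annotation practice |
| precursor length | 50–300 nt | plant precursor range |
| flank window | 150 nt each side | hosts any precursor in range around the mature |
| fold-change threshold | 1.5 | conservative two-library call; presence/absence calls are threshold-free |
| target mismatch budget | 3 (G:U = 0.5) | "fewer than four mismatches", wobble-tolerant |
| cleavage support | miRNA positions 9–11 | canonical slicing register |

All thresholds are arguments with these defaults; none is hard-coded.
The positional target rules (no mismatch opposite positions 10–11, at
most one in 2–12) are individually switchable because published analyses
vary in whether they apply them on top of the raw mismatch cut.

## The synthetic study

`simulation_spec()` describes the study the generator emulates: a
100-kb genome hosting 20 perfect-stem hairpins (mature 21 nt with 5'U
probability 0.6, loop 6–12 nt), contaminant reference classes (rRNA,
tRNA, snRNA, snoRNA) embedded in the genome, and paired control/treatment
libraries of roughly 50,000 reads each, so miRNA reads are a few percent
of the library as in real data. Per-miRNA read counts are Poisson around
planted means of 20–200 — single libraries per condition, as in the
two-library design this workflow addresses, so there is no replicate
dispersion to model. The planted response classes cycle through up (8×),
down (1/8×), treatment-only, control-only and unchanged; reads get a 3'
adapter, 1-nt end jitter with probability 0.1 (exercising the
offset-tolerant matching and star detection) and substitution errors at
rate 0.01. Everything is deterministic given the seed.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: sequencing-error profiles beyond uniform
substitutions, ligation bias, imperfect (bulged) precursor stems,
multi-locus miRNA families with divergent precursors, and genome-scale
repeat content. The perfect-stem precursors make hairpin recovery a test
of the machinery, not of the folding model's discrimination on marginal
real hairpins.

## Numerical and degenerate-input choices

- NC values are carried at full precision; the 2-decimal form is applied
  only when report tables are written.
- A record absent from both libraries classifies as "unchanged" (the
  degenerate both-zero case).
- Ties in known-matching break deterministically (cost, |offset|,
  identifier), so reports are byte-stable across runs.
- N never matches anything: not in trimming, matching, mapping, or
  pairing; reads containing N are dropped before collapsing because they
  break exact-collapse semantics.
- Windows are clamped at contig edges rather than rejected; loci that
  fall outside their contig are errors.
- Internally, all coordinates are 1-based inclusive (the
  Bioconductor/GFF3 convention), with `GenomicRanges`/`rtracklayer`
  handling GFF3 emission and round-trips.

## Problem sizes

The shipped analyses and tests run at the scale the generator defaults
describe: 100-kb genome, 20 hairpins, ~50k reads per library; the
oracle-equivalence suites use sequences up to 30 nt for folding, 10-kb
genomes for mapping, and 2-kb transcripts for target scanning. These
sizes are where the brute-force oracles remain exact and the full
workflow completes in seconds to a couple of minutes.

## Known limitations

- Maximum-pairing folding cannot rank near-miss hairpins the way a
  thermodynamic model would; it is a structure-existence engine.
- With one library per condition there is no statistical test behind the
  up/down calls — the fold-change threshold is a descriptive cutoff, and
  near-threshold calls on low counts are noisy (which is why
  presence/absence classes, not ratio classes, are the quantities carried
  to the acceptance checks).
- Exact-substring annotation cannot recognise diverged family members of
  structural RNAs; interval-based annotation against a genome browser
  track is the alternative when coordinates are available.
- The shape of this artifact is an analysis workflow, not a shell tool:
  the driver scripts and exported functions are the interface, and no
  separate command-line wrapper is provided.
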