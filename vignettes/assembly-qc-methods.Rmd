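---
title: "Perfect-read coverage QC: models, parameters and design choices"
author: "pbdqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfect-read coverage QC: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbdqc)
library(GenomicRanges)
```

## The perfect-read principle

Long reads carry the native structure of the genome. When an assembly is
locally correct, a read drawn from that locus aligns end to end; when the
assembly disagrees with the molecules — a misjoin, missing sequence, or a
repeat assembled with too few copies — reads spanning the discordant point
can only align partially. Aligners report those reads with clipped ends, so
the *depth of end-to-end ("perfectly mapped") reads* is a direct local
witness of assembly correctness, in a way total read depth is not.

`pbdqc` operationalises this as a three-stage scan:

1. **Perfect-read selection** (`selectPerfect()`). A PAF record qualifies
   when it is a primary alignment and *full-length*: the unaligned stubs at
   both read ends (`query_start` and `query_len - query_end`, measured on
   read coordinates, strand-independent) are each at most the platform
   tolerance — **200 bp for HiFi** reads and **1 kb for ultra-long ONT**
   reads. Surviving records are resolved to one per read (most residue
   matches; ties by smaller target start, then target name). Secondary and
   inversion-tagged records (`tp:A:S`, `tp:A:I`) are both excluded;
   records with no `tp` tag are counted as primary, since some aligner
   configurations omit the tag.
2. **Windowed depth** (`perfectCoverageTrack()`). Mean per-base perfect-read
   depth in sliding windows of **50 kb with a 25 kb step**, skipping
   **20 kb at each chromosome end** where depth estimates are unreliable.
   Window coverage is a mean depth, not a breadth-of-coverage fraction.
3. **Classification** (`classifyWindows()`). Each window's depth is divided
   by the chromosome's mean perfect-read depth; ratios within
   **[0.5, 2.5]** are deemed correct. Ratios strictly below 0.5 flag a
   `low` region (candidate misjoin or missing sequence); ratios strictly
   above 2.5 flag a `high` region (candidate collapsed repeat — reads from
   several true copies pile onto the surviving one). Consecutive flagged
   windows of one kind merge into a single region.

The normaliser is deliberately **per chromosome**, and computed from the
perfect set itself over the evaluated region. Sex chromosomes sequenced
from the homogametic-depth side sit at half the autosomal depth; a
genome-wide normaliser would flag such whole chromosomes as `low`, while
the per-chromosome ratio keeps the method valid there.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `endToleranceHifi` / `endToleranceOnt` | 200 / 1000 | bp | unaligned read-end stub still counted full-length |
| `window`, `step` | 50 000, 25 000 | bp | sliding-window geometry |
| `endExclusion` | 20 000 | bp | excluded at each chromosome end |
| `lowRatio`, `highRatio` | 0.5, 2.5 | ratio | correctness band around the chromosome mean |
| `mergeGap` | 0 | windows | unflagged windows tolerated inside one region |
| telomere `motif` | `TTAGG` | — | insect telomeric pentamer (left end scans `CCTAA`) |
| `terminalWindow`, `minRun` | 10 000, 2 500 | bp | completeness criterion per chromosome end |
| `maxInterruption` | 100 | bp | gap chained across between motif matches |
| triage (HiFi) | 50 kb / 8 kb / 80% | — | neighborhood flank / min aligned span / min identity |
| triage (ONT) | 200 kb / 18 kb / 80% | — | idem for ultra-long reads |
| patch accept (HiFi) | 80 kb / 95% | — | min best-alignment span / identity |
| patch accept (ONT) | 100 kb / 94% | — | idem |
| synteny `minBlock` | 20 000 | bp | minimum reference span of a collinearity block |

All defaults are exposed so the scan can be rescaled; the package's own
tests run a tenfold reduction (1 Mb chromosomes, 5 kb / 2.5 kb windows,
2 kb exclusion) to keep simulated genomes small, with all ratios and
tolerances unchanged.

## Telomere completeness

A chromosome end is complete when a telomeric run overlaps the terminal
10 kb window by at least 2.5 kb. Two choices deserve note:

* **Overlap, not containment.** Complete telomeres are typically longer
  than the terminal window itself, so requiring the whole run to lie inside
  10 kb would be unsatisfiable; `callTelomere()` instead requires at least
  `minRun` bases of the best run *inside* the window.
* **Strand per side.** On the forward strand a left telomere literally
  reads `CCTAA` (the reverse complement of `TTAGG`), so the left end is
  scanned for `CCTAA` and the right end for `TTAGG`; reverse-complementing
  a chromosome therefore swaps the two calls exactly, a property the test
  suite asserts.

Runs are chains of exact pentamer matches; `maxInterruption` (default
100 bp) admits the variant repeats real arrays carry, and tests that need
exact arithmetic set it to 0. Each call also reports `blockCount`, the
number of non-overlapping left-to-right matches of the 25-bp pentamer
block (motif × 5) inside the terminal window — a compact length proxy that
is robust to isolated variant repeats.

## Read triage and patch validation

Around every gap — and every chromosome end, treated as a zero-length gap —
reads with an anchoring alignment are pooled for local re-assembly:
the alignment must intersect the neighborhood (gap ± `region`), span at
least `minHomolog` on the *reference* (the span relevant to anchoring; the
read-side span can be inflated by insertions), and reach `minIdentity`.
A candidate patch contig is accepted when its best primary alignment back
to the reference spans `acceptOverlap` at `acceptIdentity`; with
`chain = TRUE` colinear primary pieces are summed instead, for aligners
that fragment one long match. The action is `fill` when qualifying
alignments anchor both sides of the gap, `extend` for one side — the mode
that pushes assemblies outward into telomeres.

Only a single triage round is implemented. Iterating rounds until all gaps
close involves judgment calls (accept a partial patch? re-open a filled
gap?) that are not algorithmic; the round primitive is the reusable part.

## The simulator: what it emulates, and what it does not

`simulateGenome()` builds multi-chromosome toy genomes with the features
the detectors key on: `CCTAA`/`TTAGG` telomeric arrays (10 kb per end), a
central tandem array of a shared repeat family, identical interspersed
repeat copies, and unique sequence elsewhere. `injectErrors()` corrupts a
truth genome with deletions, tandem-copy collapses, in-place expansions,
inversions and chimeric tail swaps, returning truth coordinates and a
truth↔corrupted liftover. `simulateReads()` draws error-free reads on the
study profiles — HiFi-like lognormal lengths (mean 15 kb, minimum 5 kb) at
85.8× and ONT-like (mean 90 kb, minimum 50 kb) at 133.7× by default — and
`truthAlign()` lifts them onto the corrupted assembly, producing exactly
the alignment geometry an idealised aligner would report: full-length
records inside unbroken segments, clipped primaries plus secondary pieces
across breakpoints, removed-copy reads stacked onto the collapse survivor,
and nothing from deleted sequence.

Three deliberate simplifications:

* **Reads are error-free.** The detector's signal is structural (partial
  versus full-length alignment), not base-error-driven; identity
  thresholds are exercised by degrading match counts synthetically in
  tests instead. Consequently, passing tests say nothing about
  base-error-induced clipping in real data.
* **Alignments come from the liftover, not an aligner.** This keeps tests
  exact and dependency-free and encodes precisely the mapping behaviour
  the method assumes. Real minimap2 PAF drops in unchanged through
  `readPaf()`.
* **Read starts are uniform with edge clipping.** Reads overhanging either
  chromosome end are clipped to it (molecules end where the chromosome
  does), so expected depth is uniform along the chromosome and the
  false-positive control is not confounded by end tapering.

## Numerical choices

* **Coordinates.** Interval containers are `GRanges`/`IRanges` (1-based
  closed), the convention of the surrounding ecosystem; PAF columns are
  kept 0-based half-open as the format defines them, and BED/bedGraph
  output is 0-based half-open. Conversion happens only at I/O boundaries.
* **Window bookkeeping.** The last window is truncated at the evaluated
  region's end; a truncated window shorter than one step is dropped; a
  chromosome whose evaluated region is shorter than one step yields an
  empty track and a warning rather than a degenerate estimate.
* **Ties.** Every best-of selection (perfect-read resolution, patch
  acceptance, primary piece in the simulator) has a total deterministic
  order, so identical inputs give byte-identical outputs — asserted
  down to file bytes in the tests.
* **Breakpoint localisation.** Around a junction the perfect-read depth is
  not a step function but a ramp roughly one read length wide (a read
  crossing the junction is lost from the perfect set unless its overhang
  is within tolerance). A flagged region therefore *contains* the
  breakpoint but extends several windows beyond it on both sides; the
  package's accuracy claim is that the true breakpoint lies within one
  window step of the flagged region, not that the region is one window
  wide.
* **Collapse detectability.** A collapsed repeat presents as a depth
  *gain* only for reads short enough to fit inside one repeat unit;
  reads longer than the unit cross copy junctions, leave the perfect set,
  and present as a depth *loss* instead. The simulator's default unit
  (50 kb × 4 copies) exceeds the HiFi length scale but not the ONT one,
  so the same injected collapse shows the high signature in the HiFi scan
  and the complementary behaviour in the ONT scan — matching the practical
  need for longer reads (and larger assembler overlap settings) to
  resolve large collapsed units.
* **Expansions.** A duplicated segment splits true coverage between the
  two corrupted copies; with the simulator's deterministic primary choice
  the inserted copy shows near-zero perfect depth. Expansions are
  reported through the same `low` channel, not a dedicated one.
* **Combination across read sets.** `pbdReport()` defaults to the union —
  a region flagged by either platform is suspect, and the two platforms
  see complementary error classes — with intersection mode available where
  precision matters more than recall.

## Scope of the test evidence

The simulation suite runs 20 seeded misassembly scenarios (three 1 Mb
chromosomes; a 20 kb deletion, a 4→1 collapse of a 50 kb unit, a chimeric
tail swap; both platforms at 60×) plus 10 error-free controls, asserting
full recall with correct kinds, breakpoints within one 2.5 kb step, and
zero false positives. Those sizes were chosen so the whole suite runs in
about a minute; they demonstrate the mechanism, not performance on
chromosome-scale data, heterozygous samples, or error-prone reads.

## Known limitations

* PAF only; no SAM/BAM input and no CIGAR-level identity (identity is
  gap-inclusive `matches / block_length`).
* Gap-compressed identity is not computed; thresholds interpret identity
  as the PAF columns define it.
* No interstitial telomere scan and no read-based telomere length
  estimate.
* The collinearity module classifies and groups inverted blocks; it does
  not chain or rescue split alignments before applying the block cutoff.
* Flagged regions are reported, not corrected; correction belongs to
  external assemblers operating on the triaged read bins.
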