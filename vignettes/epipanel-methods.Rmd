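---
title: "epipanel: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epipanel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipanel)
```

This vignette records the model behind `epipanel`, the conventions it
commits to, and the reasoning behind choices the interfaces themselves
cannot express.

## The model

The unit of analysis is the *gene panel*: one gene, its flanking window,
and every loaded data layer re-expressed in a TSS-relative,
orientation-corrected coordinate system.

**Coordinates.** Everything is 0-based, half-open `[start, end)` — the
native convention of BED-family formats, and the one under which interval
lengths are `end - start` and abutting intervals share no base. For a
`+`-strand gene the transcription start site (TSS) is `span_start` and
`rel = x - span_start`. For a `-`-strand gene the TSS is the *exclusive*
bound `span_end`, and an interval maps to
`(span_end - end, span_end - start)`: the reflection swaps the endpoints,
so relative intervals stay well-formed with `rel_start < rel_end`. Under
this transform negative positions are always biologically upstream and
the gene body occupies `[0, gene_length)` on both strands, which is what
makes panels from opposite strands directly comparable and lets a single
filter window like `[-5000, 2000)` mean "5 kb upstream through 2 kb into
the gene" for every gene.

**Isoform collapse.** Annotation tables are transcript-level; queries are
gene-level. Each gene is represented by its largest isoform (maximum
span; ties broken by file order, so the result is deterministic). Gene
identifiers resolve case-insensitively through all alias columns declared
in the identifier map.

**Window admission.** A peak belongs to a panel when it overlaps
`[-flank_up, L + flank_down)` by at least one base. Peaks are stored
*unclipped*: clipping would silently change sizes and make round trips
lossy; admission-by-overlap keeps the panel an honest subset of the
input. The default flanks are 20 kb each — wide enough to capture
promoter-proximal and nearby enhancer signal for typical mammalian gene
spacing, while keeping panels local. `set_flanks()` remaps from the
originals rather than trimming, so widening a window is exact.

**Distances.** The distance between two features is the half-open gap
`max(0, max(starts) - min(ends))`: overlapping or abutting intervals are
at distance 0. "A upstream of B" additionally requires `A` to end at or
before `B` starts *in relative coordinates*, so the relation is
orientation-corrected for free.

## Filter semantics

A filter chain is evaluated sequentially over the currently shown panels,
and the only mutation a filter may make is clearing the per-gene `show`
flag. Two properties follow and are tested directly:

- the trace of surviving counts is non-increasing, and
- the final set is the intersection of the per-filter gene sets, hence
  invariant under chain reordering.

Contextual windows (`window_rel = NULL`) mean "the panel window", so the
same serialized chain adapts to whatever flanks the session was built
with. A count filter over a window intersects that window with the panel
window; a filter naming an unknown track is an error naming the track,
never a silent `FALSE`. An expression filter on a gene with no loaded
value is `FALSE` — absence of evidence fails a positive cutoff.

## Summaries

Occupancy profiles report, per bin, the *fraction of genes* with at least
one overlapping interval — not mean coverage depth — because the
questions the tool answers are presence/absence questions. TSS mode tiles
`[-flank_up, flank_down)` with fixed-width bins (default 500 bp);
gene-body mode rescales every gene to 100 percent-of-body bins so genes
of different lengths superimpose. Histogram bins are right-open with
explicit underflow/overflow counts, so totals always reconcile with the
input.

The expression display scale spans the 5th–95th percentile (R's type-7
quantile, i.e. linear interpolation) of the loaded values rather than the
min–max: expression is heavy-tailed, and a single outlier would otherwise
compress the whole colour ramp. A degenerate band (all values equal) is
widened by `1e-6 * max(1, |value|)` so downstream linear maps never
divide by zero.

## Sessions

A session is a single JSON document containing settings, every panel
(tracks, expression, exons, neighbours, show flag), the filter chain and
its trace. Self-containment is a correctness property: deleting the
original inputs and reloading the session must reproduce every filter
result and summary exactly, which the test suite verifies.

Serialisation is *canonical*: object keys sorted, integers written
without exponent or decimal point, other numbers with 15 significant
digits, `NA` as `null`, and an unbounded `max_peak_size` as `null`. The
number formatting is a fixed point of parse-then-format, which is what
makes `save -> load -> save` byte-identical — a much stronger and easier
to test guarantee than structural equality, and the property that makes
sessions diff- and cache-friendly.

In SVG output, peak opacity is an affine map of score onto
`[0.3, 1.0]` over the score range present: a floor of 0.3 keeps
low-scoring peaks visible, and a flat score range renders fully opaque.

## Parsing

BED, broadPeak and narrowPeak lines map to the ENCODE BED6+3 / BED6+4
fields. `"."` and `-1` sentinels in numeric columns become `NA` — "not
provided" must never collapse to a numeric zero, because 0 is a
meaningful signal value. Malformed lines are skipped and reported with
line numbers; a conservation invariant (`accepted + reported ==
non-comment lines`) holds for every file. Only a file with *zero*
well-formed lines is fatal: one bad row should not abort a 100k-row
load, but a wholly unreadable file almost certainly indicates the wrong
input. Scores above the nominal 0–1000 cap are kept with a warning —
real ENCODE files contain them.

## The synthetic generator

The generator exists so that recovery claims are exact, not statistical.
`make_annotation` lays genes down chromosome by round robin with
inter-gene gaps of at least 25 kb; with the ±5 kb query windows used in
the bundled analyses, no planted peak near one gene can leak into
another's window. `make_background_peaks` draws Poisson counts per
chromosome with uniform placement — deliberately structureless, since its
only job is to be confusable with signal at the filter level.
`plant_pattern` then (a) inserts the wanted signature at target genes
(peaks named `planted_*`), and (b) *de-confounds*: removes or attenuates
background that would make a non-target gene satisfy the pattern by
chance, skipping planted peaks. Recovery of exactly the planted set is
therefore a hard equality, tested as such.

What the generator does **not** emulate: peak-width and score
distributions of real ChIP-seq, chromatin-domain autocorrelation, GC or
mappability bias, or replicate structure. It is a correctness instrument,
not a realism instrument.

Problem sizes in the bundled analyses (330-gene panels; 13, 1, 97 and 19
recovered genes) were chosen to exercise multi-chromosome, multi-track
search at a scale where brute-force oracles still run in seconds; nothing
in the implementation depends on them.

## Numerical and testing notes

- All randomness flows through explicit seeds; the internal `with_seed`
  helper restores the caller's RNG state, so library code never perturbs
  a user's random stream.
- Oracle tests re-derive every core computation independently:
  per-peak window scans, all-pairs overlap/distance checks, per-base
  profile coverage, and a from-the-definition type-7 percentile. The
  optimized paths (`GenomicRanges` overlap machinery, vectorised
  binning) must agree exactly.
- Orientation correction is tested by reflection: mirroring every
  coordinate on each chromosome (`x -> C - x`) and flipping strands must
  leave all relative panel content identical.
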