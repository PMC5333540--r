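---
title: "Characterizing circular RNAs from chimeric alignments: methods and design"
author: "circchar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing circular RNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circchar)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream 5′ splice site is joined
to an upstream 3′ splice site — back-splicing — yielding a covalently
closed transcript. Detection tools find the diagnostic back-splice
junction reads, but stop there: a junction call says nothing about which
exons the circle actually contains, whether several circular isoforms
share one host gene, or whether the junction might in fact come from
trans-splicing or a genomic rearrangement. `circchar` starts where
detection ends. Its inputs are (1) a SAM/BAM file of chimerically mapped
reads (linear and unmapped records may be present), (2) either a
two-column table of circle IDs with their supporting read names, or a
DCC `CircRNACount` table plus STAR `Chimeric.out.junction` files, and
(3) a BED exon annotation.

All internal coordinates are 0-based half-open (the BED convention);
1-based sources — SAM `POS`, STAR junction columns — are converted at
the reader boundary and never leak further. This single-convention rule
is deliberate: most off-by-one defects in interval pipelines come from
mixing conventions mid-stream. Strand is carried through but never used
to match reads to circles; nothing in the downstream arithmetic needs
it, and requiring strand agreement would silently drop reads from
unstranded libraries.

## Per-circle read extraction

A read belongs to a circle when its name is on the circle's
supporting-read list *and* its aligned span overlaps the circle
interval. The positional condition matters: read names are not unique
across the genome once multimappers are present, and a same-named
record on another chromosome must not contaminate the circle's file.
Secondary and unmapped records are dropped by default; supplementary
records are kept, because for a chimeric read they carry the second arm
of the junction. Each circle becomes one coordinate-sorted, indexed BAM
(named from the circle ID with filesystem-safe separators), suitable
for loading as its own browser track.

## Exon skipping within circle boundaries

Two circular isoforms can share the same back-splice junction and
differ only in an internal exon. The detection is in three steps:

1. **Linear introns.** Every inter-segment gap in a circular read's
   CIGAR is a linear splicing event. `N` operations always split
   aligned blocks; deletions split only at ≥ `min_intron` bp (default
   30 bp) — shorter deletions are indel noise, and 30 bp sits well
   below any plausible intron while comfortably above common indel
   lengths. Identical gap intervals are merged across reads, and gaps
   crossing the circle boundary are dropped (they cannot be linear
   introns of the circle).
2. **Candidate exons.** An annotated exon *fully contained* in an
   inferred intron is a skipped-exon candidate. Containment, not mere
   overlap, is required: a gap that removes an entire exon is what
   exon skipping means biologically; partial overlap is ambiguous
   alignment.
3. **Isoform support.** A read supports the skipping isoform when one
   of its gaps contains the exon, and the non-skipping isoform when a
   segment overlaps the exon body. Reads that do neither — short
   junction fragments that never reach the exon — count toward the
   total but toward neither isoform, and are reported explicitly as
   uninformative rather than being silently attributed.

The reported proportion is `n_skip / n_total`. On the packaged worked
example (one circle over four 100 bp exons, five reads, four distinct
introns) exactly two of five reads skip the third exon:

```{r worked-example}
fx <- make_skipping_example(tempfile())
env_circles <- read_circle_table(fx$circles)
ann <- read_exon_annotation(fx$annotation)
sets <- circle_read_sets(read_alignments(fx$sam), env_circles)
find_skipped_exons(sets[[1]], ann)[, c("exon_number", "n_skip",
                                       "n_total",
                                       "proportion_skipping")]
```

## Mate pairs as indirect evidence of circularity

A sequenced fragment from a genuine circle that is shorter than the
library fragment size escapes fragmentation intact, so its cDNA runs
past the junction: both mates span the back-splice (a double-breakpoint
fragment). A junction from trans-splicing or rearrangement lives on a
linear molecule and can only ever yield one junction-spanning mate.
Two evidence channels identify junction-spanning mates: presence in a
(mate-level) STAR chimeric-junction record for the circle, or an
alignment split across the back-splice — one aligned block ending at
the circle end and one starting at the circle start. Junction-file
evidence is preferred when available; read-level junction records that
cannot be attributed to a specific mate are conservatively counted as
single.

The transcribed circle length is the summed length of its covered
annotated exons (clipped to the circle), falling back to the genomic
span where no annotation overlaps. A circle is flagged *suspect* when

* its length is at most the expected fragment length (the regime where
  a true circle must produce double-breakpoint fragments),
* it has zero double-breakpoint fragments, and
* at least `min_fragments` (default 2) fragments support it — a single
  fragment has no power to demand a double observation.

Longer circles are never flagged: there, single- and double-breakpoint
geometry is uninformative. `expected_fragment_length` is a required
user parameter with no default — it is a property of the library, not
of the data the pipeline sees.

## Isoforms per host gene

A gene hosts a circle when at least one of its exons overlaps the
circle interval; circles overlapping several genes contribute to each
gene's summary independently. Every pair of circles of one host gene
is classified, in precedence order: `same_start`, `same_end`, `within`
(strict containment), `overlapping`, and `non_overlapping`. The fifth
category covers disjoint pairs so the classification is exhaustive;
it is reported separately so four-category totals remain comparable
with the classical scheme. Containment that shares a boundary is
reported by the shared boundary (`same_start`/`same_end`) — the tie
cannot be ambiguous because sharing both boundaries would make the two
circles the same circle, which is rejected. The summary also reports
the global proportion of single- vs multi-circle host genes.

## Coverage profiles

Depth counts alignment segments (each mate and supplementary record
separately) per base; fragment-level depth is not defined here. The
exon-wise table reports, per annotated exon overlapping the circle:
read count (≥ 1 bp overlap), mean per-base depth, and the fraction of
bases covered. The position-wise profile concatenates the covered
exons in genomic order into a transcribed coordinate — genomic bases
outside covered exons are excluded, since the circle is a spliced
molecule — and records per base the exon number, relative position in
circle and in exon, and depth. Circles with no annotation overlap get
a single pseudo-exon equal to their genomic span. Per-circle PNG plots
smooth the profile with a centered rolling mean of window
`max(3, circle_length / 50)` bases, chosen so the window scales with
circle size but never vanishes.

## Clustering profiles to surface false positives

Profiles are resampled onto `n_bins` (default 100) equally spaced
relative positions by linear interpolation and amplitude-scaled to a
maximum of 1; all-zero profiles carry no shape and are excluded with a
warning. Clustering uses K-means under the correlation distance
`d(x, y) = 1 − cor(x, y)` (centered Pearson — the conventional reading
of "correlation" in this context), Lloyd iterations with per-cluster
mean centroids, an empty-cluster repair that re-seeds a vacated
cluster with the point farthest from its centroid, and the best of 10
seeded restarts by total within-cluster distance (default seed 42,
both exposed). The cluster count follows a piecewise rule on the set
size *n*: no clustering for *n* ≤ 2, two clusters for 3–9, four for
10–100, and `round(n/20)` capped at 10 beyond that. Rounding is
half-away-from-zero so *n* = 110 → 6 on every platform, and the
formula is applied exactly as stated even just above 100, where it
yields fewer clusters than the 10–100 band (101 → 5) — the
discontinuity is accepted rather than smoothed.

Because profile shape tracks length (short circles are covered
throughout; very long circles only near the junction), clustering all
circles mostly recovers length groups. To see shape differences within
a length class, circles are also clustered inside the groups small
(< 500 bp), medium (500–1,000 bp) and long (≥ 1,000 bp). Clusters
whose mean profile is junction-unbalanced — mean coverage of the first
10% of bins vs the last 10% differing by more than a factor of 3
(configurable) — are flagged: a one-sided pile-up against the junction
is the signature of a non-circular origin. Flagged clusters are
surfaced, never auto-removed; the screening decision stays with the
user.

## The simulator: what it does and does not emulate

The package ships a seeded simulator so every stage is testable with
known truth. Each circle gets its own gene; with a nonzero
`skip_fraction` the gene has three exons (40/20/40% of the length,
200 bp introns) whose middle exon is skipped by a random subset of
fragments. Fragmentation cuts the circularized transcript at a uniform
position; mates of length `read_length` sit at the two ends of a
`fragment_length` fragment, and a mate spans the junction exactly when
its arc wraps past it. A circle shorter than the fragment size escapes
fragmentation intact, so its fragment wraps once past the junction
(rolling-circle reverse transcription); geometry that would wrap more
than once is rejected. Wrapped mates are emitted as primary +
supplementary records and also into mate-level STAR-layout junction
files, exercising both evidence channels. Defaults — 350 bp fragments,
150 bp reads — mirror a routine paired-end rRNA-depleted library.

Deliberately absent: sequencing errors and base qualities (no stage
uses them), GC or mappability bias, linear host-gene background beyond
non-junction fragments, real intron length distributions, and genome
sequence. Passing tests on these fixtures therefore demonstrates the
interval arithmetic, counting and clustering logic — not robustness to
alignment artifacts of real data.

The false-positive fixture emulates trans-splice-like junctions: short
(300 bp) circles whose fragments always have exactly one
junction-spanning mate (a 10 bp overhang anchors the split) and whose
coverage piles up on one side, mixed with genuine 600 bp controls in a
22:64 ratio. Tests assert that all planted false positives — and only
they — are flagged by the length rule, and that they separate from the
controls under correlation K-means.

## Problem sizes and numerical choices in the test suite

The checks run at desk scale, chosen to exercise every code path with
tight statistical bands: the five-read worked example; pileup-oracle
equivalence on 50 simulated circles; skip-fraction recovery at 200
fragments per circle over 20 seeds and three fractions (mean absolute
error below 0.05, comfortably above the binomial standard error of
~0.035); fragment-geometry sweeps over 10 seeds at four circle
lengths; and false-positive clustering over 5 seeds at 86 circles.
Ties and degenerate inputs are pinned by tests: empty read sets, gap-
less alignments, all-zero profiles, single-circle clustering groups,
and zero-variance profile rows all have defined, warning-mediated
behaviour rather than errors.

## Known limitations

* Only annotated exons can be called skipped; novel internal exons are
  out of scope by construction.
* Intron retention and rolling-circle quantification are not called.
* Depth is segment-level; fragment-level (template) coverage is not
  computed.
* The DCC coordinate convention is absorbed by a ±1 bp matching
  tolerance rather than resolved; with exactly-known conventions the
  tolerance can be set to 0.
* No statistical test is attached to the host-gene summaries; they are
  descriptive.
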