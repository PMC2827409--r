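---
title: "The finishing-effort assay: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The finishing-effort assay: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finishassay)
```

## The problem

Shotgun sequencing of a large-insert clone (a BAC of roughly 165 kb)
produces a draft assembly: a set of contigs separated by gaps. Refining a
draft into finished sequence is manual and expensive, and the effort is
dominated by a few measurable features of the draft: how many gaps there
are, whether each gap is *captured* (spanned by plasmid read pairs whose
mates land in the two flanking contigs, so contig order and orientation are
known and the spanning subclone can simply be resequenced) or *uncaptured*
(no spatial information; closing requires PCR or other templates), what
kind of sequence the gaps contain (GC-rich stretches, simple repeats and
LINEs are over-represented and hard to sequence through), and how uneven
the sequence-read redundancy is along the clone — a signature of DNA that
is toxic to the *E. coli* host propagating the subclones.

`finishassay` packages this assessment as a reproducible pipeline. Given a
finished ("human-grade") reference, a draft ("comparative-grade") contig
set derived from the same DNA, and the placements of the shotgun reads, it

1. maps the contigs onto the reference (`align_contigs()`,
   `resolve_map()`),
2. catalogues gaps (`call_gaps()`, `gap_stats()`),
3. classifies each internal gap as captured/uncaptured from read-pair
   evidence (`classify_gaps()`),
4. profiles the GC and repeat-class composition of gap versus total
   sequence (`composition_profile()`, `composition_ci()`),
5. scores variation in per-strand read redundancy (`depth_profile()`,
   `variation_score()`), and
6. aggregates per-assembly results into per-species / per-region reports
   (`summarize_assay()`, `uncaptured_burden()`).

A synthetic-data module (`generate_reference()`, `simulate_shotgun()`,
`build_draft()`, `simulate_bac()`) provides fully self-contained test
material with exact ground truth.

All coordinates are 0-based half-open, so BED output needs no conversion.
The lower median is used for even counts (deterministic and
integer-valued).

## Contig mapping

Draft and finished sequence derive from the same clone, so the mapping
problem is near-exact placement, not divergent alignment. The aligner
anchors on k-mers (default `k = 31`) that are unique in both the reference
and the contig, chains anchors that share a strand and an alignment
diagonal (within a `band` of 100 bp, to tolerate small indel noise in real
data), extends each block outward base-by-base while the sequences match
exactly, and drops blocks under `min_block = 200` bp. Identity is computed
over the extended span; interior mismatches between anchors are tolerated
and simply lower the identity. There is deliberately no gapped or
substitution-tolerant extension: for same-clone comparisons it is not
needed, and omitting it keeps the mapper fast and its behavior easy to
reason about. Externally produced alignments can be imported instead
(`read_alignments_tsv()`).

Ambiguous placements are resolved by a deterministic rule rather than
curation, so runs are reproducible: per contig the highest-scoring block
set is kept (score = aligned bp × identity), and overlaps between adjacent
placements on the reference are trimmed from the lower-identity placement
(ties: trim the shorter, then the lexicographically later contig id). A
contig producing two or more mutually non-colinear blocks is flagged as a
putative misassembly (split contig).

## Gap catalogue and capture rule

Gaps are the complement of the placed contigs. Uncovered reference ends
are reported as *terminal* gaps but excluded from headline statistics by
default (they have one flank, not two, and their size is dominated by
where the draft happens to end); the choice is flag-reversible. The
conservation identity — placed bases + internal gap bases + terminal gap
bases = reference length — is asserted on every assembly and a violation
aborts the run.

A subclone spans a gap when its two reads sit on opposite sides in proper
relative orientation (left read on the plus strand, right read on the
minus strand — mates pointing toward each other). "Appropriately spaced"
is formalized as an implied span of at most
`insert_mean + 3 * insert_sd` (default 5,200 bp for a 4,000 ± 400 bp
library); a multiplier mode (`span <= multiplier * insert_mean`) is
available via `capture_rule()`. The 3-standard-deviation bound is a
library-calibrated default, not an empirical constant: it admits
essentially all genuine spanning inserts while rejecting spans that could
not come from a single subclone. A gap with at least two qualifying
spanning subclones is *captured*, otherwise *uncaptured*. The practical
difficulty criterion tracked in reports is the fraction of assemblies with
two or more uncaptured gaps.

Note on aggregate gap rates: a cohort's "gaps per Mb" depends on the
denominator (finished length of the analysed units versus aligned
reference length). `gap_stats()` always normalizes by the finished length
of the unit supplied, and reports the inputs alongside the rate so any
other normalization can be recomputed.

## Composition

GC and repeat fractions of gap sequence are read from the finished
reference inside the gap interval. Repeat classes (Simple, LTR, SINE,
LINE, DNA) are flattened to a class-disjoint annotation before computing
fractions, with overlap priority Simple > LINE > SINE > LTR > DNA
(configurable); real annotations are ingested from the RepeatMasker `.out`
dialect. The built-in simple-repeat finder exists for synthetic truth and
annotation-free operation: it reports the union of all tandem tracts of
motif size 1–4 meeting per-size minimum lengths (12/20/21/24 bp) and a
purity of 0.9 (fraction of positions matching the base one period
earlier). These thresholds are package defaults chosen to capture the
tract lengths that cause finishing trouble; they are not estimates of any
published scan's settings.

Confidence intervals pool per-BAC fractions weighted by bases and use a
percentile bootstrap that resamples whole BACs (the natural exchangeable
unit of these cohorts) with replacement, 1,000 replicates by default.
Units are sorted by id before resampling so the result is independent of
input order under a fixed seed.

## Redundancy variation

Depth is counted per strand per base. The combined depth is cut into
2,000 bp windows, each window's coefficient of variation (population
SD/mean) is computed, and the assembly is summarized by the 90th
percentile of window CVs — chosen over the mean so that a single severe
coverage trough, the phenotype that predicts cloning bias, dominates the
score. The ordinal scale `-`, `+`, `++`, `++++` is a reconstruction: the
CV cutpoints 0.35 / 0.55 / 0.80 are implementation defaults exposed in
`variation_score()`, and the score is invariant under uniform depth
scaling. Whether per-strand or combined variation is the better predictor
is genuinely open; combined depth is used for the score and both strands
are retained in the profile.

## The simulator and what it does (not) show

The generator's defaults are the study conditions of the assay: 165 kb
templates; background GC 0.40; repeat densities 1.6% simple, 4.7% LTR,
9.3% SINE, 18.6% LINE, 2.7% DNA transposon (aggregate vertebrate BAC
composition); paired reads of 800 bp (a typical Sanger quality length)
from 4,000 ± 400 bp inserts (a 3–5 kb library), truncated-normal
distributed, at 8-fold redundancy; contigs under 2 kb discarded.
Interspersed repeat copies diverge 8% from a per-class consensus, so
copies resemble a family rather than exact duplicates. The pair count is
exactly `round(redundancy * length / (2 * read_len))`.

Cloning bias is modeled as regions with a subclone viability in [0, 1]: a
subclone whose insert overlaps such a region is accepted into the library
with that probability, and rejected subclones are resampled (the lab
sequences a fixed number of grown clones). Under a copy-control host the
depression is partly removed: `v' = v + rescue * (1 - v)`. The magnitude
of the depression in genuinely clone-toxic DNA is not known quantitatively;
the defaults (viability 0.05–0.15 in a few 0.5–4 kb regions) are
placeholders that the tests vary, not estimates of a real effect.

Subclone midpoints are drawn on a *circular* template — BAC DNA is
circular when sheared — and the rare read crossing the linear origin is
emitted as two clipped placement rows. This makes coverage statistically
stationary along the whole template, so simulated gap counts follow the
Lander–Waterman expectation `N * exp(-c)` without edge corrections, which
the test suite verifies at 4- and 8-fold redundancy over 200 replicates.

Drafts are derived from coverage truth (maximal intervals with depth ≥ 1,
emitted as the reference substring), not by running an assembler: the
object of study is the gap structure of an assembly, and this keeps the
truth exact. Consensus errors, collapsed repeats and chimeric joins are
therefore absent by default; one misassembly mechanism (joining two
non-adjacent covered segments, `chimera = TRUE`) exists to exercise the
split-contig detector. Base-call errors, quality values and chromatogram
artifacts are not simulated. Consequently, passing tests demonstrate that
the pipeline measures gap structure, capture status, composition and
redundancy variation correctly on error-free data with known truth; they
do not demonstrate robustness to assembler-specific artifacts or
sequencing error, which real Cross-Match-style alignments (importable via
the TSV path) would exercise.

## Problem sizes and determinism

Every stochastic function takes an explicit seed, and identical inputs
plus seed give byte-identical output, including the report TSVs of a full
run. The test suite exercises: exact gap-truth recovery on 100 simulated
165 kb BACs at 8× with zero-viability regions; capture classification
against a brute-force double loop on 1,000 random layouts; Lander–Waterman
agreement over 200 seeds at 4× and 8×; paired standard versus copy-control
simulations over 100 genomes (sign tests on gap count and summary CV);
simple-repeat enrichment in captured gaps over 20 cohorts; and exact
order/orientation restoration of shuffled, reverse-complemented contigs
over 100 seeds. These sizes were chosen to give stable statistics for each
check while keeping a full run comfortable on a single CPU.

## A small worked example

```{r example}
sim <- simulate_bac(length = 60000, n_bias = 2, bias_length = c(800, 1600),
                    viability = 0.1, simple_in_bias = 0.4,
                    repeat_densities = c(Simple = 0.016, LINE = 0.186),
                    shuffle = TRUE, seed = 11)
res <- assay_bac(sim$ref, sim$draft, pairs = sim$pairs,
                 annotation = sim$annotation)
res$map
res$gaps[, c("start", "end", "size", "kind", "status", "spanning_subclones")]
res$stats
res$profile$score
```

## Known limitations

* The mapper assumes near-exact same-clone sequence; cross-species contig
  ordering is out of scope.
* Fosmid and large-insert rescue libraries are not modeled; the capture
  rule sees only the primary plasmid library.
* Real repeat annotation quality bounds the composition profile; the
  built-in tandem finder covers simple repeats only.
* The ordinal redundancy scale is a reconstruction; compare scores only
  within a run or across runs with identical cutpoints.
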