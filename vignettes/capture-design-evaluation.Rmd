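---
title: "Evaluating hybrid-capture designs: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating hybrid-capture designs: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capdesign)
library(dplyr)
```

## The problem

Whole-exome and other targeted-enrichment experiments sequence only the
genomic regions pulled down by hybridization baits. Two questions dominate
the quality control of such a design: *construction* — which bases does the
design actually target once annotation sources are merged, short regions
padded, and unwanted chromosomes excluded — and *performance* — which target
regions and bases reach a usable sequencing depth, how reproducibly across
samples, and why do some regions persistently fail.

`capdesign` implements that pipeline end to end for interval data in plain
tables: every user-facing function takes a tibble of half-open, 0-based
intervals (`chrom`, `start`, `end`) or a per-base depth table (`chrom`,
`pos`, `depth`) and returns tibbles, so analyses chain naturally with the
pipe.

## Design construction

A capture design is built as

1. union of all annotation source tracks (exon, ncRNA, antisense, ...),
2. removal of excluded chromosomes (default `chrM`: mitochondrial DNA is
   massively over-captured relative to nuclear DNA, so vendors advise
   spiking dedicated baits instead of tiling it),
3. merge of overlapping and book-ended intervals (`gap = 0`, the
   `bedtools merge` default),
4. padding of regions under 100 bp to 100 bp — the padding rule capture
   vendors apply to improve bait tiling on very short targets,
5. a re-merge (padding can fuse close neighbours) and assignment of dense
   region ids in `(chrom, start)` order.

Padding is symmetric about the region midpoint. The vendor rule does not say
where an odd leftover base goes; we place it downstream (higher coordinate),
a fixed, documented, testable choice. At chromosome ends the padded interval
is pushed back inside `[0, length)` so it keeps the full 100 bp whenever the
chromosome allows. Whether the vendor padded before or after the
author-side merge is equally unstated; this package pads *after* merging,
which never leaves a sub-100 bp region either way.

A subset design (e.g. coding sequence only) is the intersection of a parent
design with a `keep` track, re-padded by default — the vendor pads whatever
design it receives, and re-padding is the conservative reading; pass
`min_len = 1` to disable it. Because one parent region may contain several
kept fragments, a subset can hold *more* regions than its parent while
covering fewer bases; the study this package models went from 242,914
regions (151.7 Mb) to 244,543 regions (71.3 Mb) this way. Printed design
summaries truncate the mean region size (151,698,592 / 242,914 = 624.48,
reported as 624), so `design_stats()` reports both the 1-decimal and the
truncated mean.

## Coverage evaluation

All depth comparisons are inclusive — "covered at 5x" means depth >= 5, and
a region is *never covered* when its maximum depth is at most threshold - 1.
The default threshold of 5 reads is the usual minimum for variant calling.
Per region we report minimum/maximum depth, bases at or above the threshold,
the covered fraction, and the two boolean outcomes (*fully covered*, *never
covered*); per sample, the complement identity
`n_fully_covered + n_min_below = n_regions` holds by construction. Mean
on-target depth is total design-base depth divided by design size. (The
study tables this package ships report an on-target depth column whose exact
formula was not published; that column is treated as an opaque printed input
and only averaged, never recomputed.)

A read is *on target* when it overlaps at least one design base — any
overlap, in half-open coordinates, so a read starting exactly at a region's
end is off-target. The overlap rule is the common convention; stricter rules
can be emulated by shrinking the design track before counting. Each read
(mate) counts once.

Reproducibility across a cohort is the strictest intersection: a region
counts only if fully covered in *every* sample (or never covered in every
sample), and a base only if it reaches the threshold in every sample.

Percentages are rounded half away from zero to one decimal throughout
(`round_half_away()`), the convention of printed sequencing tables;
`base::round()`'s banker's rounding would disagree on exact .5 ties such as
the 117,441.5625 mean variant count.

## The three-group classification and GC risk

Regions partition into three performance groups: group 1, fully covered in
all samples; group 3, never covered in any sample; group 2, the rest. Since
group 1 demonstrably sequences well, its per-region GC distribution defines
the *sequenceable GC band*: the 2.5th and 97.5th percentiles of group-1 GC
(linear interpolation between order statistics, `stats::quantile()` type 7 —
the percentile method was not specified in the source study, so we use R's
default and expose `type`). GC is computed over unambiguous bases only;
all-N regions get `NA`. A region is *extreme* when strictly outside the band
— boundary values are sequenceable, because the cut-offs are derived from
regions that did sequence.

Vendor exclusion tracks (no baits over Ns, no baits over repeats, and a
predicted-unsequenceable track that is a subset of the other two) flag a
region on any >= 1 bp overlap ("at least partially excluded"). Two combined
at-risk criteria are reported per group: extreme GC *or* Ns/repeats
exclusion, and extreme GC *or* predicted-unsequenceable. Group medians are
unweighted by region length, matching per-region box plots, and the GC
summaries are recomputed after dropping each exclusion class to show whether
the remaining regions shift.

Longer regions fail the "every base" criterion more easily, so
`size_stratified_completeness()` contrasts completion below and above a
length cut (default 260 bp, the mean region size of older exon-centric
designs).

## Design comparison

`venn_partition()` disjoins the union of any number of designs and sizes
every membership class; `venn3()` is the conventional three-way view. Mb
values are reported at two decimals (half away from zero). The partition is
exact by construction: classes are disjoint, sum to the union, and each
design's classes sum to its own size — properties the tests assert against a
per-base 3-bit mask histogram.

## The packaged study tables

The per-sample statistics of the sixteen-sample canine capture study that
motivated this pipeline ship as plain TSV fixtures (`study_sample_stats()`),
together with the design-level constants (`study_design_constants()`). They
are inputs: `validate_sample_stats()` checks their internal arithmetic
(remaining = mapped - duplicates; retained % = 100 x remaining / total at
printed precision) and `average_metrics()` recomputes every study-level
average from the rows. Nothing downstream hard-codes an average. The
study's headline cohort results (79.7% of regions fully covered on average,
95.1% of bases at >= 5x, reproducibility 63.5% of regions / 90.4% of bases,
group sizes 154,318 / 84,376 / 4,220, GC cut-offs 32.0% / 64.5%) would
require the original sixteen captures to recompute from raw data; here they
are reproduced from the printed per-sample values, and the *machinery* that
would produce them from raw tracks is validated on synthetic data instead.

## The synthetic study: what it emulates, and what it does not

`sim_config()` describes a toy study whose defaults are the package's fixed
test conditions: 3 chromosomes of 1 Mb, roughly 2,000 design regions from
multi-exon genes (with UTR/CDS structure) plus non-coding RNAs, 4 samples,
baseline on-target depth 80x, and a sequenceable GC band of 32-64.5% (the
band the real study derived). Chromosomes are tiled with 25 kb GC zones:
80% ordinary zones with target GC drawn uniformly from 35-62% — spanning
most of the band so that the band edges are re-estimable from group-1
regions — and 20% extreme zones (12% high at 72-85%, 8% low at 14-26%,
echoing the empirical asymmetry that high-GC dropout dominates).

Per-base depth is negative binomial (dispersion `nb_size = 6`, between
Poisson and the heavy overdispersion of real captures) around

```
baseline x sample_scale x gc_multiplier(windowed GC) x exclusion
```

where the GC multiplier is 1 inside the band and decays linearly to a floor
of 0.02 within 6 GC points outside it (sharp drops just outside 40%/60% GC
are well documented for hybrid capture), the window is 101 bp (about the
scale of a bait), sample scales are uniform on 0.7-1.2 (the real cohort's
mean depths varied about two-fold), and the exclusion factor zeroes depth
over N bases and the predicted-unsequenceable track. The source study gives
no depth model — only the phenomenology of GC-dependent dropout — so this is
the simplest generative model that produces all three region groups, a
realistic breadth-of-coverage curve, and recoverable GC cut-offs.

Simulated reads are Bernoulli on/off target at the configured rate (default
0.75, the study's overall on-target average); on-target reads start so they
overlap a length-weighted random region, off-target reads are uniform over
the complement with rejection of accidental overlap, so the realized rate is
unbiased.

What the generator does **not** emulate: real bait tiling and hybridization
kinetics, fragment-level (paired, duplicated, mappability-biased) reads,
reference errors, or between-region depth correlation beyond the GC field.
Passing tests therefore demonstrate that the *pipeline's computations* are
correct and that its classification logic recovers planted structure — not
that any particular laboratory design will reach these coverage numbers.

Problem sizes were chosen so the whole synthetic study (generation, four
coverage passes, classification, 100,000 reads) completes in well under a
minute: design size ~0.5 Mb keeps per-base operations cheap while leaving
hundreds of regions per group.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere inside the package; 1-based
  inputs (`samtools depth` positions, SAM records) convert at the boundary.
* Depth tracks are sparse; absent positions are depth 0 and depth-0 records
  are never stored.
* Chromosome names match as exact strings — no "chr" aliasing, so input
  mix-ups fail loudly rather than silently.
* Empty interval sets are legal inputs to all set operations; empty designs
  and empty GC vectors are errors.
* Merging drops labels: a merged region has no unique source label, and
  region identity is re-derived from the merged design.
* Ties: odd padding goes downstream; `quantile` type 7 interpolates
  percentiles; rounding is half away from zero.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, at run time,
every study-table average from the fixtures, the reproducibility
percentages, the design-size consistency of the printed three-way partition,
and the synthetic recovery measures (share of planted extreme-GC regions
landing outside group 1, the re-estimated GC band, the measured on-target
rate), writing one JSON object. The testthat suite asserts the same
quantities plus the brute-force mask-oracle equivalences.

```{r example, eval = FALSE}
sim <- simulate_study(sim_config(seed = 1))
summaries <- lapply(seq_along(sim$depths), function(i) {
  sample_coverage_summary(sim$depths[[i]], sim$design, 5, sim$chrom_sizes,
                          sample_id = paste0("s", i))
})
groups <- assign_groups(summaries)
cuts <- gc_cutoffs(sim$truth$gc[groups$group == 1])
flags <- sim$truth[, c("region_id", "has_ns", "has_repeat",
                       "any_exclusion", "predicted_unseq")]
report <- risk_report(groups, sim$truth$gc, cuts, flags)
glance(report)
autoplot(report)
```

## Known limitations

* The per-base engine materializes one integer vector per chromosome, which
  is comfortable for genomes up to tens of Mb (the QC use case on selected
  chromosomes or toy genomes); whole-mammal-genome depth tracks should be
  processed per chromosome.
* The on-target depth column of the packaged study table cannot be
  recomputed because its source formula is unpublished; it is averaged as
  printed.
* `% reads on target` summaries depend on how duplicates and mates were
  counted upstream; this package counts each alignment record once.
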