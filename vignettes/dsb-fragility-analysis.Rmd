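---
title: "Mapping and testing genomic double-strand break fragility with dsbtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and testing genomic double-strand break fragility with dsbtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbtools)
```

## The problem

Haploid spermatids undergo a dramatic chromatin remodelling in which most
histones are replaced by protamines. The torsional strain this generates is
associated with DNA double-strand breaks (DSBs) at characteristic genomic
locations, which can be mapped either as broad immunocapture peaks
(~150–6700 bp, mean ≈ 267 bp) or as 1-bp break-end records from in-situ
ligation assays. Understanding *where* these breaks fall — relative to simple
repeats, Z-DNA-prone alternating purine–pyrimidine tracts, chromatin marks,
other cell types' break maps, and regions of oxidative damage in mature sperm
— is a question about the association between genomic interval sets.

`dsbtools` implements that analysis end to end: BED-style interval algebra,
permutation-based region association, targeted motif scanning, a windowed
oxidative-damage enrichment score, break-set classification, and seeded
synthetic-data generators that make each stage verifiable on a desk-scale
genome.

## Coordinate conventions

All coordinates are **0-based, half-open** (`start` inclusive, `end`
exclusive), as in BED and bedGraph. One-based inputs are *not* auto-detected;
convert before constructing an `interval_set`. Chromosome names are matched
by exact text; `normalize_chrom_prefix()` toggles the UCSC `chr` prefix when
two sources disagree, and is never applied implicitly. Strand is carried
through I/O but ignored by all interval algebra: the region-level questions
asked here are strand-blind.

Two further conventions follow the behaviour of the standard genome-
arithmetic tools:

* `merge_intervals()` joins book-ended intervals (gap 0) by default
  (`book_ended = FALSE` restricts joining to intervals sharing ≥ 1 base).
* "Overlap" always means ≥ 1 shared base; there is no minimum-fraction rule.
* Exclusion filtering (centromeric-satellite-style) removes **whole
  records** that touch the exclusion track (`subtract_intervals(mode =
  "any-overlap")`), never clipped fragments; the per-base mode exists for
  coordinate subtraction.

## The permutation model

The statistical engine asks: does a query set (break peaks) overlap a fixed
reference annotation more than expected by chance? The null model re-places
every query interval uniformly at random **on its own chromosome**, keeping
its width; randomized intervals may overlap one another, and the whole
chromosome is available (no gap masking). The reference is never randomized.
With observed statistic $s$ and permuted values $s_1 \dots s_N$:

$$ Z = \frac{s - \mu_{perm}}{\sigma_{perm}}, \qquad
   p = \frac{b + 1}{N + 1}, $$

where $b$ counts permuted values at least as extreme as $s$ in the reported
direction and ties count as extreme (conservative). With the default
$N = 1000$ the smallest attainable $p$ is $1/1001 \approx 0.001$. Two
statistics are offered: `count` (number of query regions overlapping ≥ 1
reference region, each counted once; the default for Z-score tests) and `bp`
(total base-pair overlap; the statistic behind fold-change tests, where
`fold = observed / mean(sampled overlap)` over `n_samples = 10000`
placements, with no pseudocount by default).

Direction handling deserves a note. By default (`alternative = "auto"`) the
one-sided direction is chosen from the sign of $s - \mu_{perm}$, so
depletions are reported with `direction = "less"` and negative $Z$. For
**calibration studies under a null**, the direction must instead be fixed in
advance: with auto-selection, $p \le \alpha$ occurs whenever the observed
value falls in *either* tail, so the apparent type-I error is $\approx
2\alpha$. The calibration checks in this package therefore use
`alternative = "greater"`, and use the `bp` statistic, whose near-continuous
null avoids the tail distortion that the count statistic's discreteness
introduces at small expected counts.

A degenerate null ($\sigma_{perm} = 0$, e.g. an empty reference) raises a
classed error rather than returning `NaN`. Randomness is consumed from a
single sequential stream governed by the `seed` argument; since the package
never parallelises, this already makes every result exactly reproducible.

`stratified_association()` splits the query by any-overlap with a stratifier
track (e.g. CA-repeat loci) and tests each stratum separately — the design
used to ask whether an association survives removal of a confounding
sequence class.

## Motif scanners

Three targeted scanners cover the sequence families of interest; discovered
motifs are *inputs* here (de-novo motif discovery is out of scope):

* `scan_tandem_repeats()` — maximal runs of ≥ k copies of a short unit.
  IUPAC codes are allowed in the unit, so `"NA"` finds degenerate
  TA/CA/GA/AA mosaics. Runs are found in every phase of the unit length;
  where runs in different phases overlap, the longest (earliest on ties) is
  kept, so each locus yields one maximal hit and hit width = units × unit
  length. There is deliberately **no default k**: the choice materially
  changes a genome-wide track, so it must be explicit.
* `scan_alternating_ry()` — maximal purine/pyrimidine alternations (the
  Z-DNA-prone class), reported when ≥ k dinucleotide units are present.
  Unit count is `floor(bp/2)`; the trailing base of an odd-length stretch is
  excluded from the reported interval. Scanning is plus-strand only because
  the reverse complement of an alternating run is itself alternating — both
  strands would report the same loci.
* `scan_iupac()` — fixed-length IUPAC consensus (e.g. the topoisomerase II
  cleavage consensus `RNYNNCNNGYNGKTNYNY`), both strands by default, with
  minus-strand hits reported in plus coordinates.

Sequence handling: only A/C/G/T are informative in the subject sequence;
every other symbol is treated as N, and sequence N matches **only** the
pattern symbol N. This prevents assembly gaps from matching degenerate
pattern positions. One consequence worth stating: hits of `(CA)n` are always
contained in hits of `(NA)n` at equal k, but `(NA)n` hits are *not*
generally contained in RY-alternating runs — a degenerate unit like NA
admits AA copies, which break purine/pyrimidine alternation.

`peak_motif_fraction()` and `motif_overlap_fraction()` report the two
co-occurrence fractions used to summarise motif content (fraction of peaks
containing a hit, and fraction of hits inside peaks).

## The windowed oxidative-damage score

Damage and input samples are summarised as mean read depth per fixed-width
window (50 kb in the motivating application), then made comparable by a
low-coverage scaling: the per-window mean across all supplied samples is
ranked, the lowest 10% of windows (ties broken by genomic order) form a
common low-damage bin set, and each sample is divided by its own mean over
that set. We read "global scaling factor" as *one common bin set with a
per-sample factor*: a literally single shared factor would cancel out of the
damage/input ratio and make the fold change insensitive to scaling
altogether; `single_factor = TRUE` implements that stricter reading anyway.

Per-window enrichment is the fold change of scaled damage over scaled input.
Windows whose input falls below `epsilon = 1e-9` are flagged undefined (`NA`,
never ±Inf) and dropped before ranking. Windows overlapping a satellite-style
exclusion track are removed, and the top `ceiling(f·n)` windows (default
f = 0.01) are selected, ties at the cut resolved in genomic order. Ranking is
by fold over input rather than by raw damage value: the scaled damage value
still carries sample-intrinsic coverage structure (mappability, copy number)
that the input ratio cancels. The entire score is invariant to rescaling all
raw coverage by a constant.

## Break-set bookkeeping

`merge_replicates()` unions replicate peak files, merges, and applies
whole-record satellite exclusion. `extend_point_breaks()` widens 1-bp break
records to a target mean width with flank `floor((target-1)/2)` (so a 267-bp
target gives the ±133 bp extension; even targets add their one extra base
downstream), clamped at chromosome ends. `classify_breaks()` reports, per
reference set, the fraction of query peaks shared with it and the fraction
specific to the query (overlapping no reference). "Shared" means ≥ 1 bp
overlap with a reference record; when comparing against two replicate
break maps of another cell type, the intended reference is the records of
one replicate that overlap the other (`intersect_intervals(mode =
"count")` semantics on records, not the per-base intersection — a per-base
flag is available). `chromosome_summary()` produces per-chromosome coverage
percent and peaks/Mb (genome-wide peaks/Mb uses total peaks over total
genome length, not a mean of per-chromosome rates), and
`repeat_content_correlation()` regresses peak coverage on repeat coverage by
OLS, returning $r^2$, slope and the two-sided slope p-value. A constant
response returns $r^2 = 0$ explicitly rather than the numerically unstable
`summary.lm` value.

## Synthetic data: what it emulates, and what it does not

The generators produce the smallest data that exercise every code path with
known truth:

* `make_genome()` — i.i.d. bases at a stated GC fraction (default 0.42,
  mouse-like).
* `plant_tandem_repeats()` — exact-unit-count repeat blocks at controlled
  spacing, with flanking bases set to non-matching symbols so each block is
  a maximal run and exact-boundary recovery is well defined.
* `simulate_breaks()` — each break is attracted, with probability ρ, to
  within `proximity` bp of a random feature interval, else placed uniformly
  (chromosomes weighted by length). Widths default to a log-normal with
  median 213 bp truncated below at 146 bp, matching the empirical broad-peak
  width distribution (range 146–6662 bp, mean ≈ 267 bp). ρ = 0 gives a
  feature-independent null.
* `simulate_coverage_tracks()` — multiplicative gamma noise (mean 1) around
  a base depth, with a planted fold in designated windows. The default
  coefficient of variation is 0.1, the scale of bin-level overdispersion of
  real whole-genome coverage averaged over 50-kb windows (counting noise is
  negligible at such bin sizes; mappability and GC effects dominate), and a
  level at which a planted ≥ 2× fold is reliably separable from background —
  the property the recovery checks assert.

These fixtures deliberately idealise: no alignment artefacts, no
chromosome-specific biases, no correlated noise, no read-level structure.
Passing the recovery tests therefore demonstrates the *computational*
correctness of each stage, not robustness to every artefact of real
sequencing data.

For the fold-change recovery study, the attraction probability is calibrated
analytically to the planted enrichment: with features of uniform coverage
$c$ on every chromosome and attracted breaks placed inside a feature
(overlap fraction $q_{in} \approx 1$ up to a boundary term), the expected
fold is

$$ \text{fold} = 1 + \rho\left(\frac{q_{in}}{c} - 1\right), $$

so a 12-fold target at $c = 0.01$, $q_{in} = 0.994$ gives ρ = 0.1118.
Feature coverage must be uniform *per chromosome* for this closed form,
because the null randomizes each break within its own chromosome.

## Verification strategy and problem sizes

Every operation is tested against an implementation-independent oracle:
interval algebra against a per-base boolean-array model (1000 random cases),
scanners against naive sliding-window loops, permutation nulls against exact
enumeration of all placements on ≤ 1-kb toys, and the p-value machinery
against a 500-replicate null calibration (N = 1000 permutations, 200 query
and 2000 reference intervals on a 10-Mb five-chromosome genome) that checks
the 1/1001 floor, the [0.03, 0.07] type-I band at α = 0.05 and
Kolmogorov–Smirnov uniformity. Planted-signal studies use 2000 breaks
against 1%-coverage features (association and fold recovery), 20 enriched
windows among 2000 50-kb windows at 4-fold (damage recovery), and 15 planted
repeat blocks (exact-boundary recovery). These sizes were chosen to give
each check comfortable statistical resolution while keeping the full suite
around a minute on one core; `scripts/acceptance.R` re-runs the same studies
from scratch under a caller-supplied seed.

## Known limitations

* No mask/gap-aware randomization, GC matching, or local (shifted-window)
  nulls; placement uses whole unmasked chromosomes by design.
* No multiple-testing correction across tracks: results are per pair, and
  correction is the caller's choice.
* The scanners are exact-matching; no position-weight matrices or E-values.
* BAM/CRAM, peak calling, read simulation and plotting are out of scope;
  inputs are BED/bedGraph/FASTA/chrom.sizes.
* Interval coordinates are stored as doubles; exactness holds far beyond
  any realistic chromosome length (< 2^53), but arithmetic on non-integer
  input coordinates is not guarded against.
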