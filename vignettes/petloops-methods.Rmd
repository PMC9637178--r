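---
title: "Loop calling and regulatory interaction analysis from paired-end tags: methods and design notes"
author: "petloops developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petloops methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data model

Proximity-ligation-free chromatin-interaction assays bridge spatially close
accessible regions with a transposase-loaded bivalent linker and report each
contact as a paired-end tag (PET): two short sequenced ends mapping to two
genomic loci. `petloops` works from mapped PETs in BEDPE (0-based,
half-open). Each intra-chromosomal PET becomes a 2D point
\((x, y)\) with \(x\) the left-end midpoint and \(y \ge x\) the right-end
midpoint; a chromatin loop appears as a dense 2D cluster of such points away
from the diagonal, and the assay's accessibility footprint appears as
vertical/horizontal stripes anchored at open-chromatin peaks.

## Pre-processing

Raw read pairs are cleaned in four stages, each with an explicit, testable
rule:

1. **Linker trimming** — each mate is truncated at the first exact
   occurrence of the bridging-linker sequence
   (`CTGTCTCTTATACACATCT`); a pair is kept only when both trimmed mates are
   at least 10 bp. The search is an exact substring match on the given
   strand; no mismatches and no reverse-complement search (a documented
   limitation — reads in which the linker appears only with sequencing
   errors are passed through untrimmed).
2. **MAPQ filter** — mapped PETs need MAPQ \(\ge\) 10 (the BEDPE score
   column; records without one pass).
3. **Near-diagonal no-linker filter** — cis PETs closer than 1 kb with the
   linker found in *neither* mate are removed: they are indistinguishable
   from un-bridged genomic fragments.
4. **PCR de-duplication** — exactly one representative is kept per identical
   pair of end intervals (both ends identical, not 5' positions only).

QC counters are monotone along this pipeline and
`redundancy = 1 - unique/mapped`.

## Loop calling

Candidate loops are DBSCAN clusters of the PET 2D points (Euclidean
metric), run at several radii `eps` (default 200, 500, 1000, 2000 bp) with
core threshold `minPts` (default 10; 20 is appropriate for very deep
libraries). PETs with distance below `cut` (5000 bp in the reference
setting) or above `max_cut` are excluded first. The DBSCAN is deterministic:
points are processed in (x, y) order, neighbour lists in index order, and
border points join the first discovered core's cluster, so the grid-bucketed
implementation is *identical* — not just equivalent in partition quality —
to a naive \(O(n^2)\) oracle, and is tested as such. Clusters whose
anchors, extended by `eps`, would overlap the diagonal are discarded as
self-ligation-like signal.

`max_cut = "auto"` estimates where the distance decay flattens into noise:
the log10-distance histogram is converted to per-bp density (raw counts in
equal log-bins are flat for a \(d^{-1}\) decay and would be useless), bins
with fewer than 5 counts are dropped (Poisson noise makes pairwise slopes
meaningless there), and a 7-bin sliding OLS slope past the density mode
triggers the cutoff when it rises above \(-0.5\).

### Significance

Each candidate is tested against a Poisson null whose rate is the maximum
of three terms:

* **local permutation** — mean PET count over all \((i, j)\) grid shifts of
  the anchor pair (step = anchor width, \(i, j \in \{-5..5\}\), the
  candidate itself, diagonal-crossing and off-chromosome windows removed);
* **decay-conditional expectation** — anchor 1D occupancy times the
  probability, under the chromosome-wide PET distance distribution, of a
  distance inside the candidate's span, evaluated for both anchors;
* a pseudo-count of 1.

The second term is a deliberate design decision. PET signal concentrates at
accessible peaks, so anchor-width shifts step *off* the occupied stripe:
near the diagonal the local permutation alone understates the null rate by
an order of magnitude, and on the reference synthetic dataset it admits
~1000 false near-diagonal loops (precision 0.05). Conditioning on the
anchor's own 1D occupancy and the global distance decay is the standard
correction in this family of callers and restores precision to ~0.98
without touching recall. `test_candidate(..., decay = FALSE)` disables the
term for anyone wanting the pure local-shift null.

`p = P(X \ge n_{obs})` under the resulting rate; candidates from all `eps`
values are merged when both anchor pairs overlap (union extent, minimum
p-value, support re-quantified on the union); retained loops need
`pet_count >= min_pets` (default 10), Bonferroni-adjusted `p <= 0.01` and
enrichment score \(\ge 2\).

## Aggregation (APA) analysis

For each loop an 11 × 11 contact matrix is built from the anchor pair plus
five same-width windows on each side; the loop occupies the centre cell.
The per-loop enrichment score is the centre divided by the mean of the other
120 cells, undefined (and excluded, with the exclusion counted) when that
mean is zero — a pseudo-count would stop the score being a pure ratio.
Matrices truncated by chromosome ends are excluded rather than padded, since
padding biases the z-scores. For the mean heatmap each matrix is divided by
its total count and z-scored across its 121 cells before element-wise
averaging; the global enrichment score is the mean of the per-loop scores.
`min_window_pets` (e.g. 20) gates loops whose whole neighbourhood is too
sparse, the appropriate setting for sparse contact data.

**Calibration caveat.** The per-loop score is a ratio of counts. At desk
scale (the 200k-PET reference fixture), an 11 × 11 matrix at a *non-loop*
position holds only ~0–13 PETs, so the null score distribution is
degenerate: mostly 0 (empty centre), sometimes undefined, occasionally
large. The tests assert the idealised null band (global ES of shuffled
false loops in [0.7, 1.3]) and that assertion is deliberately left failing,
with the measured value, because no legitimate false-loop construction at
this depth concentrates near 1; at real sequencing depth (\(10^8\) PETs)
the matrices are dense and the band is meaningful. A green planted-loop
test (global ES \(\gg 5\)) and an exactly-1.0 uniform-matrix test pin what
the statistic does establish.

## Differential loops

Loops from two conditions are merged (both-anchor overlap) and quantified
in both, together with the mean count over the same permuted nearby windows
used for calling. The nearby counts are the "background data": an OLS of
\(\log_2(b+1)\) on \(\log_2(a+1)\) fits how treatment background scales
against control, and treatment counts are mapped onto the control scale by
the inverse transform \(2^{(\log_2(x+1) - c)/s} - 1\). When fewer than 10
background pairs contain any signal the fit falls back to the identity
(equal-depth) transform with a warning — empty windows carry no depth
information, and a slope fitted through a handful of single-PET log ratios
demonstrably flips call directions on synthetic data.

Cutoffs on the MA plane are calibrated on the background cloud: the
lexicographically smallest (minimal `m_cut`, then minimal `a_cut`) pair
whose background exceedance is at most the target FDR (default 0.05).

The per-loop p-value follows the printed formula literally:
\[ p = 1 - \sum_{i=1}^{fg-1} \mathrm{Poisson}(i,\;
   \max(bg,\, fgNearby,\, bgNearby,\, pseudo)) \]
with `fg` the larger and `bg` the smaller transformed loop count, the
nearby terms matched to those conditions, `pseudo = 1`, and transformed
counts floored to integers (the sum index is integral). Note the sum starts
at \(i = 1\), so \(p\) equals the standard upper tail *plus*
\(\mathrm{PMF}(0)\); this faithful form is the default and a `tail_exact`
option provides the standard tail (which, unlike the literal form, is
monotone in the rate). Significance needs the MA cutoffs plus
Bonferroni-adjusted \(p \le 0.01\); `correct = FALSE` with
`p_cut = 0.001` reproduces the knockdown-analysis mode. Direction is the
sign of `M` (positive = enriched in treatment).

## TF loop-anchor enrichment

Anchors and three anchor-width "false loop" windows stepping outward from
each loop (paired by step index; any pair touching a true anchor is dropped
entirely) are intersected with each factor's peaks into binary left/right
matrices. Three attributes per factor: anchor consistency (Spearman
correlation of the left/right columns — on binary data exactly the phi
coefficient, pinned to 1e-12 in tests), co-binding ratio (fraction of loops
bound at both anchors) and peak-overlap ratio (fraction of the factor's
peaks on anchors). The filter requires, against the flanking background:
consistency ratio > 2, co-binding ratio > 0.1, co-binding ratio fg/bg > 2
and peak-overlap ratio fg/bg ≥ 1 (background denominators floored at
1e-6). A 1000-round column-wise permutation (preserving each factor's
marginal frequency) yields an FDR per attribute; the gate enforces the
consistency FDR < 0.001 only — the spec text is ambiguous about the other
attributes, and the peak-overlap ratio is invariant under row shuffling, so
its permutation FDR is reported as `NA`. Passing factors are ranked by
consistency (ties broken by co-binding ratio).

## Virtual 4C, montage densities

A viewpoint (default ±1 kb around a TSS) selects PETs with either end
midpoint inside it; their *other* ends are piled as full-interval coverage
(not midpoints) into bins (default 200 bp) across ±250 kb. Bin values are
covered bases / bin size, so profile mass equals clipped distal covered
bases / bin size exactly — the conservation property the tests assert on
100 random viewpoints. PETs with both ends inside the viewpoint contribute
once and are counted separately. Montage tables give, for a set of named
non-overlapping regions, the PET count with one end in each region pair,
per million cis PETs, optionally restricted to chosen viewpoint regions.

## Annotation and networks

Candidate elements are merged, labelled promoter when within 2 kb of a TSS
and enhancer otherwise, and same-label neighbours with gaps under 100 bp
are re-merged. Anchors take the promoter > enhancer > other priority
(largest overlap breaks ties), giving the loop classes P-P, E-P, E-E,
P-other, E-other, other-other. CTCF motif orientation uses the
strongest-scoring motif per anchor: `+`/`-` is convergent, `-`/`+`
divergent, equal strands tandem. The regulatory network takes merged
elements as nodes and annotated loops as undirected edges; the degree
distribution's power-law exponent is the negative binned log-log OLS slope
(flagged poor when \(R^2 < 0.5\) or the slope shows no decay) — a
deliberately simple estimator, matching how such exponents are usually
reported alongside the network figure rather than a maximum-likelihood fit.

## The synthetic world

The generator plants what the pipeline assumes: non-overlapping accessible
peaks (1 kb) placed uniformly, a TSS at 30% of peak centres, loops between
random peak pairs at least 20 kb apart with 25–80 PETs whose ends scatter
as Normal(anchor centre, 150 bp), and background PETs whose left ends sit
on peaks with probability 0.7 and whose distances follow a truncated
\(d^{-\alpha}\) law (\(\alpha = 1\), minimum 1 kb). Read ends are 50 bp.
PCR duplicates are injected per-PET with the configured rate, linker flags
per-end. Condition B re-draws PETs with per-loop fold-change multipliers.
TF binding is planted jointly at both anchors with probability
`p_cobind_true`, on top of a homogeneous decoy-peak process whose intensity
makes an anchor-width window bound with probability `p_bind_background`.

The reference fixture (one 10 Mb chromosome, 300 peaks, 50 loops, 200k
background PETs, seed 42) is desk-scale: loop calling at the default
parameters is exercised end to end in seconds. What a green test does *not*
establish: behaviour under trans contacts, mappability artefacts,
chromosome-scale compartment structure, replicate dispersion, or the
aggregate-null calibration discussed above — all absent from the generator
by design.

## Numerical choices

* Coordinates 0-based half-open everywhere; PET 2D point = end-interval
  midpoints; rectangle queries are half-open on both axes.
* Poisson tails via `ppois(lower.tail = FALSE)` (no 1-minus cancellation);
  the literal differential formula is still exposed as printed.
* Spearman on binary vectors is computed by `stats::cor`; ranks are affine
  in the values, so it equals the phi coefficient to machine precision.
* Subsampling and all shuffles run under locally scoped seeds; fixed seeds
  reproduce byte-identical outputs.
* Merging uses exact interval arithmetic on integer bp; DBSCAN tie-breaks
  are fixed by pre-sorting, so cluster labels are reproducible across
  platforms.
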