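---
title: "Determining DSB end structures by coverage-normalized cross correlation"
author: "cncc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining DSB end structures by coverage-normalized cross correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cncc)
```

## The model

A double-strand break (DSB) produces two DNA ends. Break mapping and
sequencing protocols capture each end as a separate fragment and, after
alignment, report its break-proximal nucleotide as the 5′-most base of
read 1 — one count on the positive strand for one side of the break,
one on the negative strand for the other. Before adaptor ligation the
ends are blunted: 3′ overhangs are trimmed back (so the two mapped 5′
ends end up *separated* on the reference by the overhang length), 5′
overhangs are filled in (the two ends *overlap*), and blunt ends are
left as they are. The end structure of a break is therefore encoded in
the signed distance between its negative-strand and positive-strand
coverage spikes.

Genome-wide, that distance is read out by the coverage-normalized cross
correlation between the positive-strand profile $x(i)$ and the
negative-strand profile $y(i)$:

$$\mathrm{CNCC}(t) = \frac{\sum_i y(i)\,x(i-t)}
 {\sqrt{\sum_i x^2(i)\,\sum_i y^2(i)}}$$

evaluated at every integer shift $t$ in a window. A blunt break
concentrates signal at $t=-1$; a 3′ overhang of $L$ nt at $t=-1-L$; a
5′ overhang of $L$ nt at $t=-1+L$. `shiftToStructure()` and
`structureToShift()` implement this decoding bijectively.

The denominator is a single genome-wide normalization while the
numerator is accumulated per chromosome and summed, so cross-chromosome
products never occur and the result is independent of chromosome order.
Two consequences matter in practice and are enforced by tests:
$|\mathrm{CNCC}(t)| \le 1$ for any input (Cauchy–Schwarz), and the
curve is invariant to multiplying all counts by a constant — samples of
different sequencing depth are directly comparable.

**Assumptions.** The method assumes (i) single-nucleotide-accurate
5′-end positions of read 1, (ii) strand labels that distinguish the two
sides of a break, and (iii) the differential blunting chemistry above.
Protocols that blunt both overhang types the same way collapse the
three structures onto $t=-1$ and cannot be distinguished downstream.

## Implementation and numerical choices

Profiles are sparse: only positions with at least one read are stored
(`StrandProfile`, per-chromosome sorted position/count vectors, 0-based
coordinates matching `genomecov -dz` and BED). The numerator is
evaluated sparsely — for each negative-strand position the
positive-strand positions inside the shift window contribute count
products, accumulated in bounded chunks — with results identical to a
dense evaluation; the test suite checks equality against a brute-force
nested-loop implementation to 1e−12.

Ties in the curve argmax are broken toward the smallest absolute shift
(and the negative member of a ± pair), deterministically. Empty
profiles make the normalization undefined and are an error rather than
a NaN. Counts are stored as positive numerics so that rescaled
(mixture-weighted) profiles remain representable; file readers enforce
integer depths ≥ 1.

Default shift windows: ±1000 for treatment data (resection tracts reach
a few hundred nt), ±50 for single-enzyme digests. These are arguments,
not constants.

## The shuffled control

An unrestrained genome-wide shuffle of break positions produces a
near-zero background — it destroys break clustering and so controls for
nothing. The stringent control instead perturbs the data minimally, in
two steps per chromosome: (1) the multiset of coverage values is
permuted among the positions that originally had non-zero coverage,
preserving clustering and the count distribution; (2) every position
receives an independent uniform wiggle in $\{-W,\dots,-1,1,\dots,W\}$
(zero excluded). Counts colliding on one position are summed, so total
coverage is conserved exactly; positions wiggled past a chromosome edge
are reflected back inside (with $W \ll$ chromosome length the choice is
immaterial, and reflection keeps conservation exact). The wiggle
magnitude is matched to the maximum spike range under study: $W=2$ for
single-enzyme digests, $W=2000$ for resection-scale treatment data.
Suppression of a genuine spike grows with $W$; the package's tests
verify monotonicity over $W \in \{1,2,5,10\}$ and >10× suppression of a
digest spike at $W=2$.

Two points the literature leaves open were decided as follows. The two
strand profiles are shuffled *independently* (a joint permutation would
preserve exactly the pairing structure the control is meant to break);
and "the median of the shuffled control" subtracted to form the
relative CNCC is a single scalar over all shifts and replicates — the
control is used as a flat baseline — with a per-shift median available
via `relativeCNCC(..., perShift = TRUE)`. Default replicates = 1; a
seed is always required.

## Sensitivity scan and resection signatures

`sensitivityScan()` masks a random fraction of known cut sites
(removing *all* reads at each chosen site's two expected end positions,
window ±0 by default) and tracks CNCC at the species' characteristic
shift, by default over fractions 0–100% in 10% steps with 100
iterations each; per-fraction summaries report the median, quartiles
and 5/95 percentiles. Sites enter the analysis when they hold strictly
more than `minReads` reads (default 5). With equal per-site read
counts the median signal falls linearly in the masked fraction, the
drop is specific to the target shift, and a shuffled companion scan
stays flat — all three are asserted in the acceptance tests.

`resectionRange()` quantifies a spread of 3′-overhang signal: within a
window of shifts strictly below −1 (default [−201, −2], i.e. overhangs
of 1–200 nt, comfortably covering the ~165-nt tracts seen after
topoisomerase-II poisoning) it finds the peak and expands the maximal
contiguous run of shifts whose values reach 90% of it (the fraction is
an argument). The run is reported as shifts and as overhang lengths.

## Region densities

Gene models (TSS/TTS, strand-aware, 0-based) induce a five-way
partition: promoter `[TSS−1000, TSS−250)`, TSS `[TSS−250, TSS+250)`,
TTS `[TTS−250, TTS+250)`, gene body `[TSS+250, TTS−250)`, intergenic
the rest; minus-strand genes mirror the asymmetric spans. All spans are
half-open — the boundary convention had to be fixed somewhere, and
half-open intervals compose without off-by-one corrections. Overlaps
are resolved by the fixed precedence TSS > promoter > TTS > gene body,
chosen because the TSS is the most break-enriched class and the
definitions self-overlap for genes shorter than ~2 kb; the partition
property (every base exactly one label) is asserted against a per-base
sweep oracle. Density is reported as BPMM — breaks per megabase of
label per million mapped breaks — and group comparisons use
Kruskal–Wallis per label followed by pairwise Dunn z tests
(tie-corrected, BH-adjusted), computed on per-window densities
(non-overlapping 1-kb windows by default).

## Spike pairs

"Pairs separated by $g$ nt" is implemented as a $g$-nt *gap* between
the single-nucleotide negative-strand spike and the positive-strand
spike ($\mathrm{posPos} = \mathrm{negPos} + g + 1$). This is the
geometry forced by trim-to-blunt processing of a $g$-nt 3′ overhang and
is consistent with that structure's CNCC spike at $-1-g$; the phrase is
ambiguous in prose, so the convention is stated prominently here and in
`?findPairs`. Spikes are exact single positions (window maxima are out
of scope), both must carry at least `minReads` reads (default 2), and
`exportPairFasta()` writes `[negPos − flank, posPos + flank]` per pair
for external motif discovery.

## What the simulator does and does not emulate

`simulateDigest()` generates the method's actual input domain —
post-alignment 5′-end positions — not reads: a cut at $p$ emits a
negative-strand end at $p$ and a positive-strand end at $p+1+L$ (3′
overhang), $p+1$ (blunt) or $p+1-L$ (5′ overhang), with per-site
capture coin flips, configurable per-end read counts, and uniform
Poisson background on both strands. `simulateResection()` draws a
per-site overhang length from a configurable distribution;
`simulateMinorSpecies()` rescales one species' counts to an exact read
fraction. Everything is reproducible from one seed, and the emitted
profiles decompose exactly into the truth table plus the tracked
background.

The generator deliberately omits chromatin-biased background, mapping
artifacts, PCR-duplicate structure and sequence-dependent capture
efficiency. Passing tests therefore demonstrate that the *statistics*
behave as specified on data matching the stated model — they do not by
themselves certify performance on real libraries, where background is
non-uniform and capture varies.

## Problem sizes used in the tests

The validation suite runs entirely on synthetic data at desk scale,
sizes chosen once as realistic miniatures of the corresponding
experiments: digest recovery on a 10-Mb genome with 1000 cut sites,
10 reads per end, 95% capture and ~5% uniform background (≥90% of
reads at sites); shuffle-control behaviour on the same digest with 10%
background; the masking scan on a 5-Mb genome where a 300-site 2-nt
3′-overhang species contributes <1% of ~600k reads (11 fractions × 100
iterations); and resection recovery from 150,000 sites with overhang
lengths uniform on 5–45 nt, enough that multinomial noise across the 41
length classes stays well inside the 90%-of-maximum band.

## Known limitations

* Multi-mapped reads surviving the upstream flag filter are kept; no
  MAPQ cutoff is applied by default (`minMapq` exposes one) because the
  reference pipeline specifies none.
* The statistic is reported raw — no smoothing or peak deconvolution;
  overlapping resection gradients from distinct species are summed.
* The five-label partition collapses isoform structure to one TSS/TTS
  pair per gene model; supplying one record per transcript weights
  promoters by isoform count.
* BAM ingestion requires Rsamtools/GenomicAlignments; the dz/BED paths
  have no such dependency and are the guaranteed route.
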