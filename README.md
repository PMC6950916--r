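# cncc — genome-wide DNA break end structures from break-mapping data

DNA double-strand breaks (DSBs) terminate in one of three end
structures — blunt ends, 3′ overhangs, or 5′ overhangs — and that
structure helps decide how a cell repairs the break. Modern break
mapping and sequencing protocols capture both ends of every DSB at
single-nucleotide resolution, as strand-specific 5′-end coverage of
read 1. Because library preparation blunts the ends before the first
adaptor ligation (3′ overhangs are trimmed, separating the two mapped
ends on the reference; 5′ overhangs are filled in, overlapping them),
the *relative shift* between negative- and positive-strand coverage
encodes the end structure of the underlying breaks.

`cncc` recovers that information genome-wide. Its core statistic is the
**coverage-normalized cross correlation** between the positive-strand
profile *x(i)* and the negative-strand profile *y(i)*:

```
CNCC(t) = Σᵢ y(i) · x(i − t) / sqrt( Σᵢ x²(i) · Σᵢ y²(i) )
```

computed for every integer shift *t* in a window. Products are taken
only within a chromosome; the normalization is global, so the statistic
is bounded by 1 (Cauchy–Schwarz), independent of sequencing depth, and
comparable across samples. The shift at which CNCC spikes decodes the
end structure:

| characteristic shift | end structure |
|---|---|
| −1 | blunt |
| −1 − L | 3′ overhang of L nt |
| −1 + L | 5′ overhang of L nt |

The package is aimed at anyone analyzing strand-specific DSB
mapping data (DSBCapture/END-seq-style protocols, restriction-digest
controls, genotoxin treatments). Beyond the statistic itself it
implements the full surrounding workflow:

* **I/O** — per-strand `genomecov -dz` depth files, single-nucleotide
  BED6 break ends, filtered BAM ingestion (read 1, primary,
  non-duplicate; 5′-end extraction per strand), interval masking
  (e.g. centromeres).
* **Stringent shuffled control** — coverage values permuted among
  non-zero positions plus a bounded non-zero position wiggle (±W,
  W matched to the spike range under study), and "relative CNCC"
  (treatment minus control median).
* **Sensitivity scan** — random masking of known cut sites in
  increments with many iterations, tracking CNCC at the characteristic
  shift.
* **Resection signatures** — the 90%-of-maximum CNCC range over shifts
  < −1, reported as 3′-overhang lengths.
* **Region densities** — promoter/TSS/TTS/gene-body/intergenic
  partition and breaks-per-megabase-per-million (BPMM), with
  Kruskal–Wallis + Dunn (BH) group comparison.
* **Spike pairs** — negative/positive spike pairs at a fixed gap and
  FASTA export of their loci for motif discovery.
* **Simulator** — restriction-digest and resection-gradient datasets
  with per-site ground truth, so every step is testable without any
  external data.

## Worked example

Simulate a BanII-like digest (4-nt 3′ overhangs) of a 1-Mb genome with
200 cut sites and light uniform background, then decode the end
structure:

```r
library(cncc)

si  <- GenomeInfoDb::Seqinfo("chr1", 1e6)
cfg <- simConfig(si, nSites = 200,
                 endStructure = EndStructure("three_prime_overhang", 4),
                 readsPerEnd = 5, backgroundRate = 1e-4, seed = 11)
sim <- simulateDigest(cfg)

curve <- computeCNCC(sim$pos, sim$neg, minShift = -20, maxShift = 20)
dominantShifts(curve, k = 3, minProminence = 0.01)
#>   shift     cncc prominence                 kind overhang
#> 1    -5 0.981549   0.981549 three_prime_overhang        4
```

The curve spikes at shift −5 with CNCC 0.98: the two blunted 5′ ends of
each break sit 5 nt apart, i.e. a 4-nt 3′ overhang — the BanII
signature. The same pair of profiles run through the shuffled control
(`controlCurves(..., wiggle = 2)`) loses the spike, and
`findPairs(sim$pos, sim$neg, gapNt = 4, minReads = 2)` returns the 200
individual cut loci, ready for `exportPairFasta()`.

The same objects drive the rest of the workflow, e.g. a resection
analysis on a treatment-like simulation:

```r
si10 <- GenomeInfoDb::Seqinfo("chr1", 1e7)
rsim <- simulateResection(simConfig(si10, nSites = 150000,
                                    overhangDist = 5:45,
                                    readsPerEnd = 5, seed = 9))
sig <- resectionRange(computeCNCC(rsim$pos, rsim$neg, -250, 10))
overhangRange(sig)
#> [1]  5 45
```

A thin command-line interface over the same functions is installed at
`exec/cncc` (`cncc simulate`, `cncc compute`, `cncc call`,
`cncc control`, `cncc relative`, `cncc sensitivity`, `cncc density`,
`cncc pairs`, `cncc pairs-fasta`, `cncc coverage`).

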