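---
title: "Marker and phytochemical diversity of a citronella core collection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker and phytochemical diversity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cymbodiv)
```

## The data and the problem

A core collection of 72 Java citronella (*Cymbopogon winterianus*) accessions
from four northeast-Indian states (Assam 51, Manipur 9, Meghalaya 2, Arunachal
Pradesh 10) was genotyped with 28 SSR primer pairs, scored as presence/absence
of 92 gel bands, and profiled for the three oil biomarkers (citronellal,
citronellol, geraniol, in percent of essential oil). `cymbodiv` implements the
complete downstream analysis: primer informativeness, population diversity and
differentiation, distance-based clustering and ordination, AMOVA, and
chemotype clustering.

The raw band matrix was never deposited; only the per-primer summary table,
the oil-composition table and the population labels are public. The package
therefore ships those tables as fixtures (`cw_primer_table()`,
`cw_phytochem()`, `cw_populations()`) and provides a generator
(`simulate_bands()`) that emulates the band matrix under controllable
population divergence, so every pipeline stage is exercised end to end.

## Dominant-marker conventions

SSR bands are scored dominantly here: an accession either shows a band or
does not, and heterozygotes are indistinguishable from band homozygotes.
Two conventions follow from this, both settable:

* **Allele frequencies** (`allele_freqs()`): the default `"phenotypic"` mode
  takes the band-allele frequency as the carrier proportion itself. Java
  citronella propagates vegetatively and flowers rarely, so a Hardy–Weinberg
  correction has no biological basis; the `"hwe"` mode (null-allele frequency
  as the square root of the non-carrier proportion) is retained for
  comparison with software that assumes random mating.
* **PIC** (`pic_primer()`): the default `"multiallelic"` mode treats a
  primer's bands as alleles of one locus, with `p_i` the share of band *i*
  among the primer's carrier calls, and returns `1 - sum(p_i^2)`. This is the
  only reading consistent with published dominant-marker PIC values above
  0.5 (a per-band biallelic PIC is bounded by 0.5); the `"biallelic_mean"`
  mode is available for comparison with that literature.

The **effective multiplex ratio** is implemented as the polymorphic fraction
of a primer's bands, so that MI = PIC × (polymorphic/total). The published
marker-index column is consistent only with this reading: a fully polymorphic
primer has MI = PIC, and the primer with 1 polymorphic band of 3 and
PIC 0.33 prints MI 0.11 = 0.33 × 1/3. Recomputing MI this way from the
printed PIC and band counts reproduces the printed MI column within ±0.01
for all 28 primers.

A band is **polymorphic** under the strict criterion 0 < p < 1; no 95%
frequency cut-off is applied (with 72 accessions the published counts give no
evidence of one). Reported values are rounded half-up to two decimals
(`round_half_up()`) only at the reporting layer; all internal computation is
at full precision.

## Population diversity and differentiation

Per locus (band), with allele frequencies `p` and `q = 1 - p`:
`na` counts alleles present, `ne = 1/(p² + q²)`, Nei's `h = 1 - p² - q²`,
Shannon's `I = -(p log p + q log q)`. Population summaries report the mean ±
SD of each over all loci (sample SD, n−1).

Pooled statistics follow the Nei (1973) / POPGENE convention: per locus,
`Ht` is the gene diversity of the **unweighted mean** of the population
allele frequencies, `Hs` the unweighted mean of the within-population
diversities, both then averaged over loci (reported ± SD over loci);
`Gst = (Ht - Hs)/Ht` is computed from the locus-averaged values, and the
indirect gene-flow estimate is `Nm = 0.5 (1 - Gst)/Gst` (infinite when
`Gst = 0`).

With a **finite number of populations** this Gst is attenuated relative to
the generator's divergence parameter *F*: under the Balding–Nichols model
the expectation is approximately `F (k-1) / (k - F)` for `k` populations
(≈ 0.20 for `F = 0.25`, `k = 4`), the cost of estimating the total-population
frequency from only `k` population means. The parameter-recovery test
(four populations of 50, 100 loci) accordingly checks recovery to ±0.05,
not exact equality.

Nei's identity between populations is `I = Jxy / sqrt(Jx Jy)` with `Jxy`
the mean over loci of the allele-frequency cross-product, and `D = -log I`;
`upgma()` (average linkage on `D`) gives the between-population dendrogram.

## Accession-level clustering and ordination

`jaccard()` counts, per accession pair, shared band presences `a` and
one-sided mismatches `b`, `c`: similarity `a/(a+b+c)`, ignoring shared
absences (absence of a dominant band is not evidence of shared ancestry).
A pair with no presences at all is assigned similarity 1 with a warning
rather than NaN. The dissimilarity fed to the tree and ordination is
`1 - s`.

`neighbor_joining()` is a direct Saitou–Nei implementation with two
deterministic policies: Q-criterion ties are broken by the smallest
(row, column) pair, and a negative branch length arising at a join is clamped
to zero with the deficit transferred to the sibling edge, preserving the
distance through the new node (the count of clamped edges is kept as a
diagnostic attribute). On any additive matrix the output reproduces the
generating tree's path lengths to < 1e-9, which the tests verify against
random trees and against an independent library implementation.

`pcoa()` double-centers `-d²/2` (Gower) and eigendecomposes. Negative
eigenvalues — expected, since Jaccard dissimilarities need not be Euclidean —
are reported but excluded from the percent-variance denominator, and
coordinates are returned for positive axes only (eigenvalues below
`1e-9 × max |λ|` are treated as null).

## AMOVA

`amova()` partitions squared pairwise distances: with `N` accessions in `k`
populations, `SS_total = Σ_{i<j} d²_ij / N`, `SS_within = Σ_p Σ_{i<j∈p}
d²_ij / n_p`, `SS_among` by subtraction; `σ²_within = MS_within`,
`σ²_among = (MS_among - MS_within)/n0` with `n0 = (N - Σn_p²/N)/(k-1)`
handling the unequal population sizes; `PhiPT = σ²_among/(σ²_among +
σ²_within)` after truncating a negative among-component to zero (the raw
value is retained). For binary band vectors the Euclidean distance of
`band_distance()` makes `d²` the mismatch count, the standard dominant-marker
choice. Significance comes from permuting individuals among populations with
sizes held fixed, `p = (1 + #{Phi_perm ≥ Phi_obs}) / (B + 1)`, default
`B = 999`. The test suite checks exact SS additivity, a fully hand-enumerated
two-by-two toy, and the type-I error rate at α = 0.05 over 200 seeded null
replicates of 40 accessions (within the binomial 95% interval).

## Chemotype clustering

`euclidean_matrix()` computes distances over the three compound percentages;
since all three variables share the percent scale, the default is
**unstandardized**, and this choice is empirical as well: on the published
table, raw-percent complete linkage cut at k = 3 reproduces the published
cluster sizes 9/58/5, while z-scored distances do not (3/3/66).
`complete_linkage()` is a deterministic agglomerator (ties broken by smallest
original-index pair) whose merge history is validated against brute-force
agglomeration and against `hclust`; heights are also reported on the
similarity scale `100 (1 - d/d_max)`. `cut_k()` withholds the last k−1
merges and returns labels, sizes and per-cluster compound means; size-weighted
cluster means reconstruct the grand mean to 1e-9.

## The synthetic band generator

`simulate_bands()` draws, per band, an ancestral carrier frequency
`p ~ U(0.1, 0.9)`, then population frequencies from the Balding–Nichols
distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)`, and finally Bernoulli carrier
calls — directly at the population frequency in the default `"phenotypic"`
scoring (clonal propagation), or at `1-(1-q)²` in `"dominant_diploid"`
scoring. Defaults mirror the study conditions: population sizes 51/9/2/10,
the 28 published per-primer band counts (92 bands, `published_band_counts()`),
and `F = 0.25` matching the reported differentiation. The generator
reproduces the shape and divergence of the data, not its biology: bands are
independent (no linkage), frequencies are stationary (no mutation or
selection), and populations diverge symmetrically from one ancestor. Passing
tests on synthetic data therefore validate the statistics' arithmetic and
calibration, not conclusions about the real germplasm.

`simulate_phytochem()` draws Gaussian chemotype blobs (clipped to [0, 100])
around centroids defaulting to the three observed chemotype means — roughly
high-geraniol (15/15/35), high-citronellal (43/12/20) and low-everything
(6/5/7) — with cluster sizes apportioned by deterministic largest-remainder
rounding (so proportions 9/58/5 over n = 72 give exactly those sizes), and
per-compound noise SD 2, comparable to the within-chemotype spread needed for
a clean three-cluster structure.

## Problem sizes and numerical choices

The test suite and analysis scripts run at the study's own scale (72 × 92
band matrices) or smaller: property tests use n ≤ 8 trees and 7-point
clustering instances where brute-force enumeration is exact; parameter
recovery uses 4 × 50 accessions × 100 loci; the AMOVA calibration uses 200
replicates of 40 accessions with 999 permutations each. Distance matrices are
symmetrized (`(d + t(d))/2`) after validation at tolerance 1e-8; degenerate
inputs (all-zero band profiles, a single population, populations of size 1,
zero Nei identity) either receive documented sentinels (`Inf`) or errors, as
listed on each function's help page.

## Known limitations

* Missing band calls are unsupported by design — a missing cell is an error,
  not an imputation.
* The AMOVA is two-level (among/within populations); no region stratum and no
  within-individual component (dominant scores carry no heterozygosity).
* Gst has no bootstrap interval; the per-population table reports SDs over
  loci only.
* The published per-accession band data being unavailable, per-primer PIC/Rp
  values, the published Table-3 diversity means, Table-4 eigenvalues and the
  published tree topologies cannot be reproduced, only their pipeline
  exercised on synthetic data of the same shape.
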