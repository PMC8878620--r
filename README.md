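# cymbodiv

Dominant-marker and phytochemical diversity analysis of germplasm
collections, built around the 72-accession Java citronella (*Cymbopogon
winterianus*) core collection genotyped with 28 SSR primers (92 scored
bands) and profiled for the three essential-oil biomarkers citronellal,
citronellol and geraniol.

Breeders working with clonally propagated aromatic crops need to know which
primers discriminate their material, how diversity is distributed among
collection regions, and which accessions form chemically distinct groups.
`cymbodiv` implements that full analysis as a tested R package:

* **Primer informativeness** — per-primer PIC (multiallelic,
  `PIC = 1 - Σp_i²`), effective multiplex ratio (polymorphic fraction),
  marker index `MI = EMR × PIC`, band informativeness
  `I_b = 1 - 2|0.5 - p|` and resolving power `Rp = Σ I_b`
  (`primer_summary()`).
* **Population diversity** — per-population `na`, `ne = 1/Σp_i²`,
  `h = 1 - Σp_i²`, Shannon `I = -Σ p_i log p_i`; pooled `Ht`, `Hs`,
  `Gst = (Ht - Hs)/Ht` and gene flow `Nm = 0.5(1 - Gst)/Gst`
  (`population_summary()`), plus Nei identity/distance between populations
  with a UPGMA dendrogram (`nei_identity_distance()`, `upgma()`).
* **Clustering & ordination** — Jaccard similarity over band profiles
  (`jaccard()`), a deterministic Saitou–Nei neighbour-joining tree
  (`neighbor_joining()`), and principal coordinate analysis with an
  eigenvalue / %variance / cumulative table (`pcoa()`).
* **AMOVA** — distance-based variance partitioning among/within populations
  with the PhiPT statistic and a permutation test (`amova()`).
* **Chemotypes** — Euclidean complete-linkage clustering of the oil
  composition with k-cuts and cluster means (`complete_linkage()`,
  `cut_k()`, `compound_ranges()`).
* **Synthetic data** — a Balding–Nichols band-matrix generator with
  controllable divergence and a chemotype-blob generator
  (`simulate_bands()`, `simulate_phytochem()`), standing in for the
  unpublished raw band matrix.

The published oil-composition table, population assignments and per-primer
summary are packaged as plain-text fixtures (`cw_phytochem()`,
`cw_populations()`, `cw_primer_table()`).

## Worked example

```r
library(cymbodiv)

# chemotype analysis of the published oil table
t1 <- cw_phytochem()
cl <- complete_linkage(euclidean_matrix(t1))
ck <- cut_k(cl, 3, data = t1)
ck$sizes
#> [1]  9 58  5
round(ck$means, 2)
#>          citronellal citronellol geraniol
#> cluster1       15.46       15.05    34.76
#> cluster2       43.01       11.94    20.02
#> cluster3        6.03        5.07     7.51
```

Cut at three clusters, the 72 accessions split 9/58/5: a small
high-geraniol/high-citronellol group, a dominant high-citronellal group, and
five accessions poor in all three compounds.

```r
# the full marker pipeline on a simulated stand-in band matrix
sim <- simulate_bands(fst = 0.25, seed = 1)   # 72 accessions, 92 bands, 4 states
amova(band_distance(sim$bands), sim$populations, permutations = 999, seed = 1)
#>              source df        SS      MS variance pct_of_total
#>   Among populations  3  201.2479 67.0826   4.7152      24.2423
#>  Within populations 68 1001.9882 14.7351  14.7351      75.7577
#>               Total 71 1203.2361      NA  19.4503     100.0000
#> PhiPT = 0.2424, p = 0.001 (999 permutations)
```

At the divergence level reported for the real collection, about a quarter of
the molecular variance lies among the four collection-state populations and
three quarters within them, and the differentiation is highly significant
under permutation.

The numbered scripts under `analysis/` run the whole workflow in order
(simulation → marker statistics → population diversity → trees/ordination →
AMOVA → chemotypes), writing tables, Newick trees and JSON summaries under
`results/`.

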