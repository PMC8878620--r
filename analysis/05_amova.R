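#!/usr/bin/env Rscript
# Stage 5: analysis of molecular variance among/within the four populations,
# with the PhiPT permutation test (999 permutations).

library(cymbodiv)

m <- read_band_matrix("results/bands.csv")
pops <- read_population_map("results/populations.csv")

res <- amova(band_distance(m), pops, permutations = 999, seed = 1)
print(res)
utils::write.csv(res$table, "results/amova.csv", row.names = FALSE, quote = FALSE)
cat(sprintf("\n%.0f%% of the variance lies among populations and %.0f%% within;\nPhiPT = %.3f, permutation p = %.3f.\n",
            res$table$pct_of_total[1], res$table$pct_of_total[2],
            res$phi_pt, res$p_value))
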