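#!/usr/bin/env Rscript
# Compute the regional supply of not-yet-recycled stable manure carbon
# (C:N 10, humification coefficient 0.5) that caps the
# organic-fertilization measure.

suppressPackageStartupMessages(library(socpotential))

manure <- read_manure_records("results/synthetic/manure_regions.csv")
budget <- recyclable_manure_c(manure, cn_ratio = 10, hc = 0.5)
readr::write_csv(budget, "results/budgets.csv")

cat(sprintf("total excretion: %.1f Tg N/yr\n",
            sum(manure$n_excreted) / 1e9))
cat(sprintf("unrecycled surplus: %.1f Tg N/yr (%.0f%% of excretion)\n",
            sum(budget$n_surplus) / 1e9,
            100 * sum(budget$n_surplus) / sum(manure$n_excreted)))
cat(sprintf("stable C supply: %.1f Mton C/yr across %d regions\n",
            sum(budget$stable_c_supply) / 1e9, nrow(budget)))
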