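#!/usr/bin/env Rscript
# Combine the five measures into total sequestration scenarios: plain
# addition (maximum complementarity) and 1/rank-declining weights. Done
# twice: on the packaged published per-measure potentials, and on the
# potentials computed from the simulated inputs in 05_upscale.R.

suppressPackageStartupMessages(library(socpotential))

cat("published per-measure potentials:\n")
pub <- soc_global_potentials(use_m2cor = TRUE)
print(combine_max_complementarity(pub))
print(combine_rank_weighted(pub))

pot <- readr::read_csv("results/potentials.csv", show_col_types = FALSE)
syn <- pot[pot$climate == "all" &
             pot$measure %in% c("M1", "M2cor", "M3", "M4", "M5"), ]
syn$measure[syn$measure == "M2cor"] <- "M2"
syn <- syn[, c("measure", "potential_mton", "q01", "q99")]

cat("\nsimulated-input potentials:\n")
s_max <- combine_max_complementarity(syn)
s_rank <- combine_rank_weighted(syn)
print(s_max)
print(s_rank)

jsonlite::write_json(
  list(published = list(max_complementarity =
                          unclass(combine_max_complementarity(pub)),
                        rank_weighted = unclass(combine_rank_weighted(pub))),
       simulated = list(max_complementarity = unclass(s_max),
                        rank_weighted = unclass(s_rank))),
  "results/scenarios.json", auto_unbox = TRUE, digits = NA
)
cat("\nwrote results/scenarios.json\n")
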