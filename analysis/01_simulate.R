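#!/usr/bin/env Rscript
# Generate the synthetic inputs for the upscaling workflow: a cropland
# cell table whose marginal composition mirrors the global layers
# (climate 30/19/30/21%, 45% high-intensity tillage, 25% residue
# burning, 72% rotations without catch crops), raw effect-size records
# around the packaged pooled means, and regional manure N records with
# 90% of excretion already recycled.

suppressPackageStartupMessages(library(socpotential))
dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(n_cells = 10000, seed = 42)
cells <- generate_cells(cfg)
eff <- generate_effect_records(cfg)
manure <- generate_manure_records(cfg)

readr::write_csv(cells, "results/synthetic/cells.csv")
readr::write_csv(eff$records, "results/synthetic/effect_records.csv")
readr::write_csv(eff$truth, "results/synthetic/effect_truth.csv")
readr::write_csv(manure, "results/synthetic/manure_regions.csv")

cat(sprintf("cells: %d rows, %.0f kha total (target 1,416,912 kha)\n",
            nrow(cells), sum(cells$area_ha) / 1000))
cat(sprintf("effect records: %d across %d intervention-climate cells\n",
            nrow(eff$records), nrow(eff$truth)))
cat(sprintf("manure: %d regions, %.1f Tg N excreted, %.1f Tg N surplus\n",
            nrow(manure), sum(manure$n_excreted) / 1e9,
            sum(manure$n_excreted - manure$n_applied_cropland -
                  manure$n_applied_grassland) / 1e9))
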