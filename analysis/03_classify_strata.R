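#!/usr/bin/env Rscript
# Classify cropland cells into management-climate strata (fertilization
# class at 40/100 kg N/ha, manure class at 40 kg N/ha) and report the
# area composition and the area eligible for each measure.

suppressPackageStartupMessages(library(socpotential))

cells <- read_cropland_cells("results/synthetic/cells.csv")
strata <- aggregate_strata(classify_cells(cells))
shares <- summarize_shares(strata)

readr::write_csv(strata, "results/strata.csv")
jsonlite::write_json(split(shares[, c("level", "share")], shares$dimension),
                     "results/shares.json", dataframe = "rows", digits = NA)

cat(sprintf("%d strata from %d cells; area conserved: %s\n",
            nrow(strata), nrow(cells),
            isTRUE(all.equal(sum(strata$area_ha), sum(cells$area_ha)))))
for (dim in unique(shares$dimension)) {
  s <- shares[shares$dimension == dim, ]
  cat(sprintf("  %s: %s\n", dim,
              paste(sprintf("%s %.0f%%", s$level, 100 * s$share),
                    collapse = ", ")))
}
elig <- dplyr::bind_rows(lapply(soc_measures, function(m) {
  dplyr::mutate(eligible_area(strata, m), measure = m, .before = 1)
}))
readr::write_csv(elig, "results/eligible_areas.csv")
tot <- tapply(elig$area_ha, elig$measure, sum) / 1e6
cat("eligible area (Mha): ",
    paste(sprintf("%s %.0f", names(tot), tot), collapse = ", "), "\n")
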