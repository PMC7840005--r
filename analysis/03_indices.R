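#!/usr/bin/env Rscript
# Step 3 — NAD(P)-originated physiological indices.
#
# Computes ARC, CRC, the NADK phosphorylation-capacity proxies, dormancy
# depth, reducing power and all reduced/oxidized ratios per sample from
# the quantified concentrations.

library(redoxgerm)

records <- read_concentrations("results/quantified")
indices <- couple_ratios(records)
dir.create("results", showWarnings = FALSE)
utils::write.csv(indices, "results/indices.csv", row.names = FALSE)

cat("Wrote", nrow(indices), "index records to results/indices.csv\n\n")
cat("Reducing power by species (mean over all samples):\n")
print(round(tapply(indices$reducing_power, indices$species, mean), 3))
cat("\nDormancy depth (NAD/NADP pool ratio) by species:\n")
print(round(tapply(indices$dormancy_depth, indices$species, mean), 2))
cat("\nShare of samples with DHA-dominated ascorbate pool (AsA/DHA < 1):\n")
print(round(tapply(indices$dha_dominated, indices$species, mean), 2))
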