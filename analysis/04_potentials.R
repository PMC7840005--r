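#!/usr/bin/env Rscript
# Step 4 — half-cell reduction potentials.
#
# Converts per-mass amounts to molar concentrations through each sample's
# water content and evaluates the Nernst potentials of the GSSG/2GSH
# (2-electron, GSH-squared stoichiometry) and DHA/AsA couples at pH 7,
# 298.15 K.

library(redoxgerm)

records <- read_concentrations("results/quantified")
potentials <- sample_potentials(records)
utils::write.csv(potentials, "results/potentials.csv", row.names = FALSE)

cat("Wrote", nrow(potentials), "rows to results/potentials.csv\n\n")
agg <- aggregate(cbind(e_gssg_2gsh_mv, e_dha_asa_mv) ~ species + tissue,
                 data = potentials, FUN = function(x) round(mean(x), 1))
print(agg)
cat("\nMore negative E_GSSG/2GSH = more reduced glutathione pool;",
    "embryonic axes should sit below cotyledons.\n")
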