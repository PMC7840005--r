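#!/usr/bin/env Rscript
# Step 5 — statistical layer.
#
# One-way ANOVA over germination stages with Tukey HSD compact letter
# displays per variable and series (and the joint tissue x stage
# grouping), plus the four masked Pearson correlation matrices (one per
# species x tissue), with proportion-type variables arcsine-transformed.

library(redoxgerm)

records <- read_concentrations("results/quantified")
report <- run_full_report(records, alpha = 0.05)
write_report(report, "results/report")

cat("Report written under results/report/\n\n")
cat("Example letter display — NADH across stages, sycamore embryonic axis:\n")
print(report$anova_details[["sycamore|embryonic axis|stages_within_tissue|nadh"]])

cat("\nCorrelation highlights, sycamore embryonic axis:\n")
cr <- report$correlations[["sycamore / embryonic axis"]]
for (pair in list(c("nadph", "asa"), c("nadh", "gsh"),
                  c("e_gssg_2gsh_mv", "nadph"))) {
  cat(sprintf("  r(%s, %s) = %+.2f%s\n", pair[1], pair[2],
              cr$r[pair[1], pair[2]],
              ifelse(isTRUE(cr$mask[pair[1], pair[2]]),
                     " (not significant)", "")))
}
cat("\nLetter displays are consistent with their Tukey p-matrices by",
    "construction; see results/report/anova_letters.csv\n")
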