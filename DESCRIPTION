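Package: redoxgerm
Title: Redox Couple Quantification and NAD(P) Physiological Indices for
    Germinating Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for seed redox physiology: quantification of
    NAD(H), NADP(H), ascorbate and glutathione redox couples from
    plate-reader assay readouts via linear calibration curves; computation
    of NAD(P)-originated physiological indices (anabolic and catabolic
    redox charge, NAD kinase phosphorylation capacity, dormancy depth,
    reducing power) and half-cell reduction potentials of the glutathione
    and ascorbate couples via the Nernst equation; one-way ANOVA with
    Tukey HSD compact letter displays and masked Pearson correlation
    matrices. Includes a synthetic-data generator emulating a two-species,
    two-tissue, multi-stage germination study design so the whole pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
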