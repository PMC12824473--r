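#!/usr/bin/env Rscript
# Generate the synthetic study cohort: ten liver-cancer-like lines with
# triplicate viability curves over the 0-20 MBq/mL activity ladder, a
# 500-gene baseline count matrix with 5 phenotype-linked genes planted, and
# three-class marker signatures. Ground truth goes to truth.json so every
# later stage can be checked against it.

library(y90profiler)

seed <- 1L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_cohort(seed = seed)

write_viability_csv(cohort$viability, file.path(out, "viability.csv"))
write_expression_tsv(cohort$expression$counts,
                     file.path(out, "expression_counts.tsv"))
write_gmt(cohort$signatures$signature, file.path(out, "signature.gmt"))
jsonlite::write_json(
  list(true_nauc = as.list(cohort$true_nauc),
       planted_genes = cohort$expression$planted$gene,
       planted_signs = cohort$expression$planted$sign,
       true_labels = as.list(cohort$signatures$labels), seed = seed),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cat("Simulated", length(unique(cohort$viability$cell_line)), "lines,",
    nrow(cohort$expression$counts), "genes,",
    nrow(cohort$expression$planted), "planted phenotype genes.\n")
cat("True nAUC range:",
    paste(round(range(cohort$true_nauc), 3), collapse = " - "), "\n")
cat("Wrote inputs + truth to", out, "\n")
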