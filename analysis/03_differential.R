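#!/usr/bin/env Rscript
# Differential expression on the filtered, imputed matrix: per-protein
# Welch t-test, Cohen's effect size (fold change over pooled SD), DEP
# calling at p < 0.05 and |d| > 2, then the parametric |LFC| outlier
# cutoff (mean + 2 SD over the called DEPs).

library(dephub)

ds <- read_abundance_matrix("results/matrix_imputed.tsv",
                            "results/metadata_imputed.tsv")
rec <- classify_deps(dep_statistics(ds))
write.table(rec, "results/dep_records.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(volcano_table(rec), "results/volcano.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n <- table(rec$direction)
cat("DEP calling on", nrow(rec), "proteins:",
    n[["up"]], "up,", n[["down"]], "down,", n[["ns"]], "unchanged\n")
deps <- rec[rec$direction != "ns", ]
cat("Up-regulated fold changes run", round(min(deps$fc[deps$direction == "up"]), 2),
    "to", round(max(deps$fc[deps$direction == "up"]), 2), "log units\n")

out <- detect_outliers(rec)
jsonlite::write_json(out, "results/outliers.json", auto_unbox = TRUE,
                     digits = 10)
cat("\n|LFC| outlier cutoff:", round(out$cutoff, 3), "->",
    length(out$outliers_up), "up /", length(out$outliers_down),
    "down outliers\n")
if (length(c(out$outliers_up, out$outliers_down)) > 0)
  cat("  ", paste(c(out$outliers_up, out$outliers_down), collapse = ", "),
      "\n")
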