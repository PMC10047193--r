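#!/usr/bin/env Rscript
# Generate the synthetic two-group DIA-style proteome study used by every
# downstream analysis script: 5000 proteins x (6 control + 6 case)
# replicates on a log-abundance scale, with planted differential proteins
# (|d| between 2 and 5, a few extreme outliers), sparse MCAR missingness,
# ten group-exclusive proteins per group, a planted-hub PPI network,
# direction-enriched ontology annotations and a gene-disease table.

library(dephub)

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 7321L

params <- sim_params(seed = seed, frac_dep = 0.03,
                     effect_size_range = c(2, 5))
sim <- generate_abundance_dataset(params)
write_abundance_matrix(sim$dataset, file.path(out, "matrix.tsv"),
                       file.path(out, "metadata.tsv"))

net <- generate_ppi_network(n_background = 40, n_hubs = 3, clique_size = 4,
                            seed = seed)
edges <- igraph::as_data_frame(net$network)
write.table(data.frame(node_a = edges$from, node_b = edges$to,
                       score = round(edges$score, 4)),
            file.path(out, "network.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

ann <- generate_annotation_table(
  sim$dataset$protein_ids,
  up_ids = names(sim$truth$planted_d)[sim$truth$planted_d > 0],
  down_ids = names(sim$truth$planted_d)[sim$truth$planted_d < 0],
  enrichment_factor = 5, seed = seed)
write.table(ann, file.path(out, "annotations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

dis <- generate_disease_table(sim$truth$dep_ids, n_high = 10, seed = seed)
write.table(dis$records, file.path(out, "disease.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- sim$truth
truth$params <- unclass(truth$params)
truth$network_hubs <- net$truth$hub_ids
truth$high_score_genes <- dis$truth$high_score_genes
truth$enriched_categories <- attr(ann, "enriched")
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = 10)

cat("Simulated study written to", out, "\n")
cat("  proteins:", nrow(sim$dataset$values),
    " planted DEPs:", length(sim$truth$dep_ids),
    " (", length(sim$truth$outlier_ids), "extreme )",
    " exclusive per group: 10\n")
cat("  network:", igraph::vcount(net$network), "nodes,",
    igraph::ecount(net$network), "edges, planted hubs:",
    paste(net$truth$hub_ids, collapse = ", "), "\n")
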