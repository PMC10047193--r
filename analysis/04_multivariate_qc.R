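#!/usr/bin/env Rscript
# Sample-level quality control on the imputed matrix: Euclidean distances,
# Pearson correlation heat-map values, complete-linkage dendrogram and
# k-means (k = 2) followed by PCA. With only ~3% of proteins carrying a
# group effect, the leading components are expected to explain little
# variance and the groups need not separate - the same behavior reported
# for real two-group brain proteomes of this design.

library(dephub)

ds <- read_abundance_matrix("results/matrix_imputed.tsv",
                            "results/metadata_imputed.tsv")
ord <- kmeans_pca(ds, k = 2, seed = 7321L)

write.table(round(ord$distance_matrix, 4), "results/sample_distance.tsv",
            sep = "\t", quote = FALSE)
write.table(round(ord$correlation_matrix, 6),
            "results/sample_correlation.tsv", sep = "\t", quote = FALSE)
write.table(data.frame(sample_id = rownames(ord$pc_scores),
                       round(ord$pc_scores, 4),
                       kmeans = ord$kmeans_labels,
                       group = ds$group_of),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("PC1 explains", round(100 * ord$explained_variance_fraction[1], 1),
    "%, PC2", round(100 * ord$explained_variance_fraction[2], 1),
    "% of total variance\n")
agree <- table(ord$kmeans_labels, ds$group_of)
cat("k-means vs group cross-table:\n"); print(agree)
cat("Sample correlations range",
    paste(round(range(ord$correlation_matrix[upper.tri(ord$correlation_matrix)]), 3),
          collapse = "-"), "\n")
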