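#!/usr/bin/env Rscript
# Normalization, PCA on the most variable genes, SNN-Louvain clustering
# across a resolution grid with silhouette-based selection, and marker-
# panel annotation of the resulting clusters.

library(miglia)

out <- file.path("results", "clustering")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

x <- load_counts(file.path("results", "qc", "filtered_counts"), "mtx", "unknown")
reg <- read.csv(file.path("results", "qc", "filtered_counts", "regions.csv"))
x <- count_matrix(miglia:::raw_counts(x), reg$region[match(colnames(x), reg$barcode)])
truth <- read.csv(file.path("results", "data", "truth.csv"))

x <- lognormalize(x)
hvg <- select_hvg(x, 5000)
emb <- pca_embed(x, hvg, n_components = 20)
graph <- build_knn_graph(emb, k = 20)
rs <- select_resolution(emb, graph, grid = seq(0.1, 1.5, by = 0.1), seed = 1)
ann <- score_marker_panels(x, rs$labels)

write.csv(rs$scan, file.path(out, "resolution_scan.csv"), row.names = FALSE)
write.csv(data.frame(barcode = colnames(x), cluster = rs$labels$labels),
          file.path(out, "cluster_labels.csv"), row.names = FALSE)
write.csv(ann$assignments, file.path(out, "annotation.csv"), row.names = FALSE)

# dot-plot statistics for the bundled panel genes, per annotated cluster
lab2name <- setNames(ann$assignments$label, ann$assignments$cluster)
panel_genes <- intersect(unlist(default_marker_panel()), rownames(x))
dots <- group_expression_summary(x, lab2name[as.character(rs$labels$labels)],
                                 panel_genes)
write.csv(dots, file.path(out, "marker_dotplot_stats.csv"), row.names = FALSE)

tr <- truth[match(colnames(x), truth$barcode), ]
ari <- adjusted_rand_index(rs$labels$labels[tr$artifact == "none"],
                           tr$cell_type[tr$artifact == "none"])
cat(sprintf("chosen resolution %.1f -> %d clusters (best silhouette %.3f)\n",
            rs$chosen_resolution, rs$labels$n_clusters,
            max(rs$scan$mean_silhouette)))
cat(sprintf("adjusted Rand index vs planted types (clean cells): %.3f\n", ari))
cat("cluster identities:",
    paste(sprintf("%d=%s", ann$assignments$cluster, ann$assignments$label),
          collapse = ", "), "\n")
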