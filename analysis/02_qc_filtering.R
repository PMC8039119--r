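#!/usr/bin/env Rscript
# Cell and gene quality control: knee selection on the barcode-rank curve,
# the 2-of-3 MAD rule applied separately per region, and the gene filter
# (>= 5 cells, no mito/ribo symbols). Reports how the planted artifacts
# fared against the ground truth.

library(miglia)

dat <- file.path("results", "data")
out <- file.path("results", "qc")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

x <- load_counts(file.path(dat, "counts"), "mtx", region_label = "unknown")
truth <- read.csv(file.path(dat, "truth.csv"))
# region labels live in the truth table (regions.csv carries the same info)
stopifnot(identical(colnames(x), truth$barcode))
x <- count_matrix(miglia:::raw_counts(x), truth$region)

sel <- knee_select(x)
cat(sprintf("knee selection: %d of %d barcodes kept\n", ncol(sel), ncol(x)))

res <- qc_filter(sel)
filtered <- gene_filter(res$matrix)
write.csv(res$qc, file.path(out, "qc_table.csv"), row.names = FALSE)
write_counts(filtered, file.path(out, "filtered_counts"))

tr <- truth[match(colnames(filtered), truth$barcode), ]
kept_tab <- table(factor(tr$artifact,
                         c("none", "empty", "high_mito", "contaminated")))
planted <- table(factor(truth$artifact,
                        c("none", "empty", "high_mito", "contaminated")))
cat(sprintf("cells after QC: %d (%d clean of %d); genes kept: %d\n",
            ncol(filtered), kept_tab[["none"]], planted[["none"]],
            nrow(filtered)))
for (cls in c("empty", "high_mito")) {
  cat(sprintf("planted %s removed: %d of %d (%.1f%%)\n", cls,
              planted[[cls]] - kept_tab[[cls]], planted[[cls]],
              100 * (planted[[cls]] - kept_tab[[cls]]) / planted[[cls]]))
}
cat("contaminated cells survive QC by design; they are handled in 04\n")
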