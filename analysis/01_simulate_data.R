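#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a midbrain/striatum droplet count
# matrix with four planted brain cell types, microglia sub-states, empty
# droplets, high-mito cells and oligodendrocyte-contaminated microglia,
# plus a skeleton cohort for the morphometric arm. Everything downstream
# reads from results/data/.

library(miglia)

seed <- 20260924L
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- brain_sim_spec(seed = seed)
sim <- simulate_dataset(spec)
write_counts(sim$matrix, file.path(out, "counts"))
write.csv(sim$truth, file.path(out, "truth.csv"), row.names = FALSE)

cat(sprintf("simulated %d barcodes x %d genes\n",
            ncol(sim$matrix), nrow(sim$matrix)))
print(table(sim$truth$artifact))

# morphometric arm: 12 cells per region, ramified cells in cortex-like
# tissue, progressively simpler ones toward the midbrain
skel_dir <- file.path(out, "skeletons")
dir.create(skel_dir, showWarnings = FALSE)
branch_by_region <- list(cortex = 7L, striatum = 5L, midbrain = 3L)
set.seed(seed)
manifest <- do.call(rbind, lapply(names(branch_by_region), function(rg) {
  data.frame(region = rg, cell = seq_len(12),
             branches = pmax(0L, branch_by_region[[rg]] +
                               sample(-1:1, 12, replace = TRUE)),
             seg_len = round(runif(12, 4, 8), 2))
}))
manifest$file <- sprintf("%s_cell%02d.swc", manifest$region, manifest$cell)
for (i in seq_len(nrow(manifest))) {
  s <- simulate_skeleton(manifest$branches[i], manifest$seg_len[i],
                         seed = seed + i)
  write_swc(s, file.path(skel_dir, manifest$file[i]))
}
write.csv(manifest, file.path(out, "skeleton_manifest.csv"), row.names = FALSE)
cat(sprintf("wrote %d skeletons (%d per region)\n", nrow(manifest), 12))
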