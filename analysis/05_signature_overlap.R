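#!/usr/bin/env Rscript
# Compare the data-derived sub-state signature with the planted
# inflammation program (shared genes and direction concordance), and show
# the 2^-dCT relative-expression computation on a small qPCR-style table.

library(miglia)

out <- file.path("results", "comparison")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

derived <- read_signature(file.path("results", "microglia",
                                    "substate_signature.tsv"),
                          name = "substate_de")

# the reference program the generator plants in immune-alerted microglia
planted_up <- c("Cd83", "Il1b", "Cd74", "Cd14", "Gpr84", "Socs3", "Ccl4",
                "Nfkbiz", "Icam1", "Fth1")
reference <- gene_signature("planted_inflammation", planted_up, 1,
                            source = "generator ground truth")

ov <- direction_concordance(derived, reference)
res <- data.frame(n_derived = ov$n_a, n_reference = ov$n_b,
                  n_shared = ov$n_shared,
                  pct_shared_of_derived = ov$pct_shared_of_a,
                  n_concordant = ov$n_concordant,
                  pct_concordant = ov$pct_concordant)
write.csv(res, file.path(out, "signature_overlap.csv"), row.names = FALSE)
cat(sprintf("shared: %d of %d derived genes (%.0f%%); concordant: %d of %d (%.0f%%)\n",
            ov$n_shared, ov$n_a, ov$pct_shared_of_a,
            ov$n_concordant, ov$n_shared, ov$pct_concordant))

# qPCR-style check of homeostatic markers: threshold cycles vs Gapdh
qpcr <- data.frame(
  gene = c("Cx3cr1", "Fcrls", "P2ry12"),
  ct_target = c(24.1, 26.3, 25.0),
  ct_gapdh = c(19.8, 19.8, 19.8))
qpcr$rel_expr <- relative_expression(qpcr$ct_target, qpcr$ct_gapdh)
write.csv(qpcr, file.path(out, "relative_expression.csv"), row.names = FALSE)
cat("2^-dCT relative expression:\n")
print(qpcr)
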