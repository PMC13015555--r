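#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume:
# a serology cohort, an adhesion-blocking plate, a TGF-beta reporter
# assay, a monoclonal standard curve, a treatment-structured expression
# matrix with marker gene sets, and a two-genotype swiss-roll spatial
# dataset with a planted mid-colon goblet expansion. Ground truth goes
# to results/data/truth/, analysis-facing tables to results/data/.

library(avb6suite)

seed <- 1L
out <- "results/data"
dir.create(file.path(out, "truth"), recursive = TRUE, showWarnings = FALSE)

sero <- simulate_serology(seed = seed)
write.csv(sero$measurements, file.path(out, "serology.csv"),
          row.names = FALSE)
write.csv(sero$truth, file.path(out, "truth", "serology_truth.csv"),
          row.names = FALSE)
message(sprintf("serology: %d subjects (%d UC, %d HS)",
                nrow(sero$measurements),
                sum(sero$measurements$group == "UC"),
                sum(sero$measurements$group == "HS")))

std <- simulate_standard_curve(noise_sd = 0.02, replicates = 3, seed = seed)
write.csv(std$standards, file.path(out, "standards.csv"), row.names = FALSE)

adh <- simulate_adhesion(seed = seed)
write.csv(adh$plate, file.path(out, "adhesion_plate.csv"), row.names = FALSE)
write.csv(adh$truth, file.path(out, "truth", "adhesion_truth.csv"),
          row.names = FALSE)
writeLines(adh$hs_samples, file.path(out, "adhesion_hs_samples.txt"))
message(sprintf("adhesion: %d serum samples, %d planted inhibitors",
                nrow(adh$truth), sum(adh$truth$true_inhibitor)))

rep_sim <- simulate_reporter(seed = seed)
write.csv(rep_sim$reporter, file.path(out, "reporter.csv"),
          row.names = FALSE)
writeLines(rep_sim$hs_samples, file.path(out, "reporter_hs_samples.txt"))

ex <- simulate_expression(seed = seed)
write.table(data.frame(gene = rownames(ex$mat), ex$mat,
                       check.names = FALSE),
            file.path(out, "expression.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.csv(ex$samples, file.path(out, "samples.csv"), row.names = FALSE)
write_gmt(ex$gene_sets, file.path(out, "marker_sets.gmt"))
message(sprintf("expression: %d genes x %d samples, %d marker sets",
                nrow(ex$mat), ncol(ex$mat), length(ex$gene_sets)))

sw <- simulate_swiss_roll(seed = seed)
write.csv(sw$cells, file.path(out, "swissroll_cells.csv"),
          row.names = FALSE)
write.csv(sw$counts, file.path(out, "swissroll_counts.csv"),
          row.names = FALSE)
write.csv(sw$truth, file.path(out, "truth", "swissroll_truth.csv"),
          row.names = FALSE)
message(sprintf("swiss roll: %d cells across %d samples",
                nrow(sw$cells), length(unique(sw$cells$sample_id))))
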