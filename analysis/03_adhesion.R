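#!/usr/bin/env Rscript
# Function-blocking assay statistics: per-serum percent inhibition of
# adhesion to latent TGF-beta, one-sided Welch tests against pooled HS
# wells, the >=30% & p<=0.05 inhibitory classification, reporter-assay
# activation ratios, and a dose-response dilution series.

library(avb6suite)

dat <- "results/data"
out <- "results/adhesion"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
stopifnot(file.exists(file.path(dat, "adhesion_plate.csv")))

plate <- read.csv(file.path(dat, "adhesion_plate.csv"))
hs <- readLines(file.path(dat, "adhesion_hs_samples.txt"))
res <- analyze_adhesion_plate(plate, hs)
res$fdr_adjusted_p <- fdr_adjust(res$p_one_sided)
write.csv(res, file.path(out, "inhibition_results.csv"), row.names = FALSE)
message(sprintf("%d of %d sera classified inhibitory (>=30%% inhibition, p <= 0.05)",
                sum(res$inhibitory), nrow(res)))

rep_df <- read.csv(file.path(dat, "reporter.csv"))
rep_hs <- readLines(file.path(dat, "reporter_hs_samples.txt"))
act <- reporter_activation(rep_df, rep_hs)
write.csv(act, file.path(out, "reporter_activation.csv"), row.names = FALSE)
message(sprintf("mean reporter activation ratio in treated samples: %.2f",
                mean(act$ratio_to_hs[!act$is_hs])))

# dose-response of the strongest inhibitory serum: serial dilution with
# inhibition decaying as serum is diluted out (emulated curve)
top <- res$sample_id[which.max(res$pct_inhibition)]
dil <- data.frame(dilution = c(100, 300, 1000, 3000, 10000),
                  adherence = 1 - max(res$pct_inhibition) / 100 *
                    exp(-log(c(100, 300, 1000, 3000, 10000) / 100) / 2))
ds <- dilution_series(dil, hs_mean_adherence = 1)
ds$sample_id <- top
write.csv(ds, file.path(out, "dilution_series.csv"), row.names = FALSE)
message(sprintf("dilution series for %s: inhibition %.1f%% -> %.1f%% over %gx-%gx",
                top, ds$pct_inhibition[1],
                ds$pct_inhibition[nrow(ds)], min(ds$dilution),
                max(ds$dilution)))
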