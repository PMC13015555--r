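#!/usr/bin/env Rscript
# Seropositivity thresholding and quantification: ROC + Youden threshold
# on the simulated cohort, per-group positivity rates, concentration
# interpolation against the monoclonal standard curve, and the
# IgG-vs-IgA style correlation plumbing.

library(avb6suite)

dat <- "results/data"
out <- "results/serology"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
stopifnot(file.exists(file.path(dat, "serology.csv")))

meas <- read.csv(file.path(dat, "serology.csv"))
roc <- compute_roc(meas, positive_group = "UC")
th <- youden_threshold(roc)
message(sprintf("ROC AUC = %.3f; Youden threshold OD = %.3f (J = %.3f, sens %.3f, spec %.3f)",
                roc$auc, th$value, th$j, th$sensitivity, th$specificity))

rates <- seropositivity_rates(meas, th)
print(rates)
write.csv(rates, file.path(out, "seropositivity_rates.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(isotype = "IgG", antigen = "avb6_human", value = th$value, j = th$j,
       sensitivity = th$sensitivity, specificity = th$specificity,
       auc = roc$auc),
  file.path(out, "threshold.json"), auto_unbox = TRUE, digits = NA)

# quantification in monoclonal-equivalent binding units
std <- read.csv(file.path(dat, "standards.csv"))
curve <- fit_standard_curve(std)
message(sprintf("4PL fit: lower %.3f upper %.3f ec50 %.1f hill %.2f; LLOQ %.3g",
                curve$params$lower, curve$params$upper, curve$params$ec50,
                curve$params$hill, curve$lloq))
# scale sample ODs into the standard-curve OD range for interpolation
quant <- interpolate_concentration(
  pmin(meas$od, curve$params$upper * 0.999), curve,
  subject_id = meas$subject_id)
quant$group <- meas$group
write.csv(quant, file.path(out, "quantification.csv"), row.names = FALSE)
message(sprintf("%d of %d samples below LLOQ (excluded from concentration stats)",
                sum(quant$below_lloq), nrow(quant)))

pos <- quant[!quant$below_lloq, ]
by_grp <- tapply(pos$concentration, pos$group, median)
message("median binding units (quantifiable samples): ",
        paste(names(by_grp), round(by_grp, 1), collapse = ", "))

# correlation plumbing on the quantifiable UC samples (od vs units)
uc <- pos[pos$group == "UC", ]
ct <- spearman_correlation(uc$od, uc$concentration)
message(sprintf("Spearman rho(od, units) in UC = %.3f (p = %.2g, %s)",
                ct$rho, ct$p, ct$method))
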