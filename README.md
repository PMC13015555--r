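# avb6suite

Quantitative pipeline for studies of anti-αvβ6 integrin autoantibodies
in ulcerative colitis (UC). Autoantibodies against αvβ6 — the
epithelial integrin that activates latent TGF-β — are a highly specific
UC biomarker that can precede diagnosis by years, and function-blocking
antibodies inhibit epithelial TGF-β activation. Studying them requires
four kinds of computation, all implemented here as a tested R package:

1. **Serology** — ROC analysis of background-corrected ELISA ODs with
   Youden-index thresholds (J = sensitivity + specificity − 1,
   positivity at od ≥ threshold), per-group seropositivity rates, and
   quantification in monoclonal-equivalent binding units by inverting a
   four-parameter logistic standard curve, with LLOQ flagging.
2. **Blocking-assay statistics** — percent inhibition
   (1 − x̄<sub>sample</sub>/x̄<sub>HS</sub>) × 100, one-sided Welch
   tests of each serum against pooled healthy-subject wells, and the
   inhibitory classification (≥ 30% inhibition and p ≤ 0.05,
   boundaries inclusive); reporter-assay activation ratios and
   dose-response dilution series.
3. **Epithelial lineage signatures** — gene-wise Z-scores across
   samples and per-sample mean-Z scores over curated marker sets
   (absorptive, goblet, stem, ...), plus a rank-based stand-in scorer,
   with group means per treatment arm.
4. **Digital unrolling** — fits an Archimedean spiral r = a + bθ to
   swiss-roll colon cell coordinates, maps every cell to a colon-length
   position s ∈ [0, 1] (proximal → distal, distal end innermost, per
   the rolling protocol) and a crypt–lumen depth d ∈ [0, 1], assigns
   proximal/mid/distal regions, and compares goblet-cluster composition
   between genotypes along the colon with bootstrap CIs.

A seeded synthetic-data module (`simulate_*`) emulates every input with
known ground truth, so the whole pipeline runs with no download and
every claim in the test suite is checked against generator truth. See
`vignettes/methods.Rmd` for the full methods account.

## Worked example

```r
library(avb6suite)

# --- serology: threshold a simulated 194 UC / 338 HS cohort ---------
sero <- simulate_serology(seed = 1)
roc  <- compute_roc(sero$measurements, positive_group = "UC")
th   <- youden_threshold(roc)
roc$auc                     # 0.895
th$value; th$j              # OD 0.273, J = 0.771
seropositivity_rates(sero$measurements, th)
#>   group n_positive   n percent
#> 1    UC        172 194    88.7
#> 2    HS         39 338    11.5

# --- adhesion: classify 29 sera against pooled HS wells -------------
adh <- simulate_adhesion(seed = 1)      # 10 planted inhibitors
res <- analyze_adhesion_plate(adh$plate, adh$hs_samples)
sum(res$inhibitory)                     # 10 of 29

# --- unroll a two-genotype swiss roll and test the mid-colon effect -
sw  <- simulate_swiss_roll(seed = 1)    # 2-fold mid-colon GC expansion
un  <- unroll_samples(sw$cells)         # per-sample spiral fits
cmp <- compare_composition(un, n_bins = 3, B = 1000, seed = 1)
subset(cmp, bin == 2 & cluster == "gc_canonical_mid",
       c(log2_ratio, ci_lo, ci_hi))
#>   log2_ratio ci_lo ci_hi
#>        1.11  0.84  1.42
```

The numbers mean: the simulated cohort separates UC from HS with AUC
0.895 and an OD cutoff of 0.273, calling 88.7% of UC and 11.5% of HS
seropositive; 10 of 29 sera meet the printed inhibitory rule; and the
planted 2-fold knockout expansion of the mid-colon canonical goblet
cluster is recovered as a mid-bin log2 frequency ratio of ≈ 1 whose
bootstrap CI excludes 0.

## Analysis workflow

The `analysis/` scripts run the pipeline end to end on the synthetic
datasets and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # all five synthetic inputs
Rscript analysis/02_serology.R        # ROC/Youden, rates, 4PL quantification
Rscript analysis/03_adhesion.R        # inhibition calls, reporter, dilutions
Rscript analysis/04_signatures.R      # mean-Z and rank signature scores
Rscript analysis/05_spatial_unroll.R  # spiral fits, composition, maps
```

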