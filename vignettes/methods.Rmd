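---
title: "Methods: autoantibody serology, blocking-assay statistics, lineage signatures, and digital unrolling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autoantibody serology, blocking-assay statistics, lineage signatures, and digital unrolling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avb6suite)
```

# Scope

`avb6suite` implements the quantitative backbone of studies of
anti-αvβ6 integrin autoantibodies in ulcerative colitis (UC): ELISA
seropositivity thresholding and quantification, statistics for
TGF-β-blocking adhesion and reporter assays, per-sample epithelial
lineage signature scores for treatment-structured expression matrices,
and digital unrolling of swiss-roll colon spatial transcriptomics into
colon-length × crypt–lumen coordinates with goblet-cell composition
profiles. A seeded synthetic-data module emulates every input with
known ground truth, so the full pipeline — and every guarantee the test
suite makes — runs without any external download.

This vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and the limits of what the synthetic
data can demonstrate.

# Serology

## ROC, Youden threshold, and positivity

An OD readout (450 nm, background-corrected at 650 nm) per subject is
thresholded into seropositive/seronegative calls. `compute_roc()` scans
every observed OD plus a below-minimum and an above-maximum sentinel as
candidate cutoffs, with the positivity rule **od ≥ threshold**
(boundary positive — this makes the dashed-threshold convention of
serology dot plots deterministic). The AUC is the trapezoid over
(FPR, TPR), which equals the probability that a random positive OD
exceeds a random negative one with ties counted ½; the test suite
checks this identity against explicit pair enumeration on every random
cohort it draws.

`youden_threshold()` maximizes J = sensitivity + specificity − 1 by
exhaustive scan. Ties are broken toward the **lowest** threshold: for a
screening biomarker the tie should favor sensitivity, and the rule is
deterministic. Reported percentages round **half away from zero** to
one decimal (so 173/194 → 89.2, 35/338 → 10.4); base R's
round-half-even would report some of these differently.

## Quantification against monoclonal standards

Antibody levels are expressed in monoclonal-equivalent binding units by
inverting a four-parameter logistic (4PL) standard curve

$$OD(c) = lower + \frac{upper - lower}{1 + (ec_{50}/c)^{hill}},$$

fitted by Levenberg–Marquardt least squares (`minpack.lm`). Choices
worth stating:

* **LLOQ rule.** The assay's lower limit of quantification is the
  lowest standard concentration whose fitted OD exceeds blank mean +
  3·blank SD; without blank wells it falls back to the lowest standard.
  Samples below LLOQ carry `below_lloq = TRUE` with the concentration
  absent — they are flagged and excluded from concentration statistics,
  never imputed.
* **Above-range ODs.** The inverse 4PL is undefined at or above the
  upper asymptote; such samples are clamped to the top of the fitted
  range and flagged `above_range` rather than extrapolated.
* **Monotonicity guard.** Standards whose mean ODs are not rank-monotone
  in concentration (Spearman < 0.9) are rejected before fitting.

## Correlation and multiplicity

`spearman_correlation()` uses mid-ranks. For n ≤ 10 without ties the
two-sided p comes from the exact null distribution of the rank
statistic (the classical exact Spearman test); otherwise the
t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ is used. Full
enumeration of permutations was rejected on cost grounds (10! null
statistics per call); the exact-distribution route gives the same exact
small-n p where it is defined.

`fdr_adjust()` is the adaptive two-stage linear step-up (Benjamini–
Krieger–Yekutieli): a first BH pass at α′ = α/(1+α) estimates the
number of true nulls m₀, and BH-adjusted values are rescaled by
m₀/m·(1+α). The adjusted values are calibrated to the chosen α
(default 0.05) — a consequence is that even a single p-value is scaled
by 1+α, which the reference implementation in `statsmodels`
(`fdr_tsbky`) reproduces exactly and the test suite asserts.

# Adhesion and reporter assays

Percent inhibition is the printed blocking statistic

$$\left(1 - \frac{\bar{x}_{sample}}{\bar{x}_{HS}}\right)\times 100,$$

scale-invariant in the adherence units and negative when a serum
*increases* adhesion. A serum is **inhibitory** when percent inhibition
≥ 30 *and* the one-sided Welch p ≤ 0.05, boundaries inclusive, exactly
as printed. The one-sided alternative is fixed as "sample adherence
below the HS mean": a blocking antibody can only reduce
integrin-mediated adhesion, so the direction is not a free choice. The
HS reference pools all healthy-subject serum wells on the same plate
(same-plate pooling controls batch effects); the replicate unit is the
well, the finest observable unit.

At ≤ 3 wells per arm the Welch t-approximation is used knowingly: an
exhaustive permutation p at six total replicates can only take values
on a grid of 1/20, so the two quantities can differ by up to ~0.05 for
null sera and more for strong inhibitors whose Welch p is far below the
permutation floor. The classifier is protected against this
small-sample optimism by the 30% effect-size gate: on synthetic cohorts
with null sera the false-call rate is far below the nominal 5% (the
acceptance suite measures it at 0 of 500).

Reporter assays (SEAP OD620) are summarized per sample as the ratio to
the mean reporter activity across HS control samples, the dotted-line
convention of reporter dot plots. Dilution series report percent
inhibition per dilution and flag non-monotone curves (inhibition rising
with dilution fold beyond 5 percentage points) without erroring —
plate noise produces benign violations.

# Epithelial lineage signatures

Expression input is log2(normalized counts + 1); genes are filtered to
those exceeding 1 (log2 scale) in ≥ 20% of samples (both thresholds are
arguments). `zscore_genes()` standardizes each gene across samples with
the **n−1** SD — the safer small-n convention, and stated so tests can
be exact; zero-variance genes become all-zero rows and are flagged, not
dropped. The signature score of a marker set is the per-sample mean of
marker-gene Z-scores; markers absent from the matrix are dropped and
counted in `n_genes_used`, never imputed.

Because the Z denominator pools *all* samples, a planted shift of +1
noise-SD in one of two arms is recovered as a mean-Z difference of
$1/\sqrt{1 + \mathrm{var(arm\ means)}} \approx 0.894$, not 1.0 — the
between-arm variance inflates the per-gene SD. The tests assert the
analytic value, and users comparing effect sizes across designs should
expect the same compression. Direction, the quantity of scientific
interest here (suppression under TGF-β, induction under αvβ6 blockade,
stem programs opposite), is recovered in ≥ 95% of simulations at
effects ≥ 1 SD with 3 samples per arm.

`signature_score_rank()` is a clearly-labelled rank-based stand-in for
single-sample enrichment scoring: mean within-sample marker rank,
centred and rescaled to [−1, 1], invariant under any within-sample
monotone transform. It is *not* an implementation of any published
enrichment method; it exists so both a location-based and a rank-based
scorer are available on the same interface.

# Digital unrolling of swiss-roll colons

A colon opened longitudinally and rolled distal-to-proximal sits in a
section as a near-Archimedean spiral; the package's unrolling operates
entirely on segmented **cell coordinates** (one defensible definition —
the original procedure could equally be run on images or a traced
centerline, which is out of scope here).

## Model and fitting

The centerline is $r = a + b\theta$ with center $(c_x, c_y)$, $b > 0$
in µm/rad. Fitting proceeds in stages, all on the raw (x, y) µm
coordinates:

1. **Turn spacing.** Narrow angular wedges (0.3 rad) around four
   reference directions are scanned for ring structure; the median
   center-to-center ring spacing estimates $2\pi b$. Fewer than two
   rings anywhere (a circle, a blob, less than one turn) is an error —
   this is also the degeneracy guard for $b \approx 0$.
2. **Phase concentration.** The fractional radial phase
   $f = (r - b\varphi) \bmod 2\pi b$ is constant on a true spiral, so
   its circular resultant length is maximized over center, b and the
   winding direction. This objective needs no turn assignment, is
   smooth in the center, and cleanly separates the two winding
   directions. Because it has a lattice of local maxima one turn apart,
   it is seeded by a coarse grid over center offsets within ±0.6 turn.
3. **Alternating least squares.** With a reliable center, each point's
   turn index is $k = \mathrm{round}((r - a - b\varphi)/2\pi b)$,
   giving a monotone unwrapped θ; (a, b) are refit by linear least
   squares of r on θ until the assignment stabilizes, with a final
   simplex polish of the center against the residual sum of squares.
4. **Mid-band refinement.** The least-squares line tracks the
   cell-density mean, which drifts wherever the cluster mix (hence the
   typical crypt depth) varies along the colon. (a, b) are therefore
   re-anchored to the *geometric* mid-band: the midpoint between the
   2.5% and 97.5% residual quantiles per 0.5-rad window, regressed on
   window center. This removes a composition-driven bias of several
   percent in a.
5. **Half-thickness and orientation.** Local tissue half-thickness per
   window is half the 2.5–97.5% residual spread (robust to outlier
   cells). Which radial side is luminal is inferred from the side
   *opposite* a declared anchor cluster — smooth muscle, which lies
   serosal — and can be overridden (`luminal = "inner"/"outer"`).

## Coordinates

Arc length uses the closed form
$L = \frac{b}{2}\left(u\sqrt{1+u^2} + \mathrm{asinh}\,u\right)$,
$u = \theta + a/b$ (the quadrature-free route; tests pin it against
adaptive quadrature to 0.1%). The colon-length coordinate s ∈ [0, 1] is
normalized arc length oriented proximal → distal; because rolling
starts at the distal end, the **distal end is the inner terminus** by
default (a flag flips this). The crypt–lumen coordinate is
$d = 0.5 + \mathrm{sign} \cdot \Delta r / 2h(\theta)$, clipped to
[0, 1]; cells beyond ±0.1 outside the band are flagged `out_of_band`,
and cells outside the fitted angular range are flagged and excluded
from composition profiles.

Regions default to arc-length terciles with half-open bins — s = 1/3 is
mid, s = 2/3 is distal — because "proximal, mid, distal" are named
anatomically but not delimited; boundaries are arguments. Each sample
gets its own spiral fit and normalization before genotypes are pooled,
since section geometry is sample-specific.

## Composition comparison

Per colon-length bin, cluster frequencies normalize to 1 within
(genotype, bin). The knockout-vs-control effect per cluster is
$\log_2((f_{ko}+\varepsilon)/(f_{ctrl}+\varepsilon))$ with
ε = 1/(cells in the bin pair), with a seeded cell-resampling bootstrap
(equivalently multinomial count redraws, B = 1000) for percentile CIs.
Note a compositional fact the tests also encode: a 2-fold *density*
expansion of a cluster with baseline share f₀ yields an asymptotic
frequency log-ratio of $\log_2\frac{2}{1+f_0} < 1$ — about 0.94 at the
default f₀ ≈ 4% — because the expanded cluster dilutes its own bin.

# The synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and seed
(bit-identical reruns; the caller's RNG stream is untouched), and truth
objects flow only into tests, never into analysis.

* **Serology** (defaults: 194 UC / 338 HS; positive fractions 0.892 /
  0.115, the reported clinical rates): log-normal OD mixtures — ODs are
  positive and right-skewed. The distribution parameters are declared
  generator choices, not claims about the study data.
* **Adhesion** (defaults: 29 test sera, 10 planted inhibitors at
  adherence ratio 0.5, CV 10%, triplicate wells): normal replicate
  noise truncated at zero around a 1000-cell baseline.
* **Expression**: per-gene N(5, 1.5) log2 baselines, unit noise,
  marker-set effects in SD units with the suppression/induction sign
  pattern (TGF-β negative on goblet/absorptive, blockade positive, stem
  opposite).
* **Swiss roll** (defaults: 60 mm colon, a = 800 µm, b = 120 µm/rad ≈
  4 turns, half-thickness 250 µm, 200 cells/mm per genotype ≈ 24,000
  cells total, radial jitter SD 20 µm): seven clusters with
  anatomically-motivated s/d ranges — smooth muscle serosal along the
  whole length, intercrypt goblet cells at the distal luminal surface,
  one canonical goblet cluster confined to the mid colon and expanded
  2-fold in the knockout. Sizes were chosen so the full pipeline and
  test suite run in minutes on one CPU.

What passing tests therefore show: the estimators recover *their own
generative model* — an ideal Archimedean roll with radially-Gaussian
placement noise, uniform-in-range cluster geometry, and independent
log-normal/normal assay noise. What they do not show: robustness to
torn or folded sections, non-constant roll tightness, segmentation
artifacts correlated along crypts, plate-position effects, or
antigen-specific assay interference. Real sections that deviate from a
single smooth spiral should be fit per intact fragment, and the
`out_of_band`/`in_range` flags inspected before composition profiles
are trusted.

# Known limitations

* The unrolling assumes one connected spiral per sample; it has no
  notion of tissue tears (each `sample_id` must be one roll).
* Half-thickness from residual quantiles under-covers slightly when the
  crypt–lumen axis is unevenly populated; depth estimates near the band
  edges inherit that few-percent scale error.
* The Welch p at ≤ 3 replicates per arm is an approximation whose
  distance from the exact permutation p is bounded below by the
  permutation grid (see above); inference at that depth should lean on
  the effect-size gate, as the printed classification rule does.
* Signature scores are mean-Z over pooled samples: effect magnitudes
  compress as between-arm variance grows, so scores are comparable
  within one design, not across designs.
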