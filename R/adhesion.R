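#' Normalize adherent counts to untreated controls
#'
#' Each well's adherent count is divided by the mean of the plate's
#' untreated wells, so untreated wells average exactly 1.
#'
#' @param plate data.frame with columns `condition` and `adherent`
#'   (and usually `plate_id`, `well_id`, `sample_id`).
#' @param untreated label of the untreated-control condition.
#' @return the plate with an added `norm_adherence` column.
#' @export
normalize_adherence <- function(plate, untreated = "untreated") {
  stopifnot(is.data.frame(plate),
            all(c("condition", "adherent") %in% names(plate)))
  untr <- plate$adherent[plate$condition == untreated]
  if (length(untr) == 0L) stop("no untreated wells on plate")
  m <- mean(untr)
  if (!is.finite(m) || m <= 0) stop("untreated mean adherence must be > 0")
  plate$norm_adherence <- plate$adherent / m
  plate
}

#' Percent inhibition of adhesion
#'
#' The function-blocking statistic
#' \deqn{(1 - \frac{\bar{x}_{sample}}{\bar{x}_{HS}}) \times 100}
#' comparing a serum sample's mean adherence to the healthy-subject mean.
#' Negative values (adherence above the HS mean) are allowed; 100 is full
#' inhibition. Scale-invariant in the adherence units.
#'
#' @param sample_mean_adherence,hs_mean_adherence scalar means.
#' @return percent inhibition.
#' @export
percent_inhibition <- function(sample_mean_adherence, hs_mean_adherence) {
  stopifnot(is.finite(sample_mean_adherence), is.finite(hs_mean_adherence))
  if (hs_mean_adherence <= 0) stop("HS mean adherence must be > 0")
  (1 - sample_mean_adherence / hs_mean_adherence) * 100
}

#' One-sided Welch's t test for adhesion inhibition
#'
#' Tests whether a sample's replicate adherence is below the healthy-
#' subject replicates (alternative fixed as sample mean < HS mean, since
#' a blocking antibody can only reduce adhesion). Welch t with
#' Satterthwaite degrees of freedom.
#'
#' Degenerate case: when both arms have zero variance and equal means the
#' test is uninformative and returns p = 0.5 with a warning; with unequal
#' means it returns 0 or 1 by direction.
#'
#' @param sample_reps,hs_reps numeric replicate vectors, >= 2 each.
#' @return list with `p` (one-sided), `t`, `df`, `n_sample`, `n_hs`.
#' @export
welch_one_sided <- function(sample_reps, hs_reps) {
  stop_if_not_finite(sample_reps, "sample replicate")
  stop_if_not_finite(hs_reps, "HS replicate")
  n1 <- length(sample_reps); n2 <- length(hs_reps)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 replicates per arm")
  v1 <- stats::var(sample_reps); v2 <- stats::var(hs_reps)
  if (v1 == 0 && v2 == 0) {
    d <- mean(sample_reps) - mean(hs_reps)
    if (d == 0) {
      warning("zero variance in both arms with equal means; p = 0.5")
      return(list(p = 0.5, t = 0, df = NA_real_, n_sample = n1, n_hs = n2))
    }
    return(list(p = if (d < 0) 0 else 1, t = -sign(d) * Inf, df = NA_real_,
                n_sample = n1, n_hs = n2))
  }
  tt <- stats::t.test(sample_reps, hs_reps, alternative = "less",
                      var.equal = FALSE)
  list(p = unname(tt$p.value), t = unname(tt$statistic),
       df = unname(tt$parameter), n_sample = n1, n_hs = n2)
}

#' Classify a serum sample as inhibitory
#'
#' The printed rule, boundaries inclusive: inhibitory iff percent
#' inhibition >= 30 and one-sided p <= 0.05. Monotone in both arguments.
#'
#' @param pct percent inhibition.
#' @param p one-sided p-value.
#' @param min_inhibition,alpha classification boundaries.
#' @return logical.
#' @export
classify_inhibitory <- function(pct, p, min_inhibition = 30, alpha = 0.05) {
  stopifnot(is.finite(pct), is.finite(p))
  pct >= min_inhibition && p <= alpha
}

#' Per-sample inhibition analysis of an adhesion plate
#'
#' Pools all healthy-subject serum wells on the plate as the reference,
#' then for each non-HS serum sample computes percent inhibition of the
#' well means, the one-sided Welch p against the pooled HS wells, and the
#' inhibitory classification.
#'
#' @param plate data.frame with columns `condition`, `sample_id`,
#'   `adherent`; serum wells have `condition == "serum"`.
#' @param hs_samples character vector of `sample_id`s that are HS controls.
#' @param min_inhibition,alpha classification boundaries.
#' @return data.frame, one row per non-HS sample: `sample_id`,
#'   `pct_inhibition`, `p_one_sided`, `inhibitory`, `n_sample`, `n_hs`.
#' @export
analyze_adhesion_plate <- function(plate, hs_samples,
                                   min_inhibition = 30, alpha = 0.05) {
  stopifnot(is.data.frame(plate),
            all(c("condition", "sample_id", "adherent") %in% names(plate)))
  serum <- plate[plate$condition == "serum", , drop = FALSE]
  hs <- serum$adherent[serum$sample_id %in% hs_samples]
  if (length(hs) < 2L) stop("need >= 2 pooled HS serum wells")
  ids <- setdiff(unique(serum$sample_id), hs_samples)
  rows <- lapply(ids, function(id) {
    reps <- serum$adherent[serum$sample_id == id]
    pct <- percent_inhibition(mean(reps), mean(hs))
    wt <- welch_one_sided(reps, hs)
    data.frame(sample_id = id, pct_inhibition = pct, p_one_sided = wt$p,
               inhibitory = classify_inhibitory(pct, wt$p, min_inhibition,
                                                alpha),
               n_sample = wt$n_sample, n_hs = wt$n_hs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' TGF-beta reporter activation relative to HS controls
#'
#' Summarizes SEAP reporter readout (OD620) per sample and expresses it as
#' a ratio to the mean reporter activity across HS control samples (the
#' dotted-line convention of reporter dot plots). HS sample ratios average
#' to 1 by construction.
#'
#' @param reporter data.frame with columns `sample_id` and `od620`.
#' @param hs_samples character vector of HS control `sample_id`s.
#' @return data.frame: `sample_id`, `mean_od620`, `ratio_to_hs`, `is_hs`.
#' @export
reporter_activation <- function(reporter, hs_samples) {
  stopifnot(is.data.frame(reporter),
            all(c("sample_id", "od620") %in% names(reporter)))
  stop_if_not_finite(reporter$od620, "OD620")
  ids <- unique(reporter$sample_id)
  means <- vapply(ids, function(id)
    mean(reporter$od620[reporter$sample_id == id]), numeric(1))
  is_hs <- ids %in% hs_samples
  if (!any(is_hs)) stop("no HS control samples present")
  hs_mean <- mean(means[is_hs])
  if (hs_mean <= 0) stop("HS mean reporter activity must be > 0")
  data.frame(sample_id = ids, mean_od620 = unname(means),
             ratio_to_hs = unname(means) / hs_mean, is_hs = is_hs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dose-response inhibition across a serum dilution series
#'
#' Computes percent inhibition at each dilution of a serum sample against
#' a fixed HS reference adherence, as in titration experiments on
#' immunized-mouse serum. A monotonicity violation beyond `tolerance`
#' percentage points (inhibition increasing with dilution fold) is
#' flagged, not an error.
#'
#' @param series data.frame with columns `dilution` (fold, unique) and
#'   `adherence` (mean adherence at that dilution); optionally `sample_id`.
#' @param hs_mean_adherence HS reference mean adherence.
#' @param tolerance allowed non-monotonicity in percentage points.
#' @return data.frame sorted by increasing dilution fold with
#'   `pct_inhibition` per dilution and attribute `monotone_flag`.
#' @export
dilution_series <- function(series, hs_mean_adherence, tolerance = 5) {
  stopifnot(is.data.frame(series),
            all(c("dilution", "adherence") %in% names(series)))
  if (anyDuplicated(series$dilution)) stop("duplicate dilutions in series")
  if (nrow(series) < 3L) stop("need >= 3 dilutions")
  out <- series[order(series$dilution), , drop = FALSE]
  out$pct_inhibition <- vapply(out$adherence, percent_inhibition,
                               numeric(1), hs_mean_adherence)
  # higher dilution fold = more dilute serum = inhibition should not rise
  viol <- any(diff(out$pct_inhibition) > tolerance)
  attr(out, "monotone_flag") <- viol
  out
}
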