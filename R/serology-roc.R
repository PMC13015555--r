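#' ROC curve for seropositivity thresholding
#'
#' Computes the receiver-operating-characteristic curve of a background-
#' corrected OD readout for discriminating a positive group (typically UC)
#' from a negative group (typically healthy subjects, HS). Candidate
#' thresholds are the observed OD values plus sentinels below the minimum
#' and above the maximum, so that the all-positive and all-negative
#' operating points are always represented. At a threshold t a sample is
#' called positive when od >= t (see [classify_seropositive()]).
#'
#' The AUC is computed by trapezoidal integration over (FPR, TPR) and
#' equals the pairwise-comparison probability that a random positive OD
#' exceeds a random negative OD, ties counted 1/2.
#'
#' @param measurements data.frame with at least columns `od` (numeric)
#'   and `group` (character/factor). A single isotype/antigen at a time.
#' @param positive_group value of `group` treated as the disease class.
#' @return object of class `roc_curve`: list with `thresholds`, `tpr`,
#'   `fpr` (per threshold, thresholds increasing), `auc`, `positive_group`,
#'   `n_pos`, `n_neg`.
#' @export
compute_roc <- function(measurements, positive_group = "UC") {
  stopifnot(is.data.frame(measurements),
            all(c("od", "group") %in% names(measurements)))
  od <- measurements$od
  grp <- as.character(measurements$group)
  stop_if_not_finite(od, "OD")
  pos <- od[grp == positive_group]
  neg <- od[grp != positive_group]
  if (length(pos) == 0L) {
    stop(sprintf("no measurements in positive group '%s'", positive_group),
         call. = FALSE)
  }
  if (length(neg) == 0L) {
    stop("no measurements in the negative (comparison) group", call. = FALSE)
  }
  obs <- sort(unique(od))
  # sentinels: below min (everything positive) and above max (nothing positive)
  eps <- max(1e-8, diff(range(obs, finite = TRUE)) * 1e-6)
  thresholds <- c(obs[1] - eps, obs, obs[length(obs)] + eps)
  tpr <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(neg >= t), numeric(1))
  # trapezoid over the ROC polygon; points ordered by increasing threshold,
  # i.e. decreasing (fpr, tpr)
  auc <- -sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc,
         positive_group = positive_group,
         n_pos = length(pos), n_neg = length(neg)),
    class = "roc_curve"
  )
}

#' Optimal seropositivity threshold by Youden's index
#'
#' Scans every candidate threshold of a [compute_roc()] curve and returns
#' the one maximizing Youden's J = sensitivity + specificity - 1. Ties are
#' broken toward the lowest threshold, which maximizes sensitivity -- the
#' conservative choice for a screening biomarker.
#'
#' @param roc a `roc_curve` object.
#' @return object of class `sero_threshold`: list with `value`, `j`,
#'   `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$tpr - roc$fpr
  if (all(abs(j) < 1e-12)) {
    warning("all thresholds have Youden J = 0; groups are indistinguishable")
  }
  jmax <- max(j)
  i <- which(j >= jmax - 1e-12)[1L]  # lowest threshold among ties
  structure(
    list(value = roc$thresholds[i], j = j[i],
         sensitivity = roc$tpr[i], specificity = 1 - roc$fpr[i]),
    class = "sero_threshold"
  )
}

#' Classify samples as seropositive
#'
#' Boundary-inclusive rule: a sample is positive when od >= threshold,
#' mirroring the dashed-threshold-line convention of serology dot plots.
#'
#' @param od numeric vector of background-corrected ODs.
#' @param threshold a `sero_threshold` object or a numeric cutoff.
#' @return logical vector.
#' @export
classify_seropositive <- function(od, threshold) {
  stop_if_not_finite(od, "OD")
  cut <- if (inherits(threshold, "sero_threshold")) threshold$value else threshold
  stopifnot(is.numeric(cut), length(cut) == 1L, is.finite(cut))
  od >= cut
}

#' Per-group seropositivity rates
#'
#' Counts positives per group at a fixed threshold and reports percentages
#' rounded half away from zero to one decimal place (so 173/194 reports
#' as 89.2).
#'
#' @param measurements data.frame with `od` and `group` columns.
#' @param threshold a `sero_threshold` or numeric cutoff.
#' @param groups group levels to report; defaults to those observed. A
#'   requested group with no measurements gets an n = 0 row with
#'   `percent = NA`.
#' @return data.frame with columns `group`, `n_positive`, `n`, `percent`
#'   (NA for empty groups).
#' @export
seropositivity_rates <- function(measurements, threshold, groups = NULL) {
  stopifnot(is.data.frame(measurements),
            all(c("od", "group") %in% names(measurements)))
  pos <- classify_seropositive(measurements$od, threshold)
  grp <- as.character(measurements$group)
  if (is.null(groups)) groups <- unique(grp)
  out <- data.frame(
    group = groups,
    n_positive = vapply(groups, function(g) sum(pos[grp == g]), integer(1)),
    n = vapply(groups, function(g) sum(grp == g), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$percent <- ifelse(out$n > 0L,
                        round_half_away(100 * out$n_positive / out$n, 1L),
                        NA_real_)
  out
}
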