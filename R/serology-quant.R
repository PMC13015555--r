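#' Fit a four-parameter logistic monoclonal standard curve
#'
#' Antibody concentration is quantified against a dilution series of a
#' monoclonal anti-integrin antibody. The OD-vs-concentration relation is
#' modelled with the 4PL
#' \deqn{OD(c) = lower + \frac{upper - lower}{1 + (ec50/c)^{hill}}}
#' fitted by Levenberg-Marquardt least squares. `hill > 0` gives a curve
#' increasing in concentration; `ec50` is the inflection concentration.
#'
#' The lower limit of quantification (LLOQ) is the lowest standard
#' concentration whose fitted OD exceeds `blank mean + 3 * blank SD`; with
#' no blanks supplied the LLOQ is the lowest standard concentration.
#'
#' @param standards data.frame with columns `concentration` (> 0) and `od`;
#'   replicate rows allowed. At least 5 distinct concentrations spanning
#'   at least two orders of magnitude.
#' @param blanks optional numeric vector of blank-well ODs used to set the
#'   LLOQ.
#' @return object of class `standard_curve`: list with `params`
#'   (lower, upper, ec50, hill), `fit_range` (min/max standard
#'   concentration), `lloq`, and the `fitted` model object.
#' @export
fit_standard_curve <- function(standards, blanks = NULL) {
  stopifnot(is.data.frame(standards),
            all(c("concentration", "od") %in% names(standards)))
  conc <- standards$concentration
  od <- standards$od
  stopifnot(all(conc > 0))
  stop_if_not_finite(od, "OD")
  u <- sort(unique(conc))
  if (length(u) < 5L) stop("need >= 5 distinct standard concentrations")
  if (log10(max(u) / min(u)) < 2) {
    stop("standards must span at least two orders of magnitude")
  }
  mean_od <- vapply(split(od, conc), mean, numeric(1))[as.character(u)]
  if (diff(range(od)) < 1e-9) stop("flat standard curve: all ODs equal")
  # monotonicity check beyond noise: rank correlation of mean OD with conc
  if (stats::cor(mean_od, u, method = "spearman") < 0.9) {
    stop("standards are not monotone in concentration beyond noise tolerance")
  }
  start <- list(lower = min(od), upper = max(od),
                ec50 = exp(stats::approx(mean_od, log(u),
                                         xout = mean(range(mean_od)),
                                         rule = 2, ties = mean)$y),
                hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      od ~ lower + (upper - lower) / (1 + (ec50 / conc)^hill),
      data = data.frame(conc = conc, od = od),
      start = start,
      lower = c(lower = -Inf, upper = -Inf, ec50 = min(u) / 100, hill = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      stop(sprintf("4PL fit failed to converge: %s; OD range [%.3g, %.3g]",
                   conditionMessage(e), min(od), max(od)), call. = FALSE)
    }
  )
  p <- as.list(stats::coef(fit))
  if (p$upper <= p$lower) {
    stop("fitted curve is not increasing (upper asymptote <= lower)")
  }
  lloq <- min(u)
  if (!is.null(blanks) && length(blanks) >= 2L) {
    floor_od <- mean(blanks) + 3 * stats::sd(blanks)
    ok <- fpl_forward(u, p) > floor_od
    if (any(ok)) lloq <- min(u[ok]) else lloq <- max(u)
  }
  structure(
    list(params = p, fit_range = range(u), lloq = lloq, fitted = fit),
    class = "standard_curve"
  )
}

# forward 4PL evaluation
fpl_forward <- function(conc, params) {
  with(params, lower + (upper - lower) / (1 + (ec50 / conc)^hill))
}

# inverse 4PL; NA outside the open OD range (lower, upper)
fpl_inverse <- function(od, params) {
  with(params, {
    frac <- (upper - lower) / (od - lower) - 1
    out <- rep(NA_real_, length(od))
    ok <- is.finite(frac) & frac > 0 & od > lower & od < upper
    out[ok] <- ec50 * frac[ok]^(-1 / hill)
    out
  })
}

#' Interpolate antibody concentration from OD
#'
#' Inverse-4PL evaluation against a fitted [fit_standard_curve()].
#' ODs mapping below the LLOQ are flagged `below_lloq` with the
#' concentration absent; such samples are excluded from concentration-based
#' statistics downstream. ODs at or above the fitted OD of the maximum
#' standard are clamped to the top of the fit range and flagged
#' `above_range` rather than extrapolated (the inverse 4PL is undefined
#' above the upper asymptote).
#'
#' @param od numeric vector of sample ODs.
#' @param curve a `standard_curve`.
#' @param subject_id optional ids carried into the output.
#' @return data.frame with columns `subject_id`, `od`, `concentration`
#'   (NA when below LLOQ), `below_lloq`, `above_range`.
#' @export
interpolate_concentration <- function(od, curve, subject_id = NULL) {
  stopifnot(inherits(curve, "standard_curve"))
  stop_if_not_finite(od, "OD")
  if (is.null(subject_id)) subject_id <- as.character(seq_along(od))
  p <- curve$params
  od_lloq <- fpl_forward(curve$lloq, p)
  od_top <- fpl_forward(curve$fit_range[2], p)
  conc <- fpl_inverse(od, p)
  below <- od < od_lloq
  above <- od >= od_top
  conc[above] <- curve$fit_range[2]
  conc[below] <- NA_real_
  data.frame(subject_id = subject_id, od = od, concentration = conc,
             below_lloq = below, above_range = above,
             stringsAsFactors = FALSE)
}
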