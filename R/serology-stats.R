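#' Spearman rank correlation with small-sample exact p
#'
#' rho is computed from mid-ranked values. The two-sided p-value uses the
#' exact null distribution of the rank statistic for n <= 10 when there
#' are no ties (as in \code{cor.test(..., exact = TRUE)}), and the
#' t-approximation \eqn{t = rho \sqrt{(n-2)/(1-rho^2)}} otherwise.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `rho`, `p`, `n`, and `method` ("exact" or "t").
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop("non-finite values in x or y")
  n <- length(x)
  if (n < 3L) stop("need n >= 3 pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate"))
  }
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 10L && !ties) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = TRUE))
    list(rho = rho, p = ct$p.value, n = n, method = "exact")
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    list(rho = rho, p = min(p, 1), n = n, method = "t")
  }
}

#' Two-stage step-up FDR adjustment (Benjamini-Krieger-Yekutieli)
#'
#' The adaptive two-stage linear step-up procedure: a first BH pass at
#' level alpha' = alpha/(1+alpha) estimates the number of true nulls
#' m0 = m - r1, then BH-adjusted p-values are rescaled by m0/m and by
#' (1+alpha). Rejection at the original `alpha` corresponds to
#' `adjusted <= alpha`. Order-preserving within ranks; values capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param alpha FDR level the adjustment is calibrated to (default 0.05).
#' @return adjusted p-values, same order as input.
#' @export
fdr_adjust <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  bh <- stats::p.adjust(p, method = "BH")
  r1 <- sum(bh <= alpha / (1 + alpha))
  adj <- if (r1 == 0L || r1 == m) bh * (1 + alpha) else
    bh * (m - r1) / m * (1 + alpha)
  pmin(adj, 1)
}
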