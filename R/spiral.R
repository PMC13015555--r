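# Archimedean spiral model for swiss-roll colon sections.
#
# A whole colon opened longitudinally and rolled distal-to-proximal sits
# in a section as a near-Archimedean spiral r = a + b*theta of roughly
# constant tissue thickness. The model carries everything needed to map a
# cell's (x, y) back to (colon length, crypt-lumen depth): the spiral
# center, (a, b), the angular range covered by tissue, a per-angle local
# half-thickness, which radial side of the centerline is luminal, and
# which spiral end is distal.

#' Construct a spiral model
#'
#' Usually produced by [fit_spiral()]; constructing one directly is useful
#' for simulations and for unrolling with known geometry.
#'
#' @param center numeric (cx, cy) in the section's micrometer coordinates.
#' @param a,b Archimedean parameters of r = a + b*theta (a in um, b in
#'   um/rad, b > 0; theta increases outward).
#' @param theta_range angular range (rad) covered by tissue, length 2.
#' @param half_thickness local tissue half-thickness in um: a scalar or a
#'   function of theta.
#' @param luminal which radial side of the centerline is the luminal
#'   surface: `"inner"` or `"outer"`.
#' @param distal which spiral terminus is the distal colon end:
#'   `"inner"` (the default; rolling starts distally, so the distal end
#'   winds up innermost) or `"outer"`.
#' @param flip TRUE when the spiral winds clockwise in (x, y), i.e.
#'   angles are measured as -atan2.
#' @return object of class `spiral_model`.
#' @export
spiral_model <- function(center, a, b, theta_range,
                         half_thickness,
                         luminal = c("inner", "outer"),
                         distal = c("inner", "outer"),
                         flip = FALSE) {
  luminal <- match.arg(luminal)
  distal <- match.arg(distal)
  stopifnot(length(center) == 2L, is.finite(a), is.finite(b), b > 0,
            length(theta_range) == 2L, diff(theta_range) > 0)
  if (diff(theta_range) < 2 * pi) {
    stop("spiral must cover at least one full turn")
  }
  hfun <- if (is.function(half_thickness)) half_thickness else {
    stopifnot(half_thickness > 0)
    local({h <- half_thickness; function(theta) rep(h, length(theta))})
  }
  structure(
    list(center = as.numeric(center), a = a, b = b,
         theta_range = as.numeric(theta_range),
         half_thickness_fn = hfun,
         luminal = luminal,
         luminal_sign = if (luminal == "outer") 1 else -1,
         distal = distal, flip = isTRUE(flip)),
    class = "spiral_model"
  )
}

#' Arc length along an Archimedean spiral
#'
#' Closed-form cumulative arc length of r = a + b*theta from
#' `theta_from`, using
#' L = (b/2) (u sqrt(1+u^2) + asinh u) with u = theta + a/b.
#'
#' @param spiral a `spiral_model` (or any list with `a`, `b`).
#' @param theta angles (rad).
#' @param theta_from lower limit (defaults to the model's range start).
#' @return arc length in um, vectorized over `theta`.
#' @export
arc_length <- function(spiral, theta, theta_from = spiral$theta_range[1]) {
  a <- spiral$a; b <- spiral$b
  g <- function(th) {
    u <- th + a / b
    u * sqrt(1 + u^2) + asinh(u)
  }
  (b / 2) * (g(theta) - g(theta_from))
}

# Solve arc_length(spiral, theta) = L for theta (vectorized): monotone
# interpolation on a fine grid followed by two Newton steps.
invert_arc_length <- function(spiral, L) {
  th <- seq(spiral$theta_range[1], spiral$theta_range[2], length.out = 4096L)
  Lg <- arc_length(spiral, th)
  theta <- stats::approx(Lg, th, xout = L, rule = 2, ties = "ordered")$y
  for (i in 1:2) {
    r <- spiral$a + spiral$b * theta
    theta <- theta - (arc_length(spiral, theta) - L) / sqrt(r^2 + spiral$b^2)
  }
  theta
}

# Angle of each point around the spiral center, unwrapped to a monotone
# theta using the Archimedean structure: the turn index k is recovered
# from the radial distance as round((r - a - b*phi) / (2*pi*b)).
point_theta <- function(spiral, x, y) {
  dx <- x - spiral$center[1]; dy <- y - spiral$center[2]
  if (spiral$flip) dy <- -dy
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx) %% (2 * pi)
  k <- round((r - spiral$a - spiral$b * phi) / (2 * pi * spiral$b))
  list(theta = phi + 2 * pi * k, r = r)
}

# Initial estimate of the inter-turn radial spacing 2*pi*b from ring
# structure in narrow angular wedges. Returns NA when fewer than two
# rings are found anywhere (circle, blob, or < 1 turn).
estimate_turn_spacing <- function(r, phi, wedge = 0.3) {
  spacings <- c()
  for (phi0 in c(0, pi / 2, pi, 3 * pi / 2)) {
    dphi <- abs((phi - phi0 + pi) %% (2 * pi) - pi)
    rw <- sort(r[dphi < wedge])
    if (length(rw) < 10L) next
    gaps <- diff(rw)
    span <- max(rw) - min(rw)
    if (span <= 0) next
    big <- which(gaps > pmax(5 * stats::median(gaps), 0.05 * span))
    if (length(big) < 1L) next
    # ring centers = means of the segments between big gaps
    idx <- cbind(c(1L, big + 1L), c(big, length(rw)))
    centers <- apply(idx, 1L, function(ii) mean(rw[ii[1]:ii[2]]))
    if (length(centers) >= 2L) spacings <- c(spacings, diff(sort(centers)))
  }
  if (length(spacings) == 0L) return(NA_real_)
  stats::median(spacings)
}

# Circular concentration (resultant length) of the fractional radial
# phase f = (r - b*phi) mod 2*pi*b at a candidate (center, b, winding).
# On the correct spiral, r - b*phi is constant modulo one turn, so the
# phase concentrates; the statistic needs no turn assignment and is
# smooth in the center, making it a robust pre-refinement objective.
phase_concentration <- function(x, y, center, b, flip = FALSE) {
  dx <- x - center[1]; dy <- y - center[2]
  if (flip) dy <- -dy
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  ang <- (r - b * phi) / b  # phase in radians of the turn cycle
  if (!all(is.finite(ang))) return(0)
  sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
}

# Refine center and b by maximizing phase concentration, trying both
# winding directions. The concentration surface has a lattice of local
# maxima one turn apart in the center coordinates, so each direction is
# seeded by a coarse grid search over center offsets within +/- 0.6 turn
# of the centroid before the simplex polish.
# Returns list(center, b, flip, concentration).
refine_center_by_phase <- function(x, y, center0, b0) {
  period <- 2 * pi * b0
  offs <- seq(-0.6, 0.6, by = 0.15) * period
  best <- NULL
  for (flip in c(FALSE, TRUE)) {
    start <- center0
    sbest <- -Inf
    for (ox in offs) for (oy in offs) {
      cen <- center0 + c(ox, oy)
      v <- phase_concentration(x, y, cen, b0, flip = flip)
      if (v > sbest) { sbest <- v; start <- cen }
    }
    obj <- function(par) {
      b <- exp(par[3])
      # keep b near the ring-spacing estimate; far-off b is meaningless
      if (!is.finite(b) || b < b0 / 3 || b > 3 * b0) return(1)
      -phase_concentration(x, y, par[1:2], b, flip = flip)
    }
    opt <- stats::optim(c(start, log(b0)), obj, method = "Nelder-Mead",
                        control = list(maxit = 400L, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) {
      best <- list(center = opt$par[1:2], b = exp(opt$par[3]),
                   flip = flip, value = opt$value)
    }
  }
  best$concentration <- -best$value
  best
}

# Initial intercept (mod one turn) for turn-index assignment: the
# fractional radial phase f = (r - b*phi) / (2*pi*b) mod 1 concentrates
# in a band (the tissue) leaving an empty circular gap between turns;
# the band center, converted back to radius units, centers the rounding
# so no point is assigned to the wrong turn.
estimate_a0 <- function(r, phi, b0) {
  period <- 2 * pi * b0
  f <- sort(((r - b0 * phi) %% period) / period)
  gaps <- diff(c(f, f[1] + 1))
  i <- which.max(gaps)
  gap_mid <- (f[i] + gaps[i] / 2) %% 1
  band_center <- (gap_mid + 0.5) %% 1
  band_center * period
}

# Alternating least squares for (a, b) at a fixed center: assign turn
# indices, refit r ~ theta, repeat until the assignment is stable.
fit_ab_at_center <- function(x, y, center, b0, flip = FALSE,
                             max_iter = 25L) {
  dx <- x - center[1]; dy <- y - center[2]
  if (flip) dy <- -dy
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx) %% (2 * pi)
  a <- estimate_a0(r, phi, b0); b <- b0
  k_old <- NULL
  for (i in seq_len(max_iter)) {
    k <- round((r - a - b * phi) / (2 * pi * b))
    theta <- phi + 2 * pi * k
    vt <- stats::var(theta)
    if (!is.finite(vt) || vt == 0) return(NULL)
    b_new <- stats::cov(theta, r) / vt
    if (!is.finite(b_new) || b_new <= 0) return(NULL)
    a_new <- mean(r) - b_new * mean(theta)
    a <- a_new; b <- b_new
    if (!is.null(k_old) && identical(k, k_old)) break
    k_old <- k
  }
  resid <- r - (a + b * theta)
  list(a = a, b = b, theta = theta, resid = resid, ssr = sum(resid^2))
}

#' Fit an Archimedean spiral to a swiss-roll cell table
#'
#' Recovers the spiral centerline from cell coordinates alone. The center
#' is initialized at the point centroid and refined by Nelder-Mead least
#' squares; at each candidate center, per-point angles are unwrapped to a
#' monotone theta via turn-index assignment and (a, b) are fit by linear
#' least squares of radius on angle. The local tissue half-thickness is
#' estimated per angular window as half the 2.5-97.5% spread of radial
#' residuals. Which radial side is luminal is inferred from the side
#' opposite an anchor cluster (smooth muscle lies serosal, i.e. on the
#' crypt-base side) unless given explicitly.
#'
#' @param cells data.frame with columns `x`, `y` (um); optionally
#'   `cluster` for anchor-based orientation.
#' @param anchor_cluster cluster label marking the serosal (outer-tissue)
#'   side; used only when `luminal` is NULL.
#' @param luminal `"inner"` or `"outer"` to set orientation explicitly.
#' @param distal which spiral end is distal (default `"inner"`, per the
#'   distal-to-proximal rolling protocol).
#' @param window angular window (rad) for half-thickness estimation.
#' @return a `spiral_model` with fit diagnostics in attributes
#'   (`resid_sd`, `n_points`).
#' @export
fit_spiral <- function(cells, anchor_cluster = "smooth_muscle",
                       luminal = NULL, distal = "inner", window = 0.5) {
  stopifnot(is.data.frame(cells), all(c("x", "y") %in% names(cells)))
  x <- cells$x; y <- cells$y
  stop_if_not_finite(x, "x"); stop_if_not_finite(y, "y")
  n <- length(x)
  if (n < 50L) stop("too few cells to fit a spiral")
  center0 <- c(mean(x), mean(y))
  dx <- x - center0[1]; dy <- y - center0[2]
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx) %% (2 * pi)
  spacing <- estimate_turn_spacing(r, phi)
  if (!is.finite(spacing) || spacing <= 0) {
    stop(paste("points do not form a multi-turn spiral",
               "(fewer than one full turn, or degenerate b ~ 0)"))
  }
  b0 <- spacing / (2 * pi)
  # stage 1: assignment-free center/b/winding refinement by phase
  # concentration, then alternating least squares with turn assignment,
  # then a final center polish against the least-squares objective
  ph <- refine_center_by_phase(x, y, center0, b0)
  obj <- function(cen) {
    f <- fit_ab_at_center(x, y, cen, ph$b, flip = ph$flip, max_iter = 8L)
    if (is.null(f)) return(1e30)
    f$ssr
  }
  opt <- stats::optim(ph$center, obj, method = "Nelder-Mead",
                      control = list(maxit = 200L, reltol = 1e-10))
  fit <- fit_ab_at_center(x, y, opt$par, ph$b, flip = ph$flip)
  if (is.null(fit)) stop("spiral fit failed")
  best <- list(center = opt$par, fit = fit, flip = ph$flip)
  span <- diff(range(fit$theta))
  if (span < 2 * pi) stop("points cover less than one full turn")
  resid_sd <- stats::sd(fit$resid)
  if (2 * pi * fit$b < 2 * resid_sd) {
    stop("degenerate spiral: turn spacing is below the radial noise (b ~ 0)")
  }
  # refine (a, b) against the geometric mid-band: the least-squares line
  # tracks the cell-density mean, which drifts when the cluster mix (and
  # so the typical crypt-lumen depth) varies along the colon; the
  # midpoint between the 2.5% and 97.5% residual quantiles per angular
  # window tracks the tissue band itself and is robust to composition
  th_range <- range(fit$theta)
  centers <- seq(th_range[1] + window / 2, th_range[2] - window / 2,
                 by = window / 2)
  if (length(centers) < 2L) centers <- mean(th_range)
  band <- vapply(centers, function(cc) {
    inw <- abs(fit$theta - cc) <= window / 2
    if (sum(inw) < 20L) return(c(NA_real_, NA_real_))
    q <- stats::quantile(fit$resid[inw], c(0.025, 0.975), names = FALSE)
    c((q[1] + q[2]) / 2, (q[2] - q[1]) / 2)
  }, numeric(2))
  mids <- band[1, ]
  okm <- is.finite(mids)
  if (sum(okm) >= 3L) {
    mid_fit <- stats::lm.fit(cbind(1, centers[okm]), mids[okm])
    fit$a <- fit$a + mid_fit$coefficients[[1]]
    fit$b <- fit$b + mid_fit$coefficients[[2]]
    fit$resid <- fit$resid - (mid_fit$coefficients[[1]] +
                                mid_fit$coefficients[[2]] * fit$theta)
  }
  hvals <- vapply(centers, function(cc) {
    inw <- abs(fit$theta - cc) <= window / 2
    if (sum(inw) < 20L) return(NA_real_)
    q <- stats::quantile(fit$resid[inw], c(0.025, 0.975), names = FALSE)
    (q[2] - q[1]) / 2
  }, numeric(1))
  if (all(is.na(hvals))) {
    hvals <- rep((stats::quantile(fit$resid, 0.975) -
                    stats::quantile(fit$resid, 0.025)) / 2, length(centers))
  }
  ok <- is.finite(hvals) & hvals > 0
  if (!any(ok)) {
    # degenerate band (e.g. points exactly on the centerline): fall back
    # to a tiny positive thickness so d is defined (all cells at d = 0.5)
    hvals <- rep(max(resid_sd, 1e-6), length(centers))
    ok <- rep(TRUE, length(centers))
  }
  hfun <- if (sum(ok) == 1L) {
    local({h <- hvals[ok]; function(theta) rep(h, length(theta))})
  } else {
    stats::approxfun(centers[ok], hvals[ok], rule = 2, ties = mean)
  }
  # orientation: anchor cluster sits serosal (crypt-base side); luminal is
  # the opposite radial side of the centerline
  if (is.null(luminal)) {
    if (!("cluster" %in% names(cells)) ||
        !any(cells$cluster == anchor_cluster)) {
      stop(sprintf(paste("cannot infer luminal side: anchor cluster '%s'",
                         "not present; pass luminal = 'inner' or 'outer'"),
                   anchor_cluster))
    }
    med_anchor <- stats::median(fit$resid[cells$cluster == anchor_cluster])
    luminal <- if (med_anchor > 0) "inner" else "outer"
  }
  sp <- spiral_model(center = best$center, a = fit$a, b = fit$b,
                     theta_range = th_range, half_thickness = hfun,
                     luminal = luminal, distal = distal, flip = best$flip)
  attr(sp, "resid_sd") <- resid_sd
  attr(sp, "n_points") <- n
  sp
}
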