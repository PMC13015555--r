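#' Digitally unroll swiss-roll cells to colon-length and crypt-lumen axes
#'
#' Maps each cell's section coordinates onto a fitted spiral: the
#' unwrapped angle gives the cumulative arc length along the roll, which
#' is normalized into a colon-length position s in [0, 1] oriented
#' proximal -> distal (with the distal end at the inner terminus under
#' the distal-to-proximal rolling protocol). The radial residual from
#' the spiral centerline, scaled by the local half-thickness, gives the
#' crypt-lumen position d in [0, 1] with 0 = crypt base and 1 = luminal
#' surface. d is clipped to [0, 1]; cells far outside the tissue band
#' (raw d beyond [-0.1, 1.1]) are flagged `out_of_band`, and cells whose
#' angle falls outside the fitted angular range are flagged
#' `!in_range` and should be excluded from composition profiles.
#'
#' @param cells data.frame with `x`, `y` and any metadata columns
#'   (`cell_id`, `sample_id`, `genotype`, `cluster`), which are carried
#'   through.
#' @param spiral a `spiral_model` from [fit_spiral()] or [spiral_model()].
#' @param boundaries region boundaries on s for [assign_regions()].
#' @return data.frame: metadata columns plus `theta`, `residual`, `s`,
#'   `d`, `region`, `in_range`, `out_of_band`.
#' @export
unroll <- function(cells, spiral, boundaries = c(1 / 3, 2 / 3)) {
  stopifnot(inherits(spiral, "spiral_model"),
            is.data.frame(cells), all(c("x", "y") %in% names(cells)))
  pt <- point_theta(spiral, cells$x, cells$y)
  th <- pt$theta
  rng <- spiral$theta_range
  tol <- 0.25  # rad; slack at the termini before a cell is out of range
  in_range <- th >= rng[1] - tol & th <= rng[2] + tol
  th_cl <- pmin(pmax(th, rng[1]), rng[2])
  Ltot <- arc_length(spiral, rng[2])
  frac <- arc_length(spiral, th_cl) / Ltot   # 0 at inner terminus
  s <- if (spiral$distal == "inner") 1 - frac else frac
  resid <- pt$r - (spiral$a + spiral$b * th)
  h <- spiral$half_thickness_fn(th_cl)
  d_raw <- 0.5 + spiral$luminal_sign * resid / (2 * h)
  out <- cells[, setdiff(names(cells), c("x", "y")), drop = FALSE]
  out$theta <- th
  out$residual <- resid
  out$s <- pmin(pmax(s, 0), 1)
  out$d <- pmin(pmax(d_raw, 0), 1)
  out$region <- assign_regions(out$s, boundaries)
  out$in_range <- in_range
  out$out_of_band <- d_raw < -0.1 | d_raw > 1.1
  out
}

#' Fit and unroll every sample of a multi-sample cell table
#'
#' Section geometry is sample-specific, so each `sample_id` gets its own
#' spiral fit and its own arc-length normalization before pooling.
#'
#' @param cells data.frame with `x`, `y`, `sample_id` and metadata.
#' @param ... passed to [fit_spiral()].
#' @return data.frame of row-bound per-sample [unroll()] outputs, with
#'   the fitted models in attribute `spirals` (named by sample).
#' @export
unroll_samples <- function(cells, ...) {
  stopifnot("sample_id" %in% names(cells))
  ids <- unique(cells$sample_id)
  fits <- list()
  parts <- lapply(ids, function(id) {
    sub <- cells[cells$sample_id == id, , drop = FALSE]
    sp <- fit_spiral(sub, ...)
    fits[[id]] <<- sp
    unroll(sub, sp)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "spirals") <- fits
  out
}

#' Assign colon regions from normalized length
#'
#' Half-open bins on s: with the default tercile boundaries,
#' s in [0, 1/3) is proximal, [1/3, 2/3) mid, and [2/3, 1] distal.
#' A cell exactly at a boundary goes to the upper region.
#'
#' @param s normalized colon-length positions in [0, 1].
#' @param boundaries increasing interior boundaries in (0, 1).
#' @return factor with levels proximal, mid, distal (or `region1..k` for
#'   non-default boundary counts).
#' @export
assign_regions <- function(s, boundaries = c(1 / 3, 2 / 3)) {
  stopifnot(all(boundaries > 0), all(boundaries < 1),
            !is.unsorted(boundaries, strictly = TRUE))
  labs <- if (length(boundaries) == 2L) c("proximal", "mid", "distal") else
    paste0("region", seq_len(length(boundaries) + 1L))
  idx <- findInterval(s, boundaries) + 1L  # s >= boundary -> upper region
  factor(labs[idx], levels = labs)
}

# Half-open equal bins on s in [0,1]; s = 1 falls in the last bin.
s_bin_index <- function(s, n_bins) {
  pmin(floor(s * n_bins) + 1L, n_bins)
}

#' Cluster composition along the colon length
#'
#' Splits [0, 1] into `n_bins` equal arc-length bins and reports, per
#' (genotype, bin), the frequency of each cluster among in-range cells.
#' Frequencies over clusters sum to 1 within every non-empty (genotype,
#' bin); empty bins are reported with zero counts and NA frequencies.
#'
#' @param unrolled output of [unroll()]/[unroll_samples()] with `genotype`
#'   and `cluster` columns.
#' @param n_bins number of sequential colon-length bins (>= 1).
#' @param clusters declared cluster vocabulary; defaults to the observed
#'   labels. An observed label outside the vocabulary is an error.
#' @return data.frame: `genotype`, `bin`, `bin_lo`, `bin_hi`, `cluster`,
#'   `count`, `frequency`.
#' @export
composition_profile <- function(unrolled, n_bins = 3L, clusters = NULL) {
  stopifnot(is.data.frame(unrolled),
            all(c("genotype", "cluster", "s") %in% names(unrolled)),
            n_bins >= 1L)
  u <- unrolled
  if ("in_range" %in% names(u)) u <- u[u$in_range, , drop = FALSE]
  obs <- unique(as.character(u$cluster))
  if (is.null(clusters)) clusters <- sort(obs)
  unknown <- setdiff(obs, clusters)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown cluster label(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  bin <- s_bin_index(u$s, n_bins)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  rows <- list()
  for (g in unique(as.character(u$genotype))) {
    for (bi in seq_len(n_bins)) {
      sel <- u$genotype == g & bin == bi
      counts <- table(factor(as.character(u$cluster)[sel], levels = clusters))
      tot <- sum(counts)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, bin = bi, bin_lo = edges[bi], bin_hi = edges[bi + 1L],
        cluster = clusters, count = as.integer(counts),
        frequency = if (tot > 0L) as.numeric(counts) / tot else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genotype comparison of cluster composition with bootstrap CIs
#'
#' Per colon-length bin and cluster, the log2 ratio of knockout to
#' control frequency, smoothed with epsilon = 1 / (total cells in the bin
#' pair). Confidence intervals come from a seeded cell-resampling
#' bootstrap: within each (genotype, bin), cells are resampled with
#' replacement (equivalently, cluster counts are redrawn multinomially)
#' and the log-ratio recomputed; percentile intervals are reported.
#'
#' @param unrolled output of [unroll()]/[unroll_samples()] with `genotype`
#'   and `cluster`.
#' @param n_bins number of colon-length bins.
#' @param control,knockout genotype labels compared (ratio is
#'   knockout/control).
#' @param B bootstrap replicates.
#' @param conf confidence level.
#' @param seed RNG seed (bit-identical reruns for the same seed).
#' @param clusters declared cluster vocabulary.
#' @return data.frame: `bin`, `cluster`, counts and frequencies for both
#'   genotypes, `log2_ratio`, `ci_lo`, `ci_hi`. Rows where a genotype has
#'   no cells in the bin have NA log-ratio and CI.
#' @export
compare_composition <- function(unrolled, n_bins = 3L,
                                control = "control", knockout = "knockout",
                                B = 1000L, conf = 0.95, seed = 1L,
                                clusters = NULL) {
  stopifnot(all(c(control, knockout) %in% unique(unrolled$genotype)))
  prof <- composition_profile(unrolled, n_bins = n_bins, clusters = clusters)
  clusters <- unique(prof$cluster)
  alpha <- (1 - conf) / 2
  rows <- list()
  with_seed(seed, {
    for (bi in seq_len(n_bins)) {
      pc <- prof[prof$bin == bi & prof$genotype == control, ]
      pk <- prof[prof$bin == bi & prof$genotype == knockout, ]
      nc <- sum(pc$count); nk <- sum(pk$count)
      eps <- if (nc + nk > 0L) 1 / (nc + nk) else NA_real_
      if (nc == 0L || nk == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          bin = bi, cluster = clusters,
          count_control = pc$count, count_knockout = pk$count,
          freq_control = pc$frequency, freq_knockout = pk$frequency,
          log2_ratio = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      fc <- pc$count / nc; fk <- pk$count / nk
      l2 <- log2((fk + eps) / (fc + eps))
      bc <- stats::rmultinom(B, nc, prob = pc$count / nc) / nc
      bk <- stats::rmultinom(B, nk, prob = pk$count / nk) / nk
      l2b <- log2((bk + eps) / (bc + eps))  # clusters x B
      ci <- apply(l2b, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
                  names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = bi, cluster = clusters,
        count_control = pc$count, count_knockout = pk$count,
        freq_control = fc, freq_knockout = fk,
        log2_ratio = l2, ci_lo = ci[1, ], ci_hi = ci[2, ],
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median crypt-lumen position per cluster
#'
#' @param unrolled output of [unroll()] with a `cluster` column.
#' @param clusters clusters to report (default: all observed). Requesting
#'   a cluster with no cells is an error.
#' @return data.frame: `cluster`, `median_d`, `n`.
#' @export
median_crypt_position <- function(unrolled, clusters = NULL) {
  stopifnot(all(c("cluster", "d") %in% names(unrolled)))
  u <- unrolled
  if ("in_range" %in% names(u)) u <- u[u$in_range, , drop = FALSE]
  if (is.null(clusters)) clusters <- sort(unique(as.character(u$cluster)))
  rows <- lapply(clusters, function(cl) {
    d <- u$d[u$cluster == cl]
    if (length(d) == 0L) stop(sprintf("cluster '%s' has no cells", cl))
    data.frame(cluster = cl, median_d = stats::median(d), n = length(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned mean expression on the unrolled axes
#'
#' Grids the unrolled tissue into s x d bins and reports per-bin mean
#' normalized counts of one gene over the cells in the bin (cells with no
#' recorded count for the gene contribute 0). Empty bins are NA with
#' n = 0.
#'
#' @param unrolled output of [unroll()] with a `cell_id` column.
#' @param counts sparse triplet data.frame with columns `cell_id`,
#'   `gene`, `count`.
#' @param gene gene id; must be in the counts vocabulary.
#' @param s_bins,d_bins grid resolution.
#' @return list with `grid` (d_bins x s_bins matrix of mean expression,
#'   rows = d from crypt base up), `n` (cell counts per bin), `s_edges`,
#'   `d_edges`.
#' @export
expression_map <- function(unrolled, counts, gene, s_bins = 20L,
                           d_bins = 10L) {
  stopifnot(all(c("cell_id", "s", "d") %in% names(unrolled)),
            all(c("cell_id", "gene", "count") %in% names(counts)))
  if (!(gene %in% unique(counts$gene))) {
    stop(sprintf("gene '%s' not in the counts vocabulary", gene))
  }
  u <- unrolled
  if ("in_range" %in% names(u)) u <- u[u$in_range, , drop = FALSE]
  gc <- counts[counts$gene == gene, , drop = FALSE]
  expr <- gc$count[match(u$cell_id, gc$cell_id)]
  expr[is.na(expr)] <- 0
  si <- s_bin_index(u$s, s_bins)
  di <- s_bin_index(u$d, d_bins)
  grid <- matrix(NA_real_, nrow = d_bins, ncol = s_bins)
  nmat <- matrix(0L, nrow = d_bins, ncol = s_bins)
  sums <- tapply(expr, list(di, si), sum)
  cnts <- tapply(expr, list(di, si), length)
  ri <- as.integer(rownames(sums)); ci <- as.integer(colnames(sums))
  nmat[ri, ci] <- ifelse(is.na(cnts), 0L, cnts)
  grid[ri, ci] <- sums / cnts
  list(grid = grid, n = nmat,
       s_edges = seq(0, 1, length.out = s_bins + 1L),
       d_edges = seq(0, 1, length.out = d_bins + 1L))
}
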