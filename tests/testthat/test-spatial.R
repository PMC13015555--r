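# a small helper: noiseless cells laid exactly on a known spiral
spiral_points <- function(a, b, theta_max, n = 3000, center = c(0, 0),
                          d = NULL, h = 0) {
  theta <- seq(0.05, theta_max - 0.05, length.out = n)
  r <- a + b * theta
  if (!is.null(d)) r <- r - (d - 0.5) * 2 * h  # luminal side inward
  data.frame(cell_id = paste0("c", seq_len(n)),
             x = center[1] + r * cos(theta),
             y = center[2] + r * sin(theta))
}

test_that("closed-form arc length agrees with quadrature", {
  sp <- spiral_model(c(0, 0), a = 200, b = 80, theta_range = c(0, 6 * pi),
                     half_thickness = 50)
  for (th in c(1, 5, 10, 6 * pi)) {
    expect_equal(arc_length(sp, th), oracle_arc_length(200, 80, 0, th),
                 tolerance = 1e-3)
  }
  # adjacent turns differ by exactly one turn's arc length
  l1 <- arc_length(sp, 3 + 2 * pi) - arc_length(sp, 3)
  expect_equal(l1, oracle_arc_length(200, 80, 3, 3 + 2 * pi),
               tolerance = 1e-6)
})

test_that("spiral model construction enforces geometry invariants", {
  expect_error(spiral_model(c(0, 0), 100, 50, c(0, pi), 20), "full turn")
  expect_error(spiral_model(c(0, 0), 100, -5, c(0, 4 * pi), 20))
  expect_error(spiral_model(c(0, 0), 100, 50, c(0, 4 * pi), -1))
})

test_that("noiseless centerline points recover (a, b) within 1%", {
  pts <- spiral_points(200, 80, 6 * pi, center = c(500, -300))
  sp <- fit_spiral(pts, luminal = "inner")
  expect_lt(abs(sp$a - 200) / 200, 0.01)
  expect_lt(abs(sp$b - 80) / 80, 0.01)
  expect_lt(max(abs(sp$center - c(500, -300))), 5)
})

test_that("a circle (b = 0) is rejected as degenerate", {
  theta <- seq(0, 2 * pi, length.out = 1500)
  circ <- data.frame(x = 900 * cos(theta), y = 900 * sin(theta))
  expect_error(fit_spiral(circ, luminal = "inner"), "spiral")
})

test_that("unroll with known geometry is an exact inverse", {
  sim <- simulate_swiss_roll(jitter_r = 0, jitter_theta = 0,
                             cells_per_mm = 60, seed = 42)
  spt <- sim$spiral_truth
  sub <- sim$cells[sim$cells$genotype == "control", ]
  model <- spiral_model(spt$centers$control, spt$a, spt$b,
                        c(0, spt$theta_end), spt$half_thickness,
                        luminal = "inner", distal = "inner")
  un <- unroll(sub, model)
  tr <- sim$truth[match(un$cell_id, sim$truth$cell_id), ]
  expect_lt(max(abs(un$s - tr$s)), 1e-6)
  expect_lt(max(abs(un$d - tr$d)), 1e-6)
  # regions agree except for cells within numerical epsilon of a boundary
  off_boundary <- pmin(abs(tr$s - 1 / 3), abs(tr$s - 2 / 3)) > 1e-6
  expect_identical(as.character(un$region)[off_boundary],
                   as.character(tr$region)[off_boundary])
  # a cell exactly on the centerline maps to d = 0.5
  mid <- unroll(spiral_points(spt$a, spt$b, spt$theta_end, n = 200,
                              center = spt$centers$control), model)
  expect_equal(mid$d, rep(0.5, 200), tolerance = 1e-9)
})

test_that("jittered swiss rolls are recovered within tolerance", {
  sim <- simulate_swiss_roll(seed = 3)
  sub <- sim$cells[sim$cells$genotype == "control", ]
  sp <- fit_spiral(sub)
  expect_equal(sp$luminal, "inner")  # inferred from smooth muscle anchor
  expect_lt(abs(sp$b - sim$spiral_truth$b) / sim$spiral_truth$b, 0.05)
  expect_lt(abs(sp$a - sim$spiral_truth$a) / sim$spiral_truth$a, 0.05)
  un <- unroll(sub, sp)
  tr <- sim$truth[match(un$cell_id, sim$truth$cell_id), ]
  expect_gt(cor(un$s, tr$s, method = "spearman"), 0.99)
  expect_lt(unname(quantile(abs(un$d - tr$d), 0.95)), 0.1)
})

test_that("region assignment uses half-open tercile bins", {
  expect_equal(as.character(assign_regions(0)), "proximal")
  expect_equal(as.character(assign_regions(1 / 3)), "mid")
  expect_equal(as.character(assign_regions(2 / 3)), "distal")
  expect_equal(as.character(assign_regions(1)), "distal")
  s <- (seq_len(999) - 0.5) / 999
  expect_true(all(abs(table(assign_regions(s)) - 333) <= 1))
})

test_that("composition profiles normalize within bins and refine
           consistently", {
  set.seed(6)
  n <- 3000
  u <- data.frame(genotype = sample(c("control", "knockout"), n, TRUE),
                  cluster = sample(letters[1:4], n, TRUE,
                                   prob = c(0.4, 0.3, 0.2, 0.1)),
                  s = runif(n))
  p6 <- composition_profile(u, n_bins = 6)
  sums <- aggregate(frequency ~ genotype + bin, p6, sum)
  expect_equal(sums$frequency, rep(1, nrow(sums)), tolerance = 1e-12)
  # merging adjacent fine bins reproduces the coarse frequencies
  p3 <- composition_profile(u, n_bins = 3)
  for (g in c("control", "knockout")) for (bi in 1:3) {
    fine <- p6[p6$genotype == g & p6$bin %in% c(2 * bi - 1, 2 * bi), ]
    merged <- tapply(fine$count, fine$cluster, sum)
    coarse <- p3[p3$genotype == g & p3$bin == bi, ]
    expect_equal(as.integer(merged[coarse$cluster]), coarse$count)
    expect_equal(as.numeric(merged[coarse$cluster] / sum(merged)),
                 coarse$frequency, tolerance = 1e-12)
  }
  # single cluster everywhere: frequency 1 in all non-empty bins
  u1 <- data.frame(genotype = "control", cluster = "only", s = runif(50))
  p1 <- composition_profile(u1, n_bins = 4)
  expect_true(all(p1$frequency[p1$count > 0] == 1))
  expect_error(composition_profile(u, clusters = c("a", "b")), "unknown")
})

test_that("mid-colon-restricted clusters appear only in mid bins", {
  sim <- simulate_swiss_roll(seed = 9, knockout_expansion = 1)
  tru <- data.frame(genotype = sim$cells$genotype,
                    cluster = sim$truth$cluster, s = sim$truth$s)
  p <- composition_profile(tru, n_bins = 3)
  mid_only <- p[p$cluster == "gc_canonical_mid", ]
  expect_true(all(mid_only$count[mid_only$bin != 2] == 0))
  expect_true(all(mid_only$count[mid_only$bin == 2] > 0))
})

test_that("composition comparison is antisymmetric and seed-stable", {
  set.seed(12)
  n <- 4000
  u <- data.frame(genotype = rep(c("control", "knockout"), each = n / 2),
                  cluster = sample(letters[1:3], n, TRUE),
                  s = runif(n))
  c1 <- compare_composition(u, n_bins = 2, B = 400, seed = 99)
  c2 <- compare_composition(u, n_bins = 2, B = 400, seed = 99)
  expect_identical(c1, c2)  # bit-identical under the same seed
  # swapping genotype labels negates every log ratio
  uswap <- u
  uswap$genotype <- ifelse(u$genotype == "control", "knockout", "control")
  c3 <- compare_composition(uswap, n_bins = 2, B = 400, seed = 99)
  expect_equal(c3$log2_ratio, -c1$log2_ratio, tolerance = 1e-12)
  # identical per-genotype composition gives log ratio exactly 0
  ident <- data.frame(genotype = rep(c("control", "knockout"), each = 30),
                      cluster = rep(rep(c("a", "b", "c"), each = 10), 2),
                      s = rep(runif(30), 2))
  c4 <- compare_composition(ident, n_bins = 1, B = 100, seed = 1)
  expect_equal(c4$log2_ratio, rep(0, 3))
})

test_that("median crypt positions order planted layers correctly", {
  set.seed(15)
  u <- data.frame(cluster = rep(c("base", "lumen"), each = 200),
                  d = c(pmin(pmax(rnorm(200, 0.2, 0.05), 0), 1),
                        pmin(pmax(rnorm(200, 0.9, 0.05), 0), 1)))
  med <- median_crypt_position(u)
  expect_equal(med$median_d[med$cluster == "base"], 0.2, tolerance = 0.02)
  expect_lt(med$median_d[med$cluster == "base"],
            med$median_d[med$cluster == "lumen"])
  one <- median_crypt_position(data.frame(cluster = "solo", d = 0.77))
  expect_equal(one$median_d, 0.77)
  expect_error(median_crypt_position(u, clusters = "ghost"), "ghost")
})

test_that("expression maps confine signal to the planted band and ignore
           cell order", {
  set.seed(18)
  n <- 2000
  u <- data.frame(cell_id = paste0("c", 1:n), s = runif(n), d = runif(n))
  mid_crypt <- u$d >= 0.4 & u$d < 0.6
  counts <- data.frame(cell_id = u$cell_id[mid_crypt], gene = "Gsdmc4",
                       count = rpois(sum(mid_crypt), 4) + 1)
  counts <- rbind(counts, data.frame(cell_id = u$cell_id[1], gene = "Zero",
                                     count = 0))
  em <- expression_map(u, counts, "Gsdmc4", s_bins = 4, d_bins = 5)
  nz <- which(rowMeans(em$grid, na.rm = TRUE) > 0)
  expect_true(all(nz == 3))  # only the mid-d row carries signal
  em0 <- expression_map(u, counts, "Zero", s_bins = 4, d_bins = 5)
  expect_true(all(em0$grid[!is.na(em0$grid)] == 0))
  em2 <- expression_map(u[sample(n), ], counts, "Gsdmc4",
                        s_bins = 4, d_bins = 5)
  expect_equal(em$grid, em2$grid)
  expect_error(expression_map(u, counts, "Missing"), "vocabulary")
})
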