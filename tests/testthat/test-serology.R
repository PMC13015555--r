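sero_df <- function(hs, uc) {
  data.frame(od = c(hs, uc),
             group = c(rep("HS", length(hs)), rep("UC", length(uc))))
}

test_that("ROC AUC matches hand-checkable configurations", {
  expect_equal(compute_roc(sero_df(c(0.1, 0.2), c(0.3, 0.4)))$auc, 1.0)
  expect_equal(compute_roc(sero_df(0.5, 0.5))$auc, 0.5)
  # brute force over the 4 (UC, HS) pairs: 3 concordant of 4
  expect_equal(compute_roc(sero_df(c(0.1, 0.3), c(0.2, 0.4)))$auc, 0.75)
})

test_that("ROC errors name the problem", {
  expect_error(compute_roc(data.frame(od = 1, group = "HS")), "positive group")
  expect_error(compute_roc(data.frame(od = 1, group = "UC")), "negative")
  expect_error(compute_roc(sero_df(c(0.1, NA), c(0.3, 0.4))), "row")
})

test_that("AUC equals the pair-counting estimator and Youden matches an
           exhaustive scan on random cohorts", {
  set.seed(101)
  for (i in 1:60) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    hs <- round(rlnorm(n1, log(0.1), 0.6), 2)  # rounding forces ties
    uc <- round(rlnorm(n2, log(0.4), 0.8), 2)
    roc <- compute_roc(sero_df(hs, uc))
    expect_equal(roc$auc, oracle_auc_paircount(uc, hs), tolerance = 1e-12)
    th <- suppressWarnings(youden_threshold(roc))
    or <- oracle_youden(uc, hs)
    expect_equal(th$j, or$j, tolerance = 1e-12)
    # returned threshold attains the scanned maximum and classifies
    # identically to the oracle's tie-broken threshold
    expect_equal(mean(uc >= th$value) - mean(hs >= th$value), or$j,
                 tolerance = 1e-12)
    expect_identical(c(hs, uc) >= th$value, c(hs, uc) >= or$value)
    expect_equal(th$sensitivity + th$specificity - 1, th$j, tolerance = 1e-12)
  }
})

test_that("Youden threshold handles ties, separation and degeneracy", {
  th <- youden_threshold(compute_roc(sero_df(c(0.1, 0.3), c(0.2, 0.4))))
  expect_equal(th$value, 0.2)  # 0.2 and 0.4 tie at J = 0.5; lowest wins
  expect_equal(th$j, 0.5)
  expect_equal(youden_threshold(compute_roc(sero_df(c(0.1, 0.2),
                                                    c(0.3, 0.4))))$j, 1.0)
  expect_warning(th0 <- youden_threshold(compute_roc(sero_df(c(0.5, 0.5),
                                                             c(0.5, 0.5)))),
                 "indistinguishable")
  expect_equal(th0$j, 0)
})

test_that("seropositivity is boundary-inclusive at the threshold", {
  th <- youden_threshold(compute_roc(sero_df(c(0.1, 0.3), c(0.2, 0.4))))
  expect_true(classify_seropositive(th$value, th))
  expect_false(classify_seropositive(th$value - 1e-9, th))
  expect_true(classify_seropositive(0.25, th))
})

test_that("seropositivity rates reproduce printed-style percentages", {
  mk <- function(k, n, group) {
    data.frame(od = c(rep(1, k), rep(0, n - k)), group = group)
  }
  expect_equal(seropositivity_rates(mk(173, 194, "UC"), 0.5)$percent, 89.2)
  expect_equal(seropositivity_rates(mk(39, 338, "HS"), 0.5)$percent, 11.5)
  expect_equal(seropositivity_rates(mk(35, 338, "HS"), 0.5)$percent, 10.4)
  expect_equal(seropositivity_rates(mk(0, 10, "HS"), 0.5)$percent, 0.0)
  # empty requested group: n = 0 with NA percent
  r <- seropositivity_rates(mk(3, 5, "UC"), 0.5, groups = c("UC", "HS"))
  expect_equal(r$n[r$group == "HS"], 0L)
  expect_true(is.na(r$percent[r$group == "HS"]))
  # invariance under subject reordering; counts sum to n
  set.seed(7)
  df <- sero_df(runif(40), runif(25, 0.2, 1.2))
  r1 <- seropositivity_rates(df, 0.4)
  r2 <- seropositivity_rates(df[sample(nrow(df)), ], 0.4)
  expect_equal(r1[order(r1$group), ], r2[order(r2$group), ],
               ignore_attr = TRUE)
  expect_true(all(r1$n_positive <= r1$n))
})

test_that("4PL standard curve fitting recovers known parameters", {
  truth <- list(lower = 0.05, upper = 3, ec50 = 100, hill = 1.2)
  sim <- simulate_standard_curve(params = truth, noise_sd = 0)
  cv <- fit_standard_curve(sim$standards)
  for (p in names(truth)) {
    expect_lt(abs(cv$params[[p]] - truth[[p]]) / truth[[p]], 0.01)
  }
  # the OD midway between asymptotes inverts to the inflection conc
  mid_od <- (cv$params$lower + cv$params$upper) / 2
  q <- interpolate_concentration(mid_od, cv)
  expect_equal(q$concentration, cv$params$ec50, tolerance = 1e-6)
})

test_that("degenerate standards are rejected", {
  flat <- data.frame(concentration = c(1, 10, 100, 1000, 10000), od = 1)
  expect_error(fit_standard_curve(flat), "flat")
  dec <- data.frame(concentration = c(1, 10, 100, 1000, 10000),
                    od = c(3, 2.5, 1.5, 0.5, 0.1))
  expect_error(fit_standard_curve(dec), "monotone")
  few <- data.frame(concentration = c(1, 10, 100), od = c(0.1, 1, 2))
  expect_error(fit_standard_curve(few), ">= 5")
})

test_that("interpolation round-trips concentrations within 1%", {
  truth <- list(lower = 0.08, upper = 2.6, ec50 = 250, hill = 0.9)
  cv <- fit_standard_curve(
    simulate_standard_curve(params = truth, noise_sd = 0)$standards)
  set.seed(11)
  conc <- exp(runif(20, log(cv$fit_range[1] * 1.5), log(cv$fit_range[2] / 1.5)))
  od <- oracle_fpl(conc, truth$lower, truth$upper, truth$ec50, truth$hill)
  got <- interpolate_concentration(od, cv)
  expect_true(all(!got$below_lloq))
  expect_lt(max(abs(got$concentration - conc) / conc), 0.01)
})

test_that("LLOQ and above-range samples are flagged, not invented", {
  truth <- list(lower = 0.05, upper = 3, ec50 = 100, hill = 1)
  cv <- fit_standard_curve(
    simulate_standard_curve(params = truth, noise_sd = 0)$standards)
  low <- interpolate_concentration(0.051, cv)
  expect_true(low$below_lloq)
  expect_true(is.na(low$concentration))
  hi <- interpolate_concentration(2.999, cv)
  expect_true(hi$above_range)
  expect_equal(hi$concentration, cv$fit_range[2])
  expect_error(interpolate_concentration(NaN, cv), "non-finite")
  # blanks raise the LLOQ above the lowest standard when they overlap it
  cvb <- fit_standard_curve(
    simulate_standard_curve(params = truth, noise_sd = 0)$standards,
    blanks = rnorm(8, 0.06, 0.01))
  expect_gte(cvb$lloq, cv$lloq)
})

test_that("Spearman correlation matches rank arithmetic and is monotone
           invariant", {
  expect_equal(spearman_correlation(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_correlation(1:8, -(1:8))$rho, -1)
  # ranks of y = (2,1,4,3,5) give d = (-1,1,-1,1,0), sum d^2 = 4:
  # rho = 1 - 6*4/(5*24) = 0.8 (verified by enumeration)
  r <- spearman_correlation(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)
  expect_equal(r$method, "exact")
  set.seed(3)
  x <- rnorm(25); y <- x + rnorm(25)
  r1 <- spearman_correlation(x, y)
  r2 <- spearman_correlation(exp(x), y^3 + 5 * y)  # monotone transforms
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p, r2$p)
  expect_error(spearman_correlation(1:2, 2:3), "n >= 3")
  expect_true(is.na(spearman_correlation(c(1, 1, 1), 1:3)$rho))
})

test_that("two-stage step-up FDR matches an independent reference", {
  # reference values computed with statsmodels fdr_tsbky
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.5)), c(0.0105, 0.0105, 0.175),
               tolerance = 1e-12)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.03), 0.03 * 1.05)
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  p <- runif(50)^2
  adj <- fdr_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # order-preserving
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  df <- sero_df(rlnorm(30, log(0.1), 0.6), rlnorm(25, log(0.5), 0.7))
  ours <- compute_roc(df)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = df$group, predictor = df$od, levels = c("HS", "UC"),
    direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})
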