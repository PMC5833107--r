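test_that("log-log least squares recovers the power-law coefficients", {
  t <- exp(seq(-5, -1, length.out = 30))
  exact <- fit_response_curve(data.frame(t = t, f = t^1.5 * exp(-2)))
  expect_equal(exact$attenuation, 2, tolerance = 1e-12)
  expect_equal(exact$buffering, 1.5, tolerance = 1e-12)
  # two-point solve by hand: (t=e, f=e^-0.5), (t=e^2, f=e^0.5)
  two <- fit_response_curve(data.frame(t = exp(c(1, 2)),
                                       f = exp(c(-0.5, 0.5))))
  expect_equal(two$buffering, 1, tolerance = 1e-12)
  expect_equal(two$attenuation, 1.5, tolerance = 1e-12)
  # symmetric +/- noise at paired design points leaves the fit unchanged
  tp <- rep(exp(c(-3, -2, -1)), each = 2)
  eps <- rep(c(0.3, -0.3), times = 3)
  noisy <- fit_response_curve(data.frame(t = tp,
                                         f = exp(-2 + 1.5 * log(tp) + eps)))
  expect_equal(noisy$attenuation, 2, tolerance = 1e-10)
  expect_equal(noisy$buffering, 1.5, tolerance = 1e-10)
  expect_error(fit_response_curve(data.frame(t = c(1, 1), f = c(1, 2))),
               "distinct")
})

test_that("fits recover parameters under lognormal noise", {
  set.seed(77)
  a <- 2.5; b <- 2
  ok <- vapply(1:20, function(i) {
    t <- exp(stats::runif(1000, log(0.001), log(0.4)))
    f <- t^b * exp(-a) * exp(stats::rnorm(1000, 0, 0.2))
    cv <- fit_response_curve(data.frame(t = t, f = f))
    abs(cv$attenuation - a) / a < 0.05 && abs(cv$buffering - b) / b < 0.05
  }, logical(1))
  expect_true(all(ok))
})

test_that("expected shift evaluates the fitted curve", {
  ident <- structure(list(attenuation = 0, buffering = 1, scope = "profile"),
                     class = "response_curve")
  expect_equal(predict_expected_shift(ident, 0.3), 0.3)
  gut <- structure(list(attenuation = 3.487, buffering = 2.03,
                        scope = "profile"), class = "response_curve")
  expect_equal(predict_expected_shift(gut, 0.1),
               0.1^2.03 * exp(-3.487), tolerance = 1e-12)
  ts <- c(0.01, 0.05, 0.2, 0.4)
  expect_true(all(diff(predict_expected_shift(gut, ts)) > 0))
  expect_error(predict_expected_shift(gut, 0), "> 0")
})

test_that("window subsampling caps per-window counts deterministically", {
  set.seed(12)
  recs <- data.frame(t = exp(runif(5000, -6, -1)), f = runif(5000))
  out <- window_subsample(recs, seed = 3)
  lt <- log(out$t)
  edges <- seq(min(log(recs$t)), max(log(recs$t)), length.out = 51)
  win <- findInterval(lt, edges, rightmost.closed = TRUE)
  expect_true(all(table(win) <= 50))
  expect_lte(nrow(out), 2500)
  expect_identical(out, window_subsample(recs, seed = 3))
  # below-cap windows keep everything
  few <- data.frame(t = exp(runif(30, -1.01, -1)), f = runif(30))
  expect_equal(nrow(window_subsample(few, seed = 1)), 30)
  # non-positive records are dropped and counted
  mix <- rbind(recs, data.frame(t = c(0, 1), f = c(1, 0)))
  expect_equal(attr(window_subsample(mix, seed = 1), "n_dropped"), 2)
})

test_that("pseudomedian equals the Walsh-average median with a valid CI", {
  expect_equal(pseudomedian_with_ci(c(1, 2, 6))$pseudomedian, 2.75)
  expect_equal(pseudomedian_with_ci(5)$pseudomedian, 5)
  expect_equal(pseudomedian_with_ci(c(-1, 0, 1))$pseudomedian, 0)
  set.seed(14)
  x <- rnorm(25, 2)
  mine <- pseudomedian_with_ci(x)
  wt <- stats::wilcox.test(x, conf.int = TRUE)
  expect_equal(mine$pseudomedian, unname(wt$estimate), tolerance = 1e-12)
  expect_true(mine$ci_low <= mine$pseudomedian &&
                mine$pseudomedian <= mine$ci_high)
})

test_that("pseudomedian CI attains near-nominal coverage", {
  set.seed(99)
  hits <- vapply(1:500, function(i) {
    x <- rnorm(30, 1.7)  # symmetric: pseudomedian = 1.7
    ci <- pseudomedian_with_ci(x)
    ci$ci_low <= 1.7 && 1.7 <= ci$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("Mood's median test counts around the grand median", {
  res <- mood_median_test(list(1:4, 5:8))
  expect_equal(unname(res$table["above", ]), c(0, 4))
  expect_equal(unname(res$table["not_above", ]), c(4, 0))
  expect_equal(res$statistic, 8, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  # identical groups: null; identical values: degenerate flag
  same <- mood_median_test(list(c(1, 2, 3), c(1, 2, 3)))
  expect_gte(same$p_value, 0.05)
  cst <- mood_median_test(list(c(2, 2), c(2, 2)))
  expect_true(cst$degenerate)
  expect_equal(cst$p_value, 1)
  # invariance to monotone transforms
  set.seed(2)
  g <- list(rnorm(40), rnorm(40, 1))
  expect_equal(mood_median_test(g)$p_value,
               mood_median_test(lapply(g, exp))$p_value, tolerance = 1e-12)
})

test_that("most robust environment search returns planted sets", {
  set.seed(31)
  base <- list(low1 = rnorm(100, 3), low2 = rnorm(100, 3),
               high = rnorm(100, 13))
  expect_identical(most_robust_environments(base), "high")
  two_high <- list(low = rnorm(100, 3), h1 = rnorm(100, 13),
                   h2 = rnorm(100, 13))
  expect_setequal(most_robust_environments(two_high), c("h1", "h2"))
  # all drawn from one distribution: the full set qualifies
  flat <- list(a = rnorm(50, 5), b = rnorm(50, 5), c = rnorm(50, 5))
  expect_setequal(most_robust_environments(flat), c("a", "b", "c"))
})

test_that("function-specific curves skip invariant functions and track single carriers", {
  # F_shared identical in all genomes -> excluded; F_solo carried by one
  # taxon -> its relative shift equals that taxon's relative abundance
  # change after renormalization
  cn <- matrix(c(1, 2, 0,
                 1, 0, 3,
                 1, 0, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"),
                               c("F_shared", "F_a", "F_solo")))
  gc <- genome_content(cn)
  tr <- toy_tree()
  prof <- c(A = 0.5, B = 0.3, C = 0.2)
  out <- function_specific_curves(prof, gc, tr, n_magnitudes = 5,
                                  n_per_magnitude = 20, seed = 6,
                                  correct_16S = FALSE)
  expect_true("F_shared" %in% names(out$skipped))
  expect_true(all(c("F_a", "F_solo") %in% names(out$curves)))
  # brute-force check of the solo-function shift on one perturbation
  spec <- list(multipliers = c(2, 3, 1.5), directions = c(1, -1, 1))
  pert <- apply_perturbation(prof, spec)
  f0 <- predict_functional_profile(prof, gc, correct_16S = FALSE,
                                   post_normalization = "none")
  f1 <- predict_functional_profile(pert, gc, correct_16S = FALSE,
                                   post_normalization = "none")
  expect_equal(abs(f1["F_solo"] - f0["F_solo"]) / f0["F_solo"],
               abs(3 * pert["B"] - 3 * prof["B"]) / (3 * prof["B"]),
               ignore_attr = TRUE)
  # reproducible under a fixed seed
  out2 <- function_specific_curves(prof, gc, tr, n_magnitudes = 5,
                                   n_per_magnitude = 20, seed = 6,
                                   correct_16S = FALSE)
  expect_equal(out$curves, out2$curves)
})
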