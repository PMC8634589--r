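test_that("Shapiro screen detects non-normality and rejects degenerate input", {
  set.seed(1)
  heavy <- c(rnorm(400), rnorm(100, 0, 8))    # heavy-tailed mixture
  expect_lt(shapiro_normality(heavy), 0.05)
  expect_error(shapiro_normality(rep(2, 50)), class = "propcog_degenerate_input")
  expect_error(shapiro_normality(c(1, 2)), class = "propcog_insufficient_data")
  # type-I calibration: rejection rate near alpha under normality
  rej <- vapply(1:200, function(s) {
    set.seed(s + 3000)
    shapiro_normality(rnorm(100)) < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})

test_that("Kruskal-Wallis matches the hand formula and a permutation oracle", {
  g <- list(a = c(2.1, 3.4, 1.2, 5.6), b = c(4.4, 2.2, 6.1, 3.3),
            c = c(7.7, 5.5, 8.8, 6.6))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, kw_by_hand(g), tolerance = 1e-10)
  # permutation oracle: p within Monte-Carlo error
  set.seed(10)
  x <- unlist(g); lab <- rep(1:3, each = 4)
  perm <- vapply(1:4000, function(i) {
    kw_by_hand(split(x, sample(lab)))
  }, 0)
  p_perm <- mean(perm >= kw$H - 1e-12)
  expect_lt(abs(kw$p - p_perm), 4 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.02)
})

test_that("Kruskal-Wallis edge behaviour and invariance", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  tied <- kruskal_wallis(list(rep(5, 4), rep(5, 4)))
  expect_equal(tied$H, 0)
  expect_equal(tied$p, 1)
  set.seed(2)
  big <- list(rnorm(20), rnorm(20, 5), rnorm(20, 10))
  expect_lt(kruskal_wallis(big)$p, 0.001)
  # invariance under strictly monotone transforms
  h1 <- kruskal_wallis(big)$H
  h2 <- kruskal_wallis(lapply(big, function(v) exp(v / 3)))$H
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1, numeric(0))), class = "propcog_degenerate_input")
})

test_that("Dunn post hoc matches the hand z and behaves under adjustment", {
  g <- list(a = c(1.2, 2.5, 3.1, 0.8, 2.2),
            b = c(2.8, 3.9, 1.7, 2.4, 3.3),
            c = c(6.1, 5.2, 7.4, 6.6, 5.9))   # one shifted group
  d <- dunn_posthoc(g)
  expect_equal(d$z["a", "b"], unname(dunn_z_by_hand(g, 1, 2)), tolerance = 1e-10)
  expect_equal(d$z["a", "c"], unname(dunn_z_by_hand(g, 1, 3)), tolerance = 1e-10)
  # symmetry, unit diagonal, adjusted >= raw
  expect_equal(d$p, t(d$p))
  expect_equal(unname(diag(d$p)), rep(1, 3))
  expect_true(all(d$p >= d$p_raw - 1e-15, na.rm = TRUE))
  # identical groups: all adjusted p = 1
  same <- dunn_posthoc(list(a = 1:6, b = 1:6, c = 1:6))
  expect_true(all(same$p == 1))
  expect_error(dunn_posthoc(list(a = 1:3, b = numeric(0))),
               class = "propcog_degenerate_input")
})

test_that("Brown-Forsythe matches the hand formula and calibrates", {
  set.seed(3)
  g <- list(rnorm(12), rnorm(15, 0, 1), rnorm(10, 2, 1))
  lv <- levene_homoscedasticity(g)
  expect_equal(lv$W, levene_by_hand(g), tolerance = 1e-10)
  # all identical -> W = 0
  expect_equal(levene_homoscedasticity(list(rep(1, 5), rep(1, 5)))$W, 0)
  # power: a 5x SD group is detected
  set.seed(4)
  het <- list(rnorm(40), rnorm(40), rnorm(40, 0, 5))
  expect_lt(levene_homoscedasticity(het)$p, 0.01)
  # type-I: equal-variance groups rejected at ~alpha
  rej <- vapply(1:200, function(s) {
    set.seed(s + 5000)
    levene_homoscedasticity(list(rnorm(30), rnorm(30), rnorm(30)))$p < 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.1)
  expect_error(levene_homoscedasticity(list(rnorm(5), 3)),
               class = "propcog_insufficient_data")
})

test_that("sex contrast is Welch, two-sided, with not-estimable strata", {
  # identical F/M distributions: the same values for both sexes give p = 1
  v <- c(1.5, 2.5, 3.5, 4.5)
  tab <- data.frame(sex = rep(c("F", "M"), each = 4), y = c(v, v))
  sc <- sex_contrast(tab, "y")
  expect_equal(sc$p[sc$stratum == "Total"], 1)
  expect_equal(sc$t[sc$stratum == "Total"], 0)
  # Welch equals Student when variances and n are equal
  set.seed(6)
  a <- rnorm(25); b <- rnorm(25, 1)
  b <- (b - mean(b)) / sd(b) * sd(a) + mean(b)   # force equal variance
  welch <- t.test(a, b)$statistic
  student <- t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(unname(welch), unname(student), tolerance = 1e-12)
  # a stratum missing one sex is flagged, not an error
  tab2 <- data.frame(sex = c(rep("F", 6), rep("M", 6)),
                     y = rnorm(12),
                     g = c(rep("A", 6), rep("B", 6)))
  sc2 <- sex_contrast(tab2, "y", strata = tab2$g)
  expect_false(sc2$estimable[sc2$stratum == "A"])
  expect_false(sc2$estimable[sc2$stratum == "B"])
  # power: 1-SD shift at n = 40/40 detected in the majority of seeds
  hits <- vapply(1:20, function(s) {
    set.seed(s + 700)
    tt <- data.frame(sex = rep(c("F", "M"), each = 40),
                     y = c(rnorm(40), rnorm(40, 1)))
    sex_contrast(tt, "y")$p[1] < 0.01
  }, TRUE)
  expect_gt(mean(hits), 0.5)
})

test_that("bootstrap trend bands recover exact fits and cover the truth", {
  x <- seq(1, 10, length.out = 20)
  tb <- bootstrap_trend(x, 2 * x + 1, B = 200, seed = 1)
  expect_equal(tb$slope, 2, tolerance = 1e-10)
  expect_equal(tb$intercept, 1, tolerance = 1e-10)
  expect_equal(max(tb$upper - tb$lower), 0, tolerance = 1e-9)
  expect_true(all(tb$lower <= tb$fit + 1e-9 & tb$fit <= tb$upper + 1e-9))
  # coverage of a flat truth
  cover <- vapply(1:25, function(s) {
    set.seed(s + 40)
    xx <- runif(60, 0, 80); yy <- rnorm(60, 5)
    t2 <- bootstrap_trend(xx, yy, B = 300, seed = s)
    mean(t2$lower <= 5 & 5 <= t2$upper)
  }, 0)
  expect_gt(mean(cover >= 0.9), 0.5)
  # B-convergence on fixed data
  set.seed(9)
  xx <- runif(50, 0, 10); yy <- 3 + 0.5 * xx + rnorm(50)
  b1 <- bootstrap_trend(xx, yy, B = 400, seed = 2)
  b2 <- bootstrap_trend(xx, yy, B = 2000, seed = 3)
  expect_lt(max(abs(b1$lower - b2$lower)), 0.4)
  expect_error(bootstrap_trend(rep(2, 10), rnorm(10)), class = "propcog_degenerate_input")
})

test_that("group_comparison assembles a coherent report", {
  tab <- sample_cohort(default_config(seed = 6))$table
  cmp <- group_comparison(tab, "ISCA")
  expect_s3_class(cmp, "group_comparison")
  expect_equal(dim(cmp$dunn_p), c(4, 4))
  expect_true(all(cmp$dunn_p >= 0 & cmp$dunn_p <= 1))
  expect_equal(cmp$dunn_p, t(cmp$dunn_p))
  expect_equal(sum(cmp$descriptives$n) + cmp$n_excluded, nrow(tab))
  expect_true(is.finite(cmp$kw_H) && cmp$kw_H >= 0)
})
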