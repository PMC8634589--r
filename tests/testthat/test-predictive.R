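test_that("binary labels follow the cutoff convention", {
  expect_equal(make_binary_label(c(39.9, 40)), c(0L, 1L))
  tab <- sample_cohort(default_config(seed = 2))$table
  expect_equal(sum(make_binary_label(tab$age)), 64 + 55)    # Midlife + Older
  expect_equal(sum(make_binary_label(tab$age, cutoff = 60)), 55)
  expect_error(make_binary_label(c(-1, 20)))
})

test_that("the leakage filter removes computable predictors", {
  feats <- c("SVMR_IES", "RMO_mean", "age", "SVMR_mean", "ISD", "ISCA",
             "AST_mean")
  lf <- leakage_filter(feats, "ISCA")
  expect_true("SVMR_IES" %in% lf$removed)
  expect_true("SVMR_mean" %in% lf$removed)
  expect_true("ISD" %in% lf$removed)        # sibling index
  expect_true("ISCA" %in% lf$removed)       # the target itself
  expect_true(all(c("RMO_mean", "age", "AST_mean") %in% lf$allowed))
  lf2 <- leakage_filter(c("RMO_mean", "ISD"), "ISD")
  expect_equal(lf2$allowed, "RMO_mean")
  expect_error(leakage_filter(c("SVMR_mean", "DMT"), "ISDA"),
               class = "propcog_empty_features")
})

fast_cls <- function() classification_families()[c("logistic", "random_forest")]
fast_reg <- function() regression_families()[c("linear", "random_forest")]

test_that("a perfectly separating feature yields perfect pooled metrics", {
  set.seed(5)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- data.frame(sep = y * 10 + rnorm(n, 0, 0.1), noise = rnorm(n))
  rep_ <- cv_classify(X, y, families = fast_cls(), folds = 5, repeats = 2, seed = 1)
  expect_equal(rep_$per_family$accuracy_mean, rep(1, 2))
  expect_equal(rep_$per_family$auc_mean, rep(1, 2))
  expect_equal(rep_$per_family$sensitivity_mean, rep(1, 2))
})

test_that("pure-noise features give chance-level AUC", {
  aucs <- vapply(1:6, function(s) {
    set.seed(s)
    n <- 80
    y <- rep(c(0L, 1L), each = n / 2)
    X <- data.frame(a = rnorm(n), b = rnorm(n))
    rep_ <- cv_classify(X, y, families = fast_cls()["logistic"],
                        folds = 5, repeats = 2, seed = s)
    rep_$per_family$auc_mean[1]
  }, 0)
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("confusion counts reproduce the reported pooled metrics exactly", {
  set.seed(11)
  n <- 70
  y <- rbinom(n, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  X <- data.frame(x1 = y + rnorm(n), x2 = rnorm(n))
  rep_ <- cv_classify(X, y, families = fast_cls(), folds = 5, repeats = 3, seed = 2)
  for (i in seq_len(nrow(rep_$confusion))) {
    cc <- rep_$confusion[i, ]
    expect_equal(sum(cc), n * rep_$repeats)
    expect_equal(unname((cc["TP"] + cc["TN"]) / sum(cc)),
                 rep_$per_family$accuracy_mean[i], tolerance = 1e-12)
    expect_equal(unname(cc["TP"] / (cc["TP"] + cc["FN"])),
                 rep_$per_family$sensitivity_mean[i], tolerance = 1e-12)
    expect_equal(unname(cc["TN"] / (cc["TN"] + cc["FP"])),
                 rep_$per_family$specificity_mean[i], tolerance = 1e-12)
  }
})

test_that("stratification fails loudly when a class cannot fill the folds", {
  y <- c(rep(0L, 30), rep(1L, 3))
  X <- data.frame(a = rnorm(33))
  expect_error(cv_classify(X, y, families = fast_cls(), folds = 5, repeats = 1),
               class = "propcog_stratification")
  expect_error(cv_classify(X, rep(0L, 33), families = fast_cls()),
               class = "propcog_stratification")
})

test_that("regression metrics obey their definitions", {
  set.seed(12)
  n <- 80
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 2 * X$a + rnorm(n, 0, 0.5)
  rep_ <- cv_regress(X, y, families = fast_reg(), folds = 5, repeats = 2, seed = 3)
  expect_true(all(rep_$per_family$rmse_mean >= rep_$per_family$mae_mean))
  expect_equal(rep_$per_family$mae_range_pct_mean,
               100 * rep_$per_family$mae_mean / diff(range(y)),
               tolerance = 1e-12)
  # identity leak as a harness check: target equals a feature
  leak <- cv_regress(data.frame(a = y, b = rnorm(n)), y,
                     families = fast_reg()["linear"], folds = 5, repeats = 1,
                     seed = 4)
  expect_lt(leak$per_family$mae_mean[1], 1e-6)
  expect_error(cv_regress(X, rep(3, n), families = fast_reg()),
               class = "propcog_zero_range")
})

test_that("per-age-group error breakdown is reported when ages are given", {
  tab <- sample_cohort(small_config(seed = 4))$table
  lf <- leakage_filter(setdiff(names(tab), c("subject_id", "group")), "ISCA")
  rep_ <- cv_regress(tab[lf$allowed], tab$ISCA, families = fast_reg()["linear"],
                     folds = 4, repeats = 1, seed = 5, ages = tab$age)
  expect_equal(colnames(rep_$per_group),
               c("Adolescents", "YoungAdults", "MidlifeAdults", "OlderAdults"))
  expect_true(all(is.finite(rep_$per_group)))
})

test_that("index predictability comparison delegates to Kruskal-Wallis", {
  acc <- list(ISD = c(0.7, 0.71, 0.69, 0.72), ISCA = c(0.73, 0.74, 0.72, 0.75))
  out <- compare_index_predictability(acc)
  ref <- kruskal_wallis(acc)
  expect_identical(out, ref)
  same <- compare_index_predictability(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$H, 0)
  sep <- compare_index_predictability(list(a = c(0.1, 0.11, 0.12, 0.13, 0.1),
                                           b = c(0.9, 0.91, 0.92, 0.93, 0.9)))
  expect_lt(sep$p, 0.05)
})
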