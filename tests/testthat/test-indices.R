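test_that("error_fraction is mistakes over trials", {
  expect_equal(error_fraction(list(mistakes = 0, trials_no = 30)), 0)
  expect_equal(error_fraction(list(mistakes = 30, trials_no = 30)), 1)
  expect_equal(error_fraction(list(mistakes = 3, trials_no = 30)), 0.1)
  expect_error(error_fraction(list(mistakes = 0, trials_no = 0)),
               class = "propcog_degenerate_input")
})

test_that("DMT is the CVMR-SVMR latency difference", {
  expect_equal(compute_dmt(260.51, 360.77), 100.26)
  expect_equal(compute_dmt(221.03, 324.89), 103.86)
  expect_equal(compute_dmt(123.4, 123.4), 0)
  expect_lt(compute_dmt(300, 280), 0)   # negative allowed
})

test_that("IES divides latency by the correct-response fraction", {
  expect_equal(compute_ies(200, 0), 200)
  expect_equal(compute_ies(300, 0.25), 400)
  expect_error(compute_ies(250, 1), class = "propcog_undefined_ies")
})

test_that("IES dominates the mean latency and is monotone in the error rate", {
  for (e in seq(0, 0.95, by = 0.05)) {
    expect_gte(compute_ies(250, e), 250)
  }
  errs <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(compute_ies(250, errs)) > 0))
  expect_identical(compute_ies(250, 0), 250)
})

test_that("TRVI and AC follow their definitions", {
  expect_equal(compute_trvi(500, 400), 100)
  expect_equal(compute_trvi(400, 500), -100)
  expect_equal(compute_trvi(321, 321), 0)
  expect_equal(compute_ac(40, 40), 1)
  expect_equal(compute_ac(44, 40), 1.1)
  expect_error(compute_ac(40, 0), class = "propcog_degenerate_input")
})

test_that("ISD handles sign and near-zero DMT", {
  expect_equal(compute_isd(200, 50)$value, 4)
  expect_equal(compute_isd(100, -50)$value, -2)
  r <- compute_isd(200, 0)
  expect_false(r$valid)
  expect_true(is.na(r$value))
  expect_false(compute_isd(200, 0.5)$valid)      # below default epsilon
  expect_true(compute_isd(200, 0.5, dmt_epsilon = 0.1)$valid)
})

test_that("ISDA reduces to ISD at zero error and rescales otherwise", {
  expect_equal(compute_isda(200, 50, 0)$value, 4)
  expect_equal(compute_isda(200, 50, 0.1)$value, 200 / 45, tolerance = 1e-12)
  expect_false(compute_isda(200, 0, 0.1)$valid)
  expect_false(compute_isda(200, 50, 1)$valid)
})

test_that("ISCA matches hand arithmetic and rejects degenerate input", {
  expect_equal(compute_isca(200, 0, 300, 0)$value, 2 / 3, tolerance = 1e-12)
  expect_equal(compute_isca(200, 0.1, 300, 0.2)$value, 160 / 270, tolerance = 1e-12)
  expect_false(compute_isca(200, 0, -1, 0)$valid)
  expect_false(compute_isca(200, 1, 300, 0)$valid)
})

test_that("the two ISCA forms agree to 1e-12 on random valid inputs", {
  set.seed(42)
  for (i in 1:1000) {
    sm <- runif(1, 150, 500); cm <- sm + runif(1, 5, 250)
    se <- runif(1, 0, 0.8); ce <- runif(1, 0, 0.8)
    expanded <- compute_isca(sm, se, cm, ce)$value
    ies_ratio <- compute_ies(sm, se) / compute_ies(cm, ce)
    expect_equal(expanded, ies_ratio, tolerance = 1e-12)
  }
})

test_that("ISDA and ISD are mutually consistent whenever both valid", {
  set.seed(7)
  for (i in 1:1000) {
    sm <- runif(1, 150, 500); d <- runif(1, 2, 250); ce <- runif(1, 0, 0.8)
    isd <- compute_isd(sm, d)$value
    isda <- compute_isda(sm, d, ce)$value
    expect_equal(isda * (1 - ce), isd, tolerance = 1e-12)
  }
})

test_that("mobility bins partition the positive axis, lower-inclusive", {
  expect_equal(as.character(classify_mobility(150)), "pronounced_mobility")
  expect_equal(as.character(classify_mobility(205)), "average")
  expect_equal(as.character(classify_mobility(233)), "pronounced_inertia")
  # boundary membership: each threshold belongs to the upper bin
  expect_equal(as.character(classify_mobility(c(177, 200, 210))),
               c("mobile", "average", "inertial"))
  set.seed(1)
  x <- runif(500, 1, 600)
  cl <- classify_mobility(x)
  expect_false(anyNA(cl))          # every positive latency maps somewhere
  expect_error(classify_mobility(0), class = "propcog_degenerate_input")
})

test_that("RMO interpretation follows the sign semantics", {
  expect_equal(interpret_rmo(12.73), "inhibition_predominant")
  expect_equal(interpret_rmo(-8.99), "excitation_predominant")
  expect_equal(interpret_rmo(0), "balanced")
})

test_that("derive_indices composes the whole layer with per-index degeneracy", {
  b <- subject_battery(svmr_result(30, 200, 30), cvmr_result(30, 300, 40),
                       age = 25, sex = "F")
  di <- derive_indices(b)
  expect_equal(di$dmt, 100)
  expect_equal(di$isd, 2)
  expect_equal(di$isca, 2 / 3, tolerance = 1e-12)
  expect_true(di$valid)

  b0 <- subject_battery(svmr_result(30, 250, 30), cvmr_result(30, 250, 40),
                        age = 25, sex = "M")
  d0 <- derive_indices(b0)
  expect_equal(d0$dmt, 0)
  expect_true(is.na(d0$isd))
  expect_true(is.na(d0$isda))
  expect_false(is.na(d0$isca))     # degeneracy is per-index
  expect_false(d0$valid)
  expect_match(d0$reason, "ISD")

  expect_error(derive_indices(list()), class = "propcog_missing_component")
})

test_that("add_indices agrees with derive_indices row by row", {
  coh <- sample_cohort(small_config(seed = 3))
  tab <- coh$table
  for (i in c(1, 10, 25)) {
    di <- derive_indices(coh$batteries[[i]])
    expect_equal(tab$DMT[i], di$dmt)
    expect_equal(tab$ISCA[i], di$isca, tolerance = 1e-12)
    if (tab$ISD_valid[i]) expect_equal(tab$ISD[i], di$isd, tolerance = 1e-12)
  }
})

test_that("the CVMR error-definition switch changes only the accuracy terms", {
  tab <- sample_cohort(small_config(seed = 6))$table
  raw <- tab[setdiff(names(tab), c("DMT", "SVMR_IES", "CVMR_IES", "ISD",
                                   "ISDA", "ISCA", "TRVI", "AC", "ISD_valid"))]
  a_all <- add_indices(raw)
  a_fr <- add_indices(raw, cvmr_errors = "false_reactions")
  expect_equal(a_all$DMT, a_fr$DMT)
  expect_equal(a_all$ISD, a_fr$ISD)
  fr_err <- raw$CVMR_false_reaction / raw$CVMR_trialsNo
  expect_equal(a_fr$CVMR_IES, raw$CVMR_mean / (1 - fr_err), tolerance = 1e-12)
  changed <- raw$CVMR_false_reaction != raw$CVMR_mistakes
  expect_true(all(a_fr$ISCA[changed] != a_all$ISCA[changed]))
  expect_error(add_indices(raw[setdiff(names(raw), "CVMR_false_reaction")],
                           cvmr_errors = "false_reactions"),
               class = "propcog_missing_component")
})
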