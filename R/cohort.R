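# Synthetic POBA-like cohort generator.
#
# Marginal locations and scales are calibrated to the published group-level
# summaries (see poba_group_summaries()); the joint dependence between
# variables, which the publication does not report, is carried by two latent
# subject traits (general speed, error proneness) plus a shared session
# state. The methods vignette discusses every structural choice.

ln_sigma_for <- function(location, sd_target) {
  # sigma of a lognormal with given median and SD
  if (sd_target <= 0 || location <= 0) return(0)
  r <- sd_target / location
  uniroot(function(s) exp(s^2 / 2) * sqrt(exp(s^2) - 1) - r, c(1e-6, 3))$root
}

inv_g <- function(v) {
  # solve e^{s^2}(e^{s^2}-1) = v for s
  if (v <= 0) return(0)
  sqrt(log((1 + sqrt(1 + 4 * v)) / 2))
}

onesided_tail_sigma <- function(v) {
  # sigma of exp(s|z|) with variance v (relative to a unit median)
  if (v <= 0) return(0)
  f <- function(s) 2 * exp(2 * s^2) * pnorm(2 * s) -
    (2 * exp(s^2 / 2) * pnorm(s))^2 - v
  uniroot(f, c(1e-4, 3))$root
}

beta_shape_from <- function(mean_count, sd_count, trials) {
  # beta parameters of the per-subject error probability reproducing the
  # published mean and (overdispersed) SD of the mistake counts
  p <- mean_count / trials
  if (p <= 0) return(c(0, 0))
  binom_var <- trials * p * (1 - p)
  rho <- (sd_count^2 / binom_var - 1) / (trials - 1)
  rho <- max(1e-6, min(0.95, rho))
  s <- (1 - rho) / rho
  c(p * s, (1 - p) * s)
}

#' Parameters of one age stratum of the generator
#'
#' Marginal location/scale targets for one 20-year age group, in the units of
#' the feature table (ms for latencies, counts for mistakes, kgf for grip).
#' Under [default_config()] these come straight from the published group
#' summaries.
#'
#' @param name group label.
#' @param age_lo,age_hi half-open age range in years.
#' @param n_subjects subjects in the group (>= 1).
#' @param n_female female subjects (0..n_subjects).
#' @param svmr_mu,svmr_sigma location (median) and SD of the subject-level
#'   mean SVMR latency, ms.
#' @param svmr_within,svmr_within_sd location and SD of the within-subject
#'   trial SD of SVMR, ms.
#' @param cvmr_within,cvmr_within_sd same for CVMR.
#' @param dmt_mu,dmt_sigma median and SD of the decision-making-time offset, ms.
#' @param svmr_mist_mu,svmr_mist_sd mean and SD of SVMR mistake counts.
#' @param cvmr_mist_mu,cvmr_mist_sd mean and SD of CVMR mistake counts.
#' @param rmo_mu,rmo_sigma mean and SD of the subject-level RMO signed error, ms.
#' @param rmo_within within-subject trial SD of the RMO signed error, ms.
#' @param ast_mu,ast_sigma mean and SD of the attention-task latency, ms.
#' @param trvi_mu,trvi_sigma mean and SD of the interference cost, ms.
#' @param grip_mu,grip_sigma location and SD of right-wrist strength, kgf.
#' @param grip_sex_shift added to `grip_mu` for men, subtracted-half for
#'   women, kgf.
#' @param grip_ratio typical right/left strength ratio.
#' @return An object of class `group_params`.
#' @export
group_params <- function(name, age_lo, age_hi, n_subjects, n_female,
                         svmr_mu, svmr_sigma, svmr_within, svmr_within_sd,
                         cvmr_within, cvmr_within_sd, dmt_mu, dmt_sigma,
                         svmr_mist_mu, svmr_mist_sd, cvmr_mist_mu, cvmr_mist_sd,
                         rmo_mu, rmo_sigma, rmo_within,
                         ast_mu = 430, ast_sigma = 70,
                         trvi_mu = 110, trvi_sigma = 50,
                         grip_mu = 35, grip_sigma = 7,
                         grip_sex_shift = 8, grip_ratio = 1.07) {
  p <- as.list(environment())
  bad <- character()
  if (!is.numeric(n_subjects) || n_subjects < 1) bad <- c(bad, "n_subjects < 1")
  if (n_female < 0 || n_female > n_subjects) bad <- c(bad, "n_female outside 0..n_subjects")
  if (age_hi <= age_lo) bad <- c(bad, "empty age range")
  for (nm in grep("sigma|_sd$|within$", names(p), value = TRUE))
    if (is.numeric(p[[nm]]) && any(p[[nm]] < 0)) bad <- c(bad, paste(nm, "< 0"))
  if (svmr_mu <= 0 || dmt_mu <= 0) bad <- c(bad, "locations must be positive")
  if (length(bad))
    stop(errorCondition(paste("invalid group parameters:", paste(bad, collapse = "; ")),
                        class = c("propcog_invalid_config", "propcog_error")))
  structure(p, class = "group_params")
}

#' Default generator configuration (the published cohort structure)
#'
#' Four 20-year age strata with 48/64/64/55 subjects (sex ratios 19:29,
#' 36:28, 39:25, 40:15; total 231, ages 4-83), whose SVMR/CVMR/DMT/RMO and
#' mistake-count marginals are calibrated to the published group summaries.
#' Attention and grip parameters, which were not published, are fixed at
#' physiologically plausible values. The `structure` element carries the
#' latent-trait loadings and tail settings that shape the joint distribution;
#' see the methods vignette for their rationale.
#'
#' @param seed integer seed governing every random stream of the generator.
#' @param trials_per_test trials per test (default 30).
#' @param dmt_epsilon validity threshold on `|DMT|`, ms.
#' @return An object of class `generator_config`.
#' @export
#' @examples
#' cfg <- default_config(seed = 1)
#' sum(vapply(cfg$groups, `[[`, 0, "n_subjects"))  # 231
default_config <- function(seed = 1L, trials_per_test = 30L, dmt_epsilon = 1) {
  sizes <- poba_group_sizes()
  ref <- poba_group_summaries()
  val <- function(v, g, what = "location") ref[ref$variable == v & ref$group == g, what]
  ast <- c(Adolescents = 420, YoungAdults = 380, MidlifeAdults = 430, OlderAdults = 500)
  trv <- c(Adolescents = 120, YoungAdults = 90, MidlifeAdults = 100, OlderAdults = 140)
  grip <- c(Adolescents = 22, YoungAdults = 42, MidlifeAdults = 40, OlderAdults = 32)
  groups <- lapply(seq_len(nrow(sizes)), function(i) {
    g <- sizes$group[i]
    group_params(
      name = g, age_lo = sizes$lo[i], age_hi = sizes$hi[i],
      n_subjects = sizes$n[i], n_female = sizes$n_female[i],
      svmr_mu = val("SVMR_mean", g), svmr_sigma = val("SVMR_mean", g, "scale"),
      svmr_within = val("SVMR_variance", g),
      svmr_within_sd = val("SVMR_variance", g, "scale"),
      cvmr_within = val("CVMR_variance", g),
      cvmr_within_sd = val("CVMR_variance", g, "scale"),
      dmt_mu = val("DMT", g), dmt_sigma = val("DMT", g, "scale"),
      svmr_mist_mu = val("SVMR_mistakes", g),
      svmr_mist_sd = val("SVMR_mistakes", g, "scale"),
      cvmr_mist_mu = val("CVMR_mistakes", g),
      cvmr_mist_sd = val("CVMR_mistakes", g, "scale"),
      rmo_mu = val("RMO_mean", g), rmo_sigma = val("RMO_mean", g, "scale"),
      rmo_within = val("RMO_variance", g),
      ast_mu = ast[[g]], trvi_mu = trv[[g]], grip_mu = grip[[g]]
    )
  })
  structure(list(
    groups = groups,
    trials_per_test = as.integer(trials_per_test),
    seed = as.integer(seed),
    dmt_epsilon = dmt_epsilon,
    rmo_acc_window = 70,
    dmt_dist = "lognormal",
    structure = list(
      l_speed = 0.8,    # loading of the speed trait on the SVMR latent mean
      l_dmt = 0.5,      # loading of the speed trait on log DMT
      l_err = 0.8,      # loading of the error trait on both error rates
      l_feat = 0.6,     # loading of the speed trait on within-SDs / attention
      rho_session = 0.9,  # trial-noise correlation between SVMR and CVMR
      tail_frac = 0.10,   # share of subjects in the slow-DMT tail component
      dmt_core_sigma = 0.35,  # log-sd of the DMT core component
      svmr_core_cv = 0.10     # cv of the SVMR core component
    )
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  n <- vapply(x$groups, `[[`, 0, "n_subjects")
  cat(sprintf("<generator_config> %d groups, %d subjects, seed=%d, %d trials/test\n",
              length(x$groups), sum(n), x$seed, x$trials_per_test))
  invisible(x)
}

validate_config <- function(config) {
  bad <- character()
  if (!inherits(config, "generator_config")) bad <- c(bad, "not a generator_config")
  else {
    if (!length(config$groups)) bad <- c(bad, "no groups")
    if (length(config$groups) &&
        any(vapply(config$groups, `[[`, 0, "n_subjects") < 1))
      bad <- c(bad, "empty group")
    lo <- vapply(config$groups, `[[`, 0, "age_lo")
    hi <- vapply(config$groups, `[[`, 0, "age_hi")
    if (length(lo) > 1 && any(abs(hi[-length(hi)] - lo[-1]) > 1e-9))
      bad <- c(bad, "age ranges must tile contiguously")
    if (config$trials_per_test < 1) bad <- c(bad, "trials_per_test < 1")
    st <- config$structure
    for (nm in c("l_speed", "l_dmt", "l_err", "l_feat", "rho_session", "tail_frac"))
      if (st[[nm]] < 0 || st[[nm]] >= 1) bad <- c(bad, paste(nm, "outside [0, 1)"))
  }
  if (length(bad))
    stop(errorCondition(paste("invalid generator config:", paste(bad, collapse = "; ")),
                        class = c("propcog_invalid_config", "propcog_error")))
  invisible(config)
}

subject_seed <- function(seed, idx) {
  # deterministic per-subject substream, stable under reordering
  (as.numeric(seed) * 1009 + idx * 7919) %% 2147483629 + 1
}

draw_subject <- function(p, st, ntr, sseed, age, sex, rmo_window, dmt_dist) {
  set.seed(sseed)
  z_sp <- rnorm(1); z_er <- rnorm(1)
  mix <- function(lam) lam * z_sp + sqrt(1 - lam^2) * rnorm(1)
  mixe <- function(lam) lam * z_er + sqrt(1 - lam^2) * rnorm(1)

  # within-subject trial SDs, lognormal about the published location,
  # loaded on the speed trait (slower subjects are also more variable)
  sws <- ln_sigma_for(p$svmr_within, p$svmr_within_sd)
  cws <- ln_sigma_for(p$cvmr_within, p$cvmr_within_sd)
  zw <- mix(st$l_feat)
  sw <- p$svmr_within * exp(sws * zw)
  cw <- p$cvmr_within * exp(cws * zw)

  # subject latent mean SVMR: contaminated normal with a common-cv core
  Esw2 <- p$svmr_within^2 * exp(2 * sws^2)
  Ecw2 <- p$cvmr_within^2 * exp(2 * cws^2)
  Escw <- p$svmr_within * p$cvmr_within * exp((sws + cws)^2 / 2)
  svmr_lat_sd <- sqrt(max(p$svmr_sigma^2 - Esw2 / ntr, (0.25 * p$svmr_sigma)^2))
  core_sd <- st$svmr_core_cv * p$svmr_mu
  f <- st$tail_frac
  if (f <= 0 || core_sd^2 >= svmr_lat_sd^2) {
    sv_sig <- svmr_lat_sd
  } else {
    sv_tail_sd <- sqrt((svmr_lat_sd^2 - (1 - f) * core_sd^2) / f)
    sv_sig <- if (runif(1) < f) sv_tail_sd else core_sd
  }
  svmr_lat <- max(p$svmr_mu + sv_sig * mix(st$l_speed), 120)

  # DMT latent offset
  dmt_noise_var <- max(Esw2 + Ecw2 - 2 * st$rho_session * Escw, 0) / ntr
  dmt_lat_var <- max(p$dmt_sigma^2 - dmt_noise_var, 0)
  zmix <- mix(st$l_dmt)
  if (dmt_dist == "normal") {
    dmt_lat <- p$dmt_mu + sqrt(dmt_lat_var) * zmix
  } else {
    m2 <- p$dmt_mu^2
    core_var <- m2 * exp(st$dmt_core_sigma^2) * (exp(st$dmt_core_sigma^2) - 1)
    if (f <= 0 || core_var >= dmt_lat_var) {
      sig <- inv_g(dmt_lat_var / m2)
      dmt_lat <- p$dmt_mu * exp(sig * zmix)
    } else {
      tail_sig <- onesided_tail_sigma((dmt_lat_var - (1 - f) * core_var) / (f * m2))
      # keep the mixture median at the published location
      med_corr <- exp(-st$dmt_core_sigma * qnorm(0.5 / (1 - f)))
      m_adj <- p$dmt_mu * med_corr
      dmt_lat <- if (runif(1) < f) m_adj * exp(tail_sig * abs(zmix))
                 else m_adj * exp(st$dmt_core_sigma * zmix)
    }
  }
  cvmr_lat <- svmr_lat + dmt_lat

  # paired trial streams with shared session noise
  u <- rnorm(ntr)
  svmr_trials <- svmr_lat + sw * (sqrt(st$rho_session) * u +
                                    sqrt(1 - st$rho_session) * rnorm(ntr))
  cvmr_trials <- cvmr_lat + cw * (sqrt(st$rho_session) * u +
                                    sqrt(1 - st$rho_session) * rnorm(ntr))

  # per-subject error probabilities: beta marginals (dispersion solved from
  # the published mistake SDs) under a shared error-proneness trait
  draw_p <- function(mu, sd) {
    if (mu <= 0) return(0)
    ab <- beta_shape_from(mu, sd, ntr)
    min(qbeta(pnorm(mixe(st$l_err)), ab[1], ab[2]), 0.6)
  }
  sp <- draw_p(p$svmr_mist_mu, p$svmr_mist_sd)
  cp <- draw_p(p$cvmr_mist_mu, p$cvmr_mist_sd)
  svmr_mist <- rbinom(1, ntr, sp)
  cvmr_mist <- rbinom(1, ntr, cp)
  svmr_pass <- rbinom(1, svmr_mist, 0.7)
  cvmr_fr <- rbinom(1, cvmr_mist, 0.45)
  cvmr_pass <- rbinom(1, cvmr_mist - cvmr_fr, 0.6)

  # RMO: signed timing errors over ntr trials
  rmo_lat_sd <- sqrt(max(p$rmo_sigma^2 - p$rmo_within^2 / ntr, 0))
  rmo_lat <- p$rmo_mu + rmo_lat_sd * rnorm(1)
  rmo_err <- rmo_lat + p$rmo_within * rnorm(ntr)
  delays <- sum(rmo_err > rmo_window)
  rmo_fs <- sum(rmo_err < -rmo_window)

  ast <- max(p$ast_mu + p$ast_sigma * mix(st$l_feat + 0.1), 150)
  trvi <- p$trvi_mu + p$trvi_sigma * mix(0.4)
  grip_mu <- p$grip_mu + if (identical(sex, "M")) p$grip_sex_shift else -p$grip_sex_shift / 2
  wdr <- max(rnorm(1, grip_mu, p$grip_sigma), 5)
  wdl <- max(wdr / p$grip_ratio + rnorm(1, 0, 0.3 * p$grip_sigma), 5)

  svmr <- svmr_result(ntr, mean(svmr_trials), sd(svmr_trials),
                      passes = svmr_pass, falstarts = svmr_mist - svmr_pass)
  cvmr <- cvmr_result(ntr, mean(cvmr_trials), sd(cvmr_trials),
                      passes = cvmr_pass,
                      falstarts = cvmr_mist - cvmr_fr - cvmr_pass,
                      false_reactions = cvmr_fr)
  rmo <- rmo_result(ntr, mean(rmo_err), sd(rmo_err),
                    delays = delays, falstarts = rmo_fs,
                    accurate = ntr - delays - rmo_fs,
                    delays_total_time = sum(rmo_err[rmo_err > rmo_window]),
                    falstart_total_time = sum(-rmo_err[rmo_err < -rmo_window]),
                    positive_sum = sum(rmo_err[rmo_err > 0]))
  subject_battery(svmr, cvmr, rmo,
                  attention_result(ast, ast + trvi),
                  dynamometry_result(wdr, wdl),
                  age = age, sex = sex)
}

battery_row <- function(b) {
  data.frame(
    age = b$age, sex = b$sex,
    SVMR_trialsNo = b$svmr$trials_no, SVMR_mean = b$svmr$mean_rt,
    SVMR_variance = b$svmr$rt_sd, SVMR_mistakes = b$svmr$mistakes,
    SVMR_passes = b$svmr$passes, SVMR_falstart = b$svmr$falstarts,
    CVMR_trialsNo = b$cvmr$trials_no, CVMR_mean = b$cvmr$mean_rt,
    CVMR_variance = b$cvmr$rt_sd, CVMR_mistakes = b$cvmr$mistakes,
    CVMR_passes = b$cvmr$passes, CVMR_falstart = b$cvmr$falstarts,
    CVMR_false_reaction = b$cvmr$false_reactions,
    RMO_trialsNo = b$rmo$trials_no, RMO_mean = b$rmo$mean_signed,
    RMO_variance = b$rmo$rt_sd, RMO_errors = b$rmo$errors,
    RMO_delays = b$rmo$delays, RMO_falstart = b$rmo$falstarts,
    RMO_acc = b$rmo$accurate,
    RMO_delaysTotalTime = b$rmo$delays_total_time,
    RMO_falstartTotalTime = b$rmo$falstart_total_time,
    RMO_positiveSum = b$rmo$positive_sum,
    AST_mean = b$attention$ast_mean, IRT_mean = b$attention$irt_mean,
    WDR_MMS = b$dynamometry$wdr_mms, WDL_MMS = b$dynamometry$wdl_mms,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic POBA-like cohort
#'
#' Realises every subject at trial level (30 reaction times per test with
#' Bernoulli mistake events, RMO signed timing errors), so the summary
#' columns (means, SDs, mistake counts) are mutually consistent, then
#' appends the derived index columns. The same seed always yields the same
#' table, and each subject draws from its own deterministic substream.
#'
#' @param config a [generator_config][default_config()].
#' @return An object of class `poba_cohort`: list with `table` (feature
#'   data.frame in the POBA dialect, derived columns appended), `batteries`
#'   (list of [subject_battery()]), `config`, and `n_invalid_isd` (subjects
#'   whose `|DMT|` fell below `dmt_epsilon`).
#' @export
#' @examples
#' coh <- sample_cohort(default_config(seed = 42))
#' nrow(coh$table)  # 231
sample_cohort <- function(config) {
  validate_config(config)
  ntr <- config$trials_per_test
  st <- config$structure
  batteries <- list()
  idx <- 0L
  for (gi in seq_along(config$groups)) {
    p <- config$groups[[gi]]
    n <- p$n_subjects
    set.seed(subject_seed(config$seed, -gi))  # group stream: ages and sexes
    ages <- runif(n, p$age_lo, p$age_hi)
    sexes <- sample(rep(c("F", "M"), c(p$n_female, n - p$n_female)))
    for (j in seq_len(n)) {
      idx <- idx + 1L
      b <- draw_subject(p, st, ntr, subject_seed(config$seed, idx),
                        ages[j], sexes[j], config$rmo_acc_window, config$dmt_dist)
      b$id <- sprintf("S%03d", idx)
      b$group <- p$name
      batteries[[idx]] <- b
    }
  }
  tab <- do.call(rbind, lapply(batteries, battery_row))
  tab <- cbind(subject_id = vapply(batteries, `[[`, "", "id"),
               group = vapply(batteries, `[[`, "", "group"), tab,
               stringsAsFactors = FALSE)
  tab <- add_indices(tab, dmt_epsilon = config$dmt_epsilon)
  structure(list(table = tab, batteries = batteries, config = config,
                 n_invalid_isd = sum(!tab$ISD_valid)),
            class = "poba_cohort")
}

#' @export
print.poba_cohort <- function(x, ...) {
  cat(sprintf("<poba_cohort> %d subjects in %d groups (seed %d); %d invalid ISD\n",
              nrow(x$table), length(unique(x$table$group)),
              x$config$seed, x$n_invalid_isd))
  invisible(x)
}

#' Calibration z-scores of a generated cohort
#'
#' Compares per-group realised moments against the generator's own targets:
#' `z = (realised - target) / SE`. Location variables are compared on the
#' scale on which they were calibrated (mean for SVMR/RMO/mistakes, median
#' for the DMT offset). Exactly-degenerate cells (zero target scale and zero
#' deviation) report `z = 0`.
#'
#' @param table feature table from [sample_cohort()].
#' @param config the [generator_config][default_config()] that produced it.
#' @return data.frame with `group`, `variable`, `realized`, `target`, `z`.
#' @export
calibration_report <- function(table, config) {
  validate_config(config)
  rows <- list()
  for (p in config$groups) {
    sub <- table[table$group == p$name, ]
    if (!nrow(sub))
      stop_degenerate(sprintf("group '%s' is empty", p$name))
    n <- nrow(sub)
    cell <- function(variable, realized, target, scale, median_based = FALSE) {
      se <- scale / sqrt(n) * if (median_based) sqrt(pi / 2) else 1
      dev <- realized - target
      z <- if (se > 0) dev / se else if (abs(dev) < 1e-9) 0 else sign(dev) * Inf
      data.frame(group = p$name, variable = variable, realized = realized,
                 target = target, z = z, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- rbind(
      cell("SVMR_mean", mean(sub$SVMR_mean), p$svmr_mu, p$svmr_sigma),
      cell("DMT", median(sub$DMT), p$dmt_mu, p$dmt_sigma, median_based = TRUE),
      cell("SVMR_mistakes", mean(sub$SVMR_mistakes), p$svmr_mist_mu, p$svmr_mist_sd),
      cell("CVMR_mistakes", mean(sub$CVMR_mistakes), p$cvmr_mist_mu, p$cvmr_mist_sd),
      cell("RMO_mean", mean(sub$RMO_mean), p$rmo_mu, p$rmo_sigma)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort to disk (CSV + JSON provenance sidecar)
#'
#' Emits the feature table as UTF-8 CSV (`.` decimal separator, no thousands
#' separators) and the full generator configuration as a JSON sidecar next
#' to it, so any table can be regenerated.
#'
#' @param cohort a [sample_cohort()] result.
#' @param path CSV path; the sidecar is written to `<path>.config.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "poba_cohort"))
  write_feature_table(cohort$table, path)
  cfg <- cohort$config
  cfg$groups <- lapply(cfg$groups, unclass)
  jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @param table a feature data.frame.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Read a POBA-dialect feature table
#'
#' @param path CSV path.
#' @param add_indices append derived-index columns when absent?
#' @return data.frame.
#' @export
read_feature_table <- function(path, add_indices = FALSE) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (add_indices && !"ISCA" %in% names(tab)) tab <- add_indices(tab)
  tab
}
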