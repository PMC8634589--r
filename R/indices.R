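# Derived quantities of the battery: DMT, IES, the proportionality indices
# ISD / ISDA / ISCA, the attention interference cost TRVI and the grip
# asymmetry coefficient AC.

#' Fraction of trials that went wrong
#'
#' @param result an [svmr_result()] or [cvmr_result()], or a list with
#'   `mistakes` and `trials_no` fields.
#' @return `mistakes / trials_no`, a fraction in `[0, 1]`.
#' @export
#' @examples
#' error_fraction(svmr_result(30, 250, 40, passes = 2, falstarts = 1))
error_fraction <- function(result) {
  if (is.null(result$trials_no) || is.null(result$mistakes))
    stop_degenerate("result must carry 'mistakes' and 'trials_no'")
  if (result$trials_no < 1) stop_degenerate("trials_no must be >= 1")
  result$mistakes / result$trials_no
}

#' Decision-making time
#'
#' The latency cost of response selection: mean go/no-go (CVMR) latency minus
#' mean simple-reaction (SVMR) latency. May be zero or negative for subjects
#' whose choice reaction was not slower.
#'
#' @param svmr_mean,cvmr_mean mean latencies, ms.
#' @return DMT in ms (vectorised).
#' @export
#' @examples
#' compute_dmt(260.51, 360.77)  # 100.26
compute_dmt <- function(svmr_mean, cvmr_mean) {
  stopifnot(is.numeric(svmr_mean), is.numeric(cvmr_mean))
  cvmr_mean - svmr_mean
}

#' Inverse efficiency score
#'
#' Mean reaction time divided by the fraction of correct trials,
#' `IES = mean_rt / (1 - error_fraction)`. Undefined when every trial went
#' wrong.
#'
#' @param mean_rt mean reaction time, ms.
#' @param err error fraction in `[0, 1)`.
#' @return IES in ms (vectorised); always `>= mean_rt`.
#' @export
compute_ies <- function(mean_rt, err) {
  if (any(err < 0 | err >= 1, na.rm = TRUE))
    stop(errorCondition("IES undefined: error fraction must lie in [0, 1)",
                        class = c("propcog_undefined_ies", "propcog_error")))
  mean_rt / (1 - err)
}

#' Attention interference cost (TRVI)
#'
#' Latency added by visual distractors: mean interference-task response time
#' minus mean plain attention-task response time.
#'
#' @param irt_mean,ast_mean mean response times, ms.
#' @return TRVI in ms.
#' @export
compute_trvi <- function(irt_mean, ast_mean) irt_mean - ast_mean

#' Grip asymmetry coefficient
#'
#' Ratio of right to left maximum wrist strength.
#'
#' @param wdr,wdl maximum muscular strength of the right / left wrist, kgf.
#' @return AC (dimensionless).
#' @export
compute_ac <- function(wdr, wdl) {
  if (any(wdl <= 0, na.rm = TRUE)) stop_degenerate("left-wrist strength must be > 0")
  wdr / wdl
}

#' Index of simple reaction time to decision-making time (ISD)
#'
#' `ISD = SVMR_mean / DMT`. Near-zero DMT makes the ratio meaningless, so
#' when `|DMT| < dmt_epsilon` the result is flagged invalid rather than
#' returned as a huge or infinite value.
#'
#' @param svmr_mean mean simple-reaction latency, ms.
#' @param dmt decision-making time, ms.
#' @param dmt_epsilon validity threshold on `|DMT|`, ms (default 1).
#' @return A list with `value` (NA when invalid), `valid`, `reason`.
#' @export
#' @examples
#' compute_isd(200, 50)$value   # 4
#' compute_isd(200, 0)$valid    # FALSE
compute_isd <- function(svmr_mean, dmt, dmt_epsilon = 1) {
  if (!is.finite(dmt) || abs(dmt) < dmt_epsilon) {
    return(list(value = NA_real_, valid = FALSE,
                reason = sprintf("|DMT| below %g ms", dmt_epsilon)))
  }
  list(value = svmr_mean / dmt, valid = TRUE, reason = NA_character_)
}

#' ISD with accuracy adjustment (ISDA)
#'
#' `ISDA = SVMR_mean / (DMT * (1 - CVMR error fraction))`. Reduces to ISD for
#' an error-free go/no-go performance.
#'
#' @inheritParams compute_isd
#' @param cvmr_err CVMR error fraction in `[0, 1)`.
#' @return A list with `value`, `valid`, `reason`.
#' @export
compute_isda <- function(svmr_mean, dmt, cvmr_err, dmt_epsilon = 1) {
  if (!is.finite(cvmr_err) || cvmr_err < 0 || cvmr_err >= 1) {
    return(list(value = NA_real_, valid = FALSE,
                reason = "CVMR error fraction outside [0, 1)"))
  }
  base <- compute_isd(svmr_mean, dmt, dmt_epsilon)
  if (!base$valid) return(base)
  list(value = base$value / (1 - cvmr_err), valid = TRUE, reason = NA_character_)
}

#' Index of simple-to-complex performance with account for accuracy (ISCA)
#'
#' The ratio of the two inverse efficiency scores,
#' `ISCA = IES(SVMR) / IES(CVMR)`, which expands to
#' `SVMR_mean * (1 - cvmr_err) / (CVMR_mean * (1 - svmr_err))`.
#'
#' @param svmr_mean,cvmr_mean mean latencies, ms.
#' @param svmr_err,cvmr_err error fractions in `[0, 1)`.
#' @return A list with `value`, `valid`, `reason`.
#' @export
compute_isca <- function(svmr_mean, svmr_err, cvmr_mean, cvmr_err) {
  if (!is.finite(cvmr_mean) || cvmr_mean <= 0)
    return(list(value = NA_real_, valid = FALSE, reason = "CVMR mean not positive"))
  if (any(!is.finite(c(svmr_err, cvmr_err))) ||
      svmr_err < 0 || svmr_err >= 1 || cvmr_err < 0 || cvmr_err >= 1)
    return(list(value = NA_real_, valid = FALSE,
                reason = "error fraction outside [0, 1)"))
  list(value = (svmr_mean * (1 - cvmr_err)) / (cvmr_mean * (1 - svmr_err)),
       valid = TRUE, reason = NA_character_)
}

#' Nervous-process mobility category from SVMR latency
#'
#' Bins the mean simple-reaction latency into the conventional five mobility
#' categories. Bins are half-open and lower-inclusive:
#' `[0,177) [177,200) [200,210) [210,233) [233,Inf)` ms.
#'
#' @param svmr_mean mean SVMR latency, ms (> 0); vectorised.
#' @return A factor with levels `pronounced_mobility`, `mobile`, `average`,
#'   `inertial`, `pronounced_inertia`.
#' @export
#' @examples
#' classify_mobility(c(150, 190, 205, 220, 233))
classify_mobility <- function(svmr_mean) {
  if (any(!is.finite(svmr_mean) | svmr_mean <= 0))
    stop_degenerate("SVMR mean latency must be positive")
  lev <- c("pronounced_mobility", "mobile", "average", "inertial", "pronounced_inertia")
  cut(svmr_mean, breaks = c(0, 177, 200, 210, 233, Inf),
      labels = lev, right = FALSE)
}

#' Excitation/inhibition balance from the RMO mean
#'
#' A positive mean signed timing error indicates predominance of inhibition
#' (late responding), a negative one predominance of excitation (premature
#' responding); an exact zero is balanced.
#'
#' @param rmo_mean mean signed RMO timing error, ms; vectorised.
#' @return Character vector with values `inhibition_predominant`,
#'   `excitation_predominant`, `balanced`.
#' @export
interpret_rmo <- function(rmo_mean) {
  stopifnot(all(is.finite(rmo_mean)))
  ifelse(abs(rmo_mean) < 1e-9, "balanced",
         ifelse(rmo_mean > 0, "inhibition_predominant", "excitation_predominant"))
}

#' Derive all indices for one subject
#'
#' Composes the full index layer from a [subject_battery()]: DMT, both IES
#' values, ISD, ISDA, ISCA, and — when the attention and dynamometry tests
#' are present — TRVI and AC. Degeneracy is handled per index: a subject with
#' near-zero DMT has invalid ISD/ISDA but may still have a perfectly valid
#' ISCA.
#'
#' @param battery a [subject_battery()].
#' @param dmt_epsilon validity threshold on `|DMT|`, ms.
#' @return An object of class `derived_indices`: a list with `dmt`,
#'   `svmr_ies`, `cvmr_ies`, `isd`, `isda`, `isca`, `trvi`, `ac`, `valid`
#'   (TRUE when every index is defined) and `reason`.
#' @export
derive_indices <- function(battery, dmt_epsilon = 1) {
  if (!inherits(battery, "subject_battery"))
    stop(errorCondition("'battery' must be a subject_battery",
                        class = c("propcog_missing_component", "propcog_error")))
  s_err <- error_fraction(battery$svmr)
  c_err <- error_fraction(battery$cvmr)
  dmt <- compute_dmt(battery$svmr$mean_rt, battery$cvmr$mean_rt)
  svmr_ies <- if (s_err < 1) compute_ies(battery$svmr$mean_rt, s_err) else NA_real_
  cvmr_ies <- if (c_err < 1) compute_ies(battery$cvmr$mean_rt, c_err) else NA_real_
  isd <- compute_isd(battery$svmr$mean_rt, dmt, dmt_epsilon)
  isda <- compute_isda(battery$svmr$mean_rt, dmt, c_err, dmt_epsilon)
  isca <- compute_isca(battery$svmr$mean_rt, s_err, battery$cvmr$mean_rt, c_err)
  trvi <- if (!is.null(battery$attention))
    compute_trvi(battery$attention$irt_mean, battery$attention$ast_mean) else NA_real_
  ac <- if (!is.null(battery$dynamometry))
    compute_ac(battery$dynamometry$wdr_mms, battery$dynamometry$wdl_mms) else NA_real_
  invalid <- c(
    if (!isd$valid) paste("ISD:", isd$reason),
    if (!isda$valid) paste("ISDA:", isda$reason),
    if (!isca$valid) paste("ISCA:", isca$reason)
  )
  structure(list(
    dmt = dmt, svmr_ies = svmr_ies, cvmr_ies = cvmr_ies,
    isd = isd$value, isda = isda$value, isca = isca$value,
    trvi = trvi, ac = ac,
    valid = length(invalid) == 0,
    reason = if (length(invalid)) paste(invalid, collapse = "; ") else NA_character_
  ), class = "derived_indices")
}

#' @export
print.derived_indices <- function(x, ...) {
  cat(sprintf("<derived_indices> DMT=%.2f ISD=%.3f ISDA=%.3f ISCA=%.3f valid=%s\n",
              x$dmt, x$isd, x$isda, x$isca, x$valid))
  if (!x$valid) cat("  ", x$reason, "\n")
  invisible(x)
}

#' Append derived-index columns to a POBA feature table
#'
#' Takes a feature table in the POBA column dialect and appends `DMT`,
#' `SVMR_IES`, `CVMR_IES`, `ISD`, `ISDA`, `ISCA`, plus `TRVI` and `AC` when
#' the corresponding raw columns are present, and the `ISD_valid` flag
#' column. Subjects with `|DMT|` below `dmt_epsilon` get `NA` for ISD/ISDA
#' and `ISD_valid = FALSE`.
#'
#' @param table data.frame with at least `SVMR_mean`, `CVMR_mean`,
#'   `SVMR_mistakes`, `CVMR_mistakes` and a trial count (`SVMR_trialsNo`, or
#'   `trials_no` via the `trials` argument).
#' @param trials trial count per test used for error fractions, when the
#'   table has no `SVMR_trialsNo`/`CVMR_trialsNo` columns (default 30).
#' @param dmt_epsilon validity threshold on `|DMT|`, ms.
#' @param cvmr_errors which CVMR errors enter the accuracy terms of ISDA and
#'   ISCA: `"all"` (passes + false starts + false reactions, the default) or
#'   `"false_reactions"` (only wrong-colour responses, the convention of much
#'   of the go/no-go literature; requires the `CVMR_false_reaction` column).
#' @return The table with derived columns appended.
#' @export
add_indices <- function(table, trials = 30, dmt_epsilon = 1,
                        cvmr_errors = c("all", "false_reactions")) {
  cvmr_errors <- match.arg(cvmr_errors)
  need <- c("SVMR_mean", "CVMR_mean", "SVMR_mistakes", "CVMR_mistakes")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(errorCondition(paste("feature table lacks columns:", paste(miss, collapse = ", ")),
                        class = c("propcog_missing_component", "propcog_error")))
  s_tr <- if ("SVMR_trialsNo" %in% names(table)) table$SVMR_trialsNo else trials
  c_tr <- if ("CVMR_trialsNo" %in% names(table)) table$CVMR_trialsNo else trials
  s_err <- table$SVMR_mistakes / s_tr
  c_err <- if (cvmr_errors == "false_reactions") {
    if (!"CVMR_false_reaction" %in% names(table))
      stop(errorCondition("cvmr_errors = 'false_reactions' needs CVMR_false_reaction",
                          class = c("propcog_missing_component", "propcog_error")))
    table$CVMR_false_reaction / c_tr
  } else table$CVMR_mistakes / c_tr
  if (any(s_err >= 1 | c_err >= 1, na.rm = TRUE))
    stop(errorCondition("a subject has an error fraction of 1: IES undefined",
                        class = c("propcog_undefined_ies", "propcog_error")))
  table$DMT <- compute_dmt(table$SVMR_mean, table$CVMR_mean)
  table$SVMR_IES <- compute_ies(table$SVMR_mean, s_err)
  table$CVMR_IES <- compute_ies(table$CVMR_mean, c_err)
  ok <- is.finite(table$DMT) & abs(table$DMT) >= dmt_epsilon
  table$ISD <- ifelse(ok, table$SVMR_mean / table$DMT, NA_real_)
  table$ISDA <- ifelse(ok, table$SVMR_mean / (table$DMT * (1 - c_err)), NA_real_)
  table$ISCA <- (table$SVMR_mean * (1 - c_err)) / (table$CVMR_mean * (1 - s_err))
  if (all(c("IRT_mean", "AST_mean") %in% names(table)))
    table$TRVI <- compute_trvi(table$IRT_mean, table$AST_mean)
  if (all(c("WDR_MMS", "WDL_MMS") %in% names(table)))
    table$AC <- compute_ac(table$WDR_MMS, table$WDL_MMS)
  table$ISD_valid <- ok
  table
}
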