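# Battery result containers. Each constructor validates the counting
# invariants of its test so downstream index code can assume them.

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("propcog_degenerate_input", "propcog_error")))
}

check_count <- function(x, name, min = 0) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    stop_degenerate(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

#' Simple visual-motor reaction (SVMR) summary
#'
#' One subject's summary of the simple reaction task: a single stimulus type
#' with a single response, repeated over (typically 30) trials. Mistakes are
#' either missed stimuli (passes) or premature responses (false starts), and
#' the constructor enforces `mistakes = passes + falstarts <= trials_no`.
#'
#' @param trials_no number of trials (>= 1).
#' @param mean_rt mean reaction time, ms (> 0).
#' @param rt_sd trial-to-trial SD of the reaction time, ms (>= 0).
#' @param passes missed stimuli (count).
#' @param falstarts premature responses (count).
#' @return An object of class `svmr_result`.
#' @export
svmr_result <- function(trials_no, mean_rt, rt_sd, passes = 0, falstarts = 0) {
  trials_no <- check_count(trials_no, "trials_no", min = 1)
  passes <- check_count(passes, "passes")
  falstarts <- check_count(falstarts, "falstarts")
  if (!is.finite(mean_rt) || mean_rt <= 0) stop_degenerate("'mean_rt' must be > 0")
  if (!is.finite(rt_sd) || rt_sd < 0) stop_degenerate("'rt_sd' must be >= 0")
  mistakes <- passes + falstarts
  if (mistakes > trials_no)
    stop_degenerate("mistakes (passes + falstarts) exceed trials_no")
  structure(list(trials_no = trials_no, mean_rt = mean_rt, rt_sd = rt_sd,
                 passes = passes, falstarts = falstarts, mistakes = mistakes),
            class = "svmr_result")
}

#' Complex visual-motor reaction (CVMR, go/no-go) summary
#'
#' Adds the inhibitory condition: besides passes and false starts, the
#' subject can respond to the no-go stimulus (a false reaction). The
#' constructor enforces
#' `mistakes = passes + falstarts + false_reactions <= trials_no`.
#'
#' @inheritParams svmr_result
#' @param false_reactions responses to the no-go stimulus (count).
#' @return An object of class `cvmr_result`.
#' @export
cvmr_result <- function(trials_no, mean_rt, rt_sd, passes = 0, falstarts = 0,
                        false_reactions = 0) {
  trials_no <- check_count(trials_no, "trials_no", min = 1)
  passes <- check_count(passes, "passes")
  falstarts <- check_count(falstarts, "falstarts")
  false_reactions <- check_count(false_reactions, "false_reactions")
  if (!is.finite(mean_rt) || mean_rt <= 0) stop_degenerate("'mean_rt' must be > 0")
  if (!is.finite(rt_sd) || rt_sd < 0) stop_degenerate("'rt_sd' must be >= 0")
  mistakes <- passes + falstarts + false_reactions
  if (mistakes > trials_no) stop_degenerate("mistakes exceed trials_no")
  structure(list(trials_no = trials_no, mean_rt = mean_rt, rt_sd = rt_sd,
                 passes = passes, falstarts = falstarts,
                 false_reactions = false_reactions, mistakes = mistakes),
            class = "cvmr_result")
}

#' Reaction to a moving object (RMO) summary
#'
#' Anticipatory timing task: the subject responds at the moment a moving
#' target crosses a finish line. Late responses are recorded as positive
#' timing errors (delays), premature ones as negative (false starts);
#' responses within the accuracy window count as accurate. The constructor
#' enforces `delays + falstarts + accurate = trials_no`.
#'
#' @param trials_no number of trials.
#' @param mean_signed mean signed timing error, ms (positive values indicate
#'   predominance of inhibition, negative of excitation).
#' @param rt_sd SD of the signed timing error, ms.
#' @param delays,falstarts,accurate trial counts by outcome.
#' @param delays_total_time,falstart_total_time,positive_sum summed timing
#'   errors, ms.
#' @return An object of class `rmo_result`.
#' @export
rmo_result <- function(trials_no, mean_signed, rt_sd, delays, falstarts,
                       accurate, delays_total_time = NA_real_,
                       falstart_total_time = NA_real_, positive_sum = NA_real_) {
  trials_no <- check_count(trials_no, "trials_no", min = 1)
  delays <- check_count(delays, "delays")
  falstarts <- check_count(falstarts, "falstarts")
  accurate <- check_count(accurate, "accurate")
  if (delays + falstarts + accurate != trials_no)
    stop_degenerate("delays + falstarts + accurate must equal trials_no")
  if (!is.finite(mean_signed)) stop_degenerate("'mean_signed' must be finite")
  if (!is.finite(rt_sd) || rt_sd < 0) stop_degenerate("'rt_sd' must be >= 0")
  structure(list(trials_no = trials_no, mean_signed = mean_signed, rt_sd = rt_sd,
                 delays = delays, falstarts = falstarts, accurate = accurate,
                 errors = delays + falstarts,
                 delays_total_time = delays_total_time,
                 falstart_total_time = falstart_total_time,
                 positive_sum = positive_sum),
            class = "rmo_result")
}

#' Attention test summary (AST / IRT)
#'
#' @param ast_mean mean response time of the plain attention task, ms (> 0).
#' @param irt_mean mean response time of the interference-resilience task
#'   (same task with distractors), ms (> 0).
#' @return An object of class `attention_result`.
#' @export
attention_result <- function(ast_mean, irt_mean) {
  if (!is.finite(ast_mean) || ast_mean <= 0) stop_degenerate("'ast_mean' must be > 0")
  if (!is.finite(irt_mean) || irt_mean <= 0) stop_degenerate("'irt_mean' must be > 0")
  structure(list(ast_mean = ast_mean, irt_mean = irt_mean),
            class = "attention_result")
}

#' Wrist dynamometry summary
#'
#' @param wdr_mms maximum muscular strength of the right wrist, kgf (> 0).
#' @param wdl_mms maximum muscular strength of the left wrist, kgf (> 0).
#' @return An object of class `dynamometry_result`.
#' @export
dynamometry_result <- function(wdr_mms, wdl_mms) {
  if (!is.finite(wdr_mms) || wdr_mms <= 0) stop_degenerate("'wdr_mms' must be > 0")
  if (!is.finite(wdl_mms) || wdl_mms <= 0) stop_degenerate("'wdl_mms' must be > 0")
  structure(list(wdr_mms = wdr_mms, wdl_mms = wdl_mms),
            class = "dynamometry_result")
}

#' Full per-subject battery
#'
#' Bundles the five test summaries of one subject together with age and sex.
#'
#' @param svmr,cvmr,rmo,attention,dynamometry results from the respective
#'   constructors.
#' @param age years (>= 0).
#' @param sex `"F"` or `"M"`.
#' @param id optional subject identifier.
#' @return An object of class `subject_battery`.
#' @export
subject_battery <- function(svmr, cvmr, rmo = NULL, attention = NULL,
                            dynamometry = NULL, age = NA_real_, sex = NA_character_,
                            id = NA_character_) {
  for (nm in c("svmr", "cvmr")) {
    obj <- get(nm)
    if (is.null(obj))
      stop(errorCondition(sprintf("missing battery component '%s'", nm),
                          class = c("propcog_missing_component", "propcog_error")))
  }
  stopifnot(inherits(svmr, "svmr_result"), inherits(cvmr, "cvmr_result"))
  if (!is.null(rmo)) stopifnot(inherits(rmo, "rmo_result"))
  if (!is.null(attention)) stopifnot(inherits(attention, "attention_result"))
  if (!is.null(dynamometry)) stopifnot(inherits(dynamometry, "dynamometry_result"))
  if (is.finite(age) && age < 0) stop_degenerate("'age' must be >= 0")
  structure(list(id = id, age = age, sex = sex, svmr = svmr, cvmr = cvmr,
                 rmo = rmo, attention = attention, dynamometry = dynamometry),
            class = "subject_battery")
}

#' @export
print.subject_battery <- function(x, ...) {
  cat(sprintf("<subject_battery> id=%s age=%.1f sex=%s\n", x$id, x$age, x$sex))
  cat(sprintf("  SVMR %.1f ms (%d/%d mistakes); CVMR %.1f ms (%d/%d mistakes)\n",
              x$svmr$mean_rt, x$svmr$mistakes, x$svmr$trials_no,
              x$cvmr$mean_rt, x$cvmr$mistakes, x$cvmr$trials_no))
  invisible(x)
}
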