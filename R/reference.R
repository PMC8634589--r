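#' Published group-level summaries of the POBA cohort
#'
#' Group-level descriptive statistics of the POBA battery as published for the
#' 231-subject cohort (location is the printed median, scale the printed SD).
#' These numbers serve two purposes: they are the calibration targets of the
#' synthetic-cohort generator ([default_config()]), and they are the inputs of
#' the worked arithmetic examples (e.g. recovering the printed decision-making
#' time from the printed SVMR and CVMR latencies).
#'
#' @return A data.frame with one row per (variable, group) cell. Columns:
#'   `variable` (POBA variable name), `group` (one of `"Total"`,
#'   `"Adolescents"`, `"YoungAdults"`, `"MidlifeAdults"`, `"OlderAdults"`),
#'   `location` (printed median), `scale` (printed SD; `NA` for the Total
#'   column, where an interquartile range was printed instead).
#' @seealso [poba_sex_summaries()] for the sex-stratified table,
#'   [poba_group_sizes()] for cohort composition.
#' @export
#' @examples
#' ref <- poba_group_summaries()
#' subset(ref, variable == "SVMR_mean")
poba_group_summaries <- function() {
  g <- c("Adolescents", "YoungAdults", "MidlifeAdults", "OlderAdults")
  row <- function(variable, total, loc, sc) {
    rbind(
      data.frame(variable = variable, group = "Total", location = total,
                 scale = NA_real_, stringsAsFactors = FALSE),
      data.frame(variable = variable, group = g, location = loc, scale = sc,
                 stringsAsFactors = FALSE)
    )
  }
  out <- rbind(
    row("SVMR_mean",     260.51, c(282.03, 221.03, 259.76, 288.52), c(70.91, 28.92, 55.48, 53.75)),
    row("SVMR_variance",  69.88, c(89.01, 49.41, 67.69, 79.54),     c(73.36, 22.39, 36.54, 42.92)),
    row("SVMR_mistakes",   1.32, c(2.69, 0.83, 0.62, 1.49),         c(3.83, 1.32, 1.11, 1.54)),
    row("SVMR_IES",      280.06, c(339.43, 227.9, 265.77, 305.56),  c(236.3, 32.9, 59.02, 64.35)),
    row("CVMR_mean",     360.77, c(360.8, 324.89, 362.64, 400.32),  c(107.74, 56.55, 65.15, 71.9)),
    row("CVMR_variance", 108.91, c(121.55, 91.82, 92.65, 136.69),   c(94.58, 80.43, 30.46, 74.86)),
    row("CVMR_mistakes",   2.87, c(3.65, 2.58, 2.14, 3.4),          c(2.45, 2.81, 1.75, 2.26)),
    row("CVMR_IES",      402.91, c(416.17, 359.93, 390.66, 455.62), c(143.57, 81.36, 66.29, 95.44)),
    row("DMT",           100.26, c(78.76, 103.86, 102.88, 111.79),  c(52.97, 48.64, 51.65, 57.81)),
    row("RMO_mean",        0.32, c(-8.99, -2.14, 12.73, -3.12),     c(69.28, 54.25, 104.22, 75.59)),
    row("RMO_variance",  167.86, c(168.85, 111.84, 158.75, 242.81), c(103.5, 67.33, 93.83, 105.18)),
    row("RMO_errors",     20.95, c(19.96, 18.14, 22.22, 23.62),     c(5.22, 4.14, 3.82, 3.34)),
    row("ISD",             3.82, c(4.53, 3.02, 4.14, 3.76),         c(2.29, 2.98, 4.9, 3.59)),
    row("ISDA",            4.35, c(5.22, 3.57, 4.55, 4.26),         c(2.75, 4.48, 5.65, 3.99)),
    row("ISCA",            0.70, c(0.81, 0.65, 0.68, 0.68),         c(0.37, 0.1, 0.11, 0.12))
  )
  rownames(out) <- NULL
  out
}

#' Published sex-stratified summaries of the POBA cohort
#'
#' Mean plus/minus SD per sex, overall and within each 20-year age group, for
#' the variables needed by the worked DMT examples and the sex-contrast
#' report layout.
#'
#' @return A data.frame with columns `variable`, `group` (`"Total"` or an age
#'   group), `sex` (`"F"`/`"M"`), `location`, `scale`.
#' @export
poba_sex_summaries <- function() {
  cell <- function(variable, group, sex, loc, sc) {
    data.frame(variable = variable, group = group, sex = sex,
               location = loc, scale = sc, stringsAsFactors = FALSE)
  }
  sexrow <- function(variable, fm) {
    grp <- c("Total", "Adolescents", "YoungAdults", "MidlifeAdults", "OlderAdults")
    do.call(rbind, lapply(seq_along(grp), function(i) {
      rbind(cell(variable, grp[i], "F", fm[[i]][1], fm[[i]][3]),
            cell(variable, grp[i], "M", fm[[i]][2], fm[[i]][4]))
    }))
  }
  out <- rbind(
    sexrow("SVMR_mean", list(
      c(265.33, 253.84, 57.56, 61.31), c(290.9, 276.23, 82.47, 61.5),
      c(224.4, 216.69, 25.96, 31.8), c(269.65, 244.34, 50.34, 59.48),
      c(285.83, 295.71, 50.36, 61.31))),
    sexrow("CVMR_mean", list(
      c(369.13, 349.22, 81.17, 77.4), c(375.09, 351.43, 142.16, 75.82),
      c(331.23, 316.73, 47.76, 65.26), c(371.52, 348.79, 60.98, 68.91),
      c(398.07, 406.3, 68.13, 80.78))),
    sexrow("DMT", list(
      c(103.8, 95.38, 58.5, 46.4), c(84.19, 75.2, 71.55, 35.47),
      c(106.84, 100.03, 44.24, 53.53), c(101.87, 104.45, 56.28, 43.4),
      c(112.25, 110.59, 62.59, 42.51))),
    sexrow("ISCA", list(
      c(0.69, 0.71, 0.12, 0.28), c(0.77, 0.83, 0.1, 0.47),
      c(0.64, 0.65, 0.09, 0.1), c(0.7, 0.65, 0.12, 0.08),
      c(0.69, 0.67, 0.13, 0.11)))
  )
  rownames(out) <- NULL
  out
}

#' Cohort composition of the POBA sample
#'
#' @return A data.frame with one row per 20-year age group: `group`, age
#'   interval bounds `lo`/`hi` (years, half-open, last group extended to the
#'   oldest observed age), total `n`, `n_female`, `n_male`.
#' @export
poba_group_sizes <- function() {
  data.frame(
    group = c("Adolescents", "YoungAdults", "MidlifeAdults", "OlderAdults"),
    lo = c(4, 20, 40, 60),
    hi = c(20, 40, 60, 84),
    n = c(48L, 64L, 64L, 55L),
    n_female = c(19L, 36L, 39L, 40L),
    n_male = c(29L, 28L, 25L, 15L),
    stringsAsFactors = FALSE
  )
}
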