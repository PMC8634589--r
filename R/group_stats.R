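# Proportionality testing across age cohorts: normality screening, omnibus
# and post hoc nonparametric comparisons, homoscedasticity, sex contrasts,
# and bootstrap trend bands over age.

#' Shapiro-Wilk normality screen
#'
#' @param values numeric vector, `3 <= n <= 5000`.
#' @return The two-sided p-value.
#' @export
shapiro_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3)
    stop(errorCondition("need at least 3 finite values",
                        class = c("propcog_insufficient_data", "propcog_error")))
  if (diff(range(values)) == 0)
    stop_degenerate("all values identical: normality test undefined")
  shapiro.test(values)$p.value
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic with its chi-square p-value, as in
#' [stats::kruskal.test()]. The fully-tied case (all pooled values equal) is
#' defined as `H = 0, p = 1`.
#'
#' @param groups list of numeric vectors.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(!lengths(groups))) stop_degenerate("every group needs at least one value")
  if (sum(lengths(groups)) < 3) stop_degenerate("need at least 3 values overall")
  pooled <- unlist(groups)
  if (diff(range(pooled)) == 0)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Dunn post hoc test with Holm step-down adjustment
#'
#' Pairwise z-tests on the pooled mean ranks with the usual tie correction:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`,
#' `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided p-values are adjusted over
#' all pairs by Holm's step-down procedure and returned as a symmetric
#' matrix with unit diagonal.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param method p-adjustment passed to [stats::p.adjust()] (default
#'   `"holm"`).
#' @return list with `p` (adjusted p matrix), `z` (z matrix), `p_raw`.
#' @export
dunn_posthoc <- function(groups, method = "holm") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!lengths(groups))) stop_degenerate("empty group")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  x <- unlist(groups, use.names = FALSE)
  keep <- is.finite(x)
  x <- x[keep]; g <- g[keep]
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  k <- length(lv)
  zmat <- pmat <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  pairs <- combn(k, 2)
  zs <- numeric(ncol(pairs))
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    zs[c_i] <- (rbar[i] - rbar[j]) / se
  }
  p_raw <- 2 * pnorm(-abs(zs))
  p_adj <- p.adjust(p_raw, method = method)
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    zmat[i, j] <- zs[c_i]; zmat[j, i] <- -zs[c_i]
    pmat[i, j] <- pmat[j, i] <- p_adj[c_i]
  }
  diag(pmat) <- 1; diag(zmat) <- 0
  raw <- pmat; raw[] <- NA_real_
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    raw[i, j] <- raw[j, i] <- p_raw[c_i]
  }
  diag(raw) <- 1
  list(p = pmat, z = zmat, p_raw = raw)
}

#' Brown-Forsythe (median-centred Levene) homoscedasticity test
#'
#' Delegates to [car::leveneTest()] with `center = median`, the robust
#' variant. All-identical groups are defined as `W = 0, p = 1`.
#'
#' @param groups list of numeric vectors, each with at least 2 values.
#' @return list with `W`, `p`, `df`.
#' @export
levene_homoscedasticity <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(lengths(groups) < 2))
    stop(errorCondition("every group needs at least 2 values",
                        class = c("propcog_insufficient_data", "propcog_error")))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (diff(range(x)) == 0) return(list(W = 0, p = 1, df = c(length(groups) - 1L,
                                                            length(x) - length(groups))))
  lt <- car::leveneTest(x, g, center = median)
  list(W = lt[1, "F value"], p = lt[1, "Pr(>F)"],
       df = c(lt[1, "Df"], lt[2, "Df"]))
}

#' Welch sex contrast in the layout of the published sex table
#'
#' Two-sided Welch t-tests of a variable between women and men, overall and
#' within each requested age stratum. Strata missing one sex are marked not
#' estimable instead of erroring.
#'
#' @param table feature table with `sex` (`"F"`/`"M"`) and the variable.
#' @param variable column name to contrast.
#' @param strata optional factor/character of per-subject stratum labels
#'   (e.g. `assign_age_group(table$age)`); the overall contrast is always
#'   included as stratum `"Total"`.
#' @return data.frame with one row per stratum: n, mean and SD per sex,
#'   Welch `t`, `p`, and `estimable`.
#' @export
sex_contrast <- function(table, variable, strata = NULL) {
  stopifnot(variable %in% names(table), "sex" %in% names(table))
  strat_list <- list(Total = rep(TRUE, nrow(table)))
  if (!is.null(strata)) {
    strata <- as.character(strata)
    for (s in unique(strata)) strat_list[[s]] <- strata == s
  }
  rows <- lapply(names(strat_list), function(s) {
    sub <- table[strat_list[[s]], ]
    xf <- sub[[variable]][sub$sex == "F"]
    xm <- sub[[variable]][sub$sex == "M"]
    xf <- xf[is.finite(xf)]; xm <- xm[is.finite(xm)]
    base <- data.frame(stratum = s, n_f = length(xf), n_m = length(xm),
                       mean_f = mean(xf), sd_f = sd(xf),
                       mean_m = mean(xm), sd_m = sd(xm),
                       stringsAsFactors = FALSE)
    if (length(xf) < 2 || length(xm) < 2) {
      cbind(base, t = NA_real_, p = NA_real_, estimable = FALSE)
    } else {
      tt <- t.test(xf, xm)   # Welch by default, two-sided
      cbind(base, t = unname(tt$statistic), p = tt$p.value, estimable = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap trend band of a linear age regression
#'
#' Least-squares fit of `values ~ ages` plus a pointwise percentile 95%
#' band of the fitted line over `B` case-resampled replicates, evaluated on
#' an evenly spaced age grid. Replicates without age variance are redrawn
#' deterministically within the seeded stream.
#'
#' @param ages,values numeric vectors of equal length (n >= 3).
#' @param B bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param grid_n grid resolution (default 50).
#' @param level band level (default 0.95).
#' @return An object of class `trend_band`: `slope`, `intercept`, `grid`,
#'   `fit`, `lower`, `upper`, `B`, `seed`.
#' @export
bootstrap_trend <- function(ages, values, B = 1000, seed = 1, grid_n = 50,
                            level = 0.95) {
  ok <- is.finite(ages) & is.finite(values)
  ages <- ages[ok]; values <- values[ok]
  n <- length(ages)
  if (n < 3) stop(errorCondition("need at least 3 points",
                                 class = c("propcog_insufficient_data", "propcog_error")))
  if (B < 100) stop_degenerate("B must be >= 100")
  if (var(ages) == 0) stop_degenerate("zero age variance: no trend estimable")
  fit <- lm(values ~ ages)
  grid <- seq(min(ages), max(ages), length.out = grid_n)
  set.seed(seed)
  boots <- matrix(NA_real_, B, grid_n)
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    if (var(ages[idx]) == 0) next   # redraw degenerate resamples
    cf <- coef(lm(values[idx] ~ ages[idx]))
    boots[b, ] <- cf[1] + cf[2] * grid
    b <- b + 1L
  }
  alpha <- (1 - level) / 2
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    grid = grid,
    fit = unname(coef(fit)[1] + coef(fit)[2] * grid),
    lower = apply(boots, 2, quantile, alpha),
    upper = apply(boots, 2, quantile, 1 - alpha),
    B = B, seed = seed
  ), class = "trend_band")
}

#' @export
print.trend_band <- function(x, ...) {
  cat(sprintf("<trend_band> slope=%.4f intercept=%.3f (B=%d)\n",
              x$slope, x$intercept, x$B))
  invisible(x)
}

#' Full group-comparison report for one variable
#'
#' The statistics layer of the proportionality analysis for a single
#' variable: per-group descriptives (n, median, mean, SD), Shapiro-Wilk
#' normality per group, the Kruskal-Wallis omnibus, the Dunn/Holm post hoc
#' matrix, the Brown-Forsythe homoscedasticity test, and a flag listing
#' groups whose median differs from every other group at `alpha_posthoc`.
#'
#' @param table feature table.
#' @param variable column to analyse.
#' @param group_col grouping column (default `"group"`; if absent, groups
#'   are derived from `age` via [assign_age_group()]).
#' @param alpha_omnibus,alpha_posthoc significance thresholds (defaults 0.05
#'   and 0.05; both are reported, nothing is hard-coded downstream).
#' @return An object of class `group_comparison`.
#' @export
group_comparison <- function(table, variable, group_col = "group",
                             alpha_omnibus = 0.05, alpha_posthoc = 0.05) {
  stopifnot(variable %in% names(table))
  grp <- if (group_col %in% names(table)) factor(table[[group_col]])
         else assign_age_group(table$age)
  x <- table[[variable]]
  ok <- is.finite(x)
  groups <- split(x[ok], droplevels(grp[ok]))
  desc <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(group = g, n = length(v), median = median(v), mean = mean(v),
               sd = sd(v),
               shapiro_p = tryCatch(shapiro_normality(v), error = function(e) NA_real_),
               stringsAsFactors = FALSE)
  }))
  kw <- kruskal_wallis(groups)
  dunn <- dunn_posthoc(groups)
  lev <- levene_homoscedasticity(groups)
  flagged <- names(groups)[vapply(names(groups), function(g) {
    ps <- dunn$p[g, setdiff(names(groups), g)]
    all(ps < alpha_posthoc)
  }, TRUE)]
  structure(list(variable = variable, descriptives = desc,
                 kw_H = kw$H, kw_p = kw$p,
                 dunn_p = dunn$p, dunn_z = dunn$z,
                 levene_W = lev$W, levene_p = lev$p,
                 flagged_groups = flagged, n_excluded = sum(!ok),
                 alpha_omnibus = alpha_omnibus, alpha_posthoc = alpha_posthoc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s  (KW H=%.2f p=%.3g; Levene W=%.2f p=%.3g)\n",
              x$variable, x$kw_H, x$kw_p, x$levene_W, x$levene_p))
  print(x$descriptives, row.names = FALSE)
  if (length(x$flagged_groups))
    cat("groups differing from all others:", paste(x$flagged_groups, collapse = ", "), "\n")
  if (x$n_excluded) cat(x$n_excluded, "subjects excluded (non-finite values)\n")
  invisible(x)
}
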