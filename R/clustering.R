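# Unsupervised age-cohort discovery: K-means distortion profiles over
# (age, index) points, knee-point selection of k, and cluster-to-age-bin
# performance accounting.

#' Best-of-restarts K-means with a warm-started candidate
#'
#' Internal fitting routine. Besides `restarts` random initialisations it
#' also tries a warm start built from the previous (k-1)-solution's centroids
#' plus the point farthest from them, which guarantees the distortion profile
#' is non-increasing in k.
#' @noRd
fit_kmeans <- function(x, k, restarts, warm = NULL) {
  ux <- unique(x)
  if (nrow(ux) <= k) {
    # degenerate: one centroid per distinct point, zero-distortion clusters
    centers <- ux[order(ux[, 1]), , drop = FALSE]
    lab <- apply(x, 1, function(r)
      which.min(colSums((t(centers) - r)^2)))
    return(list(centers = centers, cluster = lab,
                tot.withinss = sum((x - centers[lab, , drop = FALSE])^2)))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- suppressWarnings(kmeans(x, k, iter.max = 100))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (!is.null(warm) && nrow(warm) < k) {
    dmin <- apply(x, 1, function(r) min(colSums((t(warm) - r)^2)))
    cand <- unique(rbind(warm, x[which.max(dmin), , drop = FALSE]))
    if (nrow(cand) == k) {
      km <- tryCatch(suppressWarnings(kmeans(x, cand, iter.max = 100)),
                     error = function(e) NULL)
      if (!is.null(km) && km$tot.withinss < best$tot.withinss) best <- km
    }
  }
  best
}

#' K-means distortion profile over a range of cluster counts
#'
#' The distortion score of a clustering is the sum of squared distances from
#' every point to its assigned centroid. The profile is computed on the raw,
#' unscaled 2-D points (standardise first via `scale_points` if wanted) with
#' best-of-`restarts` K-means per k, plus a warm-started candidate that makes
#' the profile non-increasing.
#'
#' @param points two-column matrix or data.frame of (age, index) points.
#' @param k_range candidate cluster counts (default `2:11`).
#' @param restarts random restarts per k (default 10).
#' @param seed integer seed.
#' @param scale_points standardise both coordinates before clustering
#'   (default `FALSE`: ages dominate, which is what puts the centroids on
#'   the age axis).
#' @return An object of class `distortion_profile` with `k_values`,
#'   `distortion`, and the fitted models in `fits`.
#' @export
distortion_profile <- function(points, k_range = 2:11, restarts = 10, seed = 1,
                               scale_points = FALSE) {
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop_degenerate("points must be finite")
  k_range <- sort(unique(as.integer(k_range)))
  if (nrow(x) < max(k_range))
    stop(errorCondition(
      sprintf("only %d points for k up to %d", nrow(x), max(k_range)),
      class = c("propcog_infeasible_k", "propcog_error")))
  if (scale_points) x <- scale(x)
  set.seed(seed)
  fits <- vector("list", length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k == 1) {
      ctr <- matrix(colMeans(x), 1)
      fits[[i]] <- list(centers = ctr, cluster = rep(1L, nrow(x)),
                        tot.withinss = sum(sweep(x, 2, ctr)^2))
    } else {
      fits[[i]] <- fit_kmeans(x, k, restarts, warm = prev)
    }
    prev <- fits[[i]]$centers
  }
  structure(list(k_values = k_range,
                 distortion = vapply(fits, `[[`, 0, "tot.withinss"),
                 fits = fits),
            class = "distortion_profile")
}

#' @export
print.distortion_profile <- function(x, ...) {
  cat("<distortion_profile>\n")
  print(setNames(signif(x$distortion, 5), x$k_values))
  invisible(x)
}

#' Knee point of a decreasing convex curve (kneedle)
#'
#' Implements the kneedle procedure for a decreasing, convex performance
#' curve: normalise both axes to `[0, 1]`, flip the curve to increasing
#' concave, and locate the first local maximum of the difference curve
#' `y - x` whose height is confirmed by a subsequent drop of more than
#' `sensitivity` times the mean x-step. A curve without curvature (e.g.
#' strictly linear) yields no knee, which is reported explicitly.
#'
#' @param profile a [distortion_profile()], or a list with `k_values` and
#'   `distortion`.
#' @param sensitivity the kneedle S parameter (default 1).
#' @return An object of class `knee_point`: list with `k` (`NA` when no knee
#'   was found), `found`, and the difference curve in `y_difference`.
#' @export
optimal_k <- function(profile, sensitivity = 1) {
  k <- profile$k_values
  y <- profile$distortion
  if (length(k) < 3) stop_degenerate("need at least 3 profile points")
  xh <- (k - min(k)) / (max(k) - min(k))
  rng <- max(y) - min(y)
  if (rng <= 0) {
    return(structure(list(k = NA_integer_, found = FALSE,
                          y_difference = rep(0, length(k))), class = "knee_point"))
  }
  yh <- (y - min(y)) / rng
  yd <- (1 - yh) - xh           # flipped difference curve
  lmx <- which(diff(sign(diff(yd))) < 0) + 1
  knee <- NA_integer_
  if (length(lmx)) {
    thr <- mean(diff(xh)) * sensitivity
    for (i in lmx) {
      drop_at <- which(seq_along(yd) > i & yd < yd[i] - thr)
      nxt <- lmx[lmx > i]
      if (length(drop_at) && (!length(nxt) || min(drop_at) <= min(nxt))) {
        knee <- k[i]
        break
      }
    }
  }
  structure(list(k = knee, found = !is.na(knee), y_difference = yd),
            class = "knee_point")
}

#' @export
print.knee_point <- function(x, ...) {
  if (x$found) cat(sprintf("<knee_point> k = %d\n", x$k))
  else cat("<knee_point> no knee detected\n")
  invisible(x)
}

#' Assign an age to its 20-year cohort
#'
#' Half-open bins: Adolescents `[0, 20)`, YoungAdults `[20, 40)`,
#' MidlifeAdults `[40, 60)`, OlderAdults `[60, Inf)`.
#'
#' @param age years (>= 0); vectorised.
#' @return Factor with the four group levels.
#' @export
#' @examples
#' assign_age_group(c(19.99, 20, 60))
assign_age_group <- function(age) {
  if (any(!is.finite(age) | age < 0))
    stop(errorCondition("ages must be finite and non-negative",
                        class = c("propcog_validation", "propcog_error")))
  cut(age, breaks = c(0, 20, 40, 60, Inf),
      labels = c("Adolescents", "YoungAdults", "MidlifeAdults", "OlderAdults"),
      right = FALSE)
}

#' Cluster a cohort on (age, index) and score against the age bins
#'
#' Runs K-means with `k` clusters on the raw (age, index) points, maps each
#' cluster to the age bin containing its centroid's age coordinate, and
#' tallies per bin how many subjects were assigned to the "right" cluster
#' (performance) versus a cluster mapped to another bin (misclassified).
#' Subjects whose index is not finite are dropped with a reported count.
#'
#' @param table feature table with `age` and the index column.
#' @param index_name one of `"ISD"`, `"ISDA"`, `"ISCA"` (any numeric column
#'   works).
#' @param k number of clusters (default 4).
#' @param bins age-bin lower bounds (default `c(0, 20, 40, 60)`).
#' @param restarts,seed,scale_points passed to the K-means fit.
#' @return An object of class `clustering_summary`: `k`, `centroids` (sorted
#'   by age), `labels`, `bin_of_cluster`, per-bin `performance` and
#'   `misclassified`, and `n_dropped`.
#' @export
cluster_and_score <- function(table, index_name = "ISCA", k = 4,
                              bins = c(0, 20, 40, 60), restarts = 10, seed = 1,
                              scale_points = FALSE) {
  stopifnot(index_name %in% names(table), "age" %in% names(table))
  ok <- is.finite(table[[index_name]]) & is.finite(table$age)
  pts <- cbind(age = table$age[ok], index = table[[index_name]][ok])
  if (k > nrow(unique(pts)))
    stop(errorCondition("more clusters than distinct points",
                        class = c("propcog_infeasible_k", "propcog_error")))
  set.seed(seed)
  km <- fit_kmeans(if (scale_points) scale(pts) else pts, k, restarts)
  centers <- km$centers
  if (scale_points) {
    # report centroids on the original scale
    centers <- t(apply(km$centers, 1, function(r)
      r * attr(scale(pts), "scaled:scale") + attr(scale(pts), "scaled:center")))
  }
  brk <- c(bins, Inf)
  bin_lab <- levels(assign_age_group(0))
  if (length(bins) != 4) bin_lab <- paste0("bin", seq_along(bins))
  cl_bin <- findInterval(centers[, 1], brk)
  if (anyDuplicated(cl_bin)) {
    dup <- bin_lab[cl_bin[duplicated(cl_bin)]]
    stop(errorCondition(
      paste("two centroids fall into the same age bin:", paste(dup, collapse = ", ")),
      class = c("propcog_ambiguous_mapping", "propcog_error")))
  }
  subj_bin <- findInterval(pts[, 1], brk)
  assigned_bin <- cl_bin[km$cluster]
  perf <- mis <- setNames(integer(length(bins)), bin_lab)
  for (b in seq_along(bins)) {
    inb <- subj_bin == b
    perf[b] <- sum(inb & assigned_bin == b)
    mis[b] <- sum(inb & assigned_bin != b)
  }
  cab <- setNames(rep(NA_real_, length(bins)), bin_lab)
  cab[bin_lab[cl_bin]] <- centers[, 1]
  ord <- order(centers[, 1])
  centers <- centers[ord, , drop = FALSE]
  dimnames(centers) <- list(NULL, c("age", "index"))
  structure(list(
    k = k,
    centroids = centers,
    centroid_age_of_bin = cab,
    labels = km$cluster,
    bin_of_cluster = setNames(bin_lab[cl_bin], seq_len(k)),
    performance = perf,
    misclassified = mis,
    n_dropped = sum(!ok),
    index = index_name
  ), class = "clustering_summary")
}

#' @export
print.clustering_summary <- function(x, ...) {
  cat(sprintf("<clustering_summary> %s, k=%d (%d subjects dropped)\n",
              x$index, x$k, x$n_dropped))
  df <- data.frame(centroid_age = round(x$centroids[, 1], 2),
                   performance = x$performance,
                   misclassified = x$misclassified)
  print(df)
  invisible(x)
}
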