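# Shared fixtures: built in code, no files.

# a small, fast generator config: same marginal structure, 12 subjects/group
small_config <- function(seed = 1) {
  cfg <- default_config(seed = seed)
  cfg$groups <- lapply(cfg$groups, function(p) {
    p$n_subjects <- 12L
    p$n_female <- 6L
    p
  })
  cfg
}

# noise-free config: every sigma zero, no mistakes
degenerate_config <- function(seed = 1) {
  cfg <- default_config(seed = seed)
  cfg$groups <- lapply(cfg$groups, function(p) {
    p$n_subjects <- 5L; p$n_female <- 2L
    p$svmr_sigma <- 0; p$svmr_within <- 0; p$svmr_within_sd <- 0
    p$cvmr_within <- 0; p$cvmr_within_sd <- 0
    p$dmt_sigma <- 0
    p$svmr_mist_mu <- 0; p$svmr_mist_sd <- 0
    p$cvmr_mist_mu <- 0; p$cvmr_mist_sd <- 0
    p$rmo_sigma <- 0; p$rmo_within <- 0
    p$ast_sigma <- 0; p$trvi_sigma <- 0; p$grip_sigma <- 0
    p
  })
  cfg$structure$tail_frac <- 0
  cfg
}

# exhaustive k-means optimum by enumerating all label assignments
brute_force_kmeans <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- Inf
  grid <- rep(list(seq_len(k)), n)
  labs <- do.call(expand.grid, grid)
  for (i in seq_len(nrow(labs))) {
    lab <- as.integer(labs[i, ])
    if (length(unique(lab)) < k) next
    d <- 0
    for (c_ in seq_len(k)) {
      pts <- x[lab == c_, , drop = FALSE]
      ctr <- colMeans(pts)
      d <- d + sum(sweep(pts, 2, ctr)^2)
    }
    best <- min(best, d)
  }
  best
}

# Brown-Forsythe W from the textbook formula
levene_by_hand <- function(groups) {
  z <- lapply(groups, function(g) abs(g - median(g)))
  k <- length(z)
  n <- lengths(z)
  N <- sum(n)
  zbar_i <- vapply(z, mean, 0)
  zbar <- mean(unlist(z))
  num <- sum(n * (zbar_i - zbar)^2) / (k - 1)
  den <- sum(unlist(lapply(z, function(zi) (zi - mean(zi))^2))) / (N - k)
  num / den
}

# tie-corrected Kruskal-Wallis H from the definition
kw_by_hand <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / tapply(r, g, length)) -
    3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn z for one pair from the rank-sum formula
dunn_z_by_hand <- function(groups, i, j) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tcor <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  (rbar[i] - rbar[j]) / sqrt((N * (N + 1) / 12 - tcor) * (1 / n[i] + 1 / n[j]))
}
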