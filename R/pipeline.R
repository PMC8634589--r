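# End-to-end orchestration: simulate -> indices -> cluster -> compare ->
# evaluate, writing paper-shaped reports plus a manifest with content hashes.

#' Pipeline configuration
#'
#' @param generator a [generator_config][default_config()].
#' @param k_max largest candidate cluster count for the distortion profile.
#' @param restarts K-means restarts.
#' @param indices indices to cluster on and compare.
#' @param alpha_omnibus,alpha_posthoc significance thresholds of the
#'   statistics stage.
#' @param cutoff classification age cutoff, years.
#' @param folds,repeats cross-validation geometry of the evaluation stage.
#' @param run_evaluation run the (slow) predictive-evaluation stage?
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = default_config(),
                            k_max = 11, restarts = 10,
                            indices = c("ISD", "ISDA", "ISCA"),
                            alpha_omnibus = 0.05, alpha_posthoc = 0.05,
                            cutoff = 40, folds = 10, repeats = 10,
                            run_evaluation = FALSE) {
  validate_config(generator)
  stopifnot(k_max >= 4, restarts >= 1, all(indices %in% c("ISD", "ISDA", "ISCA")))
  structure(as.list(environment()), class = "pipeline_config")
}

file_sha <- function(path) unname(tools::md5sum(path))

#' Run the full pipeline
#'
#' Generates (or loads) a cohort, appends the index layer, selects the
#' cluster count from the distortion profile and scores the clustering per
#' index, builds the group-comparison and sex-contrast reports, and — when
#' requested — runs the cross-validated evaluation. Every artifact is
#' written under `out_dir` (CSV/TSV/JSON), and the returned manifest lists
#' each file with a content hash so reruns can be compared byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return An object of class `pipeline_manifest`: list with `files`
#'   (name, path, hash), `results` (the in-memory stage outputs), `seed`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("propcog_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  log_msg <- function(...) message(sprintf(...))

  ## stage 1: simulate
  cohort <- sample_cohort(config$generator)
  results$cohort <- cohort
  log_msg("simulate: %d subjects, %d with invalid ISD (excluded from index analyses)",
          nrow(cohort$table), cohort$n_invalid_isd)
  csv_path <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, csv_path)

  ## stage 2: clustering per index
  tab <- cohort$table
  cluster_out <- list()
  for (idx in config$indices) {
    ok <- is.finite(tab[[idx]])
    prof <- distortion_profile(cbind(tab$age[ok], tab[[idx]][ok]),
                               k_range = 2:config$k_max,
                               restarts = config$restarts,
                               seed = config$generator$seed)
    knee <- optimal_k(prof)
    k_use <- if (knee$found) knee$k else 4L
    summ <- tryCatch(
      cluster_and_score(tab, idx, k = k_use, restarts = config$restarts,
                        seed = config$generator$seed),
      error = function(e) e)
    cluster_out[[idx]] <- list(profile = prof, knee = knee, summary = summ)
    log_msg("cluster[%s]: knee k=%s, %s", idx,
            if (knee$found) knee$k else "none",
            if (inherits(summ, "error")) conditionMessage(summ)
            else sprintf("%d misclassified", sum(summ$misclassified)))
  }
  results$clustering <- cluster_out
  tab2 <- do.call(rbind, lapply(config$indices, function(idx) {
    s <- cluster_out[[idx]]$summary
    if (inherits(s, "error")) return(NULL)
    data.frame(index = idx, group = names(s$performance),
               centroid_age = round(s$centroid_age_of_bin, 3),
               performance = s$performance, misclassified = s$misclassified)
  }))
  if (!is.null(tab2))
    write.table(tab2, file.path(out_dir, "clustering.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)

  ## stage 3: group statistics
  comp_vars <- c(config$indices, "RMO_mean")
  comparisons <- lapply(comp_vars, function(v)
    group_comparison(tab, v, alpha_omnibus = config$alpha_omnibus,
                     alpha_posthoc = config$alpha_posthoc))
  names(comparisons) <- comp_vars
  results$comparisons <- comparisons
  sexes <- lapply(comp_vars, function(v)
    sex_contrast(tab, v, strata = assign_age_group(tab$age)))
  names(sexes) <- comp_vars
  results$sex_contrasts <- sexes
  stats_json <- lapply(comparisons, function(cmp)
    list(variable = cmp$variable, kw_H = cmp$kw_H, kw_p = cmp$kw_p,
         levene_W = cmp$levene_W, levene_p = cmp$levene_p,
         flagged = cmp$flagged_groups, dunn_p = cmp$dunn_p))
  jsonlite::write_json(stats_json, file.path(out_dir, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  desc <- do.call(rbind, lapply(comparisons, function(cmp)
    cbind(variable = cmp$variable, cmp$descriptives)))
  write.table(desc, file.path(out_dir, "group_table.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  sex_tab <- do.call(rbind, lapply(comp_vars, function(v)
    cbind(variable = v, sexes[[v]])))
  write.table(sex_tab, file.path(out_dir, "sex_table.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  ## stage 4: predictive evaluation (optional; slow)
  if (isTRUE(config$run_evaluation)) {
    labels <- make_binary_label(tab$age, config$cutoff)
    base_feats <- setdiff(names(tab), c("subject_id", "group", "age",
                                        "ISD", "ISDA", "ISCA", "ISD_valid"))
    cls <- lapply(config$indices, function(idx) {
      feats <- tab[c(base_feats, idx)]
      keep <- is.finite(tab[[idx]])
      cv_classify(feats[keep, ], labels[keep], folds = config$folds,
                  repeats = config$repeats, seed = config$generator$seed)
    })
    names(cls) <- config$indices
    reg <- lapply(config$indices, function(idx) {
      lf <- leakage_filter(setdiff(names(tab), c("subject_id", "group")), idx)
      cv_regress(tab[lf$allowed], tab[[idx]], folds = config$folds,
                 repeats = config$repeats, seed = config$generator$seed,
                 ages = tab$age)
    })
    names(reg) <- config$indices
    results$classification <- cls
    results$regression <- reg
    eval_tab <- do.call(rbind, lapply(config$indices, function(idx)
      data.frame(index = idx,
                 auc = cls[[idx]]$overall["mean", "auc"],
                 acc = cls[[idx]]$overall["mean", "accuracy"],
                 mae = reg[[idx]]$overall["mean", "mae"],
                 rmse = reg[[idx]]$overall["mean", "rmse"],
                 mae_range_pct = reg[[idx]]$overall["mean", "mae_range_pct"])))
    write.table(eval_tab, file.path(out_dir, "evaluation.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- data.frame(
    file = basename(files),
    hash = vapply(files, file_sha, ""),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(files = manifest, results = results,
                 seed = config$generator$seed, out_dir = out_dir),
            class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("<pipeline_manifest> seed=%d, %d artifacts in %s\n",
              x$seed, nrow(x$files), x$out_dir))
  print(x$files, row.names = FALSE)
  invisible(x)
}
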