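# Cross-validated evaluation of the indices: classification of the binary
# age group from battery features plus one index, and regression forecasting
# of an index from leakage-filtered features.

#' Binary age label at a cutoff
#'
#' @param ages years (>= 0).
#' @param cutoff years (default 40).
#' @return integer vector, 1 iff `age >= cutoff`.
#' @export
make_binary_label <- function(ages, cutoff = 40) {
  stopifnot(all(is.finite(ages) & ages >= 0))
  as.integer(ages >= cutoff)
}

#' Remove features from which an index target is computable
#'
#' For any index target the quantities that enter its formula are excluded
#' as predictors: `SVMR_mean`, `CVMR_mean`, `DMT`, `SVMR_mistakes`,
#' `CVMR_mistakes`, `SVMR_IES`, `CVMR_IES`, plus the target itself and the
#' other two indices.
#'
#' @param feature_names candidate predictor names (POBA dialect).
#' @param target index being predicted (`"ISD"`, `"ISDA"` or `"ISCA"`).
#' @return list with `allowed` and `removed` name vectors.
#' @export
#' @examples
#' leakage_filter(c("SVMR_IES", "RMO_mean", "age"), "ISCA")$allowed
leakage_filter <- function(feature_names, target) {
  leaky <- c("SVMR_mean", "CVMR_mean", "DMT", "SVMR_mistakes", "CVMR_mistakes",
             "SVMR_IES", "CVMR_IES")
  removed <- intersect(c(leaky, target, setdiff(c("ISD", "ISDA", "ISCA"), target)),
                       feature_names)
  allowed <- setdiff(feature_names, removed)
  if (!length(allowed))
    stop(errorCondition("leakage filter removed every feature",
                        class = c("propcog_empty_features", "propcog_error")))
  list(allowed = allowed, removed = removed)
}

## ---- model families -------------------------------------------------------

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
standardize_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

# discrete AdaBoost (SAMME) over depth-1 rpart stumps
fit_adaboost_cls <- function(X, y, rounds = 50) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(y = factor(y), X)
  models <- list(); alphas <- numeric()
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != df$y)) / sum(w)
    if (err >= 0.5 || err <= 1e-12) {
      if (err <= 1e-12) { models[[m]] <- fit; alphas[m] <- 10 }
      break
    }
    a <- 0.5 * log((1 - err) / err)
    models[[m]] <- fit; alphas[m] <- a
    w <- w * exp(a * ifelse(pred != df$y, 1, -1))
    w <- w / sum(w)
  }
  list(models = models, alphas = alphas, levels = levels(df$y))
}
predict_adaboost_cls <- function(fit, X) {
  df <- data.frame(X)
  margin <- rep(0, nrow(df))
  for (m in seq_along(fit$models)) {
    pr <- predict(fit$models[[m]], df, type = "class")
    margin <- margin + fit$alphas[m] * ifelse(pr == fit$levels[2], 1, -1)
  }
  margin
}

# AdaBoost.R2 with linear loss over shallow rpart trees
fit_adaboost_reg <- function(X, y, rounds = 50) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(y = y, X)
  models <- list(); betas <- numeric()
  for (m in seq_len(rounds)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    fit <- rpart::rpart(y ~ ., data = df[idx, ],
                        control = rpart::rpart.control(maxdepth = 3, cp = 0.001, xval = 0))
    pred <- predict(fit, df)
    ae <- abs(pred - y)
    D <- max(ae)
    if (D <= 1e-12) { models[[m]] <- fit; betas[m] <- 1e-6; break }
    L <- ae / D
    Lbar <- sum(w * L)
    if (Lbar >= 0.5) break
    beta <- Lbar / (1 - Lbar)
    models[[m]] <- fit; betas[m] <- beta
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  }
  if (!length(models)) {
    fit <- rpart::rpart(y ~ ., data = df,
                        control = rpart::rpart.control(maxdepth = 3, xval = 0))
    models <- list(fit); betas <- 0.5
  }
  list(models = models, lw = log(1 / betas))
}
predict_adaboost_reg <- function(fit, X) {
  df <- data.frame(X)
  preds <- vapply(fit$models, function(m) predict(m, df), numeric(nrow(df)))
  preds <- matrix(preds, nrow = nrow(df))
  apply(preds, 1, function(p) {
    o <- order(p)
    cw <- cumsum(fit$lw[o])
    p[o][which(cw >= 0.5 * sum(fit$lw))[1]]   # weighted median
  })
}

#' Standard model families for classification
#'
#' The nine families evaluated side by side: gradient boosting, Gaussian
#' naive Bayes, AdaBoost, ridge and lasso logistic regression, linear and
#' RBF support-vector machines, plain logistic regression, and random
#' forest, each with its toolkit defaults. Every family exposes
#' `fit(X, y)` returning a function that maps a feature matrix to a
#' real-valued score (higher means class 1).
#'
#' @return Named list of family definitions.
#' @export
classification_families <- function() {
  list(
    gradient_boosting = list(scale = FALSE, fit = function(X, y) {
      bst <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = 100, verbose = 0)
      function(Xn) predict(bst, xgboost::xgb.DMatrix(Xn, nthread = 1)) * 2 - 1
    }),
    gaussian_nb = list(scale = FALSE, fit = function(X, y) {
      nb <- e1071::naiveBayes(X, factor(y))
      function(Xn) {
        pr <- predict(nb, Xn, type = "raw")[, "1"]
        pr * 2 - 1
      }
    }),
    adaboost = list(scale = FALSE, fit = function(X, y) {
      ab <- fit_adaboost_cls(X, y)
      function(Xn) predict_adaboost_cls(ab, Xn)
    }),
    ridge = list(scale = TRUE, fit = function(X, y) {
      cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0, nfolds = 5)
      function(Xn) as.numeric(predict(cv, Xn, s = "lambda.min"))
    }),
    lasso = list(scale = TRUE, fit = function(X, y) {
      cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1, nfolds = 5)
      function(Xn) as.numeric(predict(cv, Xn, s = "lambda.min"))
    }),
    svm_linear = list(scale = TRUE, fit = function(X, y) {
      sv <- e1071::svm(X, factor(y), kernel = "linear", scale = FALSE)
      nm <- colnames(attr(predict(sv, X[1, , drop = FALSE],
                                  decision.values = TRUE), "decision.values"))[1]
      sgn <- if (grepl("^1/", nm)) 1 else -1
      function(Xn)
        sgn * attr(predict(sv, Xn, decision.values = TRUE), "decision.values")[, 1]
    }),
    logistic = list(scale = TRUE, fit = function(X, y) {
      df <- data.frame(y = y, X)
      gl <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      function(Xn) suppressWarnings(predict(gl, data.frame(Xn)))
    }),
    random_forest = list(scale = FALSE, fit = function(X, y) {
      rf <- randomForest::randomForest(X, factor(y), ntree = 300)
      function(Xn) predict(rf, Xn, type = "prob")[, "1"] * 2 - 1
    }),
    svm_rbf = list(scale = TRUE, fit = function(X, y) {
      sv <- e1071::svm(X, factor(y), kernel = "radial", scale = FALSE)
      nm <- colnames(attr(predict(sv, X[1, , drop = FALSE],
                                  decision.values = TRUE), "decision.values"))[1]
      sgn <- if (grepl("^1/", nm)) 1 else -1
      function(Xn)
        sgn * attr(predict(sv, Xn, decision.values = TRUE), "decision.values")[, 1]
    })
  )
}

#' Standard model families for regression
#'
#' The regression analogues of [classification_families()]: logistic
#' regression maps to ordinary least squares and Gaussian naive Bayes is
#' dropped (no standard regression analogue), giving eight families.
#'
#' @return Named list of family definitions with `fit(X, y)` returning a
#'   prediction function.
#' @export
regression_families <- function() {
  list(
    gradient_boosting = list(scale = FALSE, fit = function(X, y) {
      bst <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", max_depth = 3, eta = 0.1,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
        nrounds = 100, verbose = 0)
      function(Xn) predict(bst, xgboost::xgb.DMatrix(Xn, nthread = 1))
    }),
    adaboost = list(scale = FALSE, fit = function(X, y) {
      ab <- fit_adaboost_reg(X, y)
      function(Xn) predict_adaboost_reg(ab, Xn)
    }),
    ridge = list(scale = TRUE, fit = function(X, y) {
      cv <- glmnet::cv.glmnet(X, y, alpha = 0, nfolds = 5)
      function(Xn) as.numeric(predict(cv, Xn, s = "lambda.min"))
    }),
    lasso = list(scale = TRUE, fit = function(X, y) {
      cv <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = 5)
      function(Xn) as.numeric(predict(cv, Xn, s = "lambda.min"))
    }),
    linear = list(scale = TRUE, fit = function(X, y) {
      df <- data.frame(y = y, X)
      fit <- lm(y ~ ., data = df)
      # collinear dialect columns (e.g. TRVI = IRT - AST) are tolerated
      function(Xn) suppressWarnings(unname(predict(fit, data.frame(Xn))))
    }),
    svm_linear = list(scale = TRUE, fit = function(X, y) {
      sv <- e1071::svm(X, y, kernel = "linear", scale = FALSE)
      function(Xn) unname(predict(sv, Xn))
    }),
    random_forest = list(scale = FALSE, fit = function(X, y) {
      rf <- randomForest::randomForest(X, y, ntree = 300)
      function(Xn) unname(predict(rf, Xn))
    }),
    svm_rbf = list(scale = TRUE, fit = function(X, y) {
      sv <- e1071::svm(X, y, kernel = "radial", scale = FALSE)
      function(Xn) unname(predict(sv, Xn))
    })
  )
}

rank_auc <- function(scores, labels) {
  pos <- labels == 1
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
}

stratified_folds <- function(labels, folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < folds)
      stop(errorCondition(
        sprintf("class %s has fewer members (%d) than folds (%d)", cl, length(idx), folds),
        class = c("propcog_stratification", "propcog_error")))
    fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold
}

as_feature_matrix <- function(features) {
  df <- as.data.frame(features)
  if ("sex" %in% names(df)) df$sex <- as.integer(df$sex == "M")
  num <- vapply(df, is.numeric, TRUE) | vapply(df, is.logical, TRUE)
  X <- as.matrix(data.frame(lapply(df[num], as.numeric), check.names = TRUE))
  storage.mode(X) <- "double"
  X
}

#' Repeated stratified cross-validated classification
#'
#' For each repeat, subjects are split into stratified folds; each family is
#' fit on the training folds (feature standardisation, when the family wants
#' it, is fitted on the training fold only), out-of-fold scores are pooled,
#' and sensitivity, specificity, accuracy and ROC AUC are computed on the
#' pooled predictions. Metrics are then averaged over repeats, and a
#' cross-family mean is reported on top.
#'
#' @param features data.frame or matrix of predictors.
#' @param labels binary vector (0/1).
#' @param families named list from [classification_families()] (or a
#'   subset).
#' @param folds,repeats cross-validation geometry (defaults 10 and 10).
#' @param seed integer seed; repeat r uses `seed + r`.
#' @return An object of class `classification_report`: `per_family`
#'   (mean and SD of each metric over repeats), `confusion` (pooled counts
#'   per family, summed over repeats), `overall` (mean +/- SD across
#'   families), `folds`, `repeats`, `seed`.
#' @export
cv_classify <- function(features, labels, families = classification_families(),
                        folds = 10, repeats = 10, seed = 1) {
  X <- as_feature_matrix(features)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(X))
  if (length(unique(labels)) != 2)
    stop(errorCondition("need both classes present",
                        class = c("propcog_stratification", "propcog_error")))
  n <- nrow(X)
  metric_names <- c("sensitivity", "specificity", "accuracy", "auc")
  res <- array(NA_real_, c(length(families), repeats, 4),
               dimnames = list(names(families), NULL, metric_names))
  confusion <- matrix(0, length(families), 4,
                      dimnames = list(names(families), c("TP", "TN", "FP", "FN")))
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold <- stratified_folds(labels, folds)
    family_seeds <- sample.int(1e8, length(families))
    for (fi in seq_along(families)) {
      fam <- families[[fi]]
      set.seed(family_seeds[fi])
      scores <- numeric(n)
      for (f in seq_len(folds)) {
        tr <- fold != f
        Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
        if (isTRUE(fam$scale)) {
          sc <- standardize_fit(Xtr)
          Xtr <- standardize_apply(Xtr, sc); Xte <- standardize_apply(Xte, sc)
        }
        pred <- fam$fit(Xtr, labels[tr])
        scores[!tr] <- pred(Xte)
      }
      cls <- as.integer(scores > 0)
      TP <- sum(cls == 1 & labels == 1); TN <- sum(cls == 0 & labels == 0)
      FP <- sum(cls == 1 & labels == 0); FN <- sum(cls == 0 & labels == 1)
      confusion[fi, ] <- confusion[fi, ] + c(TP, TN, FP, FN)
      res[fi, r, ] <- c(TP / (TP + FN), TN / (TN + FP), (TP + TN) / n,
                        rank_auc(scores, labels))
    }
  }
  per_family <- data.frame(family = names(families))
  for (m in metric_names) {
    per_family[[paste0(m, "_mean")]] <- apply(res[, , m, drop = FALSE], 1, mean)
    per_family[[paste0(m, "_sd")]] <- apply(res[, , m, drop = FALSE], 1, sd)
  }
  overall <- vapply(metric_names, function(m)
    c(mean = mean(per_family[[paste0(m, "_mean")]]),
      sd = sd(per_family[[paste0(m, "_mean")]])), numeric(2))
  structure(list(per_family = per_family, confusion = confusion,
                 overall = overall, n = n, folds = folds, repeats = repeats,
                 seed = seed, metrics = res),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d subjects, %d-fold x %d repeats\n",
              x$n, x$folds, x$repeats))
  pf <- x$per_family
  print(data.frame(family = pf$family,
                   sens = round(pf$sensitivity_mean, 3),
                   spec = round(pf$specificity_mean, 3),
                   auc = round(pf$auc_mean, 3),
                   acc = round(pf$accuracy_mean, 3)), row.names = FALSE)
  cat(sprintf("across families: AUC %.3f +/- %.3f, ACC %.3f +/- %.3f\n",
              x$overall["mean", "auc"], x$overall["sd", "auc"],
              x$overall["mean", "accuracy"], x$overall["sd", "accuracy"]))
  invisible(x)
}

#' Repeated cross-validated regression
#'
#' Out-of-fold predictions are pooled per repeat; MAE, RMSE and
#' `100 * MAE / (max - min)` of the target are computed on the pooled
#' predictions and averaged over repeats. When `ages` are supplied, the
#' MAE-to-range ratio is additionally summarised per 20-year age group.
#'
#' @param features data.frame or matrix of predictors (already
#'   leakage-filtered; see [leakage_filter()]).
#' @param target numeric vector to forecast.
#' @param families named list from [regression_families()] (or a subset).
#' @param folds,repeats cross-validation geometry.
#' @param seed integer seed.
#' @param ages optional ages for the per-group error breakdown.
#' @return An object of class `regression_report` with `per_family`,
#'   `overall`, optional `per_group`, and the cv geometry.
#' @export
cv_regress <- function(features, target, families = regression_families(),
                       folds = 10, repeats = 10, seed = 1, ages = NULL) {
  X <- as_feature_matrix(features)
  ok <- is.finite(target)
  X <- X[ok, , drop = FALSE]; target <- target[ok]
  if (!is.null(ages)) ages <- ages[ok]
  n <- nrow(X)
  rng <- diff(range(target))
  if (rng <= 0)
    stop(errorCondition("target has zero range: MAE/range undefined",
                        class = c("propcog_zero_range", "propcog_error")))
  metric_names <- c("mae", "rmse", "mae_range_pct")
  res <- array(NA_real_, c(length(families), repeats, 3),
               dimnames = list(names(families), NULL, metric_names))
  grp <- if (!is.null(ages)) assign_age_group(ages) else NULL
  per_group_acc <- if (!is.null(grp))
    matrix(0, length(families), nlevels(grp),
           dimnames = list(names(families), levels(grp))) else NULL
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold <- sample(rep(seq_len(folds), length.out = n))
    family_seeds <- sample.int(1e8, length(families))
    for (fi in seq_along(families)) {
      fam <- families[[fi]]
      set.seed(family_seeds[fi])
      preds <- numeric(n)
      for (f in seq_len(folds)) {
        tr <- fold != f
        Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
        if (isTRUE(fam$scale)) {
          sc <- standardize_fit(Xtr)
          Xtr <- standardize_apply(Xtr, sc); Xte <- standardize_apply(Xte, sc)
        }
        pred <- fam$fit(Xtr, target[tr])
        preds[!tr] <- pred(Xte)
      }
      err <- preds - target
      res[fi, r, ] <- c(mean(abs(err)), sqrt(mean(err^2)),
                        100 * mean(abs(err)) / rng)
      if (!is.null(grp))
        per_group_acc[fi, ] <- per_group_acc[fi, ] +
          vapply(levels(grp), function(g)
            100 * mean(abs(err[grp == g])) / rng, 0) / repeats
    }
  }
  per_family <- data.frame(family = names(families))
  for (m in metric_names) {
    per_family[[paste0(m, "_mean")]] <- apply(res[, , m, drop = FALSE], 1, mean)
    per_family[[paste0(m, "_sd")]] <- apply(res[, , m, drop = FALSE], 1, sd)
  }
  overall <- vapply(metric_names, function(m)
    c(mean = mean(per_family[[paste0(m, "_mean")]]),
      sd = sd(per_family[[paste0(m, "_mean")]])), numeric(2))
  structure(list(per_family = per_family, overall = overall,
                 per_group = per_group_acc, n = n, range = rng,
                 folds = folds, repeats = repeats, seed = seed, metrics = res),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> %d subjects, %d-fold x %d repeats (range %.3g)\n",
              x$n, x$folds, x$repeats, x$range))
  pf <- x$per_family
  print(data.frame(family = pf$family,
                   mae = signif(pf$mae_mean, 3),
                   rmse = signif(pf$rmse_mean, 3),
                   mae_range_pct = round(pf$mae_range_pct_mean, 2)),
        row.names = FALSE)
  cat(sprintf("across families: MAE/range %.2f%% +/- %.2f%%\n",
              x$overall["mean", "mae_range_pct"], x$overall["sd", "mae_range_pct"]))
  invisible(x)
}

#' Compare the predictability of several indices
#'
#' Kruskal-Wallis test across the per-family accuracy samples of each index
#' (delegates to [kruskal_wallis()]).
#'
#' @param accuracy_lists named list with one numeric vector of per-model
#'   accuracies per index.
#' @return list with `H`, `p`, `df`.
#' @export
compare_index_predictability <- function(accuracy_lists) {
  stopifnot(length(accuracy_lists) >= 2,
            all(lengths(accuracy_lists) >= 2))
  kruskal_wallis(accuracy_lists)
}
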