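#' One-year survival-status labels
#'
#' Label 1 if the patient died before `horizon_months`; label 0 if the
#' observed time reaches the horizon (dead or censored afterwards).
#' Patients censored before the horizon have unknown status and are
#' excluded (flagged, never silently dropped).
#'
#' @param records Clinical data.frame with `survival_time` (months) and
#'   `event`.
#' @param horizon_months Classification horizon, default 12.
#' @return Data.frame with `patient_id`, `label` (0/1/NA) and `included`.
#' @export
label_one_year <- function(records, horizon_months = 12) {
  t <- records$survival_time
  e <- records$event
  label <- ifelse(t >= horizon_months, 0L,
                  ifelse(e == 1, 1L, NA_integer_))
  included <- !is.na(label) & !is.na(t)
  label[!included] <- NA_integer_
  n_amb <- sum(!included)
  if (n_amb > 0) {
    gf_log("label_one_year: %d patient(s) censored before %g months excluded",
           n_amb, horizon_months)
  }
  data.frame(patient_id = records$patient_id, label = label,
             included = included, stringsAsFactors = FALSE)
}

#' Prediction configuration
#'
#' Settings for [run_prediction()]: SVM kernel, number of repeated
#' stratified resamplings, training fraction, cross-validation folds and
#' hyperparameter grids (log-2 ladders).
#'
#' @param kernel `"radial"` or `"linear"`.
#' @param n_repeats Number of train/test resamplings (default 100).
#' @param train_fraction Training fraction per dataset (default 0.8).
#' @param cv_folds Cross-validation folds for the grid search (default 10).
#' @param cost_grid SVM cost values (default `2^(-5:5)`).
#' @param gamma_grid Radial kernel width values (default `2^(-7:3)`;
#'   ignored for the linear kernel).
#' @param seed Master RNG seed.
#' @param horizon_months Label horizon (default 12).
#' @return A `prediction_config` list.
#' @export
prediction_config <- function(kernel = c("radial", "linear"),
                              n_repeats = 100, train_fraction = 0.8,
                              cv_folds = 10,
                              cost_grid = 2^(-5:5),
                              gamma_grid = 2^(-7:3),
                              seed = 1L, horizon_months = 12) {
  kernel <- match.arg(kernel)
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2,
            length(cost_grid) > 0, length(gamma_grid) > 0, n_repeats >= 1)
  structure(list(kernel = kernel, n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 cost_grid = cost_grid, gamma_grid = gamma_grid,
                 seed = as.integer(seed),
                 horizon_months = horizon_months),
            class = "prediction_config")
}

# Internal: rank-based AUC of scores for binary labels (1 = case).
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Internal: SVM decision values oriented so larger = more likely class "1".
svm_decision <- function(fit, newx) {
  pred <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  pos_first <- strsplit(colnames(dv)[1], "/")[[1]][1] == "1"
  if (pos_first) as.numeric(dv) else -as.numeric(dv)
}

# Internal: stratified index draw preserving label ratio within strata.
stratified_draw <- function(labels, datasets, fraction) {
  train <- integer(0)
  for (ds in unique(datasets)) {
    for (lb in unique(labels)) {
      idx <- which(datasets == ds & labels == lb)
      k <- round(fraction * length(idx))
      k <- max(min(k, length(idx) - 1L), 1L)
      train <- c(train, sample(idx, k))
    }
  }
  sort(train)
}

# Internal: stratified CV fold assignment.
cv_folds_stratified <- function(labels, k) {
  fold <- integer(length(labels))
  for (lb in unique(labels)) {
    idx <- sample(which(labels == lb))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Internal: mean CV AUC of one hyperparameter combination.
cv_auc <- function(x, y, fold, kernel, cost, gamma) {
  k <- max(fold)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
      return(NA_real_)
    }
    fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
                      kernel = kernel, cost = cost, gamma = gamma,
                      scale = FALSE)
    auc_rank(svm_decision(fit, x[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Repeated stratified-resampling SVM prediction of 1-year survival
#'
#' Per repeat: `train_fraction` of patients from each dataset are drawn
#' stratified by label and pooled as the training set; the out-of-bag
#' remainder, pooled, is the test set.  Features are standardized with
#' training statistics only.  The SVM cost (and, for the radial kernel,
#' width) is chosen by stratified k-fold cross-validation on the training
#' pool maximizing AUC; the model is refit on the full training pool and
#' scored on the test pool.  Results aggregate the per-repeat test AUCs.
#' Fully deterministic given `config$seed`.
#'
#' @param features Numeric data.frame/matrix of predictors (rows =
#'   patients): location features plus age, sex (0/1), KPS.  No missing
#'   values.
#' @param labels Binary labels from [label_one_year()] (included patients
#'   only).
#' @param dataset_ids Character vector assigning each patient to a dataset.
#' @param config A [prediction_config()].
#' @param importance If `TRUE`, also compute permutation feature importance
#'   on each test split (10 shuffles per feature per repeat).
#' @return A `prediction_result` with `auc` (per-repeat vector),
#'   `mean_auc`, `sd_auc`, `params` (chosen hyperparameters per repeat) and
#'   optionally `importance` (mean and SD of AUC drop per feature).
#' @export
run_prediction <- function(features, labels, dataset_ids, config,
                           importance = FALSE) {
  x_all <- as.matrix(features)
  storage.mode(x_all) <- "double"
  if (anyNA(x_all)) stop("features contain missing values")
  labels <- as.integer(labels)
  stopifnot(nrow(x_all) == length(labels),
            length(dataset_ids) == length(labels),
            all(labels %in% 0:1))
  for (ds in unique(dataset_ids)) {
    for (lb in 0:1) {
      if (sum(dataset_ids == ds & labels == lb) < 2) {
        stop(sprintf("dataset %s has fewer than 2 patients with label %d",
                     ds, lb))
      }
    }
  }
  grid <- if (config$kernel == "linear") {
    expand.grid(cost = config$cost_grid, gamma = 1 / ncol(x_all))
  } else {
    expand.grid(cost = config$cost_grid, gamma = config$gamma_grid)
  }
  seeds <- derive_seeds(config$seed, config$n_repeats)
  auc <- numeric(config$n_repeats)
  params <- data.frame(cost = numeric(config$n_repeats),
                       gamma = numeric(config$n_repeats))
  imp_list <- if (importance) vector("list", config$n_repeats) else NULL

  for (r in seq_len(config$n_repeats)) {
    res <- with_seed(seeds[r], {
      tr_idx <- NULL
      for (attempt in 1:10) {
        cand <- stratified_draw(labels, dataset_ids, config$train_fraction)
        if (length(unique(labels[cand])) == 2 &&
            length(unique(labels[-cand])) == 2) {
          tr_idx <- cand
          break
        }
        gf_log("run_prediction: repeat %d redraw %d (class missing)",
               r, attempt)
      }
      if (is.null(tr_idx)) stop("could not draw both classes in 10 attempts")
      xtr <- x_all[tr_idx, , drop = FALSE]
      xte <- x_all[-tr_idx, , drop = FALSE]
      ytr <- labels[tr_idx]
      yte <- labels[-tr_idx]
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2L, sd)
      sg[sg == 0] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sg, `/`)
      xte <- sweep(sweep(xte, 2L, mu), 2L, sg, `/`)
      fold <- cv_folds_stratified(ytr, config$cv_folds)
      cv <- vapply(seq_len(nrow(grid)), function(g) {
        cv_auc(xtr, ytr, fold, config$kernel, grid$cost[g], grid$gamma[g])
      }, numeric(1))
      best <- which.max(cv)
      fit <- e1071::svm(xtr, factor(ytr, levels = c(0, 1)),
                        kernel = config$kernel, cost = grid$cost[best],
                        gamma = grid$gamma[best], scale = FALSE)
      dec <- svm_decision(fit, xte)
      imp <- NULL
      if (importance) {
        base_auc <- auc_rank(dec, yte)
        imp <- vapply(seq_len(ncol(xte)), function(j) {
          drops <- vapply(1:10, function(s) {
            xp <- xte
            xp[, j] <- sample(xp[, j])
            base_auc - auc_rank(svm_decision(fit, xp), yte)
          }, numeric(1))
          mean(drops)
        }, numeric(1))
        names(imp) <- colnames(x_all)
      }
      list(auc = auc_rank(dec, yte), cost = grid$cost[best],
           gamma = grid$gamma[best], imp = imp)
    })
    auc[r] <- res$auc
    params$cost[r] <- res$cost
    params$gamma[r] <- res$gamma
    if (importance) imp_list[[r]] <- res$imp
  }
  out <- list(auc = auc, mean_auc = mean(auc), sd_auc = sd(auc),
              params = params, config = config)
  if (importance) {
    imp_mat <- do.call(rbind, imp_list)
    out$importance <- data.frame(
      feature = colnames(imp_mat),
      mean_drop = colMeans(imp_mat),
      sd_drop = apply(imp_mat, 2L, sd),
      stringsAsFactors = FALSE
    )
    rownames(out$importance) <- NULL
  }
  structure(out, class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s kernel, %d repeats: AUC %.3f +/- %.3f\n",
              x$config$kernel, length(x$auc), x$mean_auc, x$sd_auc))
  invisible(x)
}

#' Permutation feature importance of a prediction run
#'
#' Convenience accessor: the per-feature mean and SD (over repeats) of the
#' held-out AUC drop when that feature's test column is shuffled.  Requires
#' `run_prediction(..., importance = TRUE)`.
#'
#' @param result A `prediction_result`.
#' @return Data.frame with `feature`, `mean_drop`, `sd_drop`, ordered by
#'   decreasing importance.
#' @export
feature_importance <- function(result) {
  if (is.null(result$importance)) {
    stop("run_prediction was called without importance = TRUE")
  }
  imp <- result$importance
  imp[order(-imp$mean_drop), , drop = FALSE]
}
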