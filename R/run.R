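fold_rows <- function(features, pairs) {
  key <- paste(features$subject_id, features$condition_id, sep = "\x01")
  key %in% paste(pairs$subject_id, pairs$condition_id, sep = "\x01")
}

fit_fold_model <- function(model, train, model_args, fold_seed) {
  switch(model,
    linear = fit_ee_linear(train, quiet = TRUE),
    mlp = do.call(fit_ee_mlp,
                  c(list(data = train),
                    utils::modifyList(list(seed = fold_seed), model_args))),
    rnn = do.call(fit_ee_rnn,
                  c(list(data = train),
                    utils::modifyList(list(seed = fold_seed), model_args))))
}

#' Run one evaluation use case end to end
#'
#' Assembles features (or fixed windows for the recurrent model) under the
#' plan's channel subset and raw-mode flags, then for every fold fits the
#' requested estimator on the training pairs, predicts the test pairs, and
#' scores them.  Per-fold metrics are averaged across folds; condition-level
#' estimates (the mean of a condition's per-sample estimates, pooled across
#' folds) feed the pairwise ordering accuracy and, when every subject
#' contributes the same condition set, the ordering confusion matrix.
#'
#' @param trials List of trials.
#' @param plan An `ee_split_plan` from [plan_novel_condition()],
#'   [plan_novel_subject()] or [plan_both_novel()].
#' @param model `"linear"`, `"mlp"` or `"rnn"`.
#' @param labels Condition labels; computed from the trials' breath records
#'   via [condition_labels()] when omitted.
#' @param model_args Extra arguments passed to the model fitter.
#' @param seed Base seed; fold `k` trains with seed `seed + k`.
#' @param ordering_threshold Relative threshold for [ordering_accuracy()].
#' @param features Optional precomputed feature (or window) table from
#'   [assemble_features()] / [assemble_windows()].  Must have been assembled
#'   with the same channel subset and raw-mode flags as the plan; supplying
#'   it avoids re-filtering when several plans share one preprocessing.
#' @return An `ee_report`: per-fold metrics, their means, pooled
#'   condition-level estimates, ordering accuracy and confusion matrix.
#' @export
run_use_case <- function(trials, plan, model = c("linear", "mlp", "rnn"),
                         labels = NULL, model_args = list(), seed = 1,
                         ordering_threshold = 0.042, features = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(plan, "ee_split_plan"))
  if (is.null(labels)) labels <- condition_labels(trials)
  if (is.null(features)) {
    features <- if (model == "rnn") {
      assemble_windows(trials, labels, subset = plan$subset,
                       raw_mode = plan$raw_mode)
    } else {
      assemble_features(trials, labels, subset = plan$subset,
                        raw_mode = plan$raw_mode)
    }
  } else {
    fs <- attr(features, "subset"); fr <- attr(features, "raw_mode")
    if ((!is.null(fs) && fs != plan$subset) ||
        (!is.null(fr) && fr != plan$raw_mode))
      abort("Supplied features were assembled with different subset/raw flags than the plan")
  }

  fold_metrics <- list()
  preds_all <- list()
  r2_train <- rep(NA_real_, length(plan$folds))
  for (k in seq_along(plan$folds)) {
    fold <- plan$folds[[k]]
    tr <- features[fold_rows(features, fold$train), ]
    te <- features[fold_rows(features, fold$test), ]
    if (nrow(tr) == 0L || nrow(te) == 0L)
      abort(sprintf("Fold %d has an empty train or test set", k))
    stopifnot(nrow(dplyr::intersect(
      distinct(tr[c("subject_id", "condition_id")]),
      distinct(te[c("subject_id", "condition_id")]))) == 0L)
    fit <- fit_fold_model(model, tr, model_args, seed + k)
    if (model == "linear") r2_train[k] <- fit$r_squared
    preds <- tibble(subject_id = te$subject_id,
                    condition_id = te$condition_id,
                    mass = te$mass, y = te$y,
                    y_hat = predict(fit, te), fold = k)
    m <- compute_metrics(preds)
    fold_metrics[[k]] <- tibble(
      fold = k, mean_percent_error = m$mean_percent_error,
      rmse_per_kg = m$rmse_per_kg, mae_per_kg = m$mae_per_kg,
      n_test_samples = m$n_samples,
      n_test_conditions = nrow(m$per_condition))
    preds_all[[k]] <- preds
  }
  folds_tb <- bind_rows(fold_metrics)
  preds_tb <- bind_rows(preds_all)

  cond_est <- preds_tb |>
    group_by(.data$subject_id, .data$condition_id) |>
    summarise(estimate = mean(.data$y_hat), truth = .data$y[1L],
              .groups = "drop")
  per_subj <- table(cond_est$subject_id)
  ordering <- if (all(per_subj >= 2L))
    ordering_accuracy(cond_est, threshold = ordering_threshold) else NA_real_
  confusion <- tryCatch(ordering_confusion(cond_est), error = function(e) NULL)

  structure(list(
    use_case = plan$use_case, model = model,
    folds = folds_tb, predictions = preds_tb, cond_estimates = cond_est,
    mean_percent_error = mean(folds_tb$mean_percent_error),
    rmse_per_kg = mean(folds_tb$rmse_per_kg),
    mae_per_kg = mean(folds_tb$mae_per_kg),
    r2_train = if (model == "linear") mean(r2_train) else NA_real_,
    ordering_percent = ordering, confusion = confusion,
    seed = seed), class = "ee_report")
}

#' @export
print.ee_report <- function(x, ...) {
  cat(sprintf("<ee_report> %s / %s model: %d folds\n",
              x$use_case, x$model, nrow(x$folds)))
  cat(sprintf("  mean percent error: %.2f%%\n", x$mean_percent_error))
  cat(sprintf("  RMSE: %.3f W/kg; MAE: %.3f W/kg\n",
              x$rmse_per_kg, x$mae_per_kg))
  if (!is.na(x$r2_train))
    cat(sprintf("  training R^2 (mean over folds): %.4f\n", x$r2_train))
  if (!is.na(x$ordering_percent))
    cat(sprintf("  ordering accuracy: %.1f%%\n", x$ordering_percent))
  invisible(x)
}

#' @method tidy ee_report
#' @export
tidy.ee_report <- function(x, ...) x$folds

#' @method glance ee_report
#' @export
glance.ee_report <- function(x, ...) {
  tibble(use_case = x$use_case, model = x$model, n_folds = nrow(x$folds),
         mean_percent_error = x$mean_percent_error,
         rmse_per_kg = x$rmse_per_kg, mae_per_kg = x$mae_per_kg,
         r2_train = x$r2_train, ordering_percent = x$ordering_percent)
}
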