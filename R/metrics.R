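#' Error metrics for a set of test predictions
#'
#' Percent error is defined as the mean absolute error of a
#' condition's per-sample estimates scaled by that condition's true
#' (measured) power, averaged over test conditions.  RMSE and MAE are
#' computed over all test samples in Watts and normalized by the mean body
#' mass of the distinct test subjects, giving W/kg.
#'
#' @param predictions Tibble with one row per test sample: `subject_id`,
#'   `condition_id`, `mass`, `y` (true condition power, W), `y_hat`
#'   (estimate, W).
#' @param average `"condition_first"` (default: per-condition percent errors
#'   averaged over conditions) or `"sample_first"` (per-sample relative
#'   errors averaged over all samples).
#' @return A list: `per_condition` (tibble of per-condition percent errors),
#'   `mean_percent_error`, `rmse_per_kg`, `mae_per_kg`, `n_samples`.
#' @export
compute_metrics <- function(predictions,
                            average = c("condition_first", "sample_first")) {
  average <- match.arg(average)
  if (nrow(predictions) == 0L) abort("No predictions to score")
  per_cond <- predictions |>
    group_by(.data$subject_id, .data$condition_id) |>
    summarise(truth = .data$y[1L],
              estimate = mean(.data$y_hat),
              percent_error = 100 * mean(abs(.data$y_hat - .data$y)) / .data$y[1L],
              n = dplyr::n(), .groups = "drop")
  mean_mass <- predictions |>
    distinct(.data$subject_id, .data$mass) |>
    pull(.data$mass) |>
    mean()
  mpe <- if (average == "condition_first") mean(per_cond$percent_error)
  else mean(100 * abs(predictions$y_hat - predictions$y) / predictions$y)
  list(per_condition = per_cond,
       mean_percent_error = mpe,
       rmse_per_kg = sqrt(mean((predictions$y_hat - predictions$y)^2)) / mean_mass,
       mae_per_kg = mean(abs(predictions$y_hat - predictions$y)) / mean_mass,
       n_samples = nrow(predictions))
}

pair_outcome <- function(v1, v2, threshold) {
  if (abs(v1 - v2) <= threshold * v2) "within"
  else if (v1 > v2) "greater"
  else "less"
}

#' Pairwise condition-ordering accuracy
#'
#' For every ordered pair of a subject's conditions, the first value is
#' classified as greater than, within, or less than a relative threshold of
#' the second ("within" when `|v1 - v2| <= threshold * v2`), separately for
#' estimates and measured truths.  The accuracy is the percentage of pairs
#' whose estimated outcome matches the true outcome, averaged over subjects.
#' The 4.2% default threshold is the accepted error of two-minute indirect
#' calorimetry protocols used in human-in-the-loop exoskeleton optimization.
#'
#' @param cond Tibble with one row per (subject, condition): `subject_id`,
#'   `condition_id`, `estimate`, `truth` (both W).
#' @param threshold Relative equivalence threshold (default 0.042), applied
#'   to the second member of each pair.
#' @return Ordering accuracy in percent.
#' @export
ordering_accuracy <- function(cond, threshold = 0.042) {
  subjects <- unique(cond$subject_id)
  acc <- vapply(subjects, function(s) {
    d <- cond[cond$subject_id == s, ]
    k <- nrow(d)
    if (k < 2L)
      abort(sprintf("Subject %s has fewer than 2 conditions to order", s))
    match_ct <- 0L
    total <- 0L
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        est <- pair_outcome(d$estimate[i], d$estimate[j], threshold)
        tru <- pair_outcome(d$truth[i], d$truth[j], threshold)
        match_ct <- match_ct + (est == tru)
        total <- total + 1L
      }
    }
    100 * match_ct / total
  }, numeric(1))
  mean(acc)
}

#' Condition-ordering confusion matrix
#'
#' Per subject, conditions are ranked by measured power (rows, increasing)
#' and by estimated power (columns); cell `(r, c)` accumulates 1 when the
#' condition with true rank `r` receives estimated rank `c`.  Counts are
#' normalized by the subject count, so perfect ordering gives the identity
#' matrix and every row sums to 1.
#'
#' @param cond As in [ordering_accuracy()]; every subject must contribute the
#'   same condition set.
#' @return A `K x K` numeric matrix.
#' @export
ordering_confusion <- function(cond) {
  subjects <- unique(cond$subject_id)
  cond_sets <- lapply(subjects, function(s)
    sort(cond$condition_id[cond$subject_id == s]))
  if (length(unique(vapply(cond_sets, paste, "", collapse = "\x01"))) != 1L)
    abort("All subjects must share the same condition set")
  K <- length(cond_sets[[1L]])
  M <- matrix(0, K, K)
  for (s in subjects) {
    d <- cond[cond$subject_id == s, ]
    true_rank <- rank(d$truth, ties.method = "first")
    est_rank <- rank(d$estimate, ties.method = "first")
    for (i in seq_len(nrow(d))) M[true_rank[i], est_rank[i]] <-
        M[true_rank[i], est_rank[i]] + 1
  }
  M / length(subjects)
}
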