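# Cross-validation plans over (subject, condition) pairs.  Fold count always
# equals the subject count; each fold's test set never intersects its
# training set.

dataset_pairs <- function(trials) {
  distinct(tibble(
    subject_id = map_chr(trials, ~ .x$subject$subject_id),
    condition_id = map_chr(trials, ~ .x$condition$condition_id)))
}

new_split_plan <- function(use_case, folds, subset, raw_mode, seed = NA_integer_) {
  for (f in folds) {
    overlap <- dplyr::intersect(f$train, f$test)
    if (nrow(overlap) > 0L) abort("Internal error: train/test overlap in fold")
  }
  structure(list(use_case = use_case, folds = folds, subset = subset,
                 raw_mode = raw_mode, seed = seed),
            class = "ee_split_plan")
}

#' @export
print.ee_split_plan <- function(x, ...) {
  cat(sprintf("<ee_split_plan> use case '%s': %d folds, subset %s%s\n",
              x$use_case, length(x$folds), x$subset,
              if (x$raw_mode) ", raw mode" else ""))
  invisible(x)
}

#' Novel-condition cross-validation plan
#'
#' Simulates having subject-specific training data and estimating new
#' conditions: each fold holds out `round(frac * total pairs)` randomly
#' chosen (subject, condition) pairs -- not necessarily the same conditions
#' for every subject -- and trains on the rest.  Fold count equals subject
#' count; the sampling is seeded and reproducible.
#'
#' @param trials List of trials (or anything accepted by `dataset_pairs`).
#' @param frac Fraction of all pairs held out per fold, in (0, 1);
#'   default 0.10.
#' @param seed Integer seed.
#' @return An `ee_split_plan`.
#' @export
plan_novel_condition <- function(trials, frac = 0.10, seed = 1) {
  if (!is.numeric(frac) || frac <= 0 || frac >= 1)
    abort("frac must lie strictly between 0 and 1")
  pairs <- dataset_pairs(trials)
  subjects <- sort(unique(pairs$subject_id))
  cond_per_subj <- dplyr::count(pairs, .data$subject_id)
  if (any(cond_per_subj$n < 2L))
    abort("Every subject needs at least 2 conditions")
  n_test <- max(1L, round_half_up(frac * nrow(pairs)))
  folds <- withr::with_seed(seed, {
    lapply(seq_along(subjects), function(k) {
      take <- sample.int(nrow(pairs), n_test)
      list(train = pairs[-take, ], test = pairs[take, ])
    })
  })
  new_split_plan("novel_condition", folds, "all", FALSE, seed)
}

#' Novel-subject (leave-one-subject-out) cross-validation plan
#'
#' Each fold holds out one entire subject; all of that subject's conditions
#' form the test set.  The `"subject_vertical_force"` variant restricts model
#' inputs to vertical GRF plus EMG (wearable-emulating), and the
#' `"raw_subject"` variant uses all signals with no conditioning beyond EMG
#' rectification; both reuse the same folds.
#'
#' @param trials List of trials.
#' @param variant `"novel_subject"`, `"subject_vertical_force"` or
#'   `"raw_subject"`.
#' @return An `ee_split_plan` with one fold per subject.
#' @export
plan_novel_subject <- function(trials, variant = c("novel_subject",
                                                   "subject_vertical_force",
                                                   "raw_subject")) {
  variant <- match.arg(variant)
  pairs <- dataset_pairs(trials)
  subjects <- sort(unique(pairs$subject_id))
  folds <- lapply(subjects, function(s) {
    list(train = filter(pairs, .data$subject_id != s),
         test = filter(pairs, .data$subject_id == s))
  })
  new_split_plan(
    variant, folds,
    subset = if (variant == "subject_vertical_force")
      "vertical_force_plus_emg" else "all",
    raw_mode = variant == "raw_subject")
}

#' Both-novel cross-validation plan
#'
#' Each fold holds out one subject plus `n_conditions` randomly chosen
#' condition ids removed from every subject's training data; only those
#' conditions of the held-out subject are estimated.  Conditions are
#' re-sampled per fold, seeded.
#'
#' @param trials List of trials.
#' @param n_conditions Condition ids removed per fold (default 2).
#' @param seed Integer seed.
#' @return An `ee_split_plan` with one fold per subject.
#' @export
plan_both_novel <- function(trials, n_conditions = 2, seed = 1) {
  pairs <- dataset_pairs(trials)
  subjects <- sort(unique(pairs$subject_id))
  conds <- sort(unique(pairs$condition_id))
  if (length(conds) <= n_conditions)
    abort("Need more conditions than are held out per fold")
  folds <- withr::with_seed(seed, {
    lapply(subjects, function(s) {
      held <- sample(conds, n_conditions)
      list(train = filter(pairs, .data$subject_id != s,
                          !.data$condition_id %in% held),
           test = filter(pairs, .data$subject_id == s,
                         .data$condition_id %in% held))
    })
  })
  new_split_plan("both_novel", folds, "all", FALSE, seed)
}
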