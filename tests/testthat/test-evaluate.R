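test_that("novel-condition plans hold out round(frac * pairs) per fold", {
  trials <- fake_trials(sprintf("S%02d", 1:6), sprintf("c%d", 1:9))
  plan <- plan_novel_condition(trials, frac = 0.10, seed = 3)
  expect_length(plan$folds, 6L)
  for (f in plan$folds) {
    expect_identical(nrow(f$test), 5L)            # round(0.10 * 54)
    expect_identical(nrow(f$train), 49L)
    expect_identical(nrow(dplyr::intersect(f$train, f$test)), 0L)
  }
  plan2 <- plan_novel_condition(trials, frac = 0.10, seed = 3)
  expect_identical(plan, plan2)                   # seeded reproducibility
  expect_error(plan_novel_condition(trials, frac = 0), "between 0 and 1")
  expect_error(plan_novel_condition(trials, frac = 1), "between 0 and 1")
})

test_that("novel-subject plans are leave-one-subject-out partitions", {
  trials <- fake_trials(sprintf("S%02d", 1:6), sprintf("c%d", 1:9))
  plan <- plan_novel_subject(trials)
  expect_length(plan$folds, 6L)
  tests <- dplyr::bind_rows(lapply(plan$folds, `[[`, "test"))
  expect_identical(nrow(tests), 54L)              # union = full dataset
  expect_identical(nrow(dplyr::distinct(tests)), 54L)  # disjoint
  for (f in plan$folds)
    expect_identical(length(unique(f$test$subject_id)), 1L)

  # incline-load scale: 13 subjects -> 13 folds
  plan13 <- plan_novel_subject(fake_trials(sprintf("S%02d", 1:13),
                                           sprintf("c%d", 1:12)))
  expect_length(plan13$folds, 13L)

  # variants carry the channel subset / raw flags
  pv <- plan_novel_subject(trials, "subject_vertical_force")
  expect_identical(pv$subset, "vertical_force_plus_emg")
  pr <- plan_novel_subject(trials, "raw_subject")
  expect_true(pr$raw_mode)
})

test_that("both-novel plans remove the held conditions from every subject", {
  trials <- fake_trials(sprintf("S%02d", 1:6), sprintf("c%d", 1:9))
  plan <- plan_both_novel(trials, n_conditions = 2, seed = 5)
  expect_length(plan$folds, 6L)
  for (f in plan$folds) {
    expect_identical(nrow(f$test), 2L)
    expect_identical(length(unique(f$test$subject_id)), 1L)
    held <- unique(f$test$condition_id)
    expect_false(any(f$train$condition_id %in% held))
    expect_false(any(f$train$subject_id %in% f$test$subject_id))
  }
  expect_identical(plan, plan_both_novel(trials, n_conditions = 2, seed = 5))
})

test_that("metrics follow the per-condition percent-error definition", {
  perfect <- tibble::tibble(subject_id = "S1", condition_id = c("a", "a", "b"),
                            mass = 70, y = c(400, 400, 300),
                            y_hat = c(400, 400, 300))
  m <- compute_metrics(perfect)
  expect_equal(m$mean_percent_error, 0)
  expect_equal(m$rmse_per_kg, 0)

  # MAE 20 W on a 400 W condition -> 5.0%
  m2 <- compute_metrics(tibble::tibble(
    subject_id = "S1", condition_id = "a", mass = 70,
    y = c(400, 400), y_hat = c(380, 420)))
  expect_equal(m2$mean_percent_error, 5.0)

  # sample-first averaging weights conditions by their sample counts
  uneven <- tibble::tibble(
    subject_id = "S1", condition_id = c("a", "a", "a", "b"), mass = 70,
    y = c(400, 400, 400, 200), y_hat = c(420, 420, 420, 220))
  expect_equal(compute_metrics(uneven)$mean_percent_error, 7.5)
  expect_equal(compute_metrics(uneven, average = "sample_first")$mean_percent_error,
               6.25)

  # |residual| = 10 W everywhere, mean test mass 70 kg -> 10/70 W/kg
  m3 <- compute_metrics(tibble::tibble(
    subject_id = c("S1", "S2"), condition_id = "a", mass = 70,
    y = c(400, 300), y_hat = c(410, 290)))
  expect_equal(m3$rmse_per_kg, 10 / 70, tolerance = 1e-9)
  expect_equal(m3$mae_per_kg, 10 / 70, tolerance = 1e-9)
})

test_that("ordering accuracy matches exhaustive pair enumeration", {
  # independent oracle: enumerate all pairs, classify both sides
  oracle <- function(cond, thr = 0.042) {
    out <- c()
    for (s in unique(cond$subject_id)) {
      d <- cond[cond$subject_id == s, ]
      lab <- function(v1, v2) {
        if (abs(v1 - v2) <= thr * v2) "w" else if (v1 > v2) "g" else "l"
      }
      hits <- 0; tot <- 0
      for (i in seq_len(nrow(d) - 1)) for (j in (i + 1):nrow(d)) {
        hits <- hits + (lab(d$estimate[i], d$estimate[j]) ==
                          lab(d$truth[i], d$truth[j]))
        tot <- tot + 1
      }
      out <- c(out, 100 * hits / tot)
    }
    mean(out)
  }
  withr::with_seed(21, {
    for (rep in 1:10) {
      K <- sample(2:5, 1)
      cond <- tidyr::expand_grid(subject_id = c("A", "B", "C"),
                                 condition_id = paste0("c", seq_len(K)))
      cond$truth <- runif(nrow(cond), 200, 600)
      cond$estimate <- cond$truth * (1 + rnorm(nrow(cond), sd = 0.1))
      expect_equal(ordering_accuracy(cond), oracle(cond), tolerance = 1e-12)
    }
  })
})

test_that("ordering accuracy handles the threshold band and degenerate cases", {
  # perfect estimates, all gaps > 4.2% -> 100%
  cond <- tibble::tibble(subject_id = "A", condition_id = c("a", "b", "c"),
                         truth = c(300, 400, 500),
                         estimate = c(300, 400, 500))
  expect_equal(ordering_accuracy(cond), 100)

  # reverse-ranked estimates with large gaps -> 0%
  rev_cond <- cond
  rev_cond$estimate <- c(500, 400, 300)
  expect_equal(ordering_accuracy(rev_cond), 0)

  # truths within the band but estimates far apart: pair scored incorrect
  near <- tibble::tibble(subject_id = "A", condition_id = c("a", "b"),
                         truth = c(300, 310), estimate = c(300, 400))
  expect_equal(ordering_accuracy(near), 0)

  # relative threshold: common positive scaling changes nothing
  withr::with_seed(22, {
    cond2 <- tibble::tibble(subject_id = "A", condition_id = paste0("c", 1:5),
                            truth = runif(5, 200, 600),
                            estimate = runif(5, 200, 600))
    expect_equal(ordering_accuracy(cond2),
                 ordering_accuracy(dplyr::mutate(
                   cond2, truth = truth * 3.7, estimate = estimate * 3.7)))
  })

  expect_error(ordering_accuracy(tibble::tibble(
    subject_id = "A", condition_id = "a", truth = 300, estimate = 300)),
    "fewer than 2")
})

test_that("ordering confusion matrices are rank permutation tallies", {
  cond <- tidyr::expand_grid(subject_id = c("A", "B"),
                             condition_id = paste0("c", 1:4))
  cond$truth <- rep(c(300, 400, 500, 600), 2)
  cond$estimate <- cond$truth
  M <- ordering_confusion(cond)
  expect_equal(M, diag(4))

  # one adjacent swap in every subject -> two off-diagonal entries of 1
  sw <- cond
  sw$estimate[sw$condition_id == "c2"] <- 510
  sw$estimate[sw$condition_id == "c3"] <- 410
  M2 <- ordering_confusion(sw)
  expect_equal(M2[2, 3], 1)
  expect_equal(M2[3, 2], 1)
  expect_equal(rowSums(M2), rep(1, 4))
  expect_equal(colSums(M2), rep(1, 4))

  het <- cond[-1, ]
  expect_error(ordering_confusion(het), "same condition set")
})

test_that("run_use_case enforces non-empty folds and scores planted data exactly", {
  ds <- small_planted()
  labels <- ds$truth$labels
  feats <- assemble_features(ds$trials, labels)
  plan <- plan_novel_condition(ds$trials, seed = 2)
  rep <- run_use_case(ds$trials, plan, "linear", labels = labels,
                      features = feats)
  expect_lt(rep$mean_percent_error, 0.5)
  expect_identical(nrow(rep$folds), 3L)
  expect_equal(rep$r2_train, 1, tolerance = 1e-9)

  # an empty fold is an error
  bad_plan <- plan
  bad_plan$folds[[1]]$test <- tibble::tibble(subject_id = "nope",
                                             condition_id = "none")
  expect_error(run_use_case(ds$trials, bad_plan, "linear", labels = labels,
                            features = feats), "empty")

  # features assembled under different flags are rejected
  expect_error(run_use_case(ds$trials, plan_novel_subject(ds$trials, "raw_subject"),
                            "linear", labels = labels, features = feats),
               "different subset/raw")
})
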