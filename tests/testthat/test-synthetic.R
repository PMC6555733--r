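test_that("generation is fully determined by the seed", {
  cfg <- synthetic_config("assisted", n_subjects = 2, trial_s = 8, seed = 42)
  ds1 <- tiny_assisted()
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$truth$labels, ds2$truth$labels)
  expect_identical(ds1$trials[[5]]$signals, ds2$trials[[5]]$signals)
  expect_identical(ds1$trials[[5]]$breaths, ds2$trials[[5]]$breaths)

  ds3 <- generate_dataset(synthetic_config("assisted", n_subjects = 2,
                                           trial_s = 8, seed = 99))
  expect_false(identical(ds1$trials[[5]]$signals, ds3$trials[[5]]$signals))
})

test_that("designs reproduce the documented channel counts and condition grids", {
  ds <- tiny_assisted()
  expect_length(ds$trials, 2L * 9L)               # 9 assistance conditions
  expect_identical(ncol(ds$trials[[1]]$signals), 22L)

  dsi <- tiny_incline()
  idx <- trial_index(dsi$trials)
  per_subj <- dplyr::count(idx, subject_id)
  expect_true(all(per_subj$n == 12L))             # 4 loads x 3 inclines
  expect_identical(ncol(dsi$trials[[1]]$signals), 14L)
  expect_identical(nrow(dplyr::distinct(
    idx, load_fraction, incline_grade)), 12L)
})

test_that("planted heel strikes are recovered exactly from the raw GRF", {
  for (ds in list(tiny_assisted(), tiny_incline())) {
    keys <- names(ds$truth$strikes)
    idx <- trial_index(ds$trials)
    for (i in seq_along(ds$trials)) {
      t <- ds$trials[[i]]
      key <- paste(t$subject$subject_id, t$condition$condition_id, sep = "/")
      det <- detect_heel_strikes(t$signals$grf_r_z, t$sampling_rate)
      expect_identical(as.integer(det),
                       as.integer(ds$truth$strikes[[key]]))
    }
  }
})

test_that("steady-state EE recovers the generated condition power", {
  ds <- tiny_assisted()
  cfg <- ds$truth$config
  for (t in ds$trials[c(1, 7, 13)]) {
    truth <- ds$truth$labels$power_w[
      ds$truth$labels$subject_id == t$subject$subject_id &
        ds$truth$labels$condition_id == t$condition$condition_id]
    est <- steady_state_ee(t$breaths)
    n_breaths <- nrow(t$breaths)
    tol <- 3 * cfg$breath_cv / sqrt(n_breaths)
    expect_lt(abs(est - truth) / truth, tol)
  }
})

test_that("generated power rises with incline and load", {
  labs <- tiny_incline()$truth$labels
  idx <- trial_index(tiny_incline()$trials)
  labs <- dplyr::left_join(labs, idx, by = c("subject_id", "condition_id"))
  for (s in unique(labs$subject_id)) {
    d <- labs[labs$subject_id == s, ]
    for (lf in unique(d$load_fraction)) {
      sub <- dplyr::arrange(d[d$load_fraction == lf, ], incline_grade)
      expect_true(all(diff(sub$power_w) > 0))
    }
    for (ig in unique(d$incline_grade)) {
      sub <- dplyr::arrange(d[d$incline_grade == ig, ], load_fraction)
      expect_true(all(diff(sub$power_w) > 0))
    }
  }
})

test_that("planted-linear mode stores an exact feature-to-power map", {
  ds <- small_planted()
  expect_false(is.null(ds$truth$planted))
  labels <- ds$truth$labels
  feats <- assemble_features(ds$trials, labels)
  # condition labels from the breath record agree with the planted powers
  lab2 <- condition_labels(ds$trials)
  merged <- dplyr::left_join(lab2, labels, by = c("subject_id", "condition_id"))
  expect_equal(merged$power_w.x, merged$power_w.y, tolerance = 1e-9)
  # every subject/condition shares the planted map on its own features:
  # interior cycles reproduce y = w'x + b
  mid <- feats |>
    dplyr::group_by(subject_id, condition_id) |>
    dplyr::slice(dplyr::n() %/% 2) |>
    dplyr::ungroup()
  pred <- as.numeric(mid$x %*% ds$truth$planted$w) + ds$truth$planted$b
  expect_equal(pred, mid$y, tolerance = 1e-6)
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config("assisted", n_subjects = 1), ">= 2")
  expect_error(synthetic_config("assisted", sampling_rate = 500), "1000")
  cfg <- synthetic_config("assisted", n_subjects = 2, trial_s = 2, seed = 1)
  expect_error(generate_dataset(cfg), "too short")
})
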