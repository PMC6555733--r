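# On-disk dataset layout (documented schema; see also inst/extdata/schema.md):
#
#   root/<subject_id>/<condition_id>/signals.csv    one column per channel
#   root/<subject_id>/<condition_id>/breaths.csv    time,vo2,vco2
#   root/<subject_id>/<condition_id>/meta.json      subject, condition, rate
#
# Numbers are serialized at full double precision (17 significant digits) so
# filter outputs round-trip; CSV is RFC-4180 with a header row.

#' Write one trial to the on-disk layout
#'
#' Creates `root/<subject_id>/<condition_id>/` containing `signals.csv` (one
#' named column per channel), `breaths.csv` (`time,vo2,vco2`) and `meta.json`
#' (subject and condition metadata plus sampling rate).  Round-trips through
#' [read_trial()] losslessly to better than 1e-9 relative.
#'
#' @param trial A validated [trial_recording()].
#' @param root Writable directory; created if missing.
#' @return The trial directory path, invisibly.
#' @export
write_trial <- function(trial, root) {
  validate_trial(trial)
  dir <- file.path(root, trial$subject$subject_id, trial$condition$condition_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("Cannot create trial directory: ", dir))

  fmt <- function(df) {
    out <- df
    for (nm in names(out)) out[[nm]] <- sprintf("%.17g", out[[nm]])
    out
  }
  readr::write_csv(fmt(trial$signals), file.path(dir, "signals.csv"))
  readr::write_csv(fmt(trial$breaths), file.path(dir, "breaths.csv"))
  meta <- list(
    subject = list(subject_id = trial$subject$subject_id,
                   mass = trial$subject$mass,
                   leg_length = trial$subject$leg_length),
    condition = unclass(trial$condition),
    sampling_rate = trial$sampling_rate
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read one trial from the on-disk layout
#'
#' @param path A trial directory as produced by [write_trial()] (or
#'   hand-authored to the same schema).
#' @return A validated [trial_recording()]; channel order as written.
#' @export
read_trial <- function(path) {
  need <- file.path(path, c("signals.csv", "breaths.csv", "meta.json"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L)
    abort(paste0("Trial at '", path, "' is missing: ",
                 paste(basename(missing), collapse = ", ")))
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  for (fld in c("subject", "condition", "sampling_rate"))
    if (is.null(meta[[fld]]))
      abort(paste0("meta.json at '", path, "' is missing '", fld, "'"))
  if (is.null(meta$subject$mass))
    abort(paste0("meta.json at '", path, "' is missing subject 'mass'"))
  subj <- subject_meta(meta$subject$subject_id, meta$subject$mass,
                       meta$subject$leg_length)
  cond <- condition_meta(meta$condition$condition_id,
                         incline_grade = meta$condition$incline_grade %||% 0,
                         load_fraction = meta$condition$load_fraction %||% 0,
                         assistance_work = meta$condition$assistance_work %||% 0,
                         is_baseline_normal_walk =
                           isTRUE(meta$condition$is_baseline_normal_walk))
  signals <- readr::read_csv(file.path(path, "signals.csv"),
                             col_types = readr::cols(.default = readr::col_double()),
                             progress = FALSE)
  breaths <- readr::read_csv(file.path(path, "breaths.csv"),
                             col_types = readr::cols(.default = readr::col_double()),
                             progress = FALSE)
  extra <- setdiff(names(breaths), c("time", "vo2", "vco2"))
  if (length(extra) > 0L)
    abort(paste0("breaths.csv at '", path, "' has unknown column(s): ",
                 paste(extra, collapse = ", ")))
  tryCatch(
    trial_recording(subj, cond, signals, breaths, meta$sampling_rate),
    error = function(e) abort(paste0("Invalid trial at '", path, "': ",
                                     conditionMessage(e)))
  )
}

#' Load every trial under a dataset root
#'
#' Trials are returned in a deterministic order: lexicographic by subject id,
#' then condition id (C collation, platform-independent).
#'
#' @param root Dataset root directory.
#' @return List of [trial_recording()] objects.
#' @export
load_dataset <- function(root) {
  if (!dir.exists(root)) abort(paste0("Dataset root does not exist: ", root))
  dirs <- list.dirs(root, recursive = TRUE, full.names = TRUE)
  trial_dirs <- dirs[file.exists(file.path(dirs, "meta.json"))]
  if (length(trial_dirs) == 0L)
    abort(paste0("No trials found under: ", root))
  key <- vapply(trial_dirs, function(d) {
    paste(basename(dirname(d)), basename(d), sep = "\x01")
  }, "")
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  trial_dirs <- trial_dirs[order(key)]
  trials <- lapply(trial_dirs, read_trial)
  inform(sprintf("Loaded %d trials: %d subjects, %d distinct conditions",
                 length(trials),
                 length(unique(map_chr(trials, ~ .x$subject$subject_id))),
                 length(unique(map_chr(trials, ~ .x$condition$condition_id)))))
  trials
}

#' Summarise a list of trials as a tibble
#'
#' @param trials List of trials.
#' @return One row per trial: ids, mass, condition parameters, duration,
#'   channel count, breath count.
#' @export
trial_index <- function(trials) {
  purrr::map_dfr(trials, function(t) tibble(
    subject_id = t$subject$subject_id,
    condition_id = t$condition$condition_id,
    mass = t$subject$mass,
    incline_grade = t$condition$incline_grade,
    load_fraction = t$condition$load_fraction,
    assistance_work = t$condition$assistance_work,
    is_baseline_normal_walk = t$condition$is_baseline_normal_walk,
    duration_s = trial_duration(t),
    n_channels = ncol(t$signals),
    n_breaths = nrow(t$breaths)
  ))
}
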