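# Channel naming convention: "<kind>_<side>_<axis|muscle>", e.g. "grf_r_z",
# "emg_l_soleus".  The convention is load-bearing: the vertical right-foot GRF
# ("grf_r_z") drives heel-strike segmentation, and channel subsets for the
# wearable-sensor use cases are selected by parsing these names.

#' Parse channel names into kind / side / axis-or-muscle
#'
#' Channels are named `"<kind>_<side>_<axis|muscle>"` where `kind` is `"grf"`
#' or `"emg"`, `side` is `"r"` or `"l"`, and the final token is a force axis
#' (`"x"`, `"y"`, `"z"`; `"z"` vertical) or a muscle label.
#'
#' @param names Character vector of channel names.
#' @return A tibble with columns `name`, `kind`, `side`, `axis_or_muscle`.
#' @examples
#' parse_channel_names(c("grf_r_z", "emg_l_soleus"))
#' @export
parse_channel_names <- function(names) {
  stopifnot(is.character(names))
  parts <- strsplit(names, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) {
    abort(paste0("Malformed channel name(s): ",
                 paste(names[bad], collapse = ", "),
                 " (expected '<kind>_<side>_<axis|muscle>')"))
  }
  kind <- vapply(parts, `[[`, "", 1L)
  side <- vapply(parts, `[[`, "", 2L)
  rest <- vapply(parts, function(p) paste(p[-(1:2)], collapse = "_"), "")
  if (!all(kind %in% c("grf", "emg"))) {
    abort(paste0("Unknown channel kind in: ",
                 paste(names[!kind %in% c("grf", "emg")], collapse = ", ")))
  }
  tibble(name = names, kind = kind, side = side, axis_or_muscle = rest)
}

#' Select channel names for a model-input subset
#'
#' The evaluation protocol restricts model inputs in several ways: all
#' channels; vertical ground reaction forces plus EMG (emulating pressure
#' insoles + surface electrodes); forces only; EMG only.
#'
#' @param names Character vector of channel names.
#' @param subset One of `"all"`, `"vertical_force_plus_emg"`, `"forces_only"`,
#'   `"emg_only"`.
#' @return Character vector, a subset of `names` in their original order.
#' @export
select_channel_subset <- function(names,
                                  subset = c("all", "vertical_force_plus_emg",
                                             "forces_only", "emg_only")) {
  subset <- match.arg(subset)
  info <- parse_channel_names(names)
  sel <- switch(subset,
    all = rep(TRUE, nrow(info)),
    vertical_force_plus_emg =
      (info$kind == "grf" & info$axis_or_muscle == "z") | info$kind == "emg",
    forces_only = info$kind == "grf",
    emg_only = info$kind == "emg"
  )
  out <- names[sel]
  if (length(out) == 0L) abort("Channel subset selects no channels")
  out
}

right_vertical_grf_name <- function(names) {
  info <- parse_channel_names(names)
  hit <- info$name[info$kind == "grf" & info$side == "r" &
                     info$axis_or_muscle == "z"]
  if (length(hit) == 0L) {
    abort("Trial has no right-foot vertical GRF channel ('grf_r_z')")
  }
  hit[[1L]]
}
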