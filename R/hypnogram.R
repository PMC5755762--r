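#' Dark/light phase schedule
#'
#' A phase schedule is an ordered table of `(phase, n_epochs)` segments
#' describing which circadian phase each recording epoch belongs to. The
#' default emulates a 12:12 h light-dark regime at 5-s epochs: 8640 dark
#' epochs followed by 8640 light epochs.
#'
#' @param hours_dark,hours_light Segment lengths in hours for the default
#'   two-segment dark-then-light schedule.
#' @param epoch_s Epoch duration in seconds.
#' @param segments Optional tibble/data frame with columns `phase` and
#'   `n_epochs` overriding the two-segment default; segments may alternate
#'   or repeat freely.
#' @return A tibble of class `phase_schedule` with columns `phase` and
#'   `n_epochs` and attribute `epoch_s`.
#' @examples
#' phase_schedule() # 12 h dark + 12 h light
#' phase_schedule(segments = data.frame(phase = "dark", n_epochs = 1000))
#' @export
phase_schedule <- function(hours_dark = 12, hours_light = 12, epoch_s = 5,
                           segments = NULL) {
  if (is.null(segments)) {
    segments <- tibble(
      phase = c("dark", "light"),
      n_epochs = as.integer(round(c(hours_dark, hours_light) * 3600 / epoch_s))
    )
    segments <- segments[segments$n_epochs > 0, ]
  } else {
    segments <- as_tibble(segments)
    if (!all(c("phase", "n_epochs") %in% names(segments))) {
      abort("`segments` needs columns `phase` and `n_epochs`.")
    }
    segments$n_epochs <- as.integer(segments$n_epochs)
  }
  if (nrow(segments) == 0 || any(segments$n_epochs < 1)) {
    abort("Every schedule segment must contain at least one epoch.")
  }
  structure(segments,
    epoch_s = epoch_s,
    class = c("phase_schedule", class(tibble()))
  )
}

# Expand a schedule into the per-epoch phase vector.
schedule_phases <- function(schedule) {
  rep(schedule$phase, schedule$n_epochs)
}

#' Construct a hypnogram
#'
#' A hypnogram is a per-epoch sequence of behavioural state labels with a
#' parallel dark/light phase label, stored as a tibble with one row per
#' epoch. Epochs are 0-based: epoch `k` covers the half-open interval
#' `[k * epoch_s, (k + 1) * epoch_s)` seconds. Hypnograms come in two
#' arities: 3-state (`WK`, `NREM`, `REM`) as produced by staging, and
#' 4-state (`WKL`, `WKB`, `NREM`, `REM`) after the brief/long wake split.
#'
#' @param states Character vector of per-epoch state labels.
#' @param phase Character vector of per-epoch phase labels (`"dark"` /
#'   `"light"`), recycled if length 1.
#' @param epoch_s Epoch duration in seconds.
#' @param arity 3 or 4; inferred from the labels when `NULL`.
#' @return A tibble of class `hypnogram` with columns `epoch`, `onset_s`,
#'   `state`, `phase`, and attributes `epoch_s` and `arity`.
#' @examples
#' h <- hypnogram(c("WK", "WK", "NREM", "REM"), phase = "dark")
#' attr(h, "arity")
#' @export
hypnogram <- function(states, phase = "dark", epoch_s = 5, arity = NULL) {
  states <- as.character(states)
  n <- length(states)
  if (n == 0) abort("A hypnogram needs at least one epoch.")
  if (length(phase) == 1) phase <- rep(phase, n)
  if (length(phase) != n) {
    abort("`phase` must have one entry per epoch (or length 1).")
  }
  if (is.null(arity)) {
    arity <- if (any(states %in% c("WKL", "WKB"))) 4L else 3L
  }
  alphabet <- if (arity == 4L) state_levels_4 else state_levels_3
  bad <- setdiff(unique(states), alphabet)
  if (length(bad) > 0) {
    abort(sprintf(
      "State label(s) %s not in the %d-state alphabet {%s}.",
      paste(bad, collapse = ", "), arity, paste(alphabet, collapse = ", ")
    ))
  }
  out <- tibble(
    epoch = seq_len(n) - 1L,
    onset_s = (seq_len(n) - 1) * epoch_s,
    state = states,
    phase = as.character(phase)
  )
  structure(out,
    epoch_s = epoch_s, arity = as.integer(arity),
    class = c("hypnogram", class(tibble()))
  )
}

hypnogram_arity <- function(h) {
  attr(h, "arity") %||% (if (any(h$state %in% c("WKL", "WKB"))) 4L else 3L)
}

hypnogram_epoch_s <- function(h) attr(h, "epoch_s") %||% 5

#' Collapse a 4-state hypnogram to 3 states
#'
#' Maps `WKL` and `WKB` back to plain `WK`, leaving `NREM`/`REM` untouched.
#' This is the inverse direction of [relabel_four_state()].
#'
#' @param h A 4-state `hypnogram`.
#' @return A 3-state `hypnogram`.
#' @export
collapse_wake <- function(h) {
  s <- ifelse(h$state %in% c("WKL", "WKB"), "WK", h$state)
  hypnogram(s, phase = h$phase, epoch_s = hypnogram_epoch_s(h), arity = 3L)
}

#' Write or read a hypnogram as TSV
#'
#' Tab-separated with a header line and columns `epoch_index`, `onset_s`,
#' `state`, `phase`; one row per 5-s epoch.
#'
#' @param h A `hypnogram`.
#' @param path File path.
#' @param epoch_s Epoch duration used when reading (onsets in the file are
#'   cross-checked against it).
#' @return `write_hypnogram()` returns `path` invisibly; `read_hypnogram()`
#'   returns a `hypnogram`.
#' @export
write_hypnogram <- function(h, path) {
  readr::write_tsv(
    tibble(
      epoch_index = h$epoch, onset_s = h$onset_s,
      state = h$state, phase = h$phase
    ),
    path
  )
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, epoch_s = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("epoch_index", "onset_s", "state", "phase")
  if (!all(need %in% names(x))) {
    abort(sprintf(
      "Hypnogram TSV must have columns %s.",
      paste(need, collapse = ", ")
    ))
  }
  if (is.null(epoch_s)) {
    epoch_s <- if (nrow(x) > 1) x$onset_s[2] - x$onset_s[1] else 5
  }
  hypnogram(x$state, phase = x$phase, epoch_s = epoch_s)
}
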