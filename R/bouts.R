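#' Extract bouts from a hypnogram
#'
#' A bout is a maximal run of consecutive epochs in the same state. Each
#' bout carries its onset epoch, length, duration (to the nearest epoch),
#' and the phase of its first epoch (a bout spanning the dark/light
#' boundary is attributed wholly to its onset phase). The first and last
#' bouts of the recording are flagged as boundary-truncated since their
#' true duration is unobserved.
#'
#' @param h A [hypnogram()] (3- or 4-state).
#' @return A tibble of class `bout_table` with columns `state`,
#'   `start_epoch` (0-based), `n_epochs`, `duration_s`, `onset_phase`,
#'   `truncated`.
#' @examples
#' extract_bouts(hypnogram(c("WK", "WK", "NREM", "NREM", "NREM", "WK")))
#' @export
extract_bouts <- function(h) {
  if (nrow(h) == 0) abort("Hypnogram is empty.")
  epoch_s <- hypnogram_epoch_s(h)
  r <- rle(h$state)
  starts <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  out <- tibble(
    state = r$values,
    start_epoch = starts,
    n_epochs = r$lengths,
    duration_s = r$lengths * epoch_s,
    onset_phase = h$phase[starts + 1],
    truncated = seq_along(r$values) %in% c(1L, length(r$values))
  )
  structure(out,
    epoch_s = epoch_s, arity = hypnogram_arity(h),
    class = c("bout_table", class(tibble()))
  )
}

#' Split wake bouts into brief and long wake
#'
#' Relabels 3-state `WK` bouts by duration: bouts shorter than `cutoff_s`
#' become brief wake (`WKB`), bouts of at least `cutoff_s` become long wake
#' (`WKL`). A bout of exactly the cutoff is long wake, since brief wake is
#' defined as strictly shorter than the cutoff. NREM/REM bouts pass
#' through. The operation refuses 4-state input (already split).
#'
#' @param bouts A 3-state `bout_table` from [extract_bouts()].
#' @param cutoff_s Brief/long cutoff in seconds (default 150).
#' @return A 4-state `bout_table`.
#' @examples
#' b <- extract_bouts(hypnogram(rep(c("WK", "NREM"), c(29, 5))))
#' split_wake(b)$state[1] # 145 s of wake -> WKB
#' @export
split_wake <- function(bouts, cutoff_s = 150) {
  if (any(bouts$state %in% c("WKL", "WKB"))) {
    abort("Input already contains split wake states (4-state); `split_wake()` expects 3-state bouts.")
  }
  is_wk <- bouts$state == "WK"
  bouts$state[is_wk] <- ifelse(
    bouts$duration_s[is_wk] < cutoff_s, "WKB", "WKL"
  )
  attr(bouts, "arity") <- 4L
  bouts
}

#' Rebuild a hypnogram from a bout table
#'
#' Inverse of [extract_bouts()]: expands each bout back into its per-epoch
#' labels. Useful for duration-based relabelling of epochs.
#'
#' @param bouts A `bout_table`.
#' @param phase Per-epoch phase labels; reconstructed from `onset_phase`
#'   when omitted (exact only if no bout spans a phase change).
#' @return A [hypnogram()].
#' @export
bouts_to_hypnogram <- function(bouts, phase = NULL) {
  states <- rep(bouts$state, bouts$n_epochs)
  phase <- phase %||% rep(bouts$onset_phase, bouts$n_epochs)
  hypnogram(states, phase = phase, epoch_s = attr(bouts, "epoch_s") %||% 5)
}

#' Bout-duration histogram
#'
#' Bins bout durations on a linear or logarithmic grid and returns counts
#' and a density normalised to integrate to one over the binned range.
#' Log-spaced bins are the natural scale for wake durations, whose mixture
#' of brief and long bouts shows up as two local maxima.
#'
#' @param durations_s Numeric vector of bout durations in seconds.
#' @param log_bins Use log-spaced bin edges?
#' @param n_bins Number of bins.
#' @return A tibble with `bin_lo`, `bin_hi`, `mid`, `count`, `density`.
#' @export
duration_histogram <- function(durations_s, log_bins = FALSE, n_bins = 30) {
  if (length(durations_s) == 0) abort("No durations supplied.")
  lo <- min(durations_s)
  hi <- max(durations_s)
  if (lo == hi) {
    return(tibble(
      bin_lo = lo - 0.5, bin_hi = hi + 0.5, mid = lo,
      count = length(durations_s), density = 1
    ))
  }
  edges <- if (log_bins) {
    exp(seq(log(lo), log(hi), length.out = n_bins + 1))
  } else {
    seq(lo, hi, length.out = n_bins + 1)
  }
  idx <- findInterval(durations_s, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  widths <- diff(edges)
  dens <- counts / (sum(counts) * widths)
  tibble(
    bin_lo = edges[-length(edges)], bin_hi = edges[-1],
    mid = if (log_bins) sqrt(edges[-length(edges)] * edges[-1]) else (edges[-1] + edges[-length(edges)]) / 2,
    count = counts, density = dens
  )
}
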