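#' Power spectral density of a single 5-s epoch
#'
#' Hamming-windowed periodogram of one epoch with one full-epoch window (a
#' 5-s window at any sampling rate gives exactly 0.20-Hz frequency
#' resolution). The one-sided spectrum is scaled so that the sum of all
#' bins equals the windowed time-domain energy `sum((w * x)^2)` (Parseval);
#' bins above `max_hz` are discarded after scaling.
#'
#' @param x Numeric vector holding exactly one epoch of samples.
#' @param fs Sampling rate in Hz.
#' @param max_hz Upper frequency cut for the returned bins (default 120;
#'   `NULL` keeps everything up to Nyquist).
#' @param window Window function values (defaults to a Hamming window of
#'   the epoch length).
#' @return A tibble of class `power_spectrum` with columns `frequency`
#'   (Hz) and `power`.
#' @examples
#' fs <- 250
#' x <- sin(2 * pi * 8 * (0:1249) / fs)
#' ps <- epoch_psd(x, fs)
#' ps$frequency[which.max(ps$power)] # 8 Hz, on the 0.2-Hz grid
#' @export
epoch_psd <- function(x, fs, max_hz = 120, window = NULL) {
  n <- length(x)
  if (n < 2) abort("Epoch too short.")
  w <- window %||% hamming_window(n)
  if (length(w) != n) abort("Window length must match the epoch length.")
  xw <- x * w
  X <- fft(xw)
  half <- floor(n / 2)
  idx <- 1:(half + 1)
  mult <- rep(2, half + 1)
  mult[1] <- 1
  if (n %% 2 == 0) mult[half + 1] <- 1
  power <- mult * Mod(X[idx])^2 / n
  freq <- (idx - 1) * fs / n
  keep <- if (is.null(max_hz)) rep(TRUE, length(freq)) else freq <= max_hz
  structure(
    tibble(frequency = freq[keep], power = power[keep]),
    fs = fs, n = n, total_energy = sum(power),
    class = c("power_spectrum", class(tibble()))
  )
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Per-epoch Hamming periodograms of a whole channel, chunked. Returns the
# bins x epochs power matrix plus the frequency grid.
psd_matrix <- function(x, fs, epoch_s, max_hz = 120, chunk_epochs = 2000L) {
  L <- as.integer(round(epoch_s * fs))
  n_ep <- floor(length(x) / L)
  w <- hamming_window(L)
  half <- floor(L / 2)
  idx <- 1:(half + 1)
  mult <- rep(2, half + 1)
  mult[1] <- 1
  if (L %% 2 == 0) mult[half + 1] <- 1
  freq <- (idx - 1) * fs / L
  keep <- if (is.null(max_hz)) rep(TRUE, length(freq)) else freq <= max_hz
  out <- matrix(NA_real_, sum(keep), n_ep)
  e0 <- 1L
  while (e0 <= n_ep) {
    e1 <- min(n_ep, e0 + chunk_epochs - 1L)
    seg <- matrix(x[((e0 - 1) * L + 1):(e1 * L)], L, e1 - e0 + 1L) * w
    X <- mvfft(seg)
    out[, e0:e1] <- (mult * Mod(X[idx, , drop = FALSE])^2 / L)[keep, , drop = FALSE]
    e0 <- e1 + 1L
  }
  list(power = out, frequency = freq[keep], n_epochs = n_ep)
}

#' State-conditioned mean spectral profiles
#'
#' For each requested channel, per-epoch Hamming periodograms are z-scored
#' per frequency bin across all artifact-free epochs of the recording (the
#' within-animal normalisation that removes inter-individual differences in
#' absolute power), then averaged within each behavioural state. The
#' epoch-count-weighted average of all state profiles is therefore ~0 in
#' every bin.
#'
#' @param recording A `sleep_recording`.
#' @param h Hypnogram aligned to the recording (defaults to the recording's
#'   ground truth).
#' @param channels Channels to profile.
#' @param max_hz Upper frequency limit (0.20-Hz bins up to here).
#' @param artifact_mask Optional logical vector (TRUE = artifact, excluded
#'   from both the z-fit and the state means).
#' @return A tibble of class `state_spectra`: `channel`, `state`,
#'   `frequency`, `z_power`, `n_epochs`. States absent from the hypnogram
#'   are reported with `n_epochs = 0` and `NA` profiles.
#' @export
state_mean_spectrum <- function(recording, h = recording$truth,
                                channels = names(recording$channels),
                                max_hz = 120, artifact_mask = NULL) {
  if (is.null(h)) abort("No hypnogram supplied and the recording has no ground truth.")
  states <- sort(unique(h$state))
  purrr::map_dfr(channels, function(ch) {
    pm <- psd_matrix(
      recording$channels[[ch]], recording$fs,
      hypnogram_epoch_s(h), max_hz
    )
    n_ep <- pm$n_epochs
    lab <- h$state[seq_len(n_ep)]
    ok <- if (is.null(artifact_mask)) {
      rep(TRUE, n_ep)
    } else {
      !artifact_mask[seq_len(n_ep)]
    }
    mu <- rowMeans(pm$power[, ok, drop = FALSE])
    sdv <- sqrt(rowMeans((pm$power[, ok, drop = FALSE] - mu)^2))
    sdv[sdv == 0] <- 1
    z <- (pm$power - mu) / sdv
    purrr::map_dfr(states, function(st) {
      sel <- which(lab == st & ok)
      tibble(
        channel = ch, state = st, frequency = pm$frequency,
        z_power = if (length(sel) > 0) {
          rowMeans(z[, sel, drop = FALSE])
        } else {
          NA_real_
        },
        n_epochs = length(sel)
      )
    })
  }) |>
    structure(class = c("state_spectra", class(tibble())))
}

#' Per-epoch band-power time course
#'
#' Average Hamming-periodogram power over each band's frequency bins, per
#' epoch — the building block of e.g. a NREM delta-power time course across
#' the dark and light phases.
#'
#' @param recording A `sleep_recording`.
#' @param bands Tibble with `band`, `channel`, `low_hz`, `high_hz`.
#' @param epoch_s Epoch length in seconds.
#' @return A tibble `epoch`, `onset_s`, `band`, `power`.
#' @export
band_timecourse <- function(recording, bands = default_bands(recording$fs),
                            epoch_s = recording$epoch_s %||% 5) {
  purrr::map_dfr(unique(bands$channel), function(ch) {
    if (!ch %in% names(recording$channels)) {
      abort(sprintf("Channel '%s' absent from the recording.", ch))
    }
    sub <- bands[bands$channel == ch, ]
    pm <- psd_matrix(recording$channels[[ch]], recording$fs, epoch_s,
      max_hz = NULL
    )
    purrr::map_dfr(seq_len(nrow(sub)), function(i) {
      sel <- pm$frequency >= sub$low_hz[i] & pm$frequency < sub$high_hz[i]
      if (!any(sel)) {
        abort(sprintf(
          "Band '%s' (%g-%g Hz) covers no frequency bins.",
          sub$band[i], sub$low_hz[i], sub$high_hz[i]
        ))
      }
      tibble(
        epoch = seq_len(pm$n_epochs) - 1L,
        onset_s = (seq_len(pm$n_epochs) - 1) * epoch_s,
        band = sub$band[i],
        power = colMeans(pm$power[sel, , drop = FALSE])
      )
    })
  })
}

#' Detect the theta peak of a spectral profile
#'
#' Finds the argmax of the profile within the theta search range after a
#' 3-bin moving-average smoothing. Works on a `power_spectrum` (columns
#' `frequency`, `power`) or on `state_spectra` rows (grouped per channel
#' and state, column `z_power`). A flat profile is flagged as having no
#' peak.
#'
#' @param profile A `power_spectrum` or `state_spectra` tibble.
#' @param low_hz,high_hz Search range (default 4-10 Hz).
#' @return A tibble with `peak_hz`, `peak_power`, `found` (plus `channel`
#'   and `state` for `state_spectra` input).
#' @export
detect_theta_peak <- function(profile, low_hz = 4, high_hz = 10) {
  one <- function(freq, pw) {
    sm <- stats::filter(pw, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- pw[is.na(sm)]
    sel <- which(freq >= low_hz & freq <= high_hz)
    if (length(sel) == 0) {
      abort("Profile does not cover the search range.")
    }
    ps <- as.numeric(sm[sel])
    if (max(ps) - min(ps) < 1e-12) {
      return(tibble(peak_hz = NA_real_, peak_power = NA_real_, found = FALSE))
    }
    i <- sel[which.max(ps)]
    tibble(peak_hz = freq[i], peak_power = ps[which.max(ps)], found = TRUE)
  }
  if (all(c("channel", "state") %in% names(profile))) {
    profile |>
      dplyr::group_by(.data$channel, .data$state) |>
      dplyr::group_modify(function(d, key) {
        if (all(is.na(d$z_power))) {
          return(tibble(peak_hz = NA_real_, peak_power = NA_real_, found = FALSE))
        }
        one(d$frequency, d$z_power)
      }) |>
      dplyr::ungroup()
  } else {
    one(profile$frequency, profile$power)
  }
}

#' Write state spectral profiles as TSV
#'
#' Long format: `state`, `channel`, `frequency`, `z_power`.
#'
#' @param profiles A `state_spectra` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(profiles, path) {
  readr::write_tsv(
    as_tibble(profiles)[, c("state", "channel", "frequency", "z_power", "n_epochs")],
    path
  )
  invisible(path)
}
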