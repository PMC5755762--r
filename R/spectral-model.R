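#' State-conditioned spectral model for synthetic EEG/EMG
#'
#' A spectral model describes, for each channel (`cortex`, `hippocampus`,
#' `emg`) and behavioural state, the spectral content of the synthetic
#' signal as a sum of band-limited Gaussian noise components (each with a
#' per-state amplitude gain) plus narrow sinusoidal oscillators (each with a
#' per-state amplitude). It is stored tidily: one row per
#' channel/component/state combination.
#'
#' @param components A tibble with columns `channel`, `component`, `type`
#'   (`"band"` or `"oscillator"`), `low_hz`, `high_hz` (bands), `center_hz`
#'   (oscillators), `state`, `gain`.
#' @param fs Sampling rate in Hz.
#' @return An object of class `spectral_model`.
#' @seealso [default_spectral_model()], [synthesize_signals()]
#' @export
spectral_model <- function(components, fs = 250) {
  components <- as_tibble(components)
  need <- c("channel", "component", "type", "state", "gain")
  if (!all(need %in% names(components))) {
    abort(sprintf(
      "`components` needs columns %s.",
      paste(need, collapse = ", ")
    ))
  }
  if (!"low_hz" %in% names(components)) components$low_hz <- NA_real_
  if (!"high_hz" %in% names(components)) components$high_hz <- NA_real_
  if (!"center_hz" %in% names(components)) components$center_hz <- NA_real_
  if (any(components$gain < 0)) abort("Gains must be nonnegative.")
  bands <- components[components$type == "band", ]
  if (nrow(bands) > 0) {
    if (any(!is.finite(bands$low_hz)) || any(!is.finite(bands$high_hz)) ||
      any(bands$low_hz <= 0) || any(bands$low_hz >= bands$high_hz) ||
      any(bands$high_hz >= fs / 2)) {
      abort("Band edges must satisfy 0 < low < high < fs/2.")
    }
  }
  osc <- components[components$type == "oscillator", ]
  if (nrow(osc) > 0 && (any(!is.finite(osc$center_hz)) ||
    any(osc$center_hz <= 0) || any(osc$center_hz >= fs / 2))) {
    abort("Oscillator centres must lie in (0, fs/2).")
  }
  structure(list(components = components, fs = fs), class = "spectral_model")
}

#' Default state-conditioned spectral model
#'
#' The defaults emulate the qualitative spectral signatures of the four
#' mouse sleep-wake states: long wake (`WKL`) with a strong 8-Hz hippocampal
#' theta oscillation (type I theta), elevated hippocampal fast gamma
#' (55-125 Hz band, capped below Nyquist) and high EMG tone; brief wake
#' (`WKB`) with a slower 6-Hz theta peak (type II theta), reduced fast gamma
#' and reduced EMG tone; NREM with dominant cortical delta (1-4 Hz), spindle
#' (10-15 Hz) and beta (15-25 Hz) power, low gamma and low EMG; REM with
#' dominant 8-Hz theta, low delta and the lowest EMG tone. Gains are chosen
#' so the four states are linearly separable in the staging feature space.
#'
#' @param fs Sampling rate in Hz (default 250, sufficient for 0-120 Hz
#'   analysis).
#' @return A [spectral_model()].
#' @examples
#' m <- default_spectral_model()
#' subset(m$components, component == "theta8")
#' @export
default_spectral_model <- function(fs = 250) {
  g_hi <- min(124, 0.992 * fs / 2)
  band <- function(channel, component, low, high, WKL, REM, NREM, WKB) {
    tibble(
      channel = channel, component = component, type = "band",
      low_hz = low, high_hz = high, center_hz = NA_real_,
      state = state_levels_4, gain = c(WKL, REM, NREM, WKB)
    )
  }
  oscillator <- function(channel, component, center, WKL, REM, NREM, WKB) {
    tibble(
      channel = channel, component = component, type = "oscillator",
      low_hz = NA_real_, high_hz = NA_real_, center_hz = center,
      state = state_levels_4, gain = c(WKL, REM, NREM, WKB)
    )
  }
  components <- dplyr::bind_rows(
    # cortex: delta/spindle/beta structure dominates NREM
    band("cortex", "delta", 1, 4, WKL = 0.5, REM = 0.4, NREM = 2.0, WKB = 0.6),
    band("cortex", "sigma", 10, 15, WKL = 0.5, REM = 0.5, NREM = 1.5, WKB = 0.5),
    band("cortex", "beta", 15, 25, WKL = 0.7, REM = 0.6, NREM = 1.5, WKB = 0.7),
    band("cortex", "broadband", 1, 100, WKL = 0.3, REM = 0.3, NREM = 0.3, WKB = 0.3),
    # hippocampus: theta and gamma separate the wake substates
    band("hippocampus", "theta_band", 4, 10, WKL = 1.2, REM = 1.5, NREM = 0.4, WKB = 0.8),
    band("hippocampus", "gamma_slow", 25, 55, WKL = 1.2, REM = 0.7, NREM = 0.4, WKB = 1.1),
    band("hippocampus", "gamma_fast", 55, g_hi, WKL = 1.2, REM = 0.6, NREM = 0.3, WKB = 0.7),
    band("hippocampus", "broadband", 1, g_hi, WKL = 0.3, REM = 0.3, NREM = 0.3, WKB = 0.3),
    oscillator("hippocampus", "theta8", 8, WKL = 1.5, REM = 2.0, NREM = 0, WKB = 0),
    oscillator("hippocampus", "theta6", 6, WKL = 0, REM = 0, NREM = 0, WKB = 1.0),
    # emg: muscle tone, graded WKL > WKB > NREM > REM
    band("emg", "tone", 55, 90, WKL = 2.0, REM = 0.15, NREM = 0.3, WKB = 1.2),
    band("emg", "broadband", 5, 100, WKL = 0.3, REM = 0.2, NREM = 0.2, WKB = 0.25)
  )
  spectral_model(components, fs = fs)
}
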