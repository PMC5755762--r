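#' Default frequency bands for sleep staging
#'
#' The seven staging bands: cortical delta (1-4 Hz), sigma/spindle
#' (10-15 Hz) and beta (15-25 Hz); hippocampal theta (4-10 Hz), slow gamma
#' (25-55 Hz) and fast gamma (55-125 Hz, capped at 120 Hz when the sampling
#' rate puts 125 Hz at or above Nyquist); and the EMG band (55-90 Hz).
#'
#' @param fs Sampling rate in Hz; only used to cap the fast-gamma edge.
#' @return A tibble with columns `band`, `channel`, `low_hz`, `high_hz`.
#' @export
default_bands <- function(fs = 250) {
  tibble(
    band = c(
      "delta_cx", "sigma_cx", "beta_cx",
      "theta_hc", "gamma1_hc", "gamma2_hc", "emg"
    ),
    channel = c(
      "cortex", "cortex", "cortex",
      "hippocampus", "hippocampus", "hippocampus", "emg"
    ),
    low_hz = c(1, 10, 15, 4, 25, 55, 55),
    high_hz = c(4, 15, 25, 10, 55, min(125, 0.96 * fs / 2), 90)
  )
}

#' Staging configuration
#'
#' @param threshold_high,threshold_low Z-score cutoffs defining "high" and
#'   "low" feature values for the rule-based seeding pass.
#' @param index_mode How the theta/delta and beta/gamma indices are formed
#'   from band z-scores: `"difference"` (default; `z(num) - z(den)`, the
#'   bounded log-ratio analogue on standardised scales) or `"ratio"` (the
#'   literal ratio computed on shifted-positive z-scores).
#' @param artifact_z Broadband RMS z-score above which an epoch is treated
#'   as an artifact: excluded from z-score fitting but still classified.
#' @param min_bout_epochs Optional post-hoc minimum bout length; runs
#'   shorter than this are merged into the preceding state. Default 0
#'   (off).
#' @param kmeans_passes Number of K-means refinement passes (fixed at 2).
#' @param epoch_s Epoch duration in seconds.
#' @return A list of class `staging_config`.
#' @export
staging_config <- function(threshold_high = 0.5, threshold_low = -0.5,
                           index_mode = c("difference", "ratio"),
                           artifact_z = 5, min_bout_epochs = 0,
                           kmeans_passes = 2, epoch_s = 5) {
  if (threshold_high <= threshold_low) {
    abort("`threshold_high` must exceed `threshold_low`.")
  }
  structure(
    list(
      threshold_high = threshold_high, threshold_low = threshold_low,
      index_mode = match.arg(index_mode), artifact_z = artifact_z,
      min_bout_epochs = min_bout_epochs, kmeans_passes = kmeans_passes,
      epoch_s = epoch_s
    ),
    class = "staging_config"
  )
}

# Per-epoch RMS of a band-filtered channel, computed per 5-s epoch in the
# frequency domain: the epoch DFT power is weighted by the squared-magnitude
# response of a zero-phase 4th-order Butterworth band-pass and summed
# (Parseval). Equivalent to time-domain forward-backward filtering up to
# epoch-edge effects, and orders of magnitude faster on long recordings.
band_rms_fft <- function(x, fs, epoch_s, bands_ch, chunk_epochs = 5000L) {
  L <- as.integer(round(epoch_s * fs))
  n_ep <- floor(length(x) / L)
  fq <- (seq_len(L) - 1) * fs / L
  f_fold <- pmin(fq, fs - fq) # two-sided grid folded onto [0, fs/2]
  weights <- lapply(seq_len(nrow(bands_ch)), function(i) {
    butter_band_weight(f_fold, bands_ch$low_hz[i], bands_ch$high_hz[i])
  })
  out <- matrix(NA_real_, n_ep, nrow(bands_ch))
  raw_rms <- numeric(n_ep)
  e0 <- 1L
  while (e0 <= n_ep) {
    e1 <- min(n_ep, e0 + chunk_epochs - 1L)
    m <- e1 - e0 + 1L
    seg <- matrix(x[((e0 - 1) * L + 1):(e1 * L)], L, m)
    raw_rms[e0:e1] <- sqrt(colMeans(seg^2))
    pw <- Mod(mvfft(seg))^2
    for (i in seq_along(weights)) {
      out[e0:e1, i] <- sqrt(colSums(pw * weights[[i]])) / L
    }
    e0 <- e1 + 1L
  }
  list(band_rms = out, raw_rms = raw_rms, n_epochs = n_ep)
}

# Time-domain reference realisation: zero-phase Butterworth band-pass of
# the whole channel, then per-epoch RMS. Used for cross-validation on short
# signals.
band_rms_butter <- function(x, fs, epoch_s, bands_ch) {
  L <- as.integer(round(epoch_s * fs))
  n_ep <- floor(length(x) / L)
  x <- x[seq_len(n_ep * L)]
  out <- matrix(NA_real_, n_ep, nrow(bands_ch))
  for (i in seq_len(nrow(bands_ch))) {
    bf <- signal::butter(
      4, c(bands_ch$low_hz[i], bands_ch$high_hz[i]) / (fs / 2),
      type = "pass"
    )
    y <- signal::filtfilt(bf, x)
    out[, i] <- sqrt(colMeans(matrix(y^2, L, n_ep)))
  }
  list(
    band_rms = out,
    raw_rms = sqrt(colMeans(matrix(x^2, L, n_ep))),
    n_epochs = n_ep
  )
}

#' Per-epoch band z-score features for staging
#'
#' For every band, the channel is band-pass filtered (zero-phase 4th-order
#' Butterworth response), the RMS is taken per 5-s epoch, and the per-epoch
#' RMS values are z-scored across all epochs of the recording (population
#' SD; artifact epochs are excluded from the fit but still transformed).
#' Two ratio indices are then formed: a theta/delta index
#' (`theta_hc` vs `delta_cx`) and a beta/gamma index (`beta_cx` vs
#' `gamma1_hc`), by default as differences of z-scores.
#'
#' @param recording A `sleep_recording` (or any list with `channels`, `fs`).
#' @param bands Band definition tibble; see [default_bands()].
#' @param config A [staging_config()].
#' @param method `"fft"` (per-epoch frequency-domain filtering; default) or
#'   `"butter"` (time-domain forward-backward filtering of the full
#'   channel).
#' @return A tibble of class `epoch_features`: `epoch`, one z-score column
#'   per band, `theta_delta_index`, `beta_gamma_index`, `artifact`, and
#'   `phase` when the recording carries a ground-truth hypnogram.
#' @export
compute_epoch_features <- function(recording,
                                   bands = default_bands(recording$fs),
                                   config = staging_config(),
                                   method = c("fft", "butter")) {
  method <- match.arg(method)
  fs <- recording$fs
  epoch_s <- recording$epoch_s %||% config$epoch_s
  missing_ch <- setdiff(unique(bands$channel), names(recording$channels))
  if (length(missing_ch) > 0) {
    abort(sprintf(
      "Band(s) reference channel(s) absent from the recording: %s.",
      paste(missing_ch, collapse = ", ")
    ))
  }
  if (any(bands$high_hz >= fs / 2)) {
    abort("Band edges must lie strictly below fs/2.")
  }
  L <- as.integer(round(epoch_s * fs))
  n_sam <- length(recording$channels[[bands$channel[1]]])
  if (n_sam %% L != 0) {
    warn(sprintf(
      "Signal length is not a multiple of the epoch (%d samples); dropping the trailing partial epoch.",
      n_sam %% L
    ))
  }

  rms_cols <- matrix(NA_real_, floor(n_sam / L), nrow(bands))
  raw_z_max <- rep(-Inf, floor(n_sam / L))
  for (ch in unique(bands$channel)) {
    idx <- which(bands$channel == ch)
    res <- if (method == "fft") {
      band_rms_fft(recording$channels[[ch]], fs, epoch_s, bands[idx, ])
    } else {
      band_rms_butter(recording$channels[[ch]], fs, epoch_s, bands[idx, ])
    }
    rms_cols[, idx] <- res$band_rms
    raw_z_max <- pmax(raw_z_max, z_pop(res$raw_rms))
  }
  artifact <- raw_z_max > config$artifact_z

  z <- apply(rms_cols, 2, z_pop, fit = !artifact)
  colnames(z) <- bands$band

  idx_pair <- function(num, den) {
    if (config$index_mode == "difference") {
      z[, num] - z[, den]
    } else {
      shift <- function(v) v - min(v) + 1
      z_pop(shift(z[, num]) / shift(z[, den]), fit = !artifact)
    }
  }
  out <- as_tibble(z)
  out$epoch <- seq_len(nrow(out)) - 1L
  out$theta_delta_index <- idx_pair("theta_hc", "delta_cx")
  out$beta_gamma_index <- idx_pair("beta_cx", "gamma1_hc")
  out$artifact <- artifact
  if (!is.null(recording$truth)) {
    out$phase <- recording$truth$phase[seq_len(nrow(out))]
  }
  out <- out[, c(
    "epoch", bands$band, "theta_delta_index", "beta_gamma_index",
    "artifact", intersect("phase", names(out))
  )]
  structure(out,
    epoch_s = epoch_s, band_names = bands$band,
    class = c("epoch_features", class(tibble()))
  )
}

# The three rule features and the fixed-threshold state rules. `hi`/`lo`
# may be scalars (first pass) or named per-feature vectors (second pass).
apply_seed_rules <- function(td, bg, emg, hi, lo) {
  h <- function(f) if (length(hi) > 1) hi[[f]] else hi
  l <- function(f) if (length(lo) > 1) lo[[f]] else lo
  seed <- rep(NA_character_, length(td))
  seed[td > h("theta_delta_index") & emg < l("emg")] <- "REM"
  seed[td < l("theta_delta_index") & bg > h("beta_gamma_index") &
    emg < l("emg")] <- "NREM"
  seed[bg < l("beta_gamma_index") & td > h("theta_delta_index") &
    emg > h("emg")] <- "WK"
  seed
}

#' Rule-based seeding of sleep-stage labels
#'
#' Assigns provisional labels to epochs whose features fall clearly on one
#' side of the fixed thresholds: wake requires a low beta/gamma index, a
#' high theta/delta index and high EMG; NREM a low theta/delta index, high
#' beta/gamma index and low EMG; REM a high theta/delta index and low EMG.
#' Epochs matching no rule stay unassigned (`NA`) for the K-means passes.
#' Wake and REM rules cannot overlap because they require opposite EMG
#' levels.
#'
#' @param features An `epoch_features` tibble.
#' @param config A [staging_config()] supplying the thresholds.
#' @return `features` with an added `seed_state` column
#'   (`"WK"`/`"NREM"`/`"REM"`/`NA`).
#' @export
seed_labels <- function(features, config = staging_config()) {
  features$seed_state <- apply_seed_rules(
    features$theta_delta_index, features$beta_gamma_index, features$emg,
    config$threshold_high, config$threshold_low
  )
  features
}

staging_feature_matrix <- function(features) {
  cols <- c(
    attr(features, "band_names") %||%
      setdiff(
        names(features),
        c("epoch", "theta_delta_index", "beta_gamma_index", "artifact", "phase", "seed_state")
      ),
    "theta_delta_index", "beta_gamma_index"
  )
  as.matrix(features[, cols])
}

#' Two-pass K-means refinement of seeded stage labels
#'
#' Pass 1 runs K-means (k = 3) on the full feature space (seven band
#' z-scores plus the two indices), initialised at the centroids of the
#' seeded classes, which classifies the unassigned epochs. The high/low
#' thresholds of each rule feature are then recalculated as midpoints
#' between the ordered class centroids, the rules are re-applied with the
#' new thresholds, and a second K-means pass from the re-seeded centroids
#' fixes the definitive staging. The procedure is deterministic: no random
#' restarts, and cluster identity is carried by the initial centroids.
#'
#' @param features An `epoch_features` tibble.
#' @param seeds Optional character vector of seed labels; defaults to the
#'   `seed_state` column produced by [seed_labels()].
#' @param config A [staging_config()].
#' @return A 3-state [hypnogram()] covering every epoch.
#' @export
kmeans_refine <- function(features, seeds = NULL, config = staging_config()) {
  seeds <- seeds %||% features$seed_state
  if (is.null(seeds)) {
    abort("No seed labels; run `seed_labels()` first or pass `seeds`.")
  }
  fm <- staging_feature_matrix(features)
  states <- state_levels_3
  n_seed <- vapply(states, function(s) sum(seeds == s, na.rm = TRUE), 0L)
  if (any(n_seed == 0)) {
    abort(sprintf(
      "No seeded epochs for state(s) %s; adjust the seeding thresholds.",
      paste(states[n_seed == 0], collapse = ", ")
    ))
  }
  centroids <- function(lab) {
    t(vapply(
      states,
      function(s) colMeans(fm[which(lab == s), , drop = FALSE]),
      numeric(ncol(fm))
    ))
  }
  run_km <- function(centers) {
    suppressWarnings(
      kmeans(fm, centers = centers, iter.max = 200, algorithm = "Lloyd")
    )
  }

  km1 <- run_km(centroids(seeds))

  # Recalculated thresholds: for each rule feature, the midpoint between
  # the centroids of the classes the rule separates. EMG splits wake from
  # both sleep states; theta/delta splits NREM from the theta-rich states
  # (WK, REM); beta/gamma splits wake (low) and NREM (high) from the rest.
  td_col <- match("theta_delta_index", colnames(fm))
  bg_col <- match("beta_gamma_index", colnames(fm))
  emg_col <- match("emg", colnames(fm))
  cen <- km1$centers
  rownames(cen) <- states # rows follow the seeding centroid order
  emg_cut <- mean(c(cen["WK", emg_col], max(cen[c("NREM", "REM"), emg_col])))
  td_cut <- mean(c(cen["NREM", td_col], min(cen[c("WK", "REM"), td_col])))
  bg_lo <- mean(c(cen["WK", bg_col], min(cen[c("NREM", "REM"), bg_col])))
  bg_hi <- mean(c(cen["NREM", bg_col], max(cen[c("WK", "REM"), bg_col])))
  hi2 <- list(
    theta_delta_index = td_cut, beta_gamma_index = bg_hi, emg = emg_cut
  )
  lo2 <- list(
    theta_delta_index = td_cut, beta_gamma_index = bg_lo, emg = emg_cut
  )
  seeds2 <- apply_seed_rules(
    fm[, td_col], fm[, bg_col], fm[, emg_col], hi2, lo2
  )
  centers2 <- centroids(seeds2)
  empty <- !is.finite(centers2[, 1])
  if (any(empty)) {
    warn(sprintf(
      "Recalculated thresholds left state(s) %s unseeded; keeping pass-1 centroids.",
      paste(states[empty], collapse = ", ")
    ))
    centers2[empty, ] <- km1$centers[empty, , drop = FALSE]
  }
  km2 <- run_km(centers2)
  labels <- states[km2$cluster]

  if (config$min_bout_epochs > 0) {
    labels <- enforce_min_bout(labels, config$min_bout_epochs)
  }

  hypnogram(labels,
    phase = if ("phase" %in% names(features)) features$phase else "dark",
    epoch_s = attr(features, "epoch_s") %||% config$epoch_s,
    arity = 3L
  )
}

# Merge runs shorter than `min_len` into the preceding run (the first run
# merges forward). Optional smoothing; off by default.
enforce_min_bout <- function(labels, min_len) {
  repeat {
    r <- rle(labels)
    short <- which(r$lengths < min_len)
    if (length(short) == 0) {
      return(labels)
    }
    i <- short[1]
    r$values[i] <- if (i > 1) r$values[i - 1] else r$values[i + 1]
    labels <- inverse.rle(r)
  }
}

#' Stage a recording end to end
#'
#' Convenience wrapper: [compute_epoch_features()], [seed_labels()], then
#' [kmeans_refine()].
#'
#' @inheritParams compute_epoch_features
#' @return A 3-state [hypnogram()].
#' @examples
#' \donttest{
#' h <- simulate_hypnogram(ld_transition_matrices(),
#'   phase_schedule(segments = data.frame(phase = "dark", n_epochs = 200)),
#'   seed = 1, mode = "duration_faithful"
#' )
#' rec <- synthesize_signals(h, seed = 1)
#' staged <- stage_recording(rec)
#' mean(staged$state == ifelse(h$state %in% c("WKL", "WKB"), "WK", h$state))
#' }
#' @export
stage_recording <- function(recording,
                            bands = default_bands(recording$fs),
                            config = staging_config(),
                            method = c("fft", "butter")) {
  features <- compute_epoch_features(recording, bands, config, method)
  features <- seed_labels(features, config)
  kmeans_refine(features, config = config)
}
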