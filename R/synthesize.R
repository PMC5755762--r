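#' Synthesise state-conditioned EEG/EMG signals from a hypnogram
#'
#' Generates one sampled signal per model channel whose spectral content
#' follows the behavioural state of each 5-s epoch of `truth`. Each epoch of
#' each channel is a sum of independent band-limited Gaussian noise
#' components (generated in the frequency domain, unit RMS, scaled by the
#' state's gain) plus sinusoidal oscillators with a random phase and a
#' state-gated amplitude. Adjacent epochs are joined with a 0.1-s linear
#' cross-fade so state changes do not introduce discontinuities. The result
#' is bit-reproducible for a fixed seed and model.
#'
#' @param truth A 4-state [hypnogram()] giving the generating state of every
#'   epoch.
#' @param model A [spectral_model()]; defaults to [default_spectral_model()].
#' @param seed Integer seed for the synthesis RNG stream.
#' @param chunk_epochs Internal processing block size in epochs (fixed
#'   default; part of the deterministic realisation).
#' @return An object of class `sleep_recording`: a list with `channels`
#'   (named list of numeric signals of identical length
#'   `n_epochs * epoch_s * fs`), `fs`, `epoch_s`, `truth` and `seed`.
#' @examples
#' h <- hypnogram(rep(c("WKL", "NREM"), each = 3), phase = "dark")
#' rec <- synthesize_signals(h, seed = 7)
#' lengths(rec$channels)
#' @export
synthesize_signals <- function(truth,
                               model = default_spectral_model(),
                               seed,
                               chunk_epochs = 2000L) {
  if (missing(seed)) abort("`seed` is required for synthesis.")
  if (hypnogram_arity(truth) != 4L) {
    abort("`truth` must be a 4-state hypnogram (WKL/WKB/NREM/REM).")
  }
  fs <- model$fs
  epoch_s <- hypnogram_epoch_s(truth)
  L <- as.integer(round(epoch_s * fs))
  R <- as.integer(round(0.1 * fs))
  seg_len <- L + R
  nfft <- next_fast_len(seg_len)
  n <- nrow(truth)
  states <- truth$state
  fq <- (seq_len(nfft) - 1) * fs / nfft
  up <- seq_len(R) / (R + 1)
  down <- 1 - up

  set.seed(derive_seed(seed, 2L))
  comp <- model$components
  channels <- unique(comp$channel)
  out <- vector("list", length(channels))
  names(out) <- channels

  for (ch in channels) {
    ch_comp <- comp[comp$channel == ch, ]
    band_names <- unique(ch_comp$component[ch_comp$type == "band"])
    osc_names <- unique(ch_comp$component[ch_comp$type == "oscillator"])
    band_info <- lapply(band_names, function(nm) {
      rows <- ch_comp[ch_comp$component == nm & ch_comp$type == "band", ]
      bins <- which(fq >= rows$low_hz[1] & fq < rows$high_hz[1] &
        seq_len(nfft) - 1 >= 1 & seq_len(nfft) - 1 <= floor(nfft / 2))
      list(
        bins = bins,
        sigma = nfft / sqrt(length(bins)),
        gain = setNames(rows$gain, rows$state)
      )
    })
    osc_info <- lapply(osc_names, function(nm) {
      rows <- ch_comp[ch_comp$component == nm & ch_comp$type == "oscillator", ]
      list(
        f = rows$center_hz[1],
        phase = runif(1, 0, 2 * pi),
        gain = setNames(sqrt(2) * rows$gain, rows$state) # unit-RMS sinusoid
      )
    })

    sig <- numeric(n * L)
    prev_tail <- NULL
    prev_amp <- lapply(osc_info, function(o) NA_real_)
    e0 <- 1L
    while (e0 <= n) {
      e1 <- min(n, e0 + chunk_epochs - 1L)
      m <- e1 - e0 + 1L
      st <- states[e0:e1]

      spec <- matrix(0 + 0i, nfft, m)
      for (b in band_info) {
        nb <- length(b$bins)
        if (nb == 0) next
        g <- unname(b$gain[st]) * b$sigma
        z <- matrix(
          complex(real = rnorm(nb * m), imaginary = rnorm(nb * m)),
          nb, m
        )
        spec[b$bins, ] <- spec[b$bins, ] + z * rep(g, each = nb)
      }
      seg <- Re(mvfft(spec, inverse = TRUE))[seq_len(seg_len), , drop = FALSE] / nfft

      block <- seg[seq_len(L), , drop = FALSE]
      # cross-fade each epoch head with the previous epoch's tail
      tails <- seg[L + seq_len(R), , drop = FALSE]
      prev_tails <- cbind(
        if (is.null(prev_tail)) matrix(NA_real_, R, 1) else prev_tail,
        tails[, -m, drop = FALSE]
      )
      has_prev <- if (e0 == 1L) c(FALSE, rep(TRUE, m - 1L)) else rep(TRUE, m)
      if (any(has_prev)) {
        block[seq_len(R), has_prev] <-
          up * block[seq_len(R), has_prev, drop = FALSE] +
          down * prev_tails[, has_prev, drop = FALSE]
      }

      # oscillators: continuous phase, state-gated amplitude with the same
      # linear cross-fade applied to the amplitude envelope
      if (length(osc_info) > 0) {
        t_mat <- matrix(
          ((e0 - 1) * L + seq_len(m * L) - 1) / fs,
          L, m
        )
        for (j in seq_along(osc_info)) {
          o <- osc_info[[j]]
          a_cur <- unname(o$gain[st])
          if (all(a_cur == 0) && (is.na(prev_amp[[j]]) || prev_amp[[j]] == 0)) {
            prev_amp[[j]] <- a_cur[m]
            next
          }
          amp <- matrix(rep(a_cur, each = L), L, m)
          a_prev <- c(
            if (is.na(prev_amp[[j]])) a_cur[1] else prev_amp[[j]],
            a_cur[-m]
          )
          amp[seq_len(R), ] <- outer(up, a_cur) + outer(down, a_prev)
          block <- block + amp * sin(2 * pi * o$f * t_mat + o$phase)
          prev_amp[[j]] <- a_cur[m]
        }
      }

      sig[((e0 - 1) * L + 1):(e1 * L)] <- as.vector(block)
      prev_tail <- tails[, m, drop = FALSE]
      e0 <- e1 + 1L
    }
    out[[ch]] <- sig
  }

  structure(
    list(channels = out, fs = fs, epoch_s = epoch_s, truth = truth, seed = seed),
    class = "sleep_recording"
  )
}

#' @export
print.sleep_recording <- function(x, ...) {
  cat(sprintf(
    "<sleep_recording: %d channel(s) [%s], %d epochs of %g s at %g Hz>\n",
    length(x$channels), paste(names(x$channels), collapse = ", "),
    nrow(x$truth), x$epoch_s, x$fs
  ))
  invisible(x)
}

#' Write a recording as per-channel CSV files
#'
#' One plain-text CSV per channel (single `value` column, one row per
#' sample) plus the ground-truth hypnogram as TSV. Intended for small
#' desk-scale exports; signals regenerate exactly from the seed.
#'
#' @param rec A `sleep_recording`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_recording_csv <- function(rec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ch in names(rec$channels)) {
    readr::write_csv(
      tibble(value = rec$channels[[ch]]),
      file.path(dir, paste0(ch, ".csv"))
    )
  }
  write_hypnogram(rec$truth, file.path(dir, "truth_hypnogram.tsv"))
  invisible(dir)
}
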