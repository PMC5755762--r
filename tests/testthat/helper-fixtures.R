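# Fixtures built in code; nothing is read from disk.

dark_only_schedule <- function(n_epochs) {
  phase_schedule(segments = data.frame(phase = "dark", n_epochs = n_epochs))
}

light_only_schedule <- function(n_epochs) {
  phase_schedule(segments = data.frame(phase = "light", n_epochs = n_epochs))
}

# A bare recording object around hand-made channel signals.
make_recording <- function(cortex, hippocampus = cortex, emg = cortex,
                           fs = 250, epoch_s = 5, truth = NULL) {
  structure(
    list(
      channels = list(cortex = cortex, hippocampus = hippocampus, emg = emg),
      fs = fs, epoch_s = epoch_s, truth = truth, seed = NA_integer_
    ),
    class = "sleep_recording"
  )
}

# Random multi-state hypnogram for oracle comparisons.
random_hypnogram <- function(n, states = c("WKL", "REM", "NREM", "WKB"),
                             phases = c("dark", "light")) {
  hypnogram(
    sample(states, n, replace = TRUE),
    phase = sample(phases, n, replace = TRUE)
  )
}

# Brute-force transition counting by explicit pair enumeration.
brute_force_counts <- function(h, stratify_by_phase = TRUE) {
  states <- if (any(h$state %in% c("WKL", "WKB"))) {
    c("WKL", "REM", "NREM", "WKB")
  } else {
    c("WK", "NREM", "REM")
  }
  n <- nrow(h)
  strata <- if (stratify_by_phase) unique(h$phase[-n]) else "pooled"
  out <- lapply(strata, function(ph) {
    m <- matrix(0L, length(states), length(states),
      dimnames = list(states, states)
    )
    for (t in seq_len(n - 1)) {
      if (stratify_by_phase && h$phase[t] != ph) next
      m[h$state[t], h$state[t + 1]] <- m[h$state[t], h$state[t + 1]] + 1L
    }
    m
  })
  names(out) <- strata
  out
}

# A small, perfectly separated three-cluster feature table in the staging
# feature space (all 9 columns), one tight blob per state.
separated_features <- function(n_per_state = 20, seed = 42) {
  set.seed(seed)
  centers <- list(
    WK = c(
      delta_cx = -1, sigma_cx = -0.5, beta_cx = -0.5, theta_hc = 1,
      gamma1_hc = 1, gamma2_hc = 1, emg = 1.5,
      theta_delta_index = 2, beta_gamma_index = -1.5
    ),
    NREM = c(
      delta_cx = 1.5, sigma_cx = 1, beta_cx = 1, theta_hc = -1,
      gamma1_hc = -1, gamma2_hc = -1, emg = -1,
      theta_delta_index = -2.5, beta_gamma_index = 2
    ),
    REM = c(
      delta_cx = -1, sigma_cx = -0.5, beta_cx = -0.5, theta_hc = 1.5,
      gamma1_hc = 0, gamma2_hc = 0, emg = -1.5,
      theta_delta_index = 2.5, beta_gamma_index = -0.5
    )
  )
  rows <- purrr::map_dfr(names(centers), function(st) {
    mu <- centers[[st]]
    as_tib <- as.data.frame(
      matrix(rep(mu, n_per_state), n_per_state,
        byrow = TRUE,
        dimnames = list(NULL, names(mu))
      ) + matrix(rnorm(n_per_state * 9, sd = 0.05), n_per_state)
    )
    as_tib$truth <- st
    as_tib
  })
  rows <- rows[sample(nrow(rows)), ]
  f <- tibble::as_tibble(rows[, names(centers$WK)])
  f$epoch <- seq_len(nrow(f)) - 1L
  f$artifact <- FALSE
  f <- structure(f,
    epoch_s = 5,
    band_names = c(
      "delta_cx", "sigma_cx", "beta_cx", "theta_hc",
      "gamma1_hc", "gamma2_hc", "emg"
    ),
    class = c("epoch_features", class(tibble::tibble()))
  )
  list(features = f, truth = rows$truth)
}

collapse3 <- function(states) ifelse(states %in% c("WKL", "WKB"), "WK", states)
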