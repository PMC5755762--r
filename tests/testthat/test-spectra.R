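test_that("an on-grid tone lands in exactly its frequency bin", {
  fs <- 250
  x8 <- sin(2 * pi * 8 * (0:1249) / fs)
  ps <- epoch_psd(x8, fs)
  expect_equal(ps$frequency[which.max(ps$power)], 8)
  expect_equal(ps$frequency[2] - ps$frequency[1], 0.2)

  x72 <- sin(2 * pi * 7.2 * (0:1249) / fs)
  ps2 <- epoch_psd(x72, fs)
  expect_equal(ps2$frequency[which.max(ps2$power)], 7.2)

  expect_true(all(epoch_psd(rep(0, 1250), fs)$power == 0))
})

test_that("the periodogram scaling is exactly Parseval-consistent", {
  set.seed(61)
  fs <- 250
  for (i in 1:10) {
    x <- rnorm(1250, sd = runif(1, 0.5, 3))
    ps <- epoch_psd(x, fs, max_hz = NULL)
    w <- sleepchain:::hamming_window(1250)
    expect_equal(sum(ps$power), sum((x * w)^2), tolerance = 1e-10)
  }
})

test_that("average white-noise band power matches the time-domain variance", {
  set.seed(62)
  fs <- 250
  sigma <- 1.7
  n_ep <- 1000
  x <- rnorm(n_ep * 1250, sd = sigma)
  pm <- sleepchain:::psd_matrix(x, fs, 5, max_hz = NULL)
  w <- sleepchain:::hamming_window(1250)
  # E[sum of bins] = sigma^2 * sum(w^2) for white noise
  expect_equal(mean(colSums(pm$power)), sigma^2 * sum(w^2), tolerance = 0.05)
})

test_that("state profiles are z-scored so their weighted mean vanishes", {
  h <- hypnogram(rep(c("WKL", "WKB", "NREM", "REM"), c(40, 20, 60, 30)),
    phase = "dark"
  )
  rec <- synthesize_signals(h, seed = 71)
  sp <- state_mean_spectrum(rec)
  weighted <- sp |>
    dplyr::group_by(channel, frequency) |>
    dplyr::summarise(
      m = sum(z_power * n_epochs) / sum(n_epochs),
      .groups = "drop"
    )
  expect_lt(max(abs(weighted$m)), 1e-10)
})

test_that("a single-state recording has no spectral contrast", {
  h <- hypnogram(rep("NREM", 30), phase = "light", arity = 4)
  rec <- synthesize_signals(h, seed = 72)
  sp <- state_mean_spectrum(rec)
  expect_lt(max(abs(sp$z_power)), 1e-10)
})

test_that("a state with no usable epochs gets an empty profile, not a fabricated one", {
  h <- hypnogram(rep(c("WKL", "REM", "NREM"), c(10, 4, 10)), phase = "dark")
  rec <- synthesize_signals(h, seed = 73)
  mask <- h$state == "REM" # every REM epoch marked as artifact
  sp <- state_mean_spectrum(rec, channels = "hippocampus", artifact_mask = mask)
  rem <- sp[sp$state == "REM", ]
  expect_true(all(rem$n_epochs == 0))
  expect_true(all(is.na(rem$z_power)))
  expect_false(anyNA(sp$z_power[sp$state != "REM"]))
})

test_that("theta-peak detection finds the state-specific peaks", {
  set.seed(3)
  states <- sample(rep(c("WKL", "WKB", "NREM", "REM"), c(150, 80, 200, 80)))
  h <- hypnogram(states, phase = "dark")
  rec <- synthesize_signals(h, seed = 74)
  sp <- state_mean_spectrum(rec)
  pk <- detect_theta_peak(sp[sp$channel == "hippocampus", ])
  expect_equal(pk$peak_hz[pk$state == "WKL"], 8, tolerance = 0.4 / 8)
  expect_equal(pk$peak_hz[pk$state == "WKB"], 6, tolerance = 0.4 / 6)
  expect_true(all(pk$found[pk$state %in% c("WKL", "WKB", "REM")]))
})

test_that("peak detection is invariant to positive rescaling and flags flat input", {
  fs <- 250
  x <- sin(2 * pi * 7.2 * (0:1249) / fs) + 0.1 * rnorm(1250)
  ps <- epoch_psd(x, fs)
  p1 <- detect_theta_peak(ps)
  ps_scaled <- ps
  ps_scaled$power <- ps$power * 37.5
  p2 <- detect_theta_peak(ps_scaled)
  expect_equal(p1$peak_hz, p2$peak_hz)

  flat <- tibble::tibble(frequency = seq(0, 20, 0.2), power = 1)
  expect_false(detect_theta_peak(flat)$found)
})

test_that("band time-courses are constant for a stationary on-grid tone", {
  fs <- 250
  x <- sin(2 * pi * 8 * (0:(20 * 1250 - 1)) / fs)
  rec <- make_recording(x, x, x, fs = fs)
  tc <- band_timecourse(rec, tibble::tibble(
    band = "theta_hc", channel = "hippocampus", low_hz = 4, high_hz = 10
  ))
  expect_equal(nrow(tc), 20)
  expect_lt(diff(range(tc$power)) / mean(tc$power), 1e-10)

  expect_error(
    band_timecourse(rec, tibble::tibble(
      band = "empty", channel = "cortex", low_hz = 10.01, high_hz = 10.02
    )),
    "no frequency bins"
  )
})

test_that("NREM delta power in the light phase is computable from a mixed recording", {
  sched <- phase_schedule(
    segments = data.frame(phase = c("dark", "light"), n_epochs = c(150, 150))
  )
  h <- simulate_hypnogram(ld_transition_matrices(), sched,
    seed = 75,
    mode = "duration_faithful"
  )
  rec <- synthesize_signals(h, seed = 75)
  tc <- band_timecourse(rec, tibble::tibble(
    band = "delta_cx", channel = "cortex", low_hz = 1, high_hz = 4
  ))
  sel <- h$state == "NREM" & h$phase == "light"
  if (any(sel)) {
    m <- mean(tc$power[tc$epoch %in% h$epoch[sel]])
    expect_true(is.finite(m) && m > 0)
  }
})

test_that("spectral profiles export as long-format TSV", {
  h <- hypnogram(rep(c("WKL", "NREM"), each = 8), phase = "dark")
  rec <- synthesize_signals(h, seed = 76)
  sp <- state_mean_spectrum(rec, channels = "cortex")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectra(sp, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(sp))
  expect_equal(back$z_power, sp$z_power, tolerance = 1e-9)
})
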