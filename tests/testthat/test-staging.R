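test_that("constant-amplitude signals z-score to zero in every epoch", {
  fs <- 250
  tone <- sin(2 * pi * 8 * (0:(10 * 5 * fs - 1)) / fs)
  rec <- make_recording(tone, tone, tone, fs = fs)
  f <- compute_epoch_features(rec)
  expect_true(all(abs(f$theta_hc) < 1e-6))
  expect_true(all(abs(f$delta_cx) < 1e-6))
  expect_true(all(abs(f$theta_delta_index) < 1e-6))
})

test_that("a two-epoch silent/tone signal gives a two-point z-score of -1/+1", {
  fs <- 250
  L <- 5 * fs
  x <- c(rep(0, L), sin(2 * pi * 7 * (0:(L - 1)) / fs)) # 7 Hz: theta band
  rec <- make_recording(x, x, x, fs = fs)
  f <- compute_epoch_features(rec)
  expect_equal(f$theta_hc, c(-1, 1), tolerance = 1e-6)
})

test_that("a trailing partial epoch is dropped with a warning", {
  fs <- 250
  x <- rnorm(5 * fs * 3 + 17)
  rec <- make_recording(x, x, x, fs = fs)
  expect_warning(f <- compute_epoch_features(rec), "partial epoch")
  expect_equal(nrow(f), 3)
})

test_that("bands referencing a missing channel raise an error", {
  rec <- structure(
    list(channels = list(cortex = rnorm(2500)), fs = 250, epoch_s = 5),
    class = "sleep_recording"
  )
  expect_error(compute_epoch_features(rec), "hippocampus")
})

test_that("EMG feature separates true wake from NREM on synthetic data", {
  h <- simulate_hypnogram(ld_transition_matrices()["dark"],
    dark_only_schedule(600),
    seed = 6, mode = "duration_faithful"
  )
  rec <- synthesize_signals(h, seed = 6)
  f <- compute_epoch_features(rec)
  wk <- h$state %in% c("WKL", "WKB")
  nr <- h$state == "NREM"
  expect_gt(mean(f$emg[wk]), mean(f$emg[nr]))
})

test_that("seeding rules assign the textbook corners and leave the dead zone", {
  f <- tibble::tibble(
    epoch = 0:3,
    delta_cx = 0, sigma_cx = 0, beta_cx = 0, theta_hc = 0,
    gamma1_hc = 0, gamma2_hc = 0,
    emg = c(1, -1, -1, 0),
    theta_delta_index = c(1, -1, 1, 0),
    beta_gamma_index = c(-1, 1, 0, 0),
    artifact = FALSE
  )
  f <- structure(f,
    epoch_s = 5,
    band_names = c(
      "delta_cx", "sigma_cx", "beta_cx", "theta_hc",
      "gamma1_hc", "gamma2_hc", "emg"
    ),
    class = c("epoch_features", class(tibble::tibble()))
  )
  out <- seed_labels(f)
  expect_identical(out$seed_state, c("WK", "NREM", "REM", NA))
})

test_that("K-means refinement is a fixed point on fully seeded separated data", {
  fx <- separated_features()
  f <- fx$features
  f$seed_state <- fx$truth # every epoch seeded
  staged <- kmeans_refine(f)
  expect_identical(staged$state, fx$truth)
})

test_that("refinement errors when a state has no seeds", {
  fx <- separated_features()
  f <- fx$features
  f$seed_state <- ifelse(fx$truth == "REM", NA, fx$truth)
  expect_error(kmeans_refine(f), "REM")
})

test_that("staging is invariant to positive channel rescaling", {
  set.seed(14)
  h <- hypnogram(
    sample(rep(c("WKL", "WKB", "NREM", "REM"), c(120, 40, 120, 40))),
    phase = "dark"
  )
  rec <- synthesize_signals(h, seed = 14)
  rec2 <- rec
  rec2$channels$cortex <- 3.7 * rec2$channels$cortex
  rec2$channels$hippocampus <- 0.01 * rec2$channels$hippocampus
  rec2$channels$emg <- 250 * rec2$channels$emg
  expect_identical(stage_recording(rec)$state, stage_recording(rec2)$state)
})

test_that("permuting epochs permutes the labels identically", {
  fx <- separated_features(n_per_state = 15, seed = 7)
  f <- seed_labels(fx$features)
  staged <- kmeans_refine(f)
  perm <- sample(nrow(f))
  fp <- f[perm, ]
  fp$epoch <- seq_len(nrow(fp)) - 1L
  fp <- structure(fp,
    epoch_s = 5, band_names = attr(f, "band_names"),
    class = class(f)
  )
  staged_p <- kmeans_refine(fp)
  expect_identical(staged_p$state, staged$state[perm])
})

test_that("frequency-domain and time-domain band features agree closely", {
  h <- hypnogram(rep(c("WKL", "NREM", "REM"), each = 15), phase = "dark")
  rec <- synthesize_signals(h, seed = 20)
  f_fft <- compute_epoch_features(rec, method = "fft")
  f_bw <- compute_epoch_features(rec, method = "butter")
  for (b in c("delta_cx", "theta_hc", "gamma1_hc", "emg")) {
    expect_gt(stats::cor(f_fft[[b]], f_bw[[b]]), 0.98)
  }
})

test_that("the full staging pipeline recovers the generating states", {
  sched <- phase_schedule(
    segments = data.frame(phase = c("dark", "light"), n_epochs = c(2000, 2000))
  )
  h <- simulate_hypnogram(ld_transition_matrices(), sched,
    seed = 3, mode = "duration_faithful"
  )
  rec <- synthesize_signals(h, seed = 3)
  staged <- stage_recording(rec)
  expect_equal(nrow(staged), nrow(h)) # every epoch labelled
  expect_false(any(is.na(staged$state)))
  acc <- mean(staged$state == collapse3(h$state))
  expect_gte(acc, 0.95)
})

test_that("the optional minimum-bout filter merges short runs", {
  labels <- c(rep("WK", 10), "NREM", rep("WK", 10), rep("NREM", 8))
  out <- sleepchain:::enforce_min_bout(labels, 3)
  expect_identical(out, c(rep("WK", 21), rep("NREM", 8)))
})
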