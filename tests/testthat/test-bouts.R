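test_that("bout extraction is run-length encoding with onset phases", {
  h <- hypnogram(c("WK", "WK", "NREM", "NREM", "NREM", "WK"),
    phase = c("dark", "dark", "dark", "light", "light", "light")
  )
  b <- extract_bouts(h)
  expect_identical(b$state, c("WK", "NREM", "WK"))
  expect_identical(b$n_epochs, c(2L, 3L, 1L))
  expect_identical(b$start_epoch, c(0L, 2L, 5L))
  expect_identical(b$duration_s, c(10, 15, 5))
  # bout spanning the phase change is attributed to its onset phase
  expect_identical(b$onset_phase, c("dark", "dark", "light"))
  expect_identical(b$truncated, c(TRUE, FALSE, TRUE))
  expect_equal(sum(b$n_epochs), nrow(h))

  one <- extract_bouts(hypnogram(rep("REM", 7)))
  expect_equal(nrow(one), 1)
  expect_identical(one$n_epochs, 7L)
})

test_that("bout tables rebuild their hypnogram exactly", {
  set.seed(12)
  for (i in 1:20) {
    h <- random_hypnogram(sample(5:200, 1))
    b <- extract_bouts(h)
    h2 <- bouts_to_hypnogram(b, phase = h$phase)
    expect_identical(h2$state, h$state)
  }
})

test_that("the wake split honours the strict 150-s brief-wake definition", {
  b <- extract_bouts(hypnogram(rep(c("WK", "NREM", "WK"), c(29, 5, 30))))
  s <- split_wake(b)
  expect_identical(s$state, c("WKB", "NREM", "WKL")) # 145 s brief, 150 s long
  # already-split input is refused
  expect_error(split_wake(s), "4-state")
})

test_that("Kaplan-Meier survival matches hand counts and closed forms", {
  km <- km_survival(c(5, 5, 10))
  expect_equal(km$survival, c(1 / 3, 0))
  expect_equal(km$n_risk, c(3L, 1L))
  expect_equal(km$n_event, c(2L, 1L))

  km2 <- km_survival(rep(35, 9))
  expect_equal(km2$survival, c(rep(1, 6), 0))
  expect_equal(km2$time_s, seq(5, 35, 5))

  expect_error(km_survival(numeric(0)), "No durations")
  expect_error(km_survival(c(5, 7)), "multiples")
})

test_that("uncensored Kaplan-Meier equals one minus the ECDF", {
  set.seed(31)
  for (i in 1:200) {
    d <- 5 * sample(1:40, sample(1:60, 1), replace = TRUE)
    km <- km_survival(d)
    ecdf_surv <- 1 - stats::ecdf(d)(km$time_s)
    expect_equal(km$survival, ecdf_surv, tolerance = 1e-12)
  }
})

test_that("geometric samples follow their closed-form survival pointwise", {
  set.seed(9)
  p <- 0.940798439 # brief-wake self-transition, dark phase
  n <- 1e5
  d <- 5 * (1 + rgeom(n, 1 - p))
  km <- km_survival(d)
  theo <- p^(km$time_s / 5)
  se <- sqrt(pmax(theo * (1 - theo), 1e-12) / n)
  sel <- km$n_risk >= 50 # deep-tail bins carry no information
  expect_true(all(abs(km$survival - theo)[sel] < 3 * se[sel]))
})

test_that("log-rank test is null on identical groups and powered on separated ones", {
  a <- c(5, 10, 15, 20, 40)
  lr0 <- logrank_test(a, a)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)

  set.seed(17)
  g1 <- 5 * (1 + rgeom(200, 0.2))
  lr <- logrank_test(g1, g1 * 2)
  expect_lt(lr$p_value, 0.05)

  expect_error(logrank_test(numeric(0), a), "nonempty")
})

test_that("log-rank agrees with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(41)
  for (i in 1:10) {
    a <- 5 * sample(1:50, 80, replace = TRUE)
    b <- 5 * sample(1:60, 70, replace = TRUE)
    lr <- logrank_test(a, b)
    sd_ <- survival::survdiff(
      survival::Surv(c(a, b)) ~ rep(1:2, c(80, 70))
    )
    expect_equal(lr$statistic, sd_$chisq, tolerance = 1e-10)
  }
})

test_that("duration histograms resolve bimodal wake and unimodal NREM shapes", {
  single <- duration_histogram(rep(25, 10))
  expect_equal(sum(single$count > 0), 1)

  # two geometric components at the dark-phase dwell scales
  set.seed(8)
  d <- 5 * (1 + c(rgeom(4000, 5 / 84.5), rgeom(4000, 5 / 1347)))
  hist2 <- duration_histogram(d, log_bins = TRUE, n_bins = 25)
  # per-bin probability mass on the log grid (~ t * f(t)) peaks once per
  # component: one mode below the 150-s cutoff, one above, with a valley
  # in between
  below <- which(hist2$mid < 150)
  above <- which(hist2$mid > 300)
  p1 <- below[which.max(hist2$count[below])]
  p2 <- above[which.max(hist2$count[above])]
  valley <- min(hist2$count[p1:p2])
  expect_gt(hist2$count[p1], 1.2 * valley)
  expect_gt(hist2$count[p2], 1.2 * valley)

  # NREM durations from a dark simulation stay unimodal on log bins
  h <- simulate_hypnogram(
    ld_transition_matrices()["dark"], dark_only_schedule(3e5),
    seed = 15
  )
  b <- extract_bouts(h)
  histn <- duration_histogram(b$duration_s[b$state == "NREM"],
    log_bins = TRUE, n_bins = 12
  )
  # exactly one prominent mode after light smoothing
  sm <- stats::filter(histn$count, rep(1 / 3, 3))
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- histn$count[is.na(sm)]
  prominent <- which(
    diff(sign(diff(sm))) < 0
  ) + 1L
  prominent <- prominent[sm[prominent] > 0.25 * max(sm)]
  expect_identical(length(prominent), 1L)
})
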