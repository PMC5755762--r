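ld <- ld_transition_matrices()

test_that("four-state relabelling follows bout duration with the 150-s boundary", {
  h29 <- hypnogram(rep("WK", 29)) # 145 s
  expect_identical(unique(relabel_four_state(h29)$state), "WKB")
  h30 <- hypnogram(rep("WK", 30)) # exactly 150 s
  expect_identical(unique(relabel_four_state(h30)$state), "WKL")
  # mixed: each wake bout relabelled by its own duration
  h <- hypnogram(rep(c("WK", "NREM", "WK"), c(10, 4, 40)))
  r <- relabel_four_state(h)
  expect_identical(
    r$state,
    rep(c("WKB", "NREM", "WKL"), c(10, 4, 40))
  )
  # 4-state input passes through unchanged
  expect_identical(relabel_four_state(r)$state, r$state)
})

test_that("relabelling a duration-faithful simulation reproduces its truth", {
  h <- simulate_hypnogram(ld, phase_schedule(2, 2),
    seed = 19,
    mode = "duration_faithful"
  )
  rebuilt <- relabel_four_state(collapse_wake(h))
  expect_identical(rebuilt$state, h$state)
})

test_that("transition counting matches hand counts", {
  h <- hypnogram(c("WKL", "WKL", "NREM"), phase = "dark")
  cnt <- count_transitions(h)$dark
  expect_identical(cnt["WKL", "WKL"], 1L)
  expect_identical(cnt["WKL", "NREM"], 1L)
  expect_identical(sum(cnt), 2L)

  h1 <- hypnogram(rep("REM", 10), phase = "light")
  expect_identical(count_transitions(h1)$light["REM", "REM"], 9L)
})

test_that("transition counting equals brute-force pair enumeration", {
  set.seed(23)
  for (i in 1:100) {
    h <- random_hypnogram(sample(2:80, 1))
    expect_identical(
      lapply(count_transitions(h), unclass),
      brute_force_counts(h)
    )
    expect_identical(
      unclass(count_transitions(h, stratify_by_phase = FALSE)$pooled),
      brute_force_counts(h, stratify_by_phase = FALSE)$pooled
    )
  }
})

test_that("phase-boundary transitions are attributed to the earlier epoch's phase", {
  h <- hypnogram(c("WKL", "NREM"), phase = c("dark", "light"))
  cnt <- count_transitions(h)
  expect_identical(names(cnt), "dark")
  expect_identical(cnt$dark["WKL", "NREM"], 1L)
})

test_that("matrix estimation is the row-wise MLE with honest empty rows", {
  counts <- matrix(c(9, 1, 0, 10), 2, 2,
    byrow = TRUE,
    dimnames = list(c("A", "B"), c("A", "B"))
  )
  est <- estimate_matrix(counts)
  expect_equal(unname(est$probs), matrix(c(0.9, 0.1, 0, 1), 2, byrow = TRUE))
  expect_equal(est$se["A", "A"], sqrt(0.9 * 0.1 / 10))

  empty <- estimate_matrix(matrix(c(3, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_true(all(is.nan(empty$probs[2, ])))
  expect_equal(sum(empty$probs[1, ]), 1)
})

test_that("estimation is invariant to state relabelling permutations", {
  set.seed(3)
  h <- random_hypnogram(500)
  est <- fit_markov(h, stratify_by_phase = FALSE)$pooled
  perm <- c("NREM", "WKB", "WKL", "REM")
  expect_equal(est$probs[perm, perm], estimate_matrix(
    count_transitions(h, stratify_by_phase = FALSE)$pooled[perm, perm]
  )$probs)
})

test_that("estimated rows sum to one whenever the row was observed", {
  set.seed(33)
  for (i in 1:20) {
    h <- random_hypnogram(sample(10:300, 1))
    est <- fit_markov(h, stratify_by_phase = FALSE)$pooled
    observed <- est$row_totals > 0
    expect_equal(unname(rowSums(est$probs)[observed]),
      rep(1, sum(observed)),
      tolerance = 1e-12
    )
  }
})

test_that("the brief-to-long wake cell is a structural zero after relabelling", {
  set.seed(44)
  for (i in 1:25) {
    h3 <- hypnogram(
      sample(c("WK", "NREM", "REM"), 400, replace = TRUE),
      phase = "dark"
    )
    h4 <- relabel_four_state(h3)
    cnt <- count_transitions(h4, stratify_by_phase = FALSE)$pooled
    expect_identical(cnt["WKB", "WKL"], 0L)
  }
})

test_that("paired dark/light cell comparison flags the long-wake modulation", {
  # identical estimates per animal: p-value 1
  same <- tidyr::expand_grid(
    animal = 1:4, phase = c("dark", "light"),
    from = "WKL", to = "WKL"
  )
  same$estimate <- 0.99
  res0 <- compare_cells(same)
  expect_equal(res0$p_value, 1)

  # synthetic cohort of 10 animals simulated from the built-in matrices
  est_all <- purrr::map_dfr(1:10, function(a) {
    purrr::map_dfr(c("dark", "light"), function(ph) {
      sched <- phase_schedule(
        segments = data.frame(phase = ph, n_epochs = 1e5)
      )
      h <- simulate_hypnogram(ld[ph], sched, seed = 1000 + 10 * a + (ph == "light"))
      td <- tidy(fit_markov(h)[[ph]])
      td$animal <- a
      td
    })
  })
  res <- compare_cells(est_all, cells = data.frame(
    from = c("WKL", "WKL"), to = c("WKL", "NREM")
  ))
  wkl_self <- res[res$from == "WKL" & res$to == "WKL", ]
  expect_lt(wkl_self$p_value, 0.05)
  expect_equal(wkl_self$direction, 1) # more stable in the dark
  wkl_nrem <- res[res$from == "WKL" & res$to == "NREM", ]
  expect_lt(wkl_nrem$p_value, 0.05)
  expect_equal(wkl_nrem$direction, -1) # fewer exits to NREM in the dark

  # a single animal cannot support a paired test
  expect_error(compare_cells(est_all[est_all$animal == 1, ]), "2 animals")
})

test_that("transition counts export as long-format TSV", {
  h <- random_hypnogram(50)
  cnt <- count_transitions(h)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transition_counts(cnt, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(sum(back$n), sum(vapply(cnt, sum, 0L)))
})

test_that("the order-1 vs order-2 diagnostic runs and is calibrated-ish on Markov data", {
  h <- simulate_hypnogram(ld["dark"], dark_only_schedule(5e4), seed = 55)
  res <- markov_order_test(h)
  expect_true(is.finite(res$lr_statistic))
  expect_gt(res$p_value, 1e-6) # no strong evidence against order 1
})
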