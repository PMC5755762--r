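#' Relabel a 3-state hypnogram to 4 states by wake-bout duration
#'
#' Every epoch of each wake bout is relabelled `WKB` or `WKL` according to
#' the bout's total duration (strictly shorter than `cutoff_s` is brief;
#' the cutoff itself is long). NREM/REM epochs pass through. Delegates to
#' [extract_bouts()] and [split_wake()].
#'
#' @param h A 3-state [hypnogram()].
#' @param cutoff_s Brief/long cutoff in seconds.
#' @return A 4-state [hypnogram()].
#' @examples
#' h <- hypnogram(rep("WK", 29)) # 145 s
#' unique(relabel_four_state(h)$state)
#' @export
relabel_four_state <- function(h, cutoff_s = 150) {
  if (hypnogram_arity(h) == 4L) {
    return(h)
  }
  bouts <- split_wake(extract_bouts(h), cutoff_s = cutoff_s)
  bouts_to_hypnogram(bouts, phase = h$phase)
}

#' Count state-to-state transitions
#'
#' For each consecutive epoch pair `(t, t+1)` the count
#' `n[state_t, state_{t+1}]` is incremented, in the stratum of epoch `t`'s
#' phase when stratifying (so the transition spanning a phase change is
#' attributed to the earlier epoch's phase).
#'
#' @param h A 4-state [hypnogram()] (3-state input is accepted too; counts
#'   are over whatever alphabet the hypnogram declares).
#' @param stratify_by_phase Count separately per phase?
#' @return An object of class `transition_counts`: a named list of integer
#'   matrices (one per phase, or `pooled`), with attribute `states`.
#' @examples
#' h <- hypnogram(c("WKL", "WKL", "NREM"), phase = "dark")
#' count_transitions(h)$dark
#' @export
count_transitions <- function(h, stratify_by_phase = TRUE) {
  states <- if (hypnogram_arity(h) == 4L) state_levels_4 else state_levels_3
  n <- nrow(h)
  if (n < 2) abort("Need at least two epochs to count transitions.")
  from <- factor(h$state[-n], levels = states)
  to <- factor(h$state[-1], levels = states)
  strata <- if (stratify_by_phase) h$phase[-n] else rep("pooled", n - 1)
  out <- lapply(unique(strata), function(ph) {
    sel <- strata == ph
    m <- table(from[sel], to[sel])
    matrix(as.integer(m), length(states), length(states),
      dimnames = list(states, states)
    )
  })
  names(out) <- unique(strata)
  structure(out, states = states, class = "transition_counts")
}

#' Maximum-likelihood transition matrix from counts
#'
#' Row-wise MLE `p_ij = n_ij / n_i` with per-cell binomial standard errors
#' `sqrt(p (1 - p) / n_i)`. Rows with no observed transitions are flagged
#' `NaN` rather than fabricated. Optional Laplace smoothing (`pseudo`)
#' supports downstream log-likelihoods; it is off by default so structural
#' zeros stay exact.
#'
#' @param counts A single integer count matrix (one stratum of
#'   [count_transitions()]).
#' @param phase Optional phase label carried into the estimate.
#' @param pseudo Pseudocount added to every cell before normalising
#'   (default 0).
#' @return An object of class `matrix_estimate` with `probs`, `counts`,
#'   `se`, `row_totals`, `phase`.
#' @examples
#' h <- hypnogram(rep(c("WKL", "NREM"), c(50, 50)), phase = "dark")
#' estimate_matrix(count_transitions(h)$dark)$probs["WKL", "WKL"]
#' @export
estimate_matrix <- function(counts, phase = NULL, pseudo = 0) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("Counts must be nonnegative.")
  work <- counts + pseudo
  n_i <- rowSums(work)
  probs <- work / n_i # rows with n_i = 0 become NaN
  se <- sqrt(probs * (1 - probs) / n_i)
  structure(
    list(
      probs = probs, counts = counts, se = se,
      row_totals = rowSums(counts), phase = phase
    ),
    class = "matrix_estimate"
  )
}

#' @export
print.matrix_estimate <- function(x, digits = 6, ...) {
  cat(sprintf(
    "<matrix_estimate%s: %d transitions>\n",
    if (is.null(x$phase)) "" else paste0(" [", x$phase, "]"),
    sum(x$counts)
  ))
  print(round(x$probs, digits))
  invisible(x)
}

#' @export
tidy.matrix_estimate <- function(x, ...) {
  long <- as.data.frame.table(x$probs, responseName = "estimate",
    stringsAsFactors = FALSE
  )
  long$n <- as.vector(x$counts)
  long$row_total <- rep(x$row_totals, times = ncol(x$probs))
  long$se <- as.vector(x$se)
  out <- as_tibble(long) |>
    dplyr::rename(from = "Var1", to = "Var2") |>
    dplyr::mutate(phase = x$phase %||% NA_character_)
  out[, c("phase", "from", "to", "estimate", "se", "n", "row_total")]
}

#' @export
glance.matrix_estimate <- function(x, ...) {
  tibble(
    phase = x$phase %||% NA_character_,
    n_transitions = sum(x$counts),
    n_states = nrow(x$probs),
    empty_rows = sum(x$row_totals == 0)
  )
}

#' Fit phase-stratified transition matrices to a hypnogram
#'
#' Convenience wrapper: [count_transitions()] then [estimate_matrix()] per
#' stratum.
#'
#' @inheritParams count_transitions
#' @param pseudo Passed to [estimate_matrix()].
#' @return A named list of `matrix_estimate` objects, one per stratum.
#' @export
fit_markov <- function(h, stratify_by_phase = TRUE, pseudo = 0) {
  cnt <- count_transitions(h, stratify_by_phase = stratify_by_phase)
  out <- lapply(names(cnt), function(ph) {
    estimate_matrix(cnt[[ph]],
      phase = if (ph == "pooled") NULL else ph, pseudo = pseudo
    )
  })
  names(out) <- names(cnt)
  out
}

#' Compare transition-matrix cells between dark and light across animals
#'
#' Paired per-animal dark-vs-light comparison of each requested cell, with
#' a paired t-test (default) or Wilcoxon signed-rank test. Raw p-values are
#' reported alongside Bonferroni-adjusted ones (across the tested cells).
#'
#' @param estimates A tidy tibble with columns `animal`, `phase` (`dark` /
#'   `light`), `from`, `to`, `estimate` — e.g. row-bound [tidy()] outputs of
#'   per-animal [fit_markov()] estimates.
#' @param cells Optional tibble/data frame with columns `from`, `to`
#'   restricting which cells are tested; all cells with data by default.
#' @param test `"t"` or `"wilcoxon"`.
#' @return A tibble with one row per cell: `from`, `to`, `n_animals`,
#'   `mean_dark`, `mean_light`, `direction` (+1 dark > light), `statistic`,
#'   `p_value`, `p_bonferroni`.
#' @export
compare_cells <- function(estimates, cells = NULL, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  estimates <- as_tibble(estimates)
  need <- c("animal", "phase", "from", "to", "estimate")
  if (!all(need %in% names(estimates))) {
    abort(sprintf("`estimates` needs columns %s.", paste(need, collapse = ", ")))
  }
  if (dplyr::n_distinct(estimates$animal) < 2) {
    abort("Need estimates from at least 2 animals for a paired comparison.")
  }
  wide <- estimates |>
    dplyr::filter(.data$phase %in% c("dark", "light")) |>
    tidyr::pivot_wider(
      id_cols = c("animal", "from", "to"),
      names_from = "phase", values_from = "estimate"
    ) |>
    dplyr::filter(is.finite(.data$dark), is.finite(.data$light))
  if (!is.null(cells)) {
    wide <- dplyr::semi_join(wide, as_tibble(cells), by = c("from", "to"))
  }
  res <- wide |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      n_animals = dplyr::n(),
      mean_dark = mean(.data$dark),
      mean_light = mean(.data$light),
      statistic = {
        d <- .data$dark - .data$light
        if (dplyr::n() < 2 || all(d == 0)) {
          NA_real_
        } else if (test == "t") {
          unname(t.test(d)$statistic)
        } else {
          unname(suppressWarnings(wilcox.test(d))$statistic)
        }
      },
      p_value = {
        d <- .data$dark - .data$light
        if (dplyr::n() < 2 || all(d == 0)) {
          1
        } else if (test == "t") {
          t.test(d)$p.value
        } else {
          suppressWarnings(wilcox.test(d))$p.value
        }
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      direction = sign(.data$mean_dark - .data$mean_light),
      p_bonferroni = pmin(1, .data$p_value * dplyr::n())
    )
  res[, c(
    "from", "to", "n_animals", "mean_dark", "mean_light",
    "direction", "statistic", "p_value", "p_bonferroni"
  )]
}

#' First- vs second-order Markov likelihood-ratio diagnostic
#'
#' Optional extension (off the main analysis path): compares the fit of a
#' first-order chain against a second-order chain by likelihood ratio.
#' Large statistics indicate history beyond the previous epoch matters.
#'
#' @param h A [hypnogram()].
#' @return A tibble with `lr_statistic`, `df`, `p_value`.
#' @export
markov_order_test <- function(h) {
  s <- h$state
  n <- length(s)
  if (n < 3) abort("Need at least 3 epochs.")
  states <- sort(unique(s))
  k <- length(states)
  # both orders evaluated on the same conditional events s_t | history,
  # t = 3..n, so the models are nested
  prev1 <- s[2:(n - 1)]
  prev2 <- paste(s[1:(n - 2)], prev1)
  cur <- factor(s[3:n], states)
  cond_ll <- function(ctx) {
    tab <- table(ctx, cur)
    p <- tab / pmax(1, rowSums(tab))
    sum(tab * ifelse(tab > 0, log(p), 0))
  }
  lr <- 2 * (cond_ll(prev2) - cond_ll(prev1))
  df <- k * (k - 1) * (k - 1)
  tibble(
    lr_statistic = lr, df = df,
    p_value = pchisq(max(lr, 0), df = df, lower.tail = FALSE)
  )
}

#' Write transition counts as TSV
#'
#' Long format: `phase`, `from`, `to`, `n`.
#'
#' @param counts A `transition_counts` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_transition_counts <- function(counts, path) {
  long <- purrr::map_dfr(names(counts), function(ph) {
    d <- as.data.frame.table(counts[[ph]], responseName = "n",
      stringsAsFactors = FALSE
    )
    tibble(phase = ph, from = d$Var1, to = d$Var2, n = d$n)
  })
  readr::write_tsv(long, path)
  invisible(path)
}
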