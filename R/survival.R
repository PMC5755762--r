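#' Kaplan-Meier survival curve of bout durations
#'
#' Product-limit estimate on a fixed 5-s (one-epoch) grid:
#' `S(t_i) = S(t_{i-1}) * (r_i - d_i) / r_i`, where `r_i` is the number of
#' bouts still running at the start of time bin `t_i` and `d_i` the number
#' terminating during it. All bouts are treated as observed events (no
#' censoring), in which case the estimate coincides with `1 - ECDF`.
#'
#' @param durations_s Bout durations in seconds; must be positive multiples
#'   of `bin_s`.
#' @param bin_s Time-bin width in seconds (the epoch length).
#' @return A tibble of class `km_curve` with columns `time_s`, `n_risk`,
#'   `n_event`, `survival`, covering every bin from `bin_s` to the longest
#'   duration.
#' @examples
#' km_survival(c(5, 5, 10))
#' @export
km_survival <- function(durations_s, bin_s = 5) {
  if (length(durations_s) == 0) abort("No durations supplied.")
  k <- durations_s / bin_s
  if (any(k < 1) || max(abs(k - round(k))) > 1e-8) {
    abort(sprintf("Durations must be positive multiples of bin_s = %g.", bin_s))
  }
  k <- as.integer(round(k))
  kmax <- max(k)
  d <- tabulate(k, nbins = kmax)
  n <- length(k)
  r <- n - c(0L, cumsum(d)[-kmax]) # at risk entering each bin
  surv <- cumprod((r - d) / r)
  structure(
    tibble(
      time_s = seq_len(kmax) * bin_s,
      n_risk = r, n_event = d, survival = surv
    ),
    bin_s = bin_s, n = n,
    class = c("km_curve", class(tibble()))
  )
}

#' Two-sample log-rank test on uncensored durations
#'
#' Standard log-rank comparison of two survival curves with all durations
#' observed as events; the statistic is chi-squared with one degree of
#' freedom under the null of identical survival.
#'
#' @param a,b Numeric vectors of durations for the two groups.
#' @return An object of class `logrank_test` with elements `statistic`,
#'   `df`, `p_value`, `n` and the per-group observed/expected events.
#' @examples
#' logrank_test(c(5, 10, 15), c(5, 10, 15))$p_value # identical groups -> 1
#' @export
logrank_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    abort("Both groups must be nonempty.")
  }
  times <- sort(unique(c(a, b)))
  o1 <- e1 <- v <- 0
  for (t in times) {
    n1 <- sum(a >= t)
    n2 <- sum(b >= t)
    d1 <- sum(a == t)
    d2 <- sum(b == t)
    nj <- n1 + n2
    dj <- d1 + d2
    if (nj == 0 || dj == 0) next
    o1 <- o1 + d1
    e1 <- e1 + n1 * dj / nj
    if (nj > 1) {
      v <- v + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
    }
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  structure(
    list(
      statistic = stat, df = 1L,
      p_value = pchisq(stat, df = 1, lower.tail = FALSE),
      n = c(length(a), length(b)),
      observed = o1, expected = e1
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf(
    "Log-rank test: chisq = %.4g on %d df, p = %.4g (n = %d vs %d)\n",
    x$statistic, x$df, x$p_value, x$n[1], x$n[2]
  ))
  invisible(x)
}

#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p.value = x$p_value,
    n_a = x$n[1], n_b = x$n[2]
  )
}

#' @export
glance.logrank_test <- function(x, ...) tidy(x)

#' Write a survival curve as TSV
#'
#' Columns `t`, `S`, `r`, `d` (time bin, survival, at-risk, events).
#'
#' @param curve A `km_curve`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(curve, path) {
  readr::write_tsv(
    tibble(
      t = curve$time_s, S = curve$survival,
      r = curve$n_risk, d = curve$n_event
    ),
    path
  )
  invisible(path)
}

#' Write a bout table as TSV
#'
#' @param bouts A `bout_table`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bouts <- function(bouts, path) {
  readr::write_tsv(as_tibble(bouts), path)
  invisible(path)
}
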