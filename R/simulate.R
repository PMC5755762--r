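# Hypnogram simulation from phase-switched Markov dynamics.
#
# Simulation is bout-by-bout: within a constant-phase stretch the chain's
# dwell in a state is geometric with parameter (1 - p_ii), and the exit
# state is drawn from the off-diagonal row renormalised. This is exactly
# equivalent in distribution to stepping the chain epoch by epoch, and runs
# in time proportional to the number of bouts rather than epochs. At a
# phase boundary the remaining dwell is redrawn under the incoming phase's
# matrix, which is exact for the unconstrained geometric (memorylessness)
# and respects the remaining brief/long-wake allowance in
# duration-faithful mode.

# One unconstrained geometric dwell (in epochs) for self-transition p.
rdwell <- function(p_stay) {
  q <- 1 - p_stay
  if (q <= 0) {
    return(Inf)
  }
  1 + rgeom(1, q)
}

# Geometric dwell truncated to [lo, hi] epochs, by analytic inverse-CDF
# sampling. The lower bound alone uses memorylessness (lo + plain
# geometric); a finite upper bound conditions the geometric tail.
rdwell_trunc <- function(p_stay, lo = 1, hi = Inf) {
  if (hi < lo) {
    abort("Dwell truncation bounds are empty (hi < lo).")
  }
  q <- 1 - p_stay
  if (q <= 0) {
    if (is.infinite(hi)) {
      return(Inf)
    }
    return(hi) # absorbing but capped: dwell fills the allowance
  }
  if (is.infinite(hi)) {
    return(lo + rgeom(1, q))
  }
  m <- hi - lo # extra epochs beyond lo, in 0..m
  u <- runif(1)
  if (p_stay < 1e-12) {
    g <- 0
  } else if (p_stay > 1 - 1e-12) {
    g <- floor(u * (m + 1))
  } else {
    g <- floor(log(1 - u * (1 - p_stay^(m + 1))) / log(p_stay))
  }
  lo + min(max(g, 0), m)
}

#' Simulate a four-state hypnogram from dark/light transition matrices
#'
#' Generates a per-epoch state sequence from one transition matrix per
#' circadian phase, following a [phase_schedule()]. The first epoch is drawn
#' from the stationary distribution of the first segment's matrix, and the
#' matrix in force at epoch `t` governs the `t -> t+1` transition (so the
#' transition out of a segment's last epoch still uses that segment's
#' matrix).
#'
#' Two modes are available. `"matrix_faithful"` uses the matrices verbatim,
#' so brief-wake (`WKB`) dwells may occasionally exceed the 150-s
#' definitional cutoff. `"duration_faithful"` simulates bout by bout with
#' truncated geometric dwells so that every `WKB` bout is strictly shorter
#' than `cutoff_s` and every `WKL` bout at least `cutoff_s` long, making the
#' labels consistent with a duration-based relabelling; the exit state is
#' drawn from the off-diagonal row renormalised.
#'
#' @param matrices A named list of [transition_matrix()] objects, one per
#'   phase appearing in the schedule (e.g. [ld_transition_matrices()]), or a
#'   single `transition_matrix` for a single-phase schedule.
#' @param schedule A [phase_schedule()].
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param mode `"matrix_faithful"` or `"duration_faithful"`.
#' @param cutoff_s Brief/long wake cutoff in seconds (duration-faithful
#'   mode only).
#' @return A 4-state [hypnogram()].
#' @examples
#' h <- simulate_hypnogram(
#'   ld_transition_matrices(),
#'   phase_schedule(1, 1), # 1 h dark + 1 h light
#'   seed = 42
#' )
#' table(h$state)
#' @export
simulate_hypnogram <- function(matrices,
                               schedule = phase_schedule(),
                               seed,
                               mode = c("matrix_faithful", "duration_faithful"),
                               cutoff_s = 150) {
  mode <- match.arg(mode)
  if (missing(seed)) abort("`seed` is required for simulation.")
  if (inherits(matrices, "transition_matrix")) {
    nm <- matrices$phase %||% unique(schedule$phase)
    matrices <- setNames(list(matrices), nm[1])
  }
  phases <- unique(schedule$phase)
  missing_ph <- setdiff(phases, names(matrices))
  if (length(missing_ph) > 0) {
    abort(sprintf(
      "No transition matrix supplied for phase(s): %s.",
      paste(missing_ph, collapse = ", ")
    ))
  }
  P <- lapply(matrices, as_prob_matrix)
  states <- rownames(P[[1]]) %||% state_levels_4
  k <- length(states)
  for (pm in P) {
    if (nrow(pm) != k) abort("All matrices must share the same state set.")
  }
  epoch_s <- attr(schedule, "epoch_s") %||% 5
  c_ep <- as.integer(round(cutoff_s / epoch_s))
  i_wkb <- match("WKB", states)
  i_wkl <- match("WKL", states)

  if (mode == "duration_faithful") {
    for (ph in names(P)) {
      offdiag <- P[[ph]] - diag(diag(P[[ph]]), k)
      if (any(rowSums(offdiag) <= 0)) {
        abort(sprintf(
          "Phase '%s' matrix has an absorbing state (all-zero off-diagonal row); duration-faithful simulation cannot leave it.",
          ph
        ))
      }
    }
  }

  set.seed(derive_seed(seed, 1L))
  n_total <- sum(schedule$n_epochs)
  labels <- integer(n_total)
  seg_end <- cumsum(as.numeric(schedule$n_epochs))
  seg_start <- c(1, seg_end[-length(seg_end)] + 1)

  pi0 <- suppressWarnings(stationary_distribution(P[[schedule$phase[1]]]))
  s <- sample.int(k, 1, prob = pmax(pi0, 0))
  spent <- 0 # epochs of the current (possibly boundary-spanning) bout so far

  for (g in seq_len(nrow(schedule))) {
    Pm <- P[[schedule$phase[g]]]
    pos <- seg_start[g]
    send <- seg_end[g]
    while (pos <= send) {
      pstay <- Pm[s, s]
      constrained_wkb <- mode == "duration_faithful" && !is.na(i_wkb) && s == i_wkb
      constrained_wkl <- mode == "duration_faithful" && !is.na(i_wkl) && s == i_wkl
      d <- if (constrained_wkb) {
        rdwell_trunc(pstay, 1, (c_ep - 1) - spent)
      } else if (constrained_wkl) {
        rdwell_trunc(pstay, max(1, c_ep - spent), Inf)
      } else {
        rdwell(pstay)
      }
      run_end <- pos + d - 1
      if (run_end > send) {
        labels[pos:send] <- s
        spent <- spent + (send - pos + 1)
        pos <- send + 1
      } else {
        labels[pos:run_end] <- s
        spent <- 0
        row <- Pm[s, ]
        row[s] <- 0
        s <- sample.int(k, 1, prob = row)
        pos <- run_end + 1
      }
    }
  }

  # A long-wake bout cut short by the end of the recording cannot reach the
  # cutoff; relabel it brief so the labels stay duration-consistent.
  if (mode == "duration_faithful" && !is.na(i_wkl) && !is.na(i_wkb)) {
    r <- rle(labels)
    nr <- length(r$lengths)
    if (r$values[nr] == i_wkl && r$lengths[nr] < c_ep) {
      labels[(n_total - r$lengths[nr] + 1):n_total] <- i_wkb
    }
  }

  hypnogram(states[labels],
    phase = schedule_phases(schedule),
    epoch_s = epoch_s,
    arity = if (setequal(states, state_levels_4)) 4L else NULL
  )
}
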