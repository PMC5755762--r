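#' Construct a four-state transition matrix
#'
#' Builds a row-stochastic transition matrix over the four sleep-wake states
#' long wake (`WKL`), REM sleep (`REM`), NREM sleep (`NREM`) and brief wake
#' (`WKB`), at a discrete time step of one recording epoch (5 s by default).
#' Rows are renormalised to sum to one; a warning is emitted when any raw row
#' sum deviates from 1 by more than `tol`, which matters for published
#' matrices whose printed precision does not quite close the rows.
#'
#' @param probs A 4x4 numeric matrix of nonnegative transition probabilities,
#'   rows = origin state, columns = destination state, in the order of
#'   `states`.
#' @param states Ordered state labels. Defaults to
#'   `c("WKL", "REM", "NREM", "WKB")`.
#' @param phase Optional phase label, `"dark"` or `"light"`.
#' @param epoch_s Epoch duration in seconds (the Markov time step).
#' @param tol Row-sum deviation above which a warning is raised.
#'
#' @return An object of class `transition_matrix`: a list with elements
#'   `probs` (renormalised matrix with dimnames), `states`, `phase`,
#'   `epoch_s` and `raw_row_sums`.
#' @examples
#' p <- diag(4)
#' m <- transition_matrix(p, phase = "dark")
#' rowSums(m$probs)
#' @export
transition_matrix <- function(probs,
                              states = state_levels_4,
                              phase = NULL,
                              epoch_s = 5,
                              tol = 1e-4) {
  probs <- as.matrix(probs)
  if (!is.numeric(probs) || nrow(probs) != length(states) ||
    ncol(probs) != length(states)) {
    abort("`probs` must be a numeric square matrix matching `states`.")
  }
  if (any(!is.finite(probs)) || any(probs < 0)) {
    abort("All transition probabilities must be finite and nonnegative.")
  }
  if (any(probs > 1 + tol)) {
    abort("Transition probabilities cannot exceed 1.")
  }
  raw_sums <- rowSums(probs)
  if (any(raw_sums <= 0)) {
    abort("Every row must contain at least one positive entry.")
  }
  dev <- abs(raw_sums - 1)
  if (any(dev > tol)) {
    bad <- states[dev > tol]
    warn(sprintf(
      "Row(s) %s deviate from sum 1 by more than %g (max %.3g); renormalising.",
      paste(bad, collapse = ", "), tol, max(dev)
    ))
  }
  probs <- probs / raw_sums
  dimnames(probs) <- list(states, states)
  structure(
    list(
      probs = probs, states = states, phase = phase,
      epoch_s = epoch_s, raw_row_sums = unname(raw_sums)
    ),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, digits = 6, ...) {
  cat(sprintf(
    "<transition_matrix: %d states, epoch %g s%s>\n",
    length(x$states), x$epoch_s,
    if (is.null(x$phase)) "" else paste0(", phase ", x$phase)
  ))
  print(round(x$probs, digits))
  invisible(x)
}

# Published dark- and light-phase transition probabilities for the mouse
# four-state sleep-wake chain (state order WKL, REM, NREM, WKB; 5-s step).
# Kept verbatim at printed precision; renormalisation happens on load.
.ld_raw <- list(
  dark = matrix(c(
    0.996289038, 0.0001353482, 0.003576614, 0.00000000,
    0.002403548, 0.9638222661, 0.030798463, 0.002975273,
    0.003758884, 0.0025628484, 0.991916088, 0.001762179,
    0.000000000, 0.0000000000, 0.059201561, 0.940798439
  ), nrow = 4, byrow = TRUE),
  light = matrix(c(
    0.994275350, 0.0001319087, 0.005592741, 0.000000000,
    0.003242978, 0.9636607238, 0.030080758, 0.003015540,
    0.002976289, 0.0027375917, 0.992825566, 0.001460553,
    0.000000000, 0.0012345679, 0.058272307, 0.949493125
  ), nrow = 4, byrow = TRUE)
)

#' Built-in dark/light four-state transition matrices
#'
#' Returns the package's reference pair of dark- and light-phase transition
#' matrices for the mouse sleep-wake chain (states `WKL`, `REM`, `NREM`,
#' `WKB`; 5-s epochs). These are the default generating matrices of the
#' synthetic-data module. Rows are renormalised on construction; the printed
#' light-phase brief-wake row is known to over-run 1 by about 9e-3 at source
#' precision, which triggers the usual renormalisation warning unless
#' `quiet = TRUE`.
#'
#' @param quiet Suppress the row-sum warning for the known anomalous row.
#' @return A named list with `transition_matrix` elements `dark` and `light`.
#' @seealso [validate_reference_matrices()] for a row-sum integrity report.
#' @examples
#' m <- ld_transition_matrices()
#' m$dark$probs["WKB", "WKL"] # structural zero
#' @export
ld_transition_matrices <- function(quiet = TRUE) {
  build <- function(phase) {
    transition_matrix(.ld_raw[[phase]], phase = phase)
  }
  if (quiet) {
    suppressWarnings(list(dark = build("dark"), light = build("light")))
  } else {
    list(dark = build("dark"), light = build("light"))
  }
}

#' Row-sum integrity report for the built-in reference matrices
#'
#' Audits the raw (pre-normalisation) rows of the built-in dark/light
#' matrices: reports each row's printed sum and flags rows whose deviation
#' from 1 exceeds `tol`. At the default tolerance exactly one row is
#' flagged: the light-phase brief-wake row, whose printed cells sum to
#' about 1.009.
#'
#' @param tol Absolute deviation from 1 above which a row is flagged.
#' @return A tibble with columns `phase`, `state`, `row_sum`, `deviation`
#'   and `flagged`.
#' @examples
#' validate_reference_matrices()
#' @export
validate_reference_matrices <- function(tol = 1e-4) {
  purrr::map_dfr(c("dark", "light"), function(ph) {
    sums <- rowSums(.ld_raw[[ph]])
    tibble(
      phase = ph,
      state = state_levels_4,
      row_sum = sums,
      deviation = abs(sums - 1),
      flagged = abs(sums - 1) > tol
    )
  })
}

as_prob_matrix <- function(m) {
  if (inherits(m, "transition_matrix")) {
    return(m$probs)
  }
  if (inherits(m, "matrix_estimate")) {
    return(m$probs)
  }
  as.matrix(m)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of the row-stochastic matrix for eigenvalue 1,
#' normalised to sum to one: the long-run occupancy fraction of each state
#' for an ergodic chain. For a reducible chain (e.g. the identity matrix)
#' the eigenvector is not unique; a uniform distribution is returned with a
#' warning.
#'
#' @param m A `transition_matrix`, `matrix_estimate`, or bare row-stochastic
#'   matrix.
#' @return A named numeric vector of state probabilities.
#' @examples
#' stationary_distribution(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
#' @export
stationary_distribution <- function(m) {
  p <- as_prob_matrix(m)
  ev <- eigen(t(p))
  i_one <- which(abs(ev$values - 1) < 1e-8)
  if (length(i_one) > 1) {
    warn("Chain is reducible; stationary distribution is not unique. Returning uniform.")
    out <- rep(1 / nrow(p), nrow(p))
  } else {
    v <- Re(ev$vectors[, which.max(Re(ev$values))])
    out <- v / sum(v)
  }
  names(out) <- rownames(p) %||% paste0("S", seq_len(nrow(p)))
  out
}

#' Expected dwell time per state
#'
#' Closed-form mean bout duration implied by the diagonal of a transition
#' matrix: a state with self-transition probability `p` has geometric dwell
#' with mean `epoch_s / (1 - p)` seconds. States with `p = 1` (absorbing)
#' return `Inf`.
#'
#' @inheritParams stationary_distribution
#' @param epoch_s Epoch duration in seconds; taken from the object when it
#'   carries one.
#' @return Named numeric vector of mean dwell times in seconds.
#' @examples
#' expected_dwell(ld_transition_matrices()$dark)
#' @export
expected_dwell <- function(m, epoch_s = NULL) {
  epoch_s <- epoch_s %||% (if (inherits(m, "transition_matrix")) m$epoch_s else 5)
  p <- as_prob_matrix(m)
  d <- diag(p)
  out <- epoch_s / (1 - d)
  names(out) <- rownames(p) %||% paste0("S", seq_len(nrow(p)))
  out
}

#' @export
tidy.transition_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$probs, responseName = "probability",
    stringsAsFactors = FALSE
  )) |>
    dplyr::rename(from = "Var1", to = "Var2") |>
    dplyr::mutate(phase = x$phase %||% NA_character_)
}

#' Write or read a transition matrix as JSON
#'
#' The JSON carries the ordered state list, the 4x4 probability array, the
#' phase label and the epoch duration, so a written matrix reads back
#' identically.
#'
#' @param m A `transition_matrix`.
#' @param path File path.
#' @return `write_transition_matrix()` returns `path` invisibly;
#'   `read_transition_matrix()` returns a `transition_matrix`.
#' @export
write_transition_matrix <- function(m, path) {
  stopifnot(inherits(m, "transition_matrix"))
  jsonlite::write_json(
    list(
      states = m$states,
      probs = unname(m$probs),
      phase = m$phase,
      epoch_s = m$epoch_s
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  transition_matrix(
    probs = x$probs, states = x$states,
    phase = x$phase, epoch_s = as.numeric(x$epoch_s)
  )
}
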