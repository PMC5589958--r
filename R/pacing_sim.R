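#' Simulate paced beats
#'
#' Integrates a forced ODE system beat by beat. Each beat starts at stimulus
#' onset; the final state of beat \code{k} is bit-for-bit the initial state
#' of beat \code{k+1}.
#'
#' @param sys a forced-ODE [dynsys()].
#' @param state0 initial state at stimulus onset.
#' @param n_beats number of pacing cycles to simulate (>= 1).
#' @param params parameter list override.
#' @param dt_sample output sample spacing (ms) within each beat.
#' @param control [integrator_control()] tolerances.
#' @return a list of beat traces; each is a data.frame with column \code{t}
#'   (ms since that beat's stimulus onset) and one column per state variable,
#'   with attributes \code{beat_index} and \code{end_state}.
#' @export
simulate_beats <- function(sys, state0, n_beats, params = sys$params,
                           dt_sample = 1, control = integrator_control()) {
  stopifnot(sys$kind == "forced_ode", n_beats >= 1)
  T <- sys$pacing$cycle_length
  times <- seq(0, T, by = dt_sample)
  y <- apply_clamp(sys, unname(state0), params)
  traces <- vector("list", n_beats)
  for (b in seq_len(n_beats)) {
    res <- integrate_cycle(sys, y, params, control, times = times)
    df <- as.data.frame(res$samples[, c(1, 1 + seq_len(sys$dim))])
    names(df)[1] <- "t"
    attr(df, "beat_index") <- b
    attr(df, "end_state") <- res$end
    attr(df, "cycle_length") <- T
    traces[[b]] <- df
    y <- res$end
  }
  traces
}

#' State at stimulus onset
#'
#' Extracts the stroboscopic sample of a beat trace: the state at the moment
#' the stimulus is applied (t = 0 of the cycle). This is the Poincare-map
#' input convention, and the diastolic value plotted in bifurcation diagrams.
#'
#' @param trace a beat trace from [simulate_beats()].
#' @return named state vector.
#' @export
stroboscopic_sample <- function(trace) {
  stopifnot(is.data.frame(trace), trace$t[1] == 0)
  unlist(trace[1, -1])
}

#' Run to a steady periodic response
#'
#' Iterates the stroboscopic sample (the state at each stimulus application)
#' until the maximum absolute componentwise change between samples one period
#' apart falls below \code{tol}. The criterion is applied to raw state values
#' in their native mixed units (mV, mM, dimensionless), without rescaling.
#' Convergence is tested at periods 1, 2, ..., \code{period_max} in turn, so
#' a post-period-doubling alternans response is flagged as \code{period = 2}
#' rather than falsely reported as a converged period-1 response.
#'
#' Non-convergence within \code{max_beats} is a result, not an error:
#' quasiperiodic or irregular responses legitimately fail the test and are
#' returned with \code{converged = FALSE} for period-k analysis.
#'
#' @param sys a [dynsys()]; maps are iterated directly.
#' @param state0 initial state at stimulus onset.
#' @param params parameter list override.
#' @param max_beats cap on the number of pacing cycles.
#' @param tol steady-state criterion on the stroboscopic samples.
#' @param period_max largest period tested.
#' @param control [integrator_control()] tolerances (ODE systems).
#' @return list with \code{state} (last stroboscopic sample, named),
#'   \code{converged}, \code{period} (detected period, NA if not converged),
#'   \code{beats_used}, and \code{residual} (the final period-matched
#'   componentwise change).
#' @export
run_to_steady_state <- function(sys, state0, params = sys$params,
                                max_beats = 1000, tol = 1e-8, period_max = 4,
                                control = integrator_control()) {
  stopifnot(max_beats >= 2)
  y <- apply_clamp(sys, unname(state0), params)
  hist <- matrix(NA_real_, nrow = period_max + 1, ncol = sys$dim)
  hist[1, ] <- y
  nseen <- 1
  residual <- Inf
  for (b in seq_len(max_beats)) {
    y <- poincare_map(sys, y, k = 1, params = params, control = control)
    if (!all(is.finite(y)))
      return(list(state = stats::setNames(hist[1, ], sys$state_names),
                  converged = FALSE, period = NA_integer_, beats_used = b,
                  residual = Inf, diverged = TRUE))
    res_p <- rep(NA_real_, period_max)
    for (p in seq_len(min(nseen, period_max))) {
      res_p[p] <- max(abs(y - hist[p, ]))
      residual <- res_p[p]
      # a period-p claim requires clear separation from shorter lags:
      # otherwise integrator jitter near a period-1 point could tip an
      # arbitrary lag below tol first and report a spurious period
      if (residual < tol &&
          (p == 1 || all(res_p[seq_len(p - 1)] > 10 * tol)))
        return(list(state = stats::setNames(y, sys$state_names),
                    converged = TRUE, period = p, beats_used = b,
                    residual = residual, diverged = FALSE))
    }
    hist[2:(period_max + 1), ] <- hist[1:period_max, ]
    hist[1, ] <- y
    nseen <- nseen + 1
  }
  list(state = stats::setNames(y, sys$state_names), converged = FALSE,
       period = NA_integer_, beats_used = max_beats, residual = residual,
       diverged = FALSE)
}
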