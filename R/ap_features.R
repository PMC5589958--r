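#' Action-potential duration at 90% repolarisation
#'
#' The baseline is the membrane potential at stimulus onset (per beat, so
#' drifting diastolic potentials are handled); the threshold is
#' \eqn{V_{90} = V_{peak} - 0.9 (V_{peak} - V_{baseline})}. APD90 is the time
#' of the \emph{last} downward crossing of \eqn{V_{90}} (linearly
#' interpolated between samples), so transient re-depolarisations above the
#' threshold extend the measured duration — the convention under which an
#' emerging afterdepolarisation abruptly prolongs APD. If the potential
#' never returns below the threshold before the next stimulus the beat is a
#' repolarisation failure and \code{NA} is returned with attribute
#' \code{repol_failure = TRUE}; a beat with no appreciable upstroke returns
#' \code{NA} with \code{no_ap = TRUE}.
#'
#' Arrest at a depolarised potential (the extreme of the response spectrum)
#' is recognised by an absolute criterion as well: when the membrane never
#' falls below \code{diastolic_floor} during the beat, the relative V90 rule
#' is meaningless (the "baseline" is itself a depolarised plateau) and the
#' beat is flagged as a repolarisation failure outright.
#'
#' @param trace a beat trace ([simulate_beats()]) with columns \code{t} and
#'   \code{Vm} (or a single-variable trace whose second column is used).
#' @param min_upstroke minimum peak-over-baseline excursion (mV) for the
#'   beat to count as a stimulated AP.
#' @param diastolic_floor potential (mV) below which the membrane must fall
#'   at some point of the beat for repolarisation to count as complete.
#' @return duration in ms, or flagged \code{NA}.
#' @export
apd90 <- function(trace, min_upstroke = 10, diastolic_floor = -60) {
  v <- vm_column(trace)
  t <- trace$t
  baseline <- v[1]
  pk <- max(v)
  if (pk - baseline < min_upstroke)
    return(structure(NA_real_, no_ap = TRUE))
  if (min(v) > diastolic_floor)
    return(structure(NA_real_, repol_failure = TRUE))
  v90 <- pk - 0.9 * (pk - baseline)
  below <- v < v90
  cross <- which(!below[-length(below)] & below[-1])
  if (!length(cross))
    return(structure(NA_real_, repol_failure = TRUE))
  i <- cross[length(cross)]
  # linear interpolation of the crossing time
  frac <- (v[i] - v90) / (v[i] - v[i + 1])
  unname(t[i] + frac * (t[i + 1] - t[i]))
}

vm_column <- function(trace) {
  if ("Vm" %in% names(trace)) trace$Vm else trace[[2]]
}

#' Count transient depolarisations during phases 2-3
#'
#' Counts afterdepolarisation episodes after the primary upstroke peak: each
#' sign change of \eqn{dV_m/dt} from negative to positive occurring while
#' \eqn{V_m} is above the phase-2/3 floor, followed by a net rise of at
#' least the prominence threshold before the next downturn. The numeric
#' rule (floor -40 mV, prominence 1 mV) is a declared operational
#' convention, chosen to be robust to integrator jitter; the count is
#' invariant under uniform resampling at sub-millisecond resolution.
#'
#' @inheritParams apd90
#' @param floor membrane-potential floor (mV) below which episodes are not
#'   counted.
#' @param prominence minimum net rise (mV) for an episode to count.
#' @return integer count (the per-beat EAD count).
#' @export
count_tdmp <- function(trace, floor = -40, prominence = 1) {
  v <- vm_column(trace)
  ipk <- which.max(v)
  if (ipk >= length(v) - 1) return(0L)
  v <- v[ipk:length(v)]
  dv <- diff(v)
  n <- 0L
  i <- 1
  len <- length(dv)
  while (i < len) {
    if (dv[i] <= 0 && dv[i + 1] > 0 && v[i + 1] > floor) {
      # local minimum above the floor: measure the net rise that follows
      j <- i + 1
      while (j < len && dv[j + 1] > 0) j <- j + 1
      if (v[j + 1] - v[i + 1] >= prominence) n <- n + 1L
      i <- j
    }
    i <- i + 1
  }
  n
}

#' Per-beat feature set
#'
#' Bundles the standard per-beat measurements: APD90, the
#' afterdepolarisation count, diastolic ion levels read at stimulus onset
#' (the stroboscopic sample) and the within-beat calcium peak where a Cai
#' variable exists.
#'
#' @inheritParams apd90
#' @return list with \code{apd90}, \code{n_tdmp}, \code{repol_failure},
#'   \code{no_ap}, \code{di} (diastolic interval; NA when repolarisation
#'   fails), \code{dia} (named diastolic state), \code{peak_Cai}.
#' @export
beat_features <- function(trace) {
  a <- apd90(trace)
  dia <- stroboscopic_sample(trace)
  T <- attr(trace, "cycle_length") %||% max(trace$t)
  list(apd90 = as.numeric(a),
       n_tdmp = count_tdmp(trace),
       repol_failure = isTRUE(attr(a, "repol_failure")),
       no_ap = isTRUE(attr(a, "no_ap")),
       di = if (is.na(a)) NA_real_ else T - as.numeric(a),
       dia = dia,
       peak_Cai = if ("Cai" %in% names(trace)) max(trace$Cai) else NA_real_)
}

#' Diastolic and peak ion levels
#'
#' Diastolic values are read at stimulus onset (matching the stroboscopic
#' sample used in bifurcation diagrams); the calcium peak is the maximum
#' over the beat.
#'
#' @inheritParams apd90
#' @return list with \code{dia_Nai}, \code{dia_Cai}, \code{peak_Cai}
#'   (NA where the model lacks the variable).
#' @export
diastolic_and_peaks <- function(trace) {
  dia <- stroboscopic_sample(trace)
  list(dia_Nai = if ("Nai" %in% names(dia)) unname(dia["Nai"]) else NA_real_,
       dia_Cai = if ("Cai" %in% names(dia)) unname(dia["Cai"]) else NA_real_,
       peak_Cai = if ("Cai" %in% names(trace)) max(trace$Cai) else NA_real_)
}

#' Classify a steady AP response
#'
#' Maps the per-beat features of one detected period onto the response
#' taxonomy: \code{LAVO} when any beat of the period fails to repolarise
#' (arrest at a depolarised potential, with or without low-amplitude
#' oscillation), otherwise \code{EADn} with \code{n} the modal
#' afterdepolarisation count over the period (\code{noEAD} for 0,
#' \code{EADk} beyond 3), and \code{irregular} for responses that did not
#' converge to any tested period.
#'
#' @param features_list list of [beat_features()] results, one per beat of
#'   the detected period.
#' @param converged logical; was a periodic steady state reached?
#' @return character scalar response class.
#' @export
classify_response <- function(features_list, converged = TRUE) {
  if (!converged) return("irregular")
  if (any(vapply(features_list, function(f) f$repol_failure, logical(1))))
    return("LAVO")
  counts <- vapply(features_list, function(f) f$n_tdmp, integer(1))
  n <- as.integer(names(sort(table(counts), decreasing = TRUE))[1])
  if (n == 0) "noEAD" else if (n <= 3) paste0("EAD", n) else "EADk"
}

#' Settle and classify a response at the current parameters
#'
#' Convenience wrapper: runs to steady state, simulates one detected period
#' at fine sampling, and classifies the response.
#'
#' @inheritParams run_to_steady_state
#' @param dt_sample trace sampling interval (ms) for feature extraction.
#' @return list with \code{class}, \code{features} (first beat of the
#'   period), \code{steady} (the [run_to_steady_state()] result).
#' @export
settle_and_classify <- function(sys, state0, params = sys$params,
                                max_beats = 1000, tol = 1e-8,
                                dt_sample = 0.5,
                                control = integrator_control()) {
  ss <- run_to_steady_state(sys, state0, params, max_beats = max_beats,
                            tol = tol, control = control)
  per <- if (ss$converged) ss$period else 1L
  traces <- simulate_beats(sys, ss$state, n_beats = per, params = params,
                           dt_sample = dt_sample, control = control)
  feats <- lapply(traces, beat_features)
  list(class = classify_response(feats, converged = ss$converged),
       features = feats[[1]], steady = ss)
}
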