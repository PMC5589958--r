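#' Dynamical-system contract
#'
#' All analysis machinery in this package (stroboscopic maps, shooting,
#' continuation, sweep/census protocols) operates on a common pluggable
#' system object. Two kinds exist:
#' \describe{
#'   \item{\code{"map"}}{a discrete-time map \eqn{x_{k+1} = F(x_k; p)}. Maps
#'     are their own Poincare maps, so they plug directly into the shooting
#'     and continuation layers without integration error.}
#'   \item{\code{"forced_ode"}}{a periodically pulsed ODE
#'     \eqn{dy/dt = f(t, y; p)} driven by a square stimulus pulse at the
#'     start of every pacing cycle. Its stroboscopic map advances the state
#'     by whole cycles, sampling at stimulus onset.}
#' }
#'
#' @param kind \code{"map"} or \code{"forced_ode"}.
#' @param state_names character vector naming the state variables; its length
#'   declares the system dimension.
#' @param params named list of model parameters. For paced myocyte-style
#'   systems this includes \code{pctGKr}, \code{pctGKs} and \code{nai_clamp}.
#' @param map_fn for maps: \code{function(x, params)} returning the next state.
#' @param jac_fn optional analytic Jacobian \code{function(x, params)} of
#'   \code{map_fn} (used as the second, independent monodromy route for maps).
#' @param rhs_fn for ODE systems: \code{function(t, y, params, stim)} returning
#'   the derivative vector (\code{stim} is the current stimulus level, already
#'   resolved to a constant within each integration segment).
#' @param compiled optional compiled-code route for ODE systems: a list with
#'   \code{func}, \code{initfunc}, \code{dllname}, \code{nout} and
#'   \code{parms_fn(params, stim)} building the numeric parameter vector.
#' @param pacing a \code{\link{pacing_protocol}} (ODE systems only).
#' @param currents_fn optional \code{function(state, t, params)} returning the
#'   named membrane currents at a state (myocyte-style systems).
#' @param state_scale typical magnitude per state variable, used only to
#'   condition continuation arithmetic, never to redefine convergence norms.
#' @param known_features list of analytically known properties (fixed points,
#'   multipliers, bifurcation parameters) declared by the testbed factories.
#' @param name short identifier used in printing and artifact manifests.
#'
#' @return An object of class \code{dynsys}.
#' @seealso [make_logistic_map()], [make_paced_surrogate_ap()], [poincare_map()]
#' @export
dynsys <- function(kind = c("map", "forced_ode"), state_names, params,
                   map_fn = NULL, jac_fn = NULL, rhs_fn = NULL,
                   compiled = NULL, pacing = NULL, currents_fn = NULL,
                   state_scale = NULL, known_features = list(),
                   name = "dynsys") {
  kind <- match.arg(kind)
  if (kind == "map" && is.null(map_fn))
    stop("a map system needs `map_fn`")
  if (kind == "forced_ode") {
    if (is.null(rhs_fn) && is.null(compiled))
      stop("a forced_ode system needs `rhs_fn` and/or `compiled`")
    if (is.null(pacing)) pacing <- pacing_protocol()
  }
  if (is.null(state_scale)) state_scale <- rep(1, length(state_names))
  structure(list(kind = kind, dim = length(state_names),
                 state_names = state_names, params = params,
                 map_fn = map_fn, jac_fn = jac_fn, rhs_fn = rhs_fn,
                 compiled = compiled, pacing = pacing,
                 currents_fn = currents_fn, state_scale = state_scale,
                 known_features = known_features, name = name),
            class = "dynsys")
}

#' @export
print.dynsys <- function(x, ...) {
  cat(sprintf("<dynsys '%s': %s, dim %d [%s]>\n", x$name, x$kind, x$dim,
              paste(x$state_names, collapse = ", ")))
  if (x$kind == "forced_ode")
    cat(sprintf("  pacing: %g pA/pF x %g ms every %g ms\n",
                x$pacing$amplitude, x$pacing$duration, x$pacing$cycle_length))
  invisible(x)
}

#' Stimulus pacing protocol
#'
#' Square current pulses delivered at the start of every pacing cycle.
#' Defaults follow the standard bradycardia-type protocol used throughout the
#' package: 80 pA/pF, 1 ms pulses at 0.5 Hz (cycle length 2000 ms). The
#' depolarising stimulus enters the voltage equation with a positive sign.
#'
#' @param amplitude stimulus current density (pA/pF), > 0 for depolarising.
#' @param duration pulse width (ms); must be shorter than the cycle length.
#' @param cycle_length pacing cycle length (ms).
#' @return A list of class \code{pacing_protocol}.
#' @export
pacing_protocol <- function(amplitude = 80, duration = 1, cycle_length = 2000) {
  stopifnot(duration > 0, duration < cycle_length, amplitude >= 0)
  structure(list(amplitude = amplitude, duration = duration,
                 cycle_length = cycle_length), class = "pacing_protocol")
}

#' Integrator tolerances
#'
#' Defaults are two orders of magnitude below the 1e-8 steady-state
#' criterion applied to the stroboscopic samples: with looser settings the
#' integrator's own beat-to-beat jitter sits at or above the criterion and
#' settling can fail spuriously near a fixed point.
#'
#' @param rtol relative tolerance for the stiff adaptive integrator.
#' @param atol absolute tolerance.
#' @return A list with components \code{rtol}, \code{atol}.
#' @export
integrator_control <- function(rtol = 1e-10, atol = 1e-12) {
  list(rtol = rtol, atol = atol)
}

## indices of state variables that are dynamically free (a sodium clamp
## freezes the Nai component; its row/column is dropped from monodromy work)
free_indices <- function(sys, params = sys$params) {
  idx <- seq_len(sys$dim)
  if (!is.null(params$nai_clamp) && !is.na(params$nai_clamp)) {
    nai <- match("Nai", sys$state_names)
    if (!is.na(nai)) idx <- setdiff(idx, nai)
  }
  idx
}

#' Number of free state variables
#'
#' The declared dimension of the system, minus any clamped component: with a
#' sodium clamp in force the Nai equation is frozen, so the effective
#' dimension seen by monodromy analysis is one lower.
#'
#' @param sys a [dynsys()] object.
#' @param params parameter list (defaults to the system's own).
#' @return integer effective dimension.
#' @export
system_dimension <- function(sys, params = sys$params) {
  length(free_indices(sys, params))
}

## apply a clamp to a raw state vector (used before every integration so a
## clamped Nai is bit-identical at every sample)
apply_clamp <- function(sys, y, params = sys$params) {
  if (!is.null(params$nai_clamp) && !is.na(params$nai_clamp)) {
    nai <- match("Nai", sys$state_names)
    if (!is.na(nai)) y[nai] <- params$nai_clamp
  }
  y
}

## integrate one pacing cycle of a forced ODE system.
## The square pulse is handled by segmenting the integration at the pulse-off
## time, so the discontinuity never falls inside an adaptive step.
## Returns the end state; with `times`, a full sample matrix (t, states).
integrate_cycle <- function(sys, y0, params = sys$params,
                            control = integrator_control(), times = NULL,
                            amplitude = NULL) {
  pac <- sys$pacing
  amp <- if (is.null(amplitude)) pac$amplitude else amplitude
  dur <- pac$duration
  T <- pac$cycle_length
  y0 <- apply_clamp(sys, unname(y0), params)
  if (!all(is.finite(y0)))
    stop("non-finite state component: ",
         paste(sys$state_names[!is.finite(y0)], collapse = ", "))

  seg <- function(y, t0, t1, stim, tt = NULL) {
    tms <- if (is.null(tt)) c(t0, t1) else
      sort(unique(c(t0, tt[tt > t0 & tt < t1], t1)))
    if (!is.null(sys$compiled)) {
      cp <- sys$compiled
      out <- deSolve::ode(y, tms, func = cp$func,
                          parms = cp$parms_fn(params, stim),
                          dllname = cp$dllname, initfunc = cp$initfunc,
                          nout = cp$nout %||% 0, method = "lsoda",
                          rtol = control$rtol, atol = control$atol)
    } else {
      fn <- function(t, y, p) list(sys$rhs_fn(t, y, params, stim))
      out <- deSolve::ode(y, tms, fn, NULL, method = "lsoda",
                          rtol = control$rtol, atol = control$atol)
    }
    if (attr(out, "istate")[1] < 0)
      stop("integrator failure in [", t0, ", ", t1, "] ms; last state: ",
           paste(signif(out[nrow(out), 1 + seq_len(sys$dim)], 6),
                 collapse = ", "))
    out
  }

  want <- !is.null(times)
  if (amp > 0) {
    o1 <- seg(y0, 0, dur, amp, times)
    y1 <- unname(o1[nrow(o1), 1 + seq_len(sys$dim)])
    o2 <- seg(y1, dur, T, 0, times)
  } else {
    o1 <- NULL
    o2 <- seg(y0, 0, T, 0, times)
  }
  yT <- apply_clamp(sys, unname(o2[nrow(o2), 1 + seq_len(sys$dim)]), params)
  if (!want) return(yT)
  m <- rbind(if (!is.null(o1)) o1[-nrow(o1), , drop = FALSE], o2)
  colnames(m)[1 + seq_len(sys$dim)] <- sys$state_names
  list(end = yT, samples = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
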