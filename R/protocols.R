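#' Stepwise hysteresis sweep with state carry-over
#'
#' Sweeps a conductance percentage across a grid (1% steps by default),
#' settling to a steady response at each value and using the converged state
#' of the preceding step as the next step's initial condition. This
#' carry-over contract is the hysteresis mechanism itself: within a
#' multistable window the occupied attractor depends on the path, so
#' down-sweeps and up-sweeps transition at different parameter values.
#'
#' @param sys a paced [dynsys()].
#' @param from,to sweep end points (percent-of-control units).
#' @param step grid spacing (positive; direction comes from from/to).
#' @param state0 initial condition at \code{from} (defaults to the settled
#'   state at \code{from} from the system's declared rest state).
#' @param param_name swept parameter, \code{"pctGKr"} by default.
#' @param params base parameters.
#' @param max_beats,tol settling control per step.
#' @param control [integrator_control()] tolerances.
#' @param classify also extract per-step response features (slower).
#' @return data.frame with one row per grid value: \code{param},
#'   \code{direction}, \code{converged}, \code{period}, \code{class},
#'   \code{apd90}, \code{n_tdmp}, and the stroboscopic state columns.
#' @export
hysteresis_sweep <- function(sys, from, to, step = 1, state0 = NULL,
                             param_name = "pctGKr", params = sys$params,
                             max_beats = 2000, tol = 1e-8,
                             control = integrator_control(),
                             classify = TRUE) {
  grid <- seq(from, to, by = if (to >= from) abs(step) else -abs(step))
  direction <- if (to >= from) "up" else "down"
  if (is.null(state0)) {
    pp <- params; pp[[param_name]] <- from
    st <- sys$known_features$rest_state %||% rep(0, sys$dim)
    state0 <- run_to_steady_state(sys, st, pp, max_beats = max_beats,
                                  tol = tol, control = control)$state
  }
  y <- unname(state0)
  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    pp <- params; pp[[param_name]] <- grid[gi]
    ss <- run_to_steady_state(sys, y, pp, max_beats = max_beats, tol = tol,
                              control = control)
    if (all(is.finite(ss$state))) y <- unname(ss$state)  # carry best state
    cls <- NA_character_; a90 <- NA_real_; ntd <- NA_integer_
    if (classify) {
      per <- if (ss$converged) ss$period else 1L
      traces <- simulate_beats(sys, y, n_beats = per, params = pp,
                               dt_sample = 0.5, control = control)
      feats <- lapply(traces, beat_features)
      cls <- classify_response(feats, converged = ss$converged)
      a90 <- feats[[1]]$apd90
      ntd <- feats[[1]]$n_tdmp
    }
    rows[[gi]] <- data.frame(param = grid[gi], direction = direction,
                             converged = ss$converged,
                             period = if (ss$converged) ss$period else NA,
                             class = cls, apd90 = a90, n_tdmp = ntd,
                             t(stats::setNames(y, sys$state_names)))
  }
  out <- do.call(rbind, rows)
  attr(out, "param_name") <- param_name
  out
}

#' First class-transition parameter of a sweep
#'
#' @param sweep a [hysteresis_sweep()] result.
#' @return the first grid value (in sweep order) whose response class
#'   differs from the starting class, or NA when no transition occurs.
#' @export
sweep_transition <- function(sweep) {
  cls <- sweep$class
  chg <- which(cls != cls[1])
  if (!length(chg)) NA_real_ else sweep$param[chg[1]]
}

#' Default initial-condition bank for a multistability census
#'
#' A declared grid of starting states: slow-sodium values spread over the
#' physiological range, crossed with a polarised resting configuration and a
#' depolarised plateau configuration (the analogue of low/high calcium-load
#' starting conditions). The census settles every start and counts distinct
#' attractors, so it is a lower bound on the true multistability order.
#'
#' @param sys a paced [dynsys()] with states \code{Vm, h, Nai}.
#' @param n_nai number of sodium grid values.
#' @param nai_range range of starting sodium values (mM).
#' @return list of state vectors.
#' @export
default_init_bank <- function(sys, n_nai = 11, nai_range = c(0.25, 9.75)) {
  nais <- seq(nai_range[1], nai_range[2], length.out = n_nai)
  rest <- sys$known_features$rest_state %||% c(-86, 1, 7)
  plat <- sys$known_features$plateau_state %||% c(-35, 0.05, 0.5)
  c(lapply(nais, function(na) c(rest[1], rest[2], na)),
    lapply(nais, function(na) c(plat[1], plat[2], na)))
}

#' Multistability census at one parameter value
#'
#' Settles every start of an initial-condition bank and collects the set of
#' distinct attractors reached; two converged stroboscopic states are the
#' same attractor when they differ by at most \code{identity_tol} in any
#' component (raw mixed units; for period-k responses the orbit points are
#' matched up to cyclic shift). The reported order (1 = mono-, 2 = bi-,
#' 3 = tri-, 4 = tetra-stable) is a lower bound: a finite bank can miss
#' small basins.
#'
#' @param sys a paced [dynsys()].
#' @param param_value value of \code{param_name} to probe.
#' @param init_bank list of starting states ([default_init_bank()] if NULL).
#' @param param_name parameter being varied.
#' @param params base parameters.
#' @param identity_tol attractor identity threshold (componentwise).
#' @param max_beats,tol settling control.
#' @param control [integrator_control()] tolerances.
#' @param classify attach response classes per attractor.
#' @return list of class \code{census_entry}: \code{param_value},
#'   \code{order}, \code{attractors} (list of state vectors),
#'   \code{classes}, \code{periods}, \code{n_settled}, \code{n_starts}.
#' @export
multistability_census <- function(sys, param_value, init_bank = NULL,
                                  param_name = "pctGKr", params = sys$params,
                                  identity_tol = 1e-4, max_beats = 1000,
                                  tol = 1e-8, control = integrator_control(),
                                  classify = TRUE) {
  if (is.null(init_bank)) init_bank <- default_init_bank(sys)
  pp <- params; pp[[param_name]] <- param_value
  attractors <- list(); periods <- integer(0); n_settled <- 0L
  for (y0 in init_bank) {
    ss <- run_to_steady_state(sys, y0, pp, max_beats = max_beats, tol = tol,
                              control = control)
    if (!ss$converged) next
    n_settled <- n_settled + 1L
    xs <- unname(ss$state)
    dup <- FALSE
    for (ai in seq_along(attractors)) {
      if (periods[ai] == ss$period &&
          orbit_match(sys, attractors[[ai]], xs, ss$period, pp,
                      identity_tol, control)) { dup <- TRUE; break }
    }
    if (!dup) {
      attractors[[length(attractors) + 1]] <- xs
      periods <- c(periods, ss$period)
    }
  }
  classes <- rep(NA_character_, length(attractors))
  if (classify && sys$kind == "forced_ode" && "Vm" %in% sys$state_names) {
    classes <- vapply(attractors, function(a) {
      sc <- settle_and_classify(sys, a, pp, max_beats = 10, tol = tol,
                                control = control)
      sc$class
    }, character(1))
  }
  structure(list(param_value = param_value, order = length(attractors),
                 attractors = attractors, classes = classes,
                 periods = periods, n_settled = n_settled,
                 n_starts = length(init_bank)),
            class = "census_entry")
}

## do two converged states lie on the same period-k orbit?
orbit_match <- function(sys, a, b, period, params, tol, control) {
  x <- b
  for (shift in seq_len(max(period, 1))) {
    if (max(abs(x - a)) <= tol) return(TRUE)
    if (period > 1) x <- poincare_map(sys, x, 1, params, control)
  }
  FALSE
}

#' @export
print.census_entry <- function(x, ...) {
  cat(sprintf("<census at %.4g: order %d (%s); %d/%d starts settled>\n",
              x$param_value, x$order,
              paste(stats::na.omit(x$classes), collapse = " + "),
              x$n_settled, x$n_starts))
  invisible(x)
}

#' Instantaneous sodium perturbation
#'
#' Adds \code{delta_nai} to the slow sodium variable at a stimulus onset and
#' settles the paced system — the probe used to demonstrate transitions
#' among coexisting attractors: a perturbation crossing the basin boundary
#' switches the response class, one within the basin does not.
#'
#' @param sys a paced [dynsys()].
#' @param state state at stimulus onset.
#' @param delta_nai perturbation (mM) added to the Nai component.
#' @param params parameters.
#' @param max_beats,tol settling control.
#' @param control [integrator_control()] tolerances.
#' @return list with \code{class}, \code{state} (settled), \code{steady}.
#' @export
perturb_and_settle <- function(sys, state, delta_nai, params = sys$params,
                               max_beats = 1000, tol = 1e-8,
                               control = integrator_control()) {
  nai <- match("Nai", sys$state_names)
  if (is.na(nai)) stop("system has no Nai state variable")
  y <- unname(state)
  y[nai] <- y[nai] + delta_nai
  sc <- settle_and_classify(sys, y, params, max_beats = max_beats, tol = tol,
                            control = control)
  list(class = sc$class, state = sc$steady$state, steady = sc$steady)
}

#' Assemble a one-parameter bifurcation diagram
#'
#' Merges continuation branches into a single table with per-point features
#' of the periodic response (APD90, afterdepolarisation count, diastolic
#' sodium — computed on the converged orbit over one period), marks the
#' localized bifurcation points, and identifies parameter windows where two
#' or more stable branches overlap (the multistability windows shaded in
#' conductance-scan diagrams).
#'
#' @param sys the [dynsys()] the branches belong to.
#' @param branches list of [continue_branch()] results.
#' @param bif_points list of [localize_bifurcation()] results.
#' @param params base parameters.
#' @param control [integrator_control()] tolerances.
#' @param features compute per-point beat features (slower).
#' @return list of class \code{bifurcation_diagram} with \code{table}
#'   (one row per branch point), \code{bifurcations} (data.frame), and
#'   \code{multistable_windows} (data.frame of overlapping stable ranges).
#' @export
build_bifurcation_diagram <- function(sys, branches, bif_points = list(),
                                      params = sys$params,
                                      control = integrator_control(),
                                      features = FALSE) {
  param_name <- branches[[1]]$param_name
  tabs <- lapply(seq_along(branches), function(bi) {
    df <- as.data.frame(branches[[bi]])
    df$branch <- bi
    df$k <- branches[[bi]]$k
    if (features && sys$kind == "forced_ode") {
      fx <- lapply(branches[[bi]]$points, function(pt) {
        pp <- params; pp[[param_name]] <- pt$param
        tr <- simulate_beats(sys, pt$x, branches[[bi]]$k, pp,
                             dt_sample = 0.5, control = control)
        f <- beat_features(tr[[1]])
        c(apd90 = f$apd90, n_tdmp = f$n_tdmp)
      })
      df$apd90 <- vapply(fx, `[[`, numeric(1), "apd90")
      df$n_tdmp <- vapply(fx, `[[`, numeric(1), "n_tdmp")
    }
    df
  })
  tab <- do.call(rbind, tabs)

  bifs <- if (length(bif_points))
    do.call(rbind, lapply(bif_points, function(b)
      data.frame(param_value = b$param_value, type = b$type,
                 mod = Mod(b$critical_multiplier), k = b$k)))
  else data.frame()

  ## stable-overlap windows between distinct branches
  windows <- NULL
  stab_range <- function(df) {
    s <- df[df$stable, , drop = FALSE]
    if (!nrow(s)) NULL else range(s$param)
  }
  rngs <- Filter(Negate(is.null), lapply(tabs, stab_range))
  if (length(rngs) >= 2) {
    for (a in seq_along(rngs)) for (b in seq_along(rngs)) {
      if (a < b) {
        lo <- max(rngs[[a]][1], rngs[[b]][1])
        hi <- min(rngs[[a]][2], rngs[[b]][2])
        if (lo < hi)
          windows <- rbind(windows, data.frame(lo = lo, hi = hi,
                                               branch_a = a, branch_b = b))
      }
    }
  }
  structure(list(table = tab, bifurcations = bifs,
                 multistable_windows = windows %||% data.frame(),
                 param_name = param_name),
            class = "bifurcation_diagram")
}

#' Sodium-clamped bifurcation/census analysis
#'
#' Re-runs the census over a conductance range with the slow sodium
#' variable clamped at each of several fixed values — the reduced
#' (sodium-fixed) system. Comparing the resulting multistability orders
#' with the free-sodium system shows whether the multistability is carried
#' by the slow sodium dynamics (order collapses under clamp) or by the fast
#' subsystem alone.
#'
#' @param sys a paced [dynsys()] with a Nai state.
#' @param nai_values clamp levels (mM).
#' @param pct_values conductance percentages to probe.
#' @param param_name varied parameter.
#' @param params base parameters.
#' @param init_bank starting states (defaults to [default_init_bank()]).
#' @param ... passed to [multistability_census()].
#' @return data.frame with one row per (clamp, percentage): \code{nai_clamp}
#'   (NA = free), \code{param_value}, \code{order}, \code{classes}.
#' @export
nai_fixed_analysis <- function(sys, nai_values, pct_values,
                               param_name = "pctGKr", params = sys$params,
                               init_bank = NULL, ...) {
  if (is.null(init_bank)) init_bank <- default_init_bank(sys)
  rows <- list()
  for (clamp in c(NA, nai_values)) {
    pp <- params
    pp$nai_clamp <- clamp
    bank <- if (is.na(clamp)) init_bank else
      lapply(init_bank, function(y) {
        y[match("Nai", sys$state_names)] <- clamp; y
      })
    for (pct in pct_values) {
      ce <- multistability_census(sys, pct, bank, param_name, pp, ...)
      rows[[length(rows) + 1]] <-
        data.frame(nai_clamp = clamp, param_value = pct, order = ce$order,
                   classes = paste(stats::na.omit(ce$classes), collapse = "+"))
    }
  }
  do.call(rbind, rows)
}
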