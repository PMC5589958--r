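#' Pseudo-arclength continuation of periodic responses
#'
#' Traces a branch of period-k fixed points of the stroboscopic map as one
#' model parameter varies. The branch is parametrized by arclength in the
#' scaled (state, parameter) space with a secant predictor and a Newton
#' corrector on the bordered system, so saddle-node folds are traversed and
#' the branch continues onto its unstable side — natural-parameter stepping
#' cannot round a fold, and the hysteresis structure of interest here lives
#' between folds. The step length halves on corrector failure, grows by 1.3x
#' after three consecutive successes, and stays within
#' \code{[min_step, max_step]} (in percent-style parameter units).
#'
#' @param sys a [dynsys()].
#' @param seed a converged [newton_shoot()] fixed point at the starting
#'   parameter value.
#' @param param_name name of the entry of \code{sys$params} to vary.
#' @param param_range numeric length-2; continuation stops once the
#'   parameter leaves this interval.
#' @param initial_step signed first step in parameter units; its sign sets
#'   the initial direction.
#' @param k period multiple of the fixed points being continued.
#' @param max_points cap on branch length.
#' @param tol Newton residual tolerance per point.
#' @param min_step,max_step arclength step bounds (parameter-scaled units).
#' @param stop_mult terminate once the leading multiplier modulus exceeds
#'   this value (strongly unstable mid-branch orbits are expensive to track
#'   and rarely informative beyond their existence).
#' @param control [integrator_control()] tolerances.
#' @param monodromy_method Jacobian route.
#' @return object of class \code{ap_branch}: list of branch points (each
#'   with \code{x}, \code{param}, \code{multipliers}, \code{stable},
#'   \code{residual}), plus bookkeeping fields.
#' @export
continue_branch <- function(sys, seed, param_name, param_range,
                            initial_step = diff(range(param_range)) / 100,
                            k = seed$k, max_points = 500, tol = 1e-9,
                            min_step = NULL, max_step = NULL,
                            stop_mult = Inf,
                            control = integrator_control(),
                            monodromy_method = "fd") {
  stopifnot(inherits(seed, "fixed_point"))
  if (!seed$converged) stop("continuation seed has not converged")
  free <- free_indices(sys)
  sx <- sys$state_scale[free]
  sp <- max(abs(param_range), diff(range(param_range)))
  if (is.null(min_step)) min_step <- 1e-4 * abs(initial_step) / sp
  if (is.null(max_step)) max_step <- 4 * abs(initial_step) / sp

  base_params <- seed$params_at
  p0 <- base_params[[param_name]]
  at <- function(p) { pp <- base_params; pp[[param_name]] <- p; pp }
  shoot <- function(x, p, tol_ = tol)
    newton_shoot(sys, x, k, at(p), tol = tol_, control = control,
                 monodromy_method = monodromy_method)

  mk_point <- function(fp, p)
    list(x = stats::setNames(unname(fp$x), names(fp$x)), param = p,
         multipliers = fp$multipliers,
         stable = fp$stable, residual = fp$residual,
         monodromy = fp$monodromy)

  fp1 <- shoot(seed$x, p0)
  if (!fp1$converged) stop("could not re-converge seed")
  pts <- list(mk_point(fp1, p0))

  # second point by a natural-parameter step (halved on failure)
  step <- initial_step
  fp2 <- NULL
  for (tryi in 1:12) {
    p1 <- p0 + step
    cand <- shoot(pts[[1]]$x, p1)
    if (cand$converged) { fp2 <- cand; break }
    step <- step / 2
  }
  if (is.null(fp2)) stop("continuation could not take its first step")
  pts[[2]] <- mk_point(fp2, p1)

  zs <- function(pt) c(unname(pt$x)[free] / sx, pt$param / sp)
  h <- sqrt(sum((zs(pts[[2]]) - zs(pts[[1]]))^2))
  successes <- 0
  dpar <- 1e-6 * sp

  corrector <- function(zpred, tvec, x_full) {
    # unknowns: (x[free], p); bordered Newton on [P(x;p) - x ; t.(z - zpred)]
    x <- x_full
    x[free] <- zpred[seq_along(free)] * sx
    p <- zpred[length(zpred)] * sp
    for (it in 1:15) {
      params <- at(p)
      x <- apply_clamp(sys, x, params)
      Px <- poincare_map(sys, x, k, params, control)
      r1 <- (Px - x)[free]
      z <- c(x[free] / sx, p / sp)
      r2 <- sum(tvec * (z - zpred))
      if (max(abs(r1)) < tol && abs(r2) < 1e-10) {
        return(list(x = x, p = p, iters = it, res = max(abs(r1))))
      }
      M <- monodromy(sys, x, k, params, method = monodromy_method,
                     control = control)
      dPdp <- (poincare_map(sys, x, k, at(p + dpar), control) -
                 poincare_map(sys, x, k, at(p - dpar), control))[free] /
        (2 * dpar)
      J <- rbind(cbind(M - diag(length(free)), dPdp),
                 c(tvec[seq_along(free)] / sx, tvec[length(tvec)] / sp))
      delta <- tryCatch(solve(J, -c(r1, r2)), error = function(e) NULL)
      if (is.null(delta) || !all(is.finite(delta))) return(NULL)
      # cap the scaled Newton step so the corrector cannot leave the
      # predictor's neighbourhood and land on a different branch
      dzn <- sqrt(sum((delta / c(sx, sp))^2))
      if (dzn > 0.3) delta <- delta * (0.3 / dzn)
      x[free] <- x[free] + delta[seq_along(free)]
      p <- p + delta[length(delta)]
      if (!all(is.finite(x))) return(NULL)
    }
    NULL
  }

  lo <- min(param_range); hi <- max(param_range)
  termination <- "max_points"
  while (length(pts) < max_points) {
    n <- length(pts)
    z1 <- zs(pts[[n - 1]]); z2 <- zs(pts[[n]])
    tvec <- z2 - z1
    nt <- sqrt(sum(tvec^2))
    if (nt < .Machine$double.eps) { termination <- "tangent_degenerate"; break }
    tvec <- tvec / nt
    accepted <- FALSE
    while (!accepted) {
      zpred <- z2 + h * tvec
      sol <- corrector(zpred, tvec, pts[[n]]$x)
      if (!is.null(sol)) {
        zsol <- c(sol$x[free] / sx, sol$p / sp)
        if (sqrt(sum((zsol - zpred)^2)) > 3 * h + 1e-8) sol <- NULL
      }
      if (!is.null(sol)) {
        # multipliers at the accepted point; no fixed-parameter re-shoot
        # here, since (DP - I) is singular exactly at the folds the
        # arclength stepping is meant to traverse
        M <- monodromy(sys, sol$x, k, at(sol$p), method = monodromy_method,
                       control = control)
        mult <- characteristic_multipliers(M)
        pts[[n + 1]] <- list(
          x = stats::setNames(unname(sol$x), sys$state_names),
          param = sol$p, multipliers = mult,
          stable = all(Mod(mult) < 1), residual = sol$res, monodromy = M)
        successes <- successes + 1
        if (successes >= 3) { h <- min(h * 1.3, max_step); successes <- 0 }
        accepted <- TRUE
        break
      }
      successes <- 0
      h <- h / 2
      if (h < min_step) break
    }
    if (!accepted) { termination <- "step_underflow"; break }
    if (Mod(pts[[length(pts)]]$multipliers[1]) > stop_mult) {
      termination <- "stop_mult"; break
    }
    if (pts[[length(pts)]]$param < lo - 1e-9 ||
        pts[[length(pts)]]$param > hi + 1e-9) {
      termination <- "range_exit"; break
    }
  }

  structure(list(points = pts, param_name = param_name, k = k,
                 param_range = param_range, base_params = base_params,
                 termination = termination, sys_name = sys$name),
            class = "ap_branch")
}

#' @export
print.ap_branch <- function(x, ...) {
  pr <- vapply(x$points, `[[`, numeric(1), "param")
  cat(sprintf("<ap_branch: %d period-%d points in %s = [%.4g, %.4g]>\n",
              length(x$points), x$k, x$param_name, min(pr), max(pr)))
  invisible(x)
}

#' @export
as.data.frame.ap_branch <- function(x, ...) {
  do.call(rbind, lapply(x$points, function(pt) {
    data.frame(param = pt$param, t(pt$x), stable = pt$stable,
               lead_mod = Mod(pt$multipliers[1]), residual = pt$residual)
  }))
}

## greedy nearest-neighbour matching of multiplier sets between consecutive
## branch points, in the complex plane; distinguishes a real crossing at -1
## from a complex pair leaving through the unit circle
match_multipliers <- function(m1, m2) {
  used <- logical(length(m2))
  idx <- integer(length(m1))
  for (i in seq_along(m1)) {
    d <- Mod(m2 - m1[i])
    d[used] <- Inf
    j <- which.min(d)
    idx[i] <- j
    used[j] <- TRUE
  }
  idx
}

#' Detect multiplier crossings along a branch
#'
#' Flags consecutive branch-point pairs where a characteristic multiplier
#' leaves or enters the unit circle: a real multiplier crossing +1
#' (saddle-node, co-detected with a fold in the parameter direction), a real
#' multiplier crossing -1 (period doubling), or a complex-conjugate pair
#' whose modulus crosses 1 (Neimark-Sacker). Multipliers are tracked across
#' steps by nearest-neighbour matching in the complex plane; a pair with
#' imaginary part below \code{imag_tol} is treated as real.
#'
#' @param branch an [continue_branch()] result.
#' @param imag_tol threshold on |Im| separating real multipliers from
#'   complex pairs.
#' @return data.frame of candidate brackets: index \code{i} (between points
#'   \code{i} and \code{i+1}), \code{type}, the bracketing parameter values
#'   and the tracked multiplier at both ends.
#' @export
detect_crossings <- function(branch, imag_tol = 1e-6) {
  pts <- branch$points
  out <- NULL
  add <- function(i, type, m1, m2)
    rbind(out, data.frame(i = i, type = type,
                          param_lo = pts[[i]]$param, param_hi = pts[[i + 1]]$param,
                          re1 = Re(m1), im1 = Im(m1), re2 = Re(m2), im2 = Im(m2)))
  for (i in seq_len(length(pts) - 1)) {
    m1 <- pts[[i]]$multipliers
    m2 <- pts[[i + 1]]$multipliers[match_multipliers(m1, pts[[i + 1]]$multipliers)]
    fold_here <- i >= 2 &&
      sign(pts[[i + 1]]$param - pts[[i]]$param) !=
      sign(pts[[i]]$param - pts[[i - 1]]$param)
    seen_sn <- FALSE
    for (j in seq_along(m1)) {
      a <- m1[j]; b <- m2[j]
      realpair <- abs(Im(a)) < imag_tol && abs(Im(b)) < imag_tol
      if (realpair) {
        if ((Re(a) - 1) * (Re(b) - 1) < 0 && !seen_sn) {
          out <- add(i, "SN", a, b); seen_sn <- TRUE
        } else if ((Re(a) + 1) * (Re(b) + 1) < 0) {
          out <- add(i, "PD", a, b)
        }
      } else if (Im(a) > imag_tol) {   # one member of each conjugate pair
        if ((Mod(a) - 1) * (Mod(b) - 1) < 0) out <- add(i, "NS", a, b)
      }
    }
    if (fold_here && !seen_sn) {
      # fold in parameter direction whose +1 crossing straddles point i
      jj <- which.min(abs(Re(m1) - 1))
      out <- add(i - 1, "SN", pts[[i - 1]]$multipliers[1], m1[jj])
    }
  }
  ## a branch truncated by step underflow with a real multiplier climbing
  ## towards +1 has stalled against an un-rounded fold: emit a candidate at
  ## its end so the extended-system solve can pin the fold from there
  if (identical(branch$termination, "step_underflow") && length(pts) >= 2) {
    n <- length(pts)
    mend <- pts[[n]]$multipliers[1]
    mprev <- pts[[n - 1]]$multipliers[1]
    if (abs(Im(mend)) < imag_tol && Re(mend) > 0.7 && Re(mend) < 1.3 &&
        abs(Re(mend) - 1) < abs(Re(mprev) - 1) &&
        (is.null(out) || !any(out$type == "SN" & out$i >= n - 2))) {
      out <- add(n - 1, "SN", mprev, mend)
    }
  }
  if (!is.null(out)) {
    out <- out[!duplicated(out[, c("i", "type")]), ]
    ## a fold produces one genuine +1 crossing; when several adjacent SN
    ## rows fire (nearest-neighbour matching is ambiguous among near-zero
    ## multipliers) keep the row whose endpoints sit closest to +1
    sn <- which(out$type == "SN")
    if (length(sn) > 1) {
      badness <- pmax(abs(out$re1[sn] - 1), abs(out$re2[sn] - 1))
      grp <- cumsum(c(1, diff(out$i[sn]) > 2))
      keep <- sn[unlist(lapply(split(seq_along(sn), grp),
                               function(ii) ii[which.min(badness[ii])]))]
      out <- out[sort(c(setdiff(seq_len(nrow(out)), sn), keep)), ]
    }
  }
  out
}

#' Localize a bifurcation point
#'
#' Refines a [detect_crossings()] bracket to a parameter value. Period
#' doubling and Neimark-Sacker points persist through the bifurcation, so
#' the fixed point is re-shot at trial parameters and the crossing function
#' (tracked real multiplier + 1, or pair modulus - 1) is driven to zero by
#' bracketed root finding. A saddle-node point is solved directly from the
#' Moore-Spence extended system
#' \eqn{\{P(x;p)-x = 0,\ (DP-I)v = 0,\ c\cdot v = 1\}}
#' by damped Newton, which pins the fold to the tolerance of the underlying
#' map evaluation.
#'
#' @param sys the [dynsys()] the branch was computed on.
#' @param branch the [continue_branch()] result.
#' @param crossing one row of [detect_crossings()].
#' @param tol_param parameter tolerance for root bracketing (PD/NS).
#' @param control [integrator_control()] tolerances.
#' @param monodromy_method Jacobian route.
#' @return object of class \code{bifurcation_point}: \code{param_value},
#'   \code{type}, \code{critical_multiplier}, \code{state},
#'   \code{localization_width}, \code{k}.
#' @export
localize_bifurcation <- function(sys, branch, crossing, tol_param = 1e-9,
                                 control = integrator_control(),
                                 monodromy_method = NULL) {
  # the fold solve needs the most accurate Jacobian available: the
  # variational route for ODE systems, plain FD for (polynomial) maps
  if (is.null(monodromy_method))
    monodromy_method <- if (sys$kind == "forced_ode" &&
                            !is.null(sys$rhs_fn)) "variational" else "fd"
  if (is.null(crossing) || !nrow(crossing) || is.na(crossing$type[1]))
    stop("no valid crossing bracket supplied to localize_bifurcation()")
  pts <- branch$points
  k <- branch$k
  param_name <- branch$param_name
  i <- crossing$i
  base_params <- branch$base_params %||% sys$params
  at <- function(p) { pp <- base_params; pp[[param_name]] <- p; pp }
  free <- free_indices(sys)
  type <- as.character(crossing$type)

  if (type %in% c("PD", "NS")) {
    x1 <- pts[[i]]$x; x2 <- pts[[i + 1]]$x
    p1 <- pts[[i]]$param; p2 <- pts[[i + 1]]$param
    gfun <- function(p) {
      w <- if (p2 != p1) (p - p1) / (p2 - p1) else 0.5
      fp <- newton_shoot(sys, x1 + w * (x2 - x1), k, at(p), tol = 1e-11,
                         control = control,
                         monodromy_method = monodromy_method)
      m <- fp$multipliers
      if (type == "PD") {
        mr <- m[abs(Im(m)) < 1e-6]
        if (!length(mr)) mr <- m
        Re(mr[which.min(abs(Re(mr) + 1))]) + 1
      } else {
        mc <- m[Im(m) > 1e-6]
        if (!length(mc)) mc <- m
        Mod(mc[which.min(abs(Mod(mc) - 1))]) - 1
      }
    }
    root <- stats::uniroot(gfun, lower = min(p1, p2), upper = max(p1, p2),
                           tol = tol_param, extendInt = "no")
    pstar <- root$root
    w <- if (p2 != p1) (pstar - p1) / (p2 - p1) else 0.5
    fp <- newton_shoot(sys, x1 + w * (x2 - x1), k, at(pstar), tol = 1e-11,
                       control = control, monodromy_method = monodromy_method)
    m <- fp$multipliers
    crit <- if (type == "PD") m[which.min(abs(m + 1))] else
      m[which.min(abs(Mod(m) - 1) + (Im(m) <= 0))]
    return(structure(list(param_value = pstar, type = type,
                          critical_multiplier = crit,
                          state = fp$x, localization_width = root$estim.prec,
                          k = k), class = "bifurcation_point"))
  }

  ## SN: Moore-Spence extended system from the bracket endpoint
  nf <- length(free)
  x0 <- pts[[i]]$x
  p0 <- pts[[i]]$param
  M0 <- pts[[i]]$monodromy %||%
    monodromy(sys, x0, k, at(p0), method = monodromy_method, control = control)
  ev <- eigen(M0)
  jcrit <- which.min(abs(ev$values - 1))
  v0 <- Re(ev$vectors[, jcrit])
  v0 <- v0 / sqrt(sum(v0^2))
  cvec <- v0
  sxp <- c(sys$state_scale[free], max(abs(branch$param_range)))

  Fms <- function(z) {
    x <- x0; x[free] <- z[seq_len(nf)]
    p <- z[nf + 1]
    v <- z[nf + 1 + seq_len(nf)]
    params <- at(p)
    Px <- poincare_map(sys, x, k, params, control)
    M <- monodromy(sys, x, k, params, method = monodromy_method,
                   control = control)
    c((Px - x)[free], as.vector((M - diag(nf)) %*% v), sum(cvec * v) - 1)
  }

  z <- c(x0[free], p0, v0)
  Fz <- Fms(z)
  for (it in 1:25) {
    if (max(abs(Fz)) < 1e-10) break
    steps <- 1e-6 * pmax(abs(z), c(sxp, rep(1, nf)))
    J <- fd_jacobian(Fms, z, steps)
    dz <- tryCatch(solve(J, -Fz), error = function(e) NULL)
    if (is.null(dz)) break
    lambda <- 1
    for (hh in 0:8) {
      zn <- z + lambda * dz
      Fn <- tryCatch(Fms(zn), error = function(e) NULL)
      if (!is.null(Fn) && all(is.finite(Fn)) &&
          max(abs(Fn)) < max(abs(Fz))) { z <- zn; Fz <- Fn; break }
      lambda <- lambda / 2
    }
    if (lambda < 1 / 300) break
  }
  xstar <- unname(x0); xstar[free] <- unname(z[seq_len(nf)])
  pstar <- unname(z[nf + 1])
  Mstar <- monodromy(sys, xstar, k, at(pstar), method = monodromy_method,
                     control = control)
  m <- characteristic_multipliers(Mstar)
  structure(list(param_value = pstar, type = "SN",
                 critical_multiplier = m[which.min(abs(m - 1))],
                 state = stats::setNames(xstar, sys$state_names),
                 localization_width = max(abs(Fz)), k = k),
            class = "bifurcation_point")
}

#' @export
print.bifurcation_point <- function(x, ...) {
  cat(sprintf("<%s bifurcation at param = %.8g (k = %d), |mult| = %.6f>\n",
              x$type, x$param_value, x$k, Mod(x$critical_multiplier)))
  invisible(x)
}

#' Response reached just past a bifurcation
#'
#' Steps the parameter slightly beyond a localized bifurcation point and
#' simulates forward from the pre-bifurcation state until steady state,
#' classifying the destination attractor. Under multistability the
#' destination is the one reached from \emph{this} initial condition, which
#' is exactly the state-transition mechanism: past a saddle-node the orbit
#' must leave for whatever coexisting attractor remains (or diverge, when
#' none exists, as in the bare normal form).
#'
#' @param sys the [dynsys()].
#' @param bif a [localize_bifurcation()] result.
#' @param param_name parameter being varied.
#' @param side +1/-1: direction in which to step past the bifurcation.
#' @param delta parameter offset beyond the bifurcation point.
#' @param params base parameter list.
#' @param max_beats,tol as in [run_to_steady_state()].
#' @param control [integrator_control()] tolerances.
#' @return list with \code{steady} (the settling result), \code{class}
#'   (response class for voltage-bearing systems, else NA) and
#'   \code{diverged}.
#' @export
post_bifurcation_transition <- function(sys, bif, param_name, side = +1,
                                        delta = 0.5, params = sys$params,
                                        max_beats = 2000, tol = 1e-8,
                                        control = integrator_control()) {
  params[[param_name]] <- bif$param_value + side * delta
  ss <- run_to_steady_state(sys, bif$state, params, max_beats = max_beats,
                            tol = tol, control = control)
  cls <- NA_character_
  if (isTRUE(ss$diverged)) {
    return(list(steady = ss, class = NA_character_, diverged = TRUE))
  }
  if (sys$kind == "forced_ode" && "Vm" %in% sys$state_names) {
    sc <- settle_and_classify(sys, ss$state, params, max_beats = 10,
                              tol = tol, control = control)
    cls <- sc$class
  }
  list(steady = ss, class = cls, diverged = FALSE)
}
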