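#' Stroboscopic Poincare map
#'
#' Advances a state through \code{k} pacing cycles (or \code{k} iterations
#' for a map system) from stimulus onset to stimulus onset. Periodic AP
#' responses of the paced system are exactly the fixed points of this map
#' (of its k-th power for period-k responses); the qualitative study of the
#' periodically forced system reduces to this diffeomorphism.
#'
#' @param sys a [dynsys()].
#' @param x state at stimulus onset.
#' @param k number of cycles (the period multiple), >= 1.
#' @param params parameter list override.
#' @param control [integrator_control()] tolerances (ODE systems).
#' @return the image state (unnamed numeric vector).
#' @export
poincare_map <- function(sys, x, k = 1, params = sys$params,
                         control = integrator_control()) {
  stopifnot(k >= 1)
  x <- unname(x)
  if (sys$kind == "map") {
    for (i in seq_len(k)) x <- unname(sys$map_fn(x, params))
    return(x)
  }
  for (i in seq_len(k)) x <- integrate_cycle(sys, x, params, control)
  x
}

## central-difference Jacobian of an arbitrary vector function
fd_jacobian <- function(f, x, steps) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- steps[j]
    J[, j] <- (f(x + e) - f(x - e)) / (2 * steps[j])
  }
  J
}

#' Monodromy matrix of the Poincare map
#'
#' The Jacobian of \code{P^k} at a state, restricted to the free state
#' variables (a clamped Nai contributes no dynamics and is excluded). Two
#' independent routes are provided and are expected to agree on smooth
#' systems:
#' \describe{
#'   \item{\code{"fd"}}{central finite differences of the Poincare map, with
#'     per-variable steps scaled by the state's typical magnitude.}
#'   \item{\code{"variational"}}{integration of the variational equations
#'     \eqn{dM/dt = J_f(t, y(t)) M} alongside the flow, with the right-hand
#'     side Jacobian obtained by central differencing of the model
#'     derivatives; for map systems, the chain-rule product of the analytic
#'     map Jacobians along the orbit (requires \code{jac_fn}).}
#' }
#'
#' @inheritParams poincare_map
#' @param method Jacobian route, see Details.
#' @param fd_rel relative finite-difference step (scaled per variable class).
#' @return square matrix of order [system_dimension()].
#' @export
monodromy <- function(sys, x, k = 1, params = sys$params,
                      method = c("fd", "variational"),
                      control = integrator_control(), fd_rel = 1e-5) {
  method <- match.arg(method)
  x <- apply_clamp(sys, unname(x), params)
  free <- free_indices(sys, params)

  if (method == "fd") {
    fmap <- function(xf) {
      xx <- x; xx[free] <- xf
      poincare_map(sys, xx, k, params, control)[free]
    }
    steps <- fd_rel * pmax(sys$state_scale[free], abs(x[free]))
    return(fd_jacobian(fmap, x[free], steps))
  }

  if (sys$kind == "map") {
    if (is.null(sys$jac_fn))
      stop("variational route for a map system needs an analytic `jac_fn`")
    M <- diag(length(free))
    xx <- x
    for (i in seq_len(k)) {
      M <- sys$jac_fn(xx, params)[free, free, drop = FALSE] %*% M
      xx <- unname(sys$map_fn(xx, params))
    }
    return(M)
  }

  variational_cycle_k(sys, x, k, params, control, fd_rel)
}

## integrate state + variational equations over k cycles (R rhs route)
variational_cycle_k <- function(sys, x, k, params, control, fd_rel) {
  free <- free_indices(sys, params)
  nf <- length(free)
  n <- sys$dim
  pac <- sys$pacing
  steps <- fd_rel * sys$state_scale

  aug_rhs <- function(t, z, stim) {
    y <- z[seq_len(n)]
    M <- matrix(z[-seq_len(n)], nf, nf)
    dy <- sys$rhs_fn(t, y, params, stim)
    if (!is.null(params$nai_clamp) && !is.na(params$nai_clamp)) {
      nai <- match("Nai", sys$state_names)
      if (!is.na(nai)) dy[nai] <- 0
    }
    Jf <- matrix(NA_real_, nf, nf)
    for (jj in seq_along(free)) {
      e <- numeric(n); e[free[jj]] <- steps[free[jj]]
      Jf[, jj] <- (sys$rhs_fn(t, y + e, params, stim)[free] -
                   sys$rhs_fn(t, y - e, params, stim)[free]) /
        (2 * steps[free[jj]])
    }
    list(c(dy, as.vector(Jf %*% M)))
  }

  z <- c(x, as.vector(diag(nf)))
  for (i in seq_len(k)) {
    segs <- if (pac$amplitude > 0)
      list(c(0, pac$duration, pac$amplitude),
           c(pac$duration, pac$cycle_length, 0))
    else list(c(0, pac$cycle_length, 0))
    for (s in segs) {
      fn <- function(t, zz, p) aug_rhs(t, zz, s[3])
      out <- deSolve::ode(z, c(s[1], s[2]), fn, NULL, method = "lsoda",
                          rtol = control$rtol, atol = control$atol)
      z <- unname(out[nrow(out), -1])
    }
  }
  matrix(z[-seq_len(n)], nf, nf)
}

#' Characteristic multipliers
#'
#' Eigenvalues of the monodromy matrix, sorted by descending modulus. A
#' periodic response of the paced (non-autonomous) system is asymptotically
#' stable iff every multiplier lies strictly inside the unit circle; unlike
#' autonomous systems there is no trivial multiplier pinned at +1.
#'
#' @param M monodromy matrix.
#' @return complex vector of eigenvalues.
#' @export
characteristic_multipliers <- function(M) {
  ev <- eigen(M, only.values = TRUE)$values
  ev <- as.complex(ev)
  ev[order(-Mod(ev))]
}

#' Newton shooting for periodic responses
#'
#' Solves \eqn{P^k(x) - x = 0} by damped Newton iteration with the
#' monodromy-based Jacobian \eqn{DP^k - I}, converging to stable and
#' unstable fixed points alike — the route to saddle responses that forward
#' simulation can never reach. Steps are halved (up to \code{max_halvings})
#' whenever the residual fails to decrease.
#'
#' A nearly singular \eqn{DP^k - I} signals proximity to a bifurcation; it
#' is reported through \code{near_singular}/\code{min_sv} rather than raised
#' as an error, since it is a detection signal.
#'
#' @inheritParams poincare_map
#' @param x_guess starting state at stimulus onset.
#' @param tol convergence tolerance on the sup-norm residual
#'   \eqn{\|P^k(x)-x\|_\infty} in native mixed units.
#' @param max_iter Newton iteration cap.
#' @param max_halvings damping cap per iteration.
#' @param monodromy_method Jacobian route for the Newton matrix.
#' @return an object of class \code{fixed_point}: the refined state
#'   \code{x}, the period multiple \code{k}, parameter snapshot, multipliers,
#'   stability flag, residual, convergence flag, iteration count, and
#'   singularity diagnostics.
#' @export
newton_shoot <- function(sys, x_guess, k = 1, params = sys$params,
                         tol = 1e-9, max_iter = 30, max_halvings = 8,
                         control = integrator_control(),
                         monodromy_method = "fd") {
  x <- apply_clamp(sys, unname(x_guess), params)
  free <- free_indices(sys, params)
  resid_of <- function(xx) poincare_map(sys, xx, k, params, control) - xx
  r <- resid_of(x)
  res <- max(abs(r[free]))
  it <- 0L
  min_sv <- NA_real_
  while (res > tol && it < max_iter) {
    it <- it + 1L
    M <- monodromy(sys, x, k, params, method = monodromy_method,
                   control = control)
    A <- M - diag(length(free))
    sv <- svd(A, nu = 0, nv = 0)$d
    min_sv <- sv[length(sv)]
    dx <- tryCatch(solve(A, -r[free]), error = function(e) NULL)
    if (is.null(dx)) { # exactly singular: regularized least-squares step
      dx <- -qr.solve(rbind(A, 1e-8 * diag(length(free))),
                      c(r[free], numeric(length(free))))
    }
    lambda <- 1
    improved <- FALSE
    for (hh in 0:max_halvings) {
      xn <- x
      xn[free] <- x[free] + lambda * dx
      rn <- tryCatch(resid_of(xn), error = function(e) NULL)
      if (!is.null(rn) && all(is.finite(rn)) &&
          (max(abs(rn[free])) < res || res > 1e6)) {
        x <- xn; r <- rn; res <- max(abs(r[free])); improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  M <- monodromy(sys, x, k, params, method = monodromy_method,
                 control = control)
  mult <- characteristic_multipliers(M)
  structure(list(x = stats::setNames(x, sys$state_names), k = k,
                 params_at = params, multipliers = mult,
                 stable = all(Mod(mult) < 1), residual = res,
                 converged = res <= tol, iterations = it,
                 near_singular = is.finite(min_sv) && min_sv < 1e-8,
                 min_sv = min_sv, monodromy = M),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("<fixed_point k=%d %s residual=%.3g iter=%d>\n", x$k,
              if (x$converged) "converged" else "NOT converged",
              x$residual, x$iterations))
  cat("  x:", paste(sprintf("%s=%.6g", names(x$x), x$x), collapse = ", "),
      "\n")
  cat("  multipliers (|.|):",
      paste(sprintf("%.4f", Mod(x$multipliers)), collapse = ", "),
      if (x$stable) " [stable]" else " [unstable]", "\n")
  invisible(x)
}
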