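#' Analytically tractable testbed systems
#'
#' These factories generate small dynamical systems whose fixed points,
#' multipliers and bifurcations are known in closed form (or verifiable by
#' brute force), so every stage of the shooting / continuation / census
#' pipeline can be validated without a full ionic model. Map-type systems
#' bypass the integrator entirely — a map is its own Poincare map — which
#' isolates the continuation and classification logic from integration
#' error. Declared \code{known_features} are the oracles the test-suite
#' re-verifies through the pipeline itself.
#'
#' @name testbed
NULL

#' @describeIn testbed the logistic map \eqn{x \to r x (1 - x)}: fixed point
#'   \eqn{x^* = 1 - 1/r}, multiplier \eqn{2 - r}, period doubling at
#'   \eqn{r = 3}.
#' @param r map parameter.
#' @export
make_logistic_map <- function(r = 2.5) {
  dynsys(kind = "map", state_names = "x", params = list(r = r),
         map_fn = function(x, p) p$r * x * (1 - x),
         jac_fn = function(x, p) matrix(p$r * (1 - 2 * x), 1, 1),
         known_features = list(
           fixed_point = function(r) 1 - 1 / r,
           multiplier = function(r) 2 - r,
           pd_at = 3),
         name = "logistic_map")
}

#' @describeIn testbed the delayed logistic map
#'   \eqn{(x, y) \to (r x (1 - y), x)}: fixed point \eqn{(1-1/r, 1-1/r)},
#'   multiplier pair with modulus \eqn{\sqrt{r - 1}} (characteristic
#'   polynomial \eqn{\lambda^2 - \lambda + (r-1)} at the fixed point for
#'   \eqn{r > 5/4}), Neimark-Sacker bifurcation at \eqn{r = 2}.
#' @export
make_delayed_logistic_map <- function(r = 1.5) {
  dynsys(kind = "map", state_names = c("x", "y"), params = list(r = r),
         map_fn = function(x, p) c(p$r * x[1] * (1 - x[2]), x[1]),
         jac_fn = function(x, p)
           matrix(c(p$r * (1 - x[2]), 1, -p$r * x[1], 0), 2, 2),
         known_features = list(
           fixed_point = function(r) rep(1 - 1 / r, 2),
           modulus = function(r) sqrt(r - 1),
           ns_at = 2),
         name = "delayed_logistic_map")
}

#' @describeIn testbed the saddle-node normal form \eqn{x \to x + \mu + x^2}:
#'   fixed points \eqn{x^* = \pm\sqrt{-\mu}} for \eqn{\mu < 0} with
#'   multipliers \eqn{1 \pm 2\sqrt{-\mu}}, fold at \eqn{\mu = 0}, no fixed
#'   point for \eqn{\mu > 0}.
#' @param mu normal-form parameter.
#' @export
make_sn_normal_form <- function(mu = -0.25) {
  dynsys(kind = "map", state_names = "x", params = list(mu = mu),
         map_fn = function(x, p) x + p$mu + x^2,
         jac_fn = function(x, p) matrix(1 + 2 * x, 1, 1),
         known_features = list(
           fixed_points = function(mu)
             if (mu <= 0) c(-sqrt(-mu), sqrt(-mu)) else numeric(0),
           multipliers = function(mu)
             if (mu <= 0) c(1 - 2 * sqrt(-mu), 1 + 2 * sqrt(-mu)),
           sn_at = 0),
         name = "sn_normal_form")
}

#' @describeIn testbed a pulsed linear relaxation
#'   \eqn{x' = -x/\tau + } square pulse train: the stroboscopic map is
#'   affine, \eqn{P(x) = e^{-T/\tau} x + c}, with the single multiplier
#'   \eqn{e^{-T/\tau}} independent of the forcing, and the closed-form fixed
#'   point \eqn{x^* = c / (1 - e^{-T/\tau})}.
#' @param tau relaxation time constant (ms).
#' @param T pacing cycle length (ms).
#' @param amplitude,duration pulse height and width (ms).
#' @export
make_forced_linear <- function(tau = 1000, T = 2000, amplitude = 80,
                               duration = 1) {
  pac <- pacing_protocol(amplitude, duration, T)
  mult <- exp(-T / tau)
  # variation of constants over one cycle:
  # x(dur) = x0 e^{-dur/tau} + A tau (1 - e^{-dur/tau}); then free decay
  cval <- amplitude * tau * (1 - exp(-duration / tau)) *
    exp(-(T - duration) / tau)
  dynsys(kind = "forced_ode", state_names = "x",
         params = list(tau = tau),
         rhs_fn = function(t, y, p, stim) stim - y / p$tau,
         pacing = pac,
         known_features = list(
           multiplier = mult,
           affine_offset = cval,
           fixed_point = cval / (1 - mult),
           closed_map = function(x) mult * x + cval),
         name = "forced_linear")
}

#' Verify a testbed system's declared features by brute force
#'
#' Re-checks the closed-form \code{known_features} of a testbed factory
#' against direct iteration/integration (generation-time self-consistency:
#' a failure here is a fixture bug, not a user error).
#'
#' @param sys a testbed [dynsys()].
#' @param tol agreement tolerance.
#' @return \code{TRUE} invisibly; stops on discrepancy.
#' @export
verify_known_features <- function(sys, tol = 1e-6) {
  kf <- sys$known_features
  p <- sys$params
  if (!is.null(kf$fixed_point) && is.function(kf$fixed_point)) {
    xs <- kf$fixed_point(p[[1]])
    err <- max(abs(poincare_map(sys, xs) - xs))
    if (err > tol) stop("declared fixed point fails: err = ", err)
  }
  if (!is.null(kf$multiplier) && is.function(kf$multiplier)) {
    m <- characteristic_multipliers(monodromy(sys, kf$fixed_point(p[[1]])))
    if (abs(Re(m[1]) - kf$multiplier(p[[1]])) > tol)
      stop("declared multiplier fails")
  }
  if (identical(sys$name, "forced_linear")) {
    x0 <- 3.21
    err <- abs(poincare_map(sys, x0, control = integrator_control(1e-10, 1e-12)) -
                 kf$closed_map(x0))
    if (err > 1e-7) stop("closed-form stroboscopic map fails: err = ", err)
  }
  invisible(TRUE)
}
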