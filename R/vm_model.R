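#' Myocyte model parameters
#'
#' Parameter container for paced ventricular-myocyte-style systems. The two
#' delayed-rectifier conductances are expressed as percentages of their
#' control values, the conventional way of dialling repolarisation reserve:
#' the effective conductance is \code{control * pct/100}, so scaled currents
#' are exactly linear in the percentage at fixed state.
#'
#' For the mid-myocardial human ventricular cell formulation that motivates
#' this package the control values are gKs = 0.0257 and gKr = 0.00738 nS/pF
#' with external Ca/Na/K fixed at 2/140/5.4 mM and internal K fixed at
#' 140 mM; those constants are kept here so a full transcription of that
#' model can drop into the same contract. The bundled surrogate testbed
#' declares its own control conductances.
#'
#' @param pctGKr,pctGKs percentage of the control conductance, >= 0.
#' @param pacing a [pacing_protocol()].
#' @param nai_clamp optional fixed intracellular Na level (mM). When set, the
#'   Nai equation is frozen and the effective system dimension drops by one.
#' @param gKr_control,gKs_control control conductances (nS/pF).
#' @param Cao,Nao,Ko,Ki fixed external / internal concentrations (mM).
#' @param ... further model-specific constants, passed through verbatim.
#' @return named list of class \code{model_params}.
#' @export
model_params <- function(pctGKr = 100, pctGKs = 100,
                         pacing = pacing_protocol(), nai_clamp = NA,
                         gKr_control = 0.00738, gKs_control = 0.0257,
                         Cao = 2, Nao = 140, Ko = 5.4, Ki = 140, ...) {
  stopifnot(pctGKr >= 0, pctGKs >= 0, Cao > 0, Nao > 0, Ko > 0, Ki > 0)
  structure(c(list(pctGKr = pctGKr, pctGKs = pctGKs, pacing = pacing,
                   nai_clamp = nai_clamp, gKr_control = gKr_control,
                   gKs_control = gKs_control, Cao = Cao, Nao = Nao,
                   Ko = Ko, Ki = Ki), list(...)),
            class = c("model_params", "list"))
}

#' State-vector derivative of a paced model
#'
#' Evaluates the right-hand side \eqn{dy/dt} of a forced ODE system at a
#' state and time within the pacing cycle. The voltage component follows the
#' membrane equation \eqn{dV_m/dt = I_{stim} - I_{net}} with the net ionic
#' current the sum of all membrane currents (outward positive). With a sodium
#' clamp in force the Nai derivative is exactly zero.
#'
#' @param sys a forced-ODE [dynsys()].
#' @param state named or unnamed state vector (length \code{sys$dim}).
#' @param t time since stimulus onset (ms); determines whether the stimulus
#'   pulse is active.
#' @param params parameter list override.
#' @return named derivative vector.
#' @export
derivatives <- function(sys, state, t = 0, params = sys$params) {
  stopifnot(sys$kind == "forced_ode", t >= 0)
  state <- unname(state)
  if (!all(is.finite(state)))
    stop("non-finite state component: ",
         paste(sys$state_names[!is.finite(state)], collapse = ", "))
  pac <- sys$pacing
  tc <- t %% pac$cycle_length
  stim <- if (tc < pac$duration) pac$amplitude else 0
  d <- sys$rhs_fn(tc, state, params, stim)
  if (!is.null(params$nai_clamp) && !is.na(params$nai_clamp)) {
    nai <- match("Nai", sys$state_names)
    if (!is.na(nai)) d[nai] <- 0
  }
  stats::setNames(d, sys$state_names)
}

#' Membrane currents at a state
#'
#' Returns every named membrane current of a myocyte-style system at the
#' given state, together with the net ionic current \code{Inet} (their sum,
#' outward positive) and the stimulus current at time \code{t}. Currents not
#' present in a particular formulation are reported as zero so the full
#' inventory is always populated.
#'
#' @inheritParams derivatives
#' @return named numeric vector of current densities (pA/pF) including
#'   \code{Inet} and \code{Istim}.
#' @export
compute_currents <- function(sys, state, t = 0, params = sys$params) {
  if (is.null(sys$currents_fn))
    stop("system '", sys$name, "' does not expose membrane currents")
  state <- unname(state)
  pac <- sys$pacing
  tc <- t %% pac$cycle_length
  stim <- if (tc < pac$duration) pac$amplitude else 0
  cur <- sys$currents_fn(state, tc, params)
  inventory <- c("ICaL", "IKr", "IKs", "Ito", "INa", "IK1", "INab", "ICab",
                 "INaK", "INCX", "IpCa", "Iw")
  full <- stats::setNames(numeric(length(inventory)), inventory)
  full[names(cur)] <- unlist(cur)
  c(full, Inet = sum(full), Istim = stim)
}

## ---- bundled paced surrogate myocyte -------------------------------------

## frozen surrogate constants (see the methods vignette for their rationale)
surrogate_constants <- function() {
  list(gin = 0.30, Ein = 55, gKr_control = 0.04, gKs_control = 0.04,
       gK1 = 0.30, EK = -85, kp = 0.28, rin = 5e-4, rout = 5e-5,
       tauh_plateau = 300, tauh_rest = 20, gw = 0.012)
}

sigf <- function(x) 1 / (1 + exp(-x))

## R transcription of the surrogate right-hand side. This mirrors the
## compiled C version independently (it is the reference implementation used
## by the variational route and by the double-implementation consistency
## tests; the C version is the fast path used for protocols).
surrogate_rhs_r <- function(t, y, params, stim) {
  cs <- params$constants
  v <- y[1]; h <- y[2]; na <- y[3]
  gKr <- cs$gKr_control * params$pctGKr / 100
  gKs <- cs$gKs_control * params$pctGKs / 100
  minf <- sigf((v + 35) / 4)
  hinf <- sigf(-(v + 60) / 6)
  tauh <- cs$tauh_rest + (cs$tauh_plateau - cs$tauh_rest) * sigf((v + 50) / 8)
  wact <- sigf((v + 45) / 3) * sigf(-(v + 22) / 3)
  rho <- sigf(-(v + 75) / 3)
  Iin <- cs$gin * minf * h * (v - cs$Ein)
  Iw  <- cs$gw * wact * (v - cs$Ein)
  IKr <- gKr * sigf((v + 45) / 5) * (v - cs$EK)
  IKs <- gKs * sigf((v + 10) / 8) * (v - cs$EK)
  IK1 <- cs$gK1 * sigf(-(v + 75) / 5) * (v - cs$EK)
  Ip  <- cs$kp * na * sigf((v + 70) / 10)
  dna <- if (!is.null(params$nai_clamp) && !is.na(params$nai_clamp)) 0 else
    cs$rin * rho - cs$rout * na
  c(stim - (Iin + Iw + IKr + IKs + IK1 + Ip),
    (hinf - h) / tauh,
    dna)
}

surrogate_currents <- function(state, t, params) {
  cs <- params$constants
  v <- state[1]; h <- state[2]; na <- state[3]
  gKr <- cs$gKr_control * params$pctGKr / 100
  gKs <- cs$gKs_control * params$pctGKs / 100
  list(ICaL = cs$gin * sigf((v + 35) / 4) * h * (v - cs$Ein),
       Iw   = cs$gw * sigf((v + 45) / 3) * sigf(-(v + 22) / 3) * (v - cs$Ein),
       IKr  = gKr * sigf((v + 45) / 5) * (v - cs$EK),
       IKs  = gKs * sigf((v + 10) / 8) * (v - cs$EK),
       IK1  = cs$gK1 * sigf(-(v + 75) / 5) * (v - cs$EK),
       INaK = cs$kp * na * sigf((v + 70) / 10))
}

## parameter vector for the compiled rhs; order matches src/surrogate.c
surrogate_parms <- function(params, stim) {
  cs <- params$constants
  clamped <- !is.null(params$nai_clamp) && !is.na(params$nai_clamp)
  c(gin = cs$gin, Ein = cs$Ein,
    gKr = cs$gKr_control * params$pctGKr / 100,
    gKs = cs$gKs_control * params$pctGKs / 100,
    gK1 = cs$gK1, EK = cs$EK, kp = cs$kp, rin = cs$rin, rout = cs$rout,
    tauh_pl = cs$tauh_plateau, tauh_rs = cs$tauh_rest, gw = cs$gw,
    stim = stim, clampna = as.numeric(clamped),
    naclamp = if (clamped) params$nai_clamp else 0, unused1 = 0)
}

#' Paced surrogate myocyte model
#'
#' A three-variable periodically pulsed excitable system (membrane potential
#' \code{Vm}, inactivation gate \code{h}, slow sodium-like variable
#' \code{Nai}) built as a desk-scale stand-in for a full paced ventricular
#' myocyte model. Its fast subsystem fires an action potential on each
#' stimulus; a window inward current can capture repolarisation into a
#' sustained depolarised plateau (a repolarisation-failure response), while a
#' sodium-activated pump current — fed by diastolic Na accumulation —
#' protects normal repolarisation. Over an intermediate range of the
#' rectifier-conductance percentage \code{pctGKr} a short-AP attractor and a
#' long (repolarisation-failure) attractor coexist, bounded by saddle-node
#' folds: the minimal bistability-plus-hysteresis structure the analysis
#' machinery is designed to resolve. All constants are frozen in code, so
#' surrogate-based results are exactly reproducible without seeds.
#'
#' With \code{bistable = FALSE} the window current is removed, yielding a
#' monostable control variant with the same dimension and interface.
#'
#' @param bistable logical; keep the window current responsible for the
#'   coexisting repolarisation-failure attractor.
#' @param params a [model_params()] list; percentages, pacing and the sodium
#'   clamp are honoured, conductance controls are fixed by the surrogate.
#' @param use_compiled integrate with the compiled right-hand side (fast
#'   path); the R transcription is always available as \code{sys$rhs_fn}.
#' @return a [dynsys()] of kind \code{"forced_ode"} with states
#'   \code{Vm, h, Nai}.
#' @export
make_paced_surrogate_ap <- function(bistable = TRUE, params = model_params(),
                                    use_compiled = TRUE) {
  cs <- surrogate_constants()
  if (!bistable) cs$gw <- 0
  p <- params
  p$gKr_control <- cs$gKr_control
  p$gKs_control <- cs$gKs_control
  p$constants <- cs
  dynsys(kind = "forced_ode", state_names = c("Vm", "h", "Nai"), params = p,
         rhs_fn = surrogate_rhs_r,
         compiled = if (use_compiled)
           list(func = "surr_derivs", initfunc = "surr_init",
                dllname = "eadmap", nout = 6, parms_fn = surrogate_parms),
         pacing = p$pacing, currents_fn = surrogate_currents,
         state_scale = c(100, 1, 10),
         known_features = list(
           bistable = bistable,
           rest_state = c(-86, 1, 7),
           plateau_state = c(-35, 0.05, 0.5),
           bistable_window_approx = if (bistable) c(25, 75)),
         name = if (bistable) "surrogate_ap" else "surrogate_ap_monostable")
}
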