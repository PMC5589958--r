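# Shared fixtures: all built in code, no stored data.

surr <- make_paced_surrogate_ap()
surr_mono <- make_paced_surrogate_ap(bistable = FALSE)

params_at_pct <- function(sys, pct, ...) {
  p <- sys$params
  p$pctGKr <- pct
  extra <- list(...)
  p[names(extra)] <- extra
  p
}

## settle the surrogate onto a named attractor at a given pctGKr
surr_attractor <- function(pct, which = c("short", "lavo"), sys = surr,
                           max_beats = 1500) {
  which <- match.arg(which)
  start <- if (which == "short") c(-86, 1, 9) else c(-35, 0.05, 0.2)
  run_to_steady_state(sys, start, params_at_pct(sys, pct),
                      max_beats = max_beats)
}

## synthetic trapezoidal AP trace: instantaneous upstroke to `peak`,
## flat plateau, linear ramp back to baseline, then rest
trapezoid_trace <- function(baseline = -85, peak = 40, plateau = 300,
                            ramp = 100, T = 2000, dt = 0.5) {
  t <- seq(0, T, by = dt)
  v <- ifelse(t <= 0, baseline,
       ifelse(t <= plateau, peak,
       ifelse(t <= plateau + ramp,
              peak - (peak - baseline) * (t - plateau) / ramp, baseline)))
  v[1] <- baseline
  df <- data.frame(t = t, Vm = v)
  attr(df, "cycle_length") <- T
  df
}

## synthetic AP whose plateau carries `n_bumps` sinusoidal re-depolarisations:
## a distinct upstroke spike holds the global maximum, so every sine trough
## that follows is a countable episode
bumpy_trace <- function(n_bumps = 2, amp = 5, baseline = -85, peak = 40,
                        spike = 20, plateau = 420, T = 2000, dt = 0.5) {
  t <- seq(0, T, by = dt)
  v <- rep(baseline, length(t))
  v[t > 0 & t <= spike] <- peak
  pl <- t > spike & t <= plateau
  phase <- (t[pl] - spike) / (plateau - spike)
  v[pl] <- 15 + if (n_bumps > 0)
    amp * sin(2 * pi * n_bumps * phase - pi / 2) else 0
  dn <- t > plateau & t <= plateau + 80
  vend <- v[max(which(pl))]
  v[dn] <- vend + (baseline - vend) * (t[dn] - plateau) / 80
  v[1] <- baseline
  df <- data.frame(t = t, Vm = v)
  attr(df, "cycle_length") <- T
  df
}
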