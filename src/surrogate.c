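/* Paced excitable surrogate myocyte: Vm (mV), h (gate), Nai (mM).
 *
 * Currents (outward positive, pA/pF), dVm/dt = Istim - Inet:
 *   Iin   fast inward (ICaL-like): gin * minf(V) * h * (V - Ein)
 *   Iw    ungated window inward:   gw * wact(V) * (V - Ein)
 *   IKr   pct-scaled delayed rectifier (repolarisation-reserve dial)
 *   IKs   second rectifier, pct-scaled independently
 *   IK1   inward rectifier, rest only
 *   Ip    Na-pump-like, kp * Nai * pump voltage gate
 * dNai/dt = rin * rho(V) - rout * Nai (diastolic influx, linear efflux),
 * frozen to 0 when the clamp flag is set.
 *
 * Parameter vector order must match surrogate_parms() on the R side.
 */
#include <R.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double parms[16];
#define gin     parms[0]
#define Ein     parms[1]
#define gKr     parms[2]   /* effective, already pct-scaled */
#define gKs     parms[3]   /* effective, already pct-scaled */
#define gK1     parms[4]
#define EK      parms[5]
#define kp      parms[6]
#define rin     parms[7]
#define rout    parms[8]
#define tauh_pl parms[9]
#define tauh_rs parms[10]
#define gw      parms[11]
#define stim    parms[12]
#define clampna parms[13]
#define naclamp parms[14]
#define unused1 parms[15]

static double sig(double x) { return 1.0 / (1.0 + exp(-x)); }

void surr_init(void (*odeparms)(int *, double *)) {
  int N = 16;
  odeparms(&N, parms);
}

void surr_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip) {
  double v = y[0], h = y[1], na = y[2];
  double minf = sig((v + 35.0) / 4.0);
  double hinf = sig(-(v + 60.0) / 6.0);
  double tauh = tauh_rs + (tauh_pl - tauh_rs) * sig((v + 50.0) / 8.0);
  double wact = sig((v + 45.0) / 3.0) * sig(-(v + 22.0) / 3.0);
  double rho  = sig(-(v + 75.0) / 3.0);

  double Iin = gin * minf * h * (v - Ein);
  double Iw  = gw * wact * (v - Ein);
  double IKr = gKr * sig((v + 45.0) / 5.0) * (v - EK);
  double IKs = gKs * sig((v + 10.0) / 8.0) * (v - EK);
  double IK1 = gK1 * sig(-(v + 75.0) / 5.0) * (v - EK);
  double Ip  = kp * na * sig((v + 70.0) / 10.0);

  ydot[0] = stim - (Iin + Iw + IKr + IKs + IK1 + Ip);
  ydot[1] = (hinf - h) / tauh;
  ydot[2] = (clampna > 0.5) ? 0.0 : (rin * rho - rout * na);
  if (ip[0] >= 6) {
    yout[0] = Iin; yout[1] = Iw;  yout[2] = IKr;
    yout[3] = IKs; yout[4] = IK1; yout[5] = Ip;
  }
}

static const R_CMethodDef cMethods[] = {
  {"surr_init",   (DL_FUNC) &surr_init,   1},
  {"surr_derivs", (DL_FUNC) &surr_derivs, 6},
  {NULL, NULL, 0}
};

void R_init_eadmap(DllInfo *dll) {
  R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
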