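/* Compiled right-hand side of the competition ODE system for use by
 * deSolve's adaptive integrators (the independent reference solver).
 * Parameters: K_N, mu_max, k, l_T, f_A, f_B (investments held constant
 * per output interval by the R caller). */

#include <R.h>

static double parms[6];

void toxwar_initmod(void (*odeparms)(int *, double *)) {
  int n = 6;
  odeparms(&n, parms);
}

void toxwar_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip) {
  double K = parms[0], mu = parms[1], k = parms[2], lT = parms[3];
  double fA = parms[4], fB = parms[5];
  double CA = y[0], CB = y[1], TA = y[2], TB = y[3], N = y[4];
  double den = N + K;
  double M = (den > 0) ? N / den : 0.0;
  ydot[0] = (1.0 - fA) * mu * M * CA - k * TB * CA;
  ydot[1] = (1.0 - fB) * mu * M * CB - k * TA * CB;
  ydot[2] = fA * M * CA - lT * TA;
  ydot[3] = fB * M * CB - lT * TB;
  ydot[4] = -M * (CA + CB);
}
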