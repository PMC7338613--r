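/* Compiled right-hand side of the five-state tumor-immune-drug ODE system,
 * in the form deSolve expects for its "compiled code" interface, plus a
 * fixed-step classical RK4 integrator used as an independent numerical
 * oracle for the adaptive solver.
 *
 * State order:     y = (C, T, I, X, Y)
 * Parameter order: p = (k1, k2, ka, kb, kc, kd, ke, kf, kg, kh,
 *                       ki, kj, kk, kl, km, overflow_cap)
 * The 16th slot is the tumor-volume overflow cap used by the root function,
 * not a model parameter.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define N_PAR 16

static double parms[N_PAR];

/* deSolve parameter initialiser */
void mi_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PAR;
    odeparms(&n, parms);
}

/* Between boluses the administration rate u(t) is identically zero, so it
 * does not appear here; dose events add to C outside the integrator. */
void mi_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double k1 = parms[0], k2 = parms[1], ka = parms[2],
                 kb = parms[3], kc = parms[4], kd = parms[5],
                 ke = parms[6], kf = parms[7], kg = parms[8],
                 kh = parms[9], ki = parms[10], kj = parms[11],
                 kk = parms[12], kl = parms[13], km = parms[14];
    const double C = y[0], T = y[1], I = y[2], X = y[3], Y = y[4];

    ydot[0] = -k1 * C / (k2 + C);
    ydot[1] = ka * T - kb * C * T / (kc + T) - kd * T * I;
    ydot[2] = X - ke * T * I - kf * C * I - kg * Y * I - kh * I;
    ydot[3] = C / (1.0 + C / ki) - kj * X - kk * X * Y;
    ydot[4] = I / (1.0 + C / kl) - km * Y * C;
}

/* Terminal root: tumor volume reaching the overflow cap. */
void mi_root(int *neq, double *t, double *y, int *ng, double *gout,
             double *out, int *ip)
{
    gout[0] = y[1] - parms[15];
}

/* ------------------------------------------------------------------ */
/* Fixed-step RK4 oracle.  The derivative is transcribed here a second
 * time, on purpose, so that the oracle shares no code with the deSolve
 * path it is used to cross-check. */

static void rk4_deriv(const double *p, const double *y, double *dy)
{
    dy[0] = -p[0] * y[0] / (p[1] + y[0]);
    dy[1] = p[2] * y[1]
          - p[3] * y[0] * y[1] / (p[4] + y[1])
          - p[5] * y[1] * y[2];
    dy[2] = y[3]
          - p[6] * y[1] * y[2]
          - p[7] * y[0] * y[2]
          - p[8] * y[4] * y[2]
          - p[9] * y[2];
    dy[3] = y[0] / (1.0 + y[0] / p[10])
          - p[11] * y[3]
          - p[12] * y[3] * y[4];
    dy[4] = y[2] / (1.0 + y[0] / p[13])
          - p[14] * y[4] * y[0];
}

/* Integrate over nsteps steps of size h starting from y, recording the
 * state every `thin` steps (plus the initial and final states).  `out`
 * must hold 5 * nrec doubles where nrec = floor(nsteps / thin) + 1 +
 * (nsteps % thin != 0).  Returns the states in row-major blocks of 5. */
void mi_rk4(double *p, double *y, double *h, int *nsteps, int *thin,
            double *out)
{
    double k1v[5], k2v[5], k3v[5], k4v[5], tmp[5], st[5];
    int i, s, rec = 0;
    const double hh = *h;

    for (i = 0; i < 5; i++) st[i] = y[i];
    for (i = 0; i < 5; i++) out[rec * 5 + i] = st[i];
    rec++;

    for (s = 1; s <= *nsteps; s++) {
        rk4_deriv(p, st, k1v);
        for (i = 0; i < 5; i++) tmp[i] = st[i] + 0.5 * hh * k1v[i];
        rk4_deriv(p, tmp, k2v);
        for (i = 0; i < 5; i++) tmp[i] = st[i] + 0.5 * hh * k2v[i];
        rk4_deriv(p, tmp, k3v);
        for (i = 0; i < 5; i++) tmp[i] = st[i] + hh * k3v[i];
        rk4_deriv(p, tmp, k4v);
        for (i = 0; i < 5; i++)
            st[i] += hh / 6.0 *
                     (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
        if (s % *thin == 0 || s == *nsteps) {
            for (i = 0; i < 5; i++) out[rec * 5 + i] = st[i];
            rec++;
        }
    }
    for (i = 0; i < 5; i++) y[i] = st[i];
}

static const R_CMethodDef cMethods[] = {
    {"mi_rk4", (DL_FUNC) &mi_rk4, 6},
    {NULL, NULL, 0}
};

void R_init_metroimmune(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
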