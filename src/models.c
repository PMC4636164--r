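/* Compiled right-hand sides for the simple (3-variable) and detailed
 * (10-variable) CRISPR coevolution models, in the deSolve compiled-model
 * interface.  These mirror the reference R implementations simple_rhs()
 * and detailed_rhs() exactly; a test asserts the agreement.
 *
 * State is clamped at zero for rate evaluation so that small negative
 * solver excursions cannot feed back as spurious sources; the zero fixed
 * points are preserved exactly.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* ---- simple model -------------------------------------------------- */

static double sparms[8];
/* order: A_P, G_Pphi, G_Qphi, G_Qp, G_Qv, G_V, alpha_v, delta */

void crisprcoevo_init_simple(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, sparms);
}

static double pos(double x) { return x > 0 ? x : 0; }

void crisprcoevo_derivs_simple(int *neq, double *t, double *y, double *ydot,
                               double *yout, int *ip)
{
    double A_P = sparms[0], G_Pphi = sparms[1], G_Qphi = sparms[2];
    double G_Qp = sparms[3], G_Qv = sparms[4], G_V = sparms[5];
    double alpha_v = sparms[6], delta = sparms[7];
    double P = pos(y[0]), Q = pos(y[1]), V = pos(y[2]);

    ydot[0] = A_P * P * (1 - P - Q) - delta * G_Pphi * P + G_Qp * Q - P * V;
    ydot[1] = P * V - (G_Qphi + G_Qp + G_Qv) * Q;
    ydot[2] = alpha_v * G_Qv * Q - G_V * V - P * V;
}

/* ---- detailed model ------------------------------------------------ */

static double dparms[15];
/* order: A_P, A_V, G_Qp, G_Qphi, G_Qv, G_V, G_C, M_V, beta, delta,
 *        mu_v, alpha_v, variant (0 baseline, 1 no_abi, 2 del_const,
 *        3 del_inverse), eps_pop, pop_gate */

void crisprcoevo_init_detailed(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, dparms);
}

void crisprcoevo_derivs_detailed(int *neq, double *t, double *y, double *ydot,
                                 double *yout, int *ip)
{
    double A_P = dparms[0], A_V = dparms[1], G_Qp = dparms[2];
    double G_Qphi = dparms[3], G_Qv = dparms[4], G_V = dparms[5];
    double G_C = dparms[6], M_V = dparms[7], beta = dparms[8];
    double delta = dparms[9], mu_v = dparms[10], alpha_v = dparms[11];
    int variant = (int) dparms[12];
    double eps_pop = dparms[13], pop_gate = dparms[14];

    double P = pos(y[0]), Q = pos(y[1]), V = pos(y[2]);
    double X_A = pos(y[3]);
    double Y_QA = pos(y[4]), Y_QI = pos(y[5]), Y_QS = pos(y[6]);
    double Y_PA = pos(y[7]), Y_PI = pos(y[8]), Y_PS = pos(y[9]);

    /* per-capita deletion rates by variant */
    double del_free, del_inf;
    switch (variant) {
    case 2:  del_free = G_C;         del_inf = G_C; break; /* constitutive */
    case 3:  del_free = G_C;         del_inf = 0;   break; /* inverse      */
    default: del_free = delta * G_C; del_inf = G_C; break;
    }
    /* infected-cell autoimmunity loss removed under no_abi */
    double abi = (variant == 1) ? 0 : G_Qphi * Y_QS;

    /* Singular per-capita ratios: denominators floored at eps_pop and
     * the whole ratio gated smoothly to zero as the carrier population
     * falls below pop_gate, via the C1 ramp x^2/(x^2+g^2) (a hard
     * cutoff makes the integrator chatter whenever a dying population
     * hovers at the threshold).  The non-singular quota reactions stay
     * active, so after infected cells go extinct their formal
     * per-capita quotas relax to the acquisition/deletion balance --
     * the zero-density limit of the dynamics. */
    double gQ = Q * Q / (Q * Q + pop_gate * pop_gate);
    double gP = P * P / (P * P + pop_gate * pop_gate);
    double fluxQ = gQ * A_V * P * V / (Q > eps_pop ? Q : eps_pop);
    double mixP = gP * G_Qp * Y_QA * Q / (P > eps_pop ? P : eps_pop);

    ydot[0] = A_P * P * (1 - P - Q) + G_Qp * Y_QA * Q - A_V * P * V
              - delta * G_Qphi * Y_PS * P;
    ydot[1] = A_V * P * V - (G_Qp * Y_QA + abi + G_Qv) * Q;
    ydot[2] = G_Qv * Q - G_V * V - (A_V / alpha_v) * P * V;
    ydot[3] = fluxQ * ((1 - mu_v) - X_A);
    ydot[4] = X_A + fluxQ * (Y_PA - Y_QA) - del_inf * Y_QA;
    ydot[5] = fluxQ * (Y_PI - Y_QI) - del_inf * Y_QI;
    ydot[6] = beta + fluxQ * (Y_PS - Y_QS) - del_inf * Y_QS;
    ydot[7] = M_V * (Y_PI - Y_PA) + mixP * (Y_QA - Y_PA) - del_free * Y_PA;
    ydot[8] = M_V * (Y_PA - Y_PI) + mixP * (Y_QI - Y_PI) - del_free * Y_PI;
    ydot[9] = delta * beta + mixP * (Y_QS - Y_PS) - del_free * Y_PS;
}

/* ---- registration -------------------------------------------------- */

void R_init_crisprcoevo(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    /* deSolve locates the derivative functions by symbol name */
    R_useDynamicSymbols(dll, TRUE);
}
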