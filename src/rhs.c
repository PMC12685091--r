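/* Compiled right-hand side of the cancer-effector-macrophage model for
 * deSolve. State y = (C, E, M, Mstar); all kill terms carry C, so C >= 0 is
 * preserved; negative excursions from the integrator are guarded to 0.
 *
 * Parameter vector (see R/model.R):
 *  0 c1   1 cmax  2 phi_e  3 gamma_e  4 eta_e  5 delta_e
 *  6 phi_m  7 gamma_m  8 eta_m  9 delta_m
 * 10 phi_mstar 11 gamma_mstar 12 eta_mstar 13 delta_mstar
 * 14 F (active post-RT growth factor)
 * 15 use_E 16 use_M 17 use_Mstar 18 scale_growth_only   (0/1 flags)
 */
#include <R.h>
#include <R_ext/Rdynload.h>

#define N_PARMS 19
static double parms[N_PARMS];

void icdrt_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void icdrt_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double C = y[0] > 0 ? y[0] : 0;
    double E = y[1] > 0 ? y[1] : 0;
    double M = y[2] > 0 ? y[2] : 0;
    double Ms = y[3] > 0 ? y[3] : 0;

    double c1 = parms[0], cmax = parms[1];
    double F = parms[14];
    int use_E = parms[15] != 0, use_M = parms[16] != 0,
        use_Ms = parms[17] != 0, growth_only = parms[18] != 0;

    if (!use_E) E = 0;
    if (!use_M) M = 0;
    if (!use_Ms) Ms = 0;

    double growth = c1 * C * (1 - C / cmax);
    double kill = parms[2] * C * E + parms[6] * C * M + parms[10] * C * Ms;

    ydot[0] = growth_only ? F * growth - kill : F * (growth - kill);
    ydot[1] = use_E ? parms[3] - parms[4] * C * E - parms[5] * E : 0;
    ydot[2] = use_M ? parms[7] - parms[8] * C * M - parms[9] * M : 0;
    ydot[3] = use_Ms ? parms[11] - parms[12] * C * Ms - parms[13] * Ms : 0;
}

static const R_CMethodDef cMethods[] = {
    {"icdrt_initmod", (DL_FUNC) &icdrt_initmod, 1},
    {"icdrt_derivs",  (DL_FUNC) &icdrt_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_icdrt(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
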