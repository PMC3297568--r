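/* Compartmental ODE right-hand side for the CLP sepsis model.
 *
 * 19 states: B, N_bm, N_r, N_p, N_a, N_t, N_s, N_l, PIv, AIv, D and eight
 * observable states (TNF, IL-1b, IL-6, IL-10, L-selectin, HMGB1, CRT, ALT).
 *
 * Parameter block (length 68), passed through deSolve's parms:
 *   p[0..56]  registry parameters k1..k57 (see parameter_registry())
 *   p[57]     g        CLP severity grade in [0,1]
 *   p[58]     ha_on    1 if a hemoadsorption window is configured
 *   p[59..64] r_na, K_na, r_pi, K_pi, r_ai, K_ai   HA elimination terms
 *   p[65..66] t_on, t_off                          HA treatment window (hr)
 *   p[67]     n_ha     HA Hill coefficient
 *
 * This file must stay in exact agreement with the R reference implementation
 * in R/model.R (sepsis_derivatives); a test compares the two on random states.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 68

static double p[N_PARMS];

void sepsis_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

/* plain Hill, n = 3; x clamped at 0 for solver undershoot */
static double hill3(double x, double K)
{
    double xn, Kn;
    if (x < 0.0) x = 0.0;
    xn = x * x * x;
    Kn = K * K * K;
    return xn / (xn + Kn);
}

/* normalized HillCube for unit-interval regulators: equals 1 at x = 1 */
static double hilln3(double x, double K)
{
    double xn, Kn;
    if (x < 0.0) x = 0.0;
    if (x > 1.0) x = 1.0;
    xn = x * x * x;
    Kn = K * K * K;
    return xn * (1.0 + Kn) / (xn + Kn);
}

static double hill_pow(double x, double K, double n)
{
    double xn, Kn;
    if (x < 0.0) x = 0.0;
    xn = pow(x, n);
    Kn = pow(K, n);
    return xn / (xn + Kn);
}

void sepsis_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double B   = y[0] > 0 ? y[0] : 0;
    double Nbm = y[1] > 0 ? y[1] : 0;
    double Nr  = y[2] > 0 ? y[2] : 0;
    double Np  = y[3] > 0 ? y[3] : 0;
    double Na  = y[4] > 0 ? y[4] : 0;
    double Nt  = y[5] > 0 ? y[5] : 0;
    double Ns  = y[6] > 0 ? y[6] : 0;
    double Nl  = y[7] > 0 ? y[7] : 0;
    double PIv  = y[8];
    double AIv  = y[9];
    double D   = y[10];

    double g       = p[57];
    double r_grow  = p[50], r_mac = p[51];
    double B_inf   = p[52], B_mac = p[53], Nt_max = p[54];
    double v_bt    = p[55], v_bl = p[56];

    double Bn = B / B_inf;              /* normalized bacterial load */
    double fB = B < B_inf ? B : B_inf;  /* saturating killing capacity */

    /* neutrophil fluxes */
    double rel    = (p[7] + p[9] * hill3(Bn, p[8])) * Nbm;
    double prime  = hill3(B, p[11]) * Nr / p[12];
    double act_r  = hilln3(PIv, p[13]) * Nr / p[14];
    double act_p  = hilln3(PIv, p[16]) * Np / p[17];
    double seq    = hilln3(PIv, p[20]) * Na / p[21];
    double mig_t  = hill3(B, p[24]) * (1.0 - hilln3(PIv, p[25])) * Np / p[18];
    double mig_l  = hilln3(PIv, p[27]) * Ns / p[23];
    double flux   = act_r + act_p + seq;   /* neutrophil activation flux */

    /* hemoadsorption elimination (zero outside the treatment window) */
    double ha_na = 0.0, ha_pi = 0.0, ha_ai = 0.0;
    if (p[58] > 0.5 && *t >= p[65] && *t < p[66]) {
        double n_ha = p[67];
        ha_na = p[59] * hill_pow(Na, p[60], n_ha);
        ha_pi = p[61] * hill_pow(PIv > 0 ? PIv : 0, p[62], n_ha);
        ha_ai = p[63] * hill_pow(AIv > 0 ? AIv : 0, p[64], n_ha);
    }

    /* bacteria: CLP source + logistic growth, neutrophil killing, resident
       macrophage removal saturating at B_mac */
    ydot[0] = (p[32] * g + r_grow * B) * (1.0 - Bn)
              - p[33] * fB * Nt
              - r_mac * (B < B_mac ? B : B_mac);

    /* bone marrow reserve: basal release balanced by granulopoiesis, the
       infection-driven surge depletes the reserve */
    ydot[1] = -p[9] * hill3(Bn, p[8]) * Nbm;

    ydot[2] = rel - Nr / p[10] - prime - act_r;                  /* N_r */
    ydot[3] = prime - Np / p[15] - act_p - mig_t;                /* N_p */
    ydot[4] = act_r + act_p - Na / p[19] - seq - ha_na;          /* N_a */
    ydot[5] = v_bt * mig_t * (1.0 - Nt / Nt_max) - Nt / p[26];   /* N_t */
    ydot[6] = seq - Ns / p[22] - mig_l;                          /* N_s */
    ydot[7] = v_bl * mig_l - Nl / p[28];                         /* N_l */

    /* PIv: OR-gated activation by bacteria or damage, partially inhibited by
       AIv (inhibition moderated at high PIv) */
    {
        double a_b = hill3(Bn, p[0]);
        double a_d = hilln3(D, p[1]);
        double act = 1.0 - (1.0 - a_b) * (1.0 - a_d);
        double inh = 1.0 - hilln3(AIv, p[2]) * (1.0 - hilln3(PIv, p[5]));
        ydot[8] = (act * inh - PIv) / p[3] - ha_pi;
    }
    ydot[9] = (hilln3(PIv, p[4]) - AIv) / p[6] - ha_ai;            /* AIv */
    {
        double d_ns = hill3(Ns / Nt_max, p[29]);
        double d_nl = hill3(Nl / Nt_max, p[30]);
        double act  = 1.0 - (1.0 - d_ns) * (1.0 - d_nl);
        ydot[10] = (act - D) / p[31];                            /* D  */
    }

    /* observation mappings: sigmoidal reflections of PIv, AIv, D and the
       activation flux (L-selectin), each with first-order relaxation */
    ydot[11] = (hilln3(PIv, p[34]) - y[11]) / p[35];              /* TNF   */
    ydot[12] = (hilln3(PIv, p[36]) - y[12]) / p[37];              /* IL-1b */
    ydot[13] = (hilln3(PIv, p[38]) - y[13]) / p[39];              /* IL-6  */
    ydot[14] = (hilln3(AIv, p[40]) - y[14]) / p[41];              /* IL-10 */
    ydot[15] = (hill3(flux / Nt_max, p[42]) - y[15]) / p[43];    /* Lsel  */
    ydot[16] = (hilln3(D, p[44]) - y[16]) / p[45];               /* HMGB1 */
    ydot[17] = (hilln3(D, p[46]) - y[17]) / p[47];               /* CRT   */
    ydot[18] = (hilln3(D, p[48]) - y[18]) / p[49];               /* ALT   */
}

static const R_CMethodDef cMethods[] = {
    {"sepsis_initmod", (DL_FUNC) &sepsis_initmod, 1},
    {"sepsis_derivs",  (DL_FUNC) &sepsis_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_sepsisflow(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
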