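/* Right-hand side of the hydrolysis / SSCF mass-balance ODE system,
 * in the compiled-model form expected by deSolve.
 *
 * State vector y (between feed events; total broth mass is constant):
 *   y[0] S    residual water-insoluble solids, g
 *   y[1] C    residual cellulose, g
 *   y[2] Xn   residual xylan, g
 *   y[3] Ead  adsorbed enzyme, FPU per g residual WIS
 *   y[4] G    glucose, g per kg broth
 *   y[5] Xl   xylose, g per kg broth
 *   y[6] EtOH ethanol, g per kg broth
 *   y[7] X    viable cells, g per kg broth
 */
#include <R.h>
#include <math.h>

static double parms[14];
#define k_ad    parms[0]
#define k_hyd   parms[1]
#define K_G     parms[2]
#define gamma_x parms[3]
#define K_iEtOH parms[4]
#define q_G     parms[5]
#define K_sat   parms[6]
#define Y_EtOH  parms[7]
#define alpha_d parms[8]
#define beta_d  parms[9]
#define E_load  parms[10]
#define S_zero  parms[11]
#define w_tot   parms[12]
#define sscf_on parms[13]

/* smooth clamp width for xylan exhaustion, g per kg */
#define XN_EPS 1e-6

void sscf_initmod(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, parms);
}

void sscf_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double S    = y[0] > 1e-12 ? y[0] : 1e-12;
    double C    = y[1] > 0 ? y[1] : 0;
    double Xn   = y[2] > 0 ? y[2] : 0;
    double Ead  = y[3] > 0 ? y[3] : 0;
    double G    = y[4] > 0 ? y[4] : 0;
    double EtOH = y[6] > 0 ? y[6] : 0;
    double X    = y[7] > 0 ? y[7] : 0;

    /* adsorption: second order in distance from equilibrium;
     * one-sided so Ead never overshoots Eeq */
    double Eeq = E_load * S_zero / S;
    double dE  = Eeq - Ead;
    ydot[3] = k_ad * (dE > 0 ? dE * dE : 0);

    /* cellulose hydrolysis, glucose-inhibited; ethanol-inhibited in SSCF */
    double Cc = C / w_tot * 1000.0;          /* g per kg broth */
    double rh = k_hyd * Ead * Cc / (1.0 + G / K_G);
    if (sscf_on > 0.5)
        rh /= (1.0 + EtOH / K_iEtOH);

    /* xylan release proportional to cellulose, clamped at exhaustion */
    double Xnc = Xn / w_tot * 1000.0;
    double rx  = gamma_x * rh * Xnc / (Xnc + XN_EPS);

    ydot[1] = -rh * w_tot / 1000.0;
    ydot[2] = -rx * w_tot / 1000.0;
    ydot[0] = ydot[1] + ydot[2];             /* non-carbohydrate solids inert */

    double rcons = 0.0, rd = 0.0;
    if (sscf_on > 0.5) {
        rcons = q_G * G / (K_sat + G) * X;   /* Monod uptake */
        rd    = alpha_d * exp(beta_d * EtOH) * X;
    }

    ydot[4] = 1.111 * rh - rcons;            /* anhydro correction glucan->glucose */
    ydot[5] = 1.136 * rx;                    /* xylan->xylose */
    ydot[6] = Y_EtOH * rcons;
    ydot[7] = -rd;
}
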