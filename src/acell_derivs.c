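/* Membrane ODE right-hand side for the alpha-cell model, in the deSolve
 * compiled-model convention (initmod/derivs).  Units: mV, ms, nS, pA, pF, mM.
 *
 * State vector y (length 19):
 *   y[0]        V (mV)
 *   y[1..12]    gates, two slots per channel in the fixed order
 *               NaV, CaT, CaL, CaPQ, KA, Kdr  (m then h; h slot unused
 *               when the channel has no inactivation gate)
 *   y[13..18]   SGLT2 occupancies p1..p6 (fractions, sum 1)
 *
 * Parameter vector (length 126), packed by pack_cell_params() on the R side:
 *   [0]         C_m (pF)
 *   [1+16*i ..] per channel i: g, v_rev, p_exp,
 *               m: v_half, slope, tau_floor, tau_peak, tau_vc, tau_w,
 *               has_h, h: v_half, slope, tau_floor, tau_peak, tau_vc, tau_w
 *   [97..100]   g_katp, v_k, g_leak, v_leak
 *   [101..107]  n_eff, theta, rtf, na_out, na_in, glc_out, glc_in
 *               (glc_in < 0 means "tied to glc_out")
 *   [108..119]  k12 k21 k23 k32 k34 k43 k45 k54 k56 k65 k61 k16 (per ms;
 *               binding rates per mM per ms)
 *   [120..125]  valences z of the six forward transitions 1->2 ... 6->1,
 *               inward-positive charge moved
 *
 * Output slots (nout = 10): I_NaV, I_CaT, I_CaL, I_CaPQ, I_KA, I_Kdr,
 * I_KATP, I_leak, I_SGLT2 (pA, outward positive) and the net sugar-loaded
 * translocation flux J_glc (molecules per ms, whole cell, inward positive).
 */

#include <R.h>
#include <math.h>

#define N_PARMS 126
#define E_PA_PER_MS 1.602176634e-4 /* e * (1/ms -> 1/s) / (1 pA) */

static double parms[N_PARMS];

void acell_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double boltz(double v, double vh, double s)
{
    return 1.0 / (1.0 + exp((vh - v) / s));
}

static double tau_of_v(double v, const double *tp)
{
    /* tp = {floor, peak, vc, w}; constant tau has peak = 0 */
    double d = (v - tp[2]) / tp[3];
    return tp[0] + tp[1] * exp(-d * d);
}

void acell_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    if (ip[0] < 10)
        error("nout must be at least 10");

    double V = y[0];
    double itot = 0.0;
    int i;

    for (i = 0; i < 6; i++) {
        const double *cp = parms + 1 + 16 * i;
        double g = cp[0], vrev = cp[1], pexp = cp[2];
        double m = y[1 + 2 * i], h = y[2 + 2 * i];

        double minf = boltz(V, cp[3], cp[4]);
        ydot[1 + 2 * i] = (minf - m) / tau_of_v(V, cp + 5);

        double heff;
        if (cp[9] > 0.5) {
            double hinf = boltz(V, cp[10], cp[11]);
            ydot[2 + 2 * i] = (hinf - h) / tau_of_v(V, cp + 12);
            heff = h;
        } else {
            ydot[2 + 2 * i] = 0.0;
            heff = 1.0;
        }

        double mp = (pexp == 1.0) ? m : pow(m, pexp);
        double I = g * mp * heff * (V - vrev);
        yout[i] = I;
        itot += I;
    }

    double ikatp = parms[97] * (V - parms[98]);
    double ileak = parms[99] * (V - parms[100]);
    yout[6] = ikatp;
    yout[7] = ileak;
    itot += ikatp + ileak;

    /* SGLT2 six-state cycle */
    {
        double n_eff = parms[101], theta = parms[102], rtf = parms[103];
        double na_o = parms[104], na_i = parms[105];
        double go = parms[106], gi = parms[107];
        const double *k = parms + 108;
        const double *z = parms + 120;
        double u = V / rtf;
        double f[6], b[6], J[6];
        const double *po = y + 13;
        int s;

        if (gi < 0.0) gi = go;

        f[0] = k[0] * na_o; b[0] = k[1];
        f[1] = k[2] * go;   b[1] = k[3];
        f[2] = k[4];        b[2] = k[5];
        f[3] = k[6];        b[3] = k[7] * gi;
        f[4] = k[8];        b[4] = k[9] * na_i;
        f[5] = k[10];       b[5] = k[11];

        for (s = 0; s < 6; s++) {
            if (z[s] != 0.0) {
                f[s] *= exp(-z[s] * theta * u);
                b[s] *= exp(z[s] * (1.0 - theta) * u);
            }
        }

        for (s = 0; s < 6; s++)
            ydot[13 + s] = 0.0;
        double zflux = 0.0;
        for (s = 0; s < 6; s++) {
            int to = (s + 1) % 6;
            J[s] = f[s] * po[s] - b[s] * po[to];
            ydot[13 + s] -= J[s];
            ydot[13 + to] += J[s];
            zflux += z[s] * J[s];
        }

        double isglt2 = -E_PA_PER_MS * n_eff * zflux;
        yout[8] = isglt2;
        yout[9] = n_eff * J[2]; /* net 3->4 sugar translocation, per ms */
        itot += isglt2;
    }

    ydot[0] = -itot / parms[0];
}
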