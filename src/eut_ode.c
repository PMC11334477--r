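/* Dynamic 13C isotopic model of EA + glycerol co-metabolism through the Eut
 * BMC, as a deSolve-compiled right-hand side.
 *
 * States (mM except biomass in gDW/L):
 *  0 X          7 ace_l     14 acp_l
 *  1 gly        8 aale_u    15 s_co2      (cumulative sinks, mM C or N)
 *  2 ea_u       9 aale_l    16 s_bio_gly
 *  3 ea_l      10 nh4       17 s_pta_u
 *  4 etoh_u    11 aalb_u    18 s_pta_l
 *  5 etoh_l    12 aalb_l    19 s_evap_u
 *  6 ace_u     13 acp_u     20 s_evap_l
 *                           21 s_nh4
 *                           22 s_cyt_src
 *
 * Fluxes are biomass-specific and constant; each uptake/consumption is gated
 * by a saturating availability factor S/(S+eps) so pools never go negative
 * once a substrate is exhausted (a numerical guard, not a kinetic law: eps is
 * far below measured concentrations). Label routing is proportional to the
 * instantaneous label fraction of the consumed pool (well-mixed pools).
 */
#include <R.h>

static double p[14];
#define P_MU      p[0]
#define P_KEVAP   p[1]
#define P_VGLY    p[2]   /* glycerol uptake */
#define P_VGLYC   p[3]   /* glycolysis -> acetyl-P */
#define P_VEA     p[4]   /* EA uptake into the BMC */
#define P_VEUTG   p[5]   /* BMC ethanol release */
#define P_VEUTD   p[6]   /* BMC acetyl-P export (EutE/EutD) */
#define P_VAAL    p[7]   /* BMC acetaldehyde leak */
#define P_VACEX   p[8]   /* acetate excretion */
#define P_VPTA    p[9]   /* acetyl-P -> acetyl-CoA (anabolism) */
#define P_VNH4X   p[10]  /* ammonium excretion */
#define P_VCYT    p[11]  /* cytosolic (unlabeled) ethanol formation */
#define P_EPS     p[12]  /* availability guard, environment pools (mM) */
#define P_EPSP    p[13]  /* availability guard, intracellular pools (mM) */

void eut_init(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, p);
}

static double frac(double lab, double unl)
{
    double tot = lab + unl;
    return (tot > 1e-300) ? lab / tot : 0.0;
}

static double gate(double s, double eps)
{
    if (s <= 0.0) return 0.0;
    return s / (s + eps);
}

void eut_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double X = y[0];
    double g_gly = gate(y[1], P_EPS);
    double ea_tot = y[2] + y[3];
    double g_ea = gate(ea_tot, P_EPS);
    double g_b = gate(y[11] + y[12], P_EPSP);
    double g_c = gate(y[13] + y[14], P_EPSP);
    double f_ea = frac(y[3], y[2]);
    double f_b = frac(y[12], y[11]);
    double f_c = frac(y[14], y[13]);

    double up_ea = P_VEA * X * g_ea;                 /* EA uptake */
    double out_b = (P_VEUTG + P_VEUTD + P_VAAL) * X * g_b;
    double out_c = (P_VACEX + P_VPTA) * X * g_c;

    ydot[0] = P_MU * X * g_gly;                      /* growth */
    ydot[1] = -P_VGLY * X * g_gly;                   /* glycerol */
    ydot[2] = -up_ea * (1 - f_ea);
    ydot[3] = -up_ea * f_ea;
    ydot[4] = P_VEUTG * X * g_b * (1 - f_b) + P_VCYT * X * g_gly
              - P_KEVAP * y[4];
    ydot[5] = P_VEUTG * X * g_b * f_b - P_KEVAP * y[5];
    ydot[6] = P_VACEX * X * g_c * (1 - f_c);
    ydot[7] = P_VACEX * X * g_c * f_c;
    ydot[8] = P_VAAL * X * g_b * (1 - f_b);
    ydot[9] = P_VAAL * X * g_b * f_b;
    ydot[10] = P_VNH4X * X * g_ea;
    ydot[11] = up_ea * (1 - f_ea) - out_b * (1 - f_b);
    ydot[12] = up_ea * f_ea - out_b * f_b;
    ydot[13] = P_VGLYC * X * g_gly + P_VEUTD * X * g_b * (1 - f_b)
               - out_c * (1 - f_c);
    ydot[14] = P_VEUTD * X * g_b * f_b - out_c * f_c;
    ydot[15] = P_VGLYC * X * g_gly;                  /* CO2, 1 C per glycerol */
    ydot[16] = 3 * (P_VGLY - P_VGLYC) * X * g_gly;   /* glycerol C to biomass */
    ydot[17] = 2 * P_VPTA * X * g_c * (1 - f_c);     /* AcCoA sink, C */
    ydot[18] = 2 * P_VPTA * X * g_c * f_c;
    ydot[19] = P_KEVAP * y[4];                       /* evaporated ethanol */
    ydot[20] = P_KEVAP * y[5];
    ydot[21] = (P_VEA - P_VNH4X) * X * g_ea;         /* assimilated N */
    ydot[22] = 2 * P_VCYT * X * g_gly;               /* cytosolic EtOH C source */
}
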