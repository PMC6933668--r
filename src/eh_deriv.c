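/* ODE right-hand side for the two-phase substrate hydrolysis model,
 * in deSolve's compiled-function form. One routine serves both the batch
 * reactor (all stream terms zero) and the membrane CSTR.
 *
 * State y (mass fractions, total-slurry basis):
 *   0 f_GR  recalcitrant glucan      5 f_g   glucose
 *   1 f_GF  facile glucan            6 f_x   xylose
 *   2 f_X   xylan                    7 f_sL  soluble lignin
 *   3 f_L   insoluble lignin         8 f_ET  total enzyme
 *   4 f_O   inert insolubles
 *
 * Parameter vector p (see pack_parms() on the R side, same order):
 *   0-3  k_R k_F k_X k_L        9-15 MW_G MW_X MW_L MW_g MW_x MW_sL MW_E
 *   4    K_dR                  16-18 rho_l rho_is use_constant_density
 *   5-8  kap_RF kap_RX kap_RL  19-24 mdot_s mdot_e mdot_m mdot_p m_T eta_E
 *        kap_Rs                25-32 slurry-feed fractions f_GR..f_sL
 *                              33    enzyme-stream mass fraction f_E0
 *                              34    lignin_couples_facile flag
 */

#include <R.h>

#define NP 35
static double p[NP];

void eh_init(void (*odeparms)(int *, double *))
{
    int n = NP;
    odeparms(&n, p);
}

static double pos(double x) { return x > 0.0 ? x : 0.0; }

/* smooth cutoff switching reaction off as a substrate pool empties */
static double cut(double f) { return f / (f + 1e-12); }

void eh_deriv(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
    const double k_R = p[0], k_F = p[1], k_X = p[2], k_L = p[3];
    const double K_dR = p[4], kRF = p[5], kRX = p[6], kRL = p[7], kRs = p[8];
    const double MW_G = p[9], MW_X = p[10], MW_L = p[11], MW_g = p[12],
                 MW_x = p[13], MW_sL = p[14], MW_E = p[15];
    const double rho_l = p[16], rho_is = p[17];
    const int const_rho = p[18] != 0.0;
    const double a_s = p[19] / p[23], a_e = p[20] / p[23],
                 a_m = p[21] / p[23], a_p = p[22] / p[23];
    const double eta_E = p[24];
    const int lig_fac = p[34] != 0.0;

    double fGR = pos(y[0]), fGF = pos(y[1]), fX = pos(y[2]), fL = pos(y[3]),
           fO = pos(y[4]), fg = pos(y[5]), fx = pos(y[6]), fsL = pos(y[7]),
           fET = pos(y[8]);

    double f_is = fGR + fGF + fX + fL + fO;
    double f_l = 1.0 - f_is;
    double rho_T = const_rho ? rho_l
                             : 1.0 / (f_is / rho_is + f_l / rho_l);
    double eps_l = rho_T / rho_l * f_l;

    double cET = fET * rho_T / MW_E;
    double cGR = fGR * rho_T / MW_G;
    double cGF = fGF * rho_T / MW_G;
    double cX  = fX * rho_T / MW_X;
    double cL  = fL * rho_T / MW_L;
    double c_sL = fsL * rho_T / MW_sL / eps_l;
    double c_ss = (fg * rho_T / MW_g + fx * rho_T / MW_x) / eps_l;

    /* regularized partition denominator D' = c_GR * D */
    double Dp = cGR + kRF * cGF + kRX * cX +
                eps_l * (K_dR + kRL * c_sL + kRs * c_ss);
    double s = cET / Dp;
    double cEGR = cGR * s;
    double cEGF = kRF * cGF * s;
    double cEX  = kRX * cX * s;
    double cEf  = eps_l * K_dR * s;
    double cEsL = eps_l * kRL * c_sL * s;
    double cEss = eps_l * kRs * c_ss * s;

    double rGR = -k_R * cEGR * cut(fGR);
    double rGF = -k_F * cEGF * cut(fGF);
    double rX  = -k_X * cEX * cut(fX);
    double carb = lig_fac ? (rGR + rGF + rX) : (rGR + rX);
    double rL = k_L * cL * carb * cut(fL);

    double R_GR = MW_G * rGR / rho_T;
    double R_GF = MW_G * rGF / rho_T;
    double R_X  = MW_X * rX / rho_T;
    double R_L  = MW_L * rL / rho_T;
    double R_g  = MW_g * (-(rGR + rGF)) / rho_T;
    double R_x  = MW_x * (-rX) / rho_T;
    double R_sL = MW_sL * (-rL) / rho_T;

    /* insolubles: in with slurry feed, out with purge only */
    ydot[0] = a_s * p[25] - a_p * fGR + R_GR;
    ydot[1] = a_s * p[26] - a_p * fGF + R_GF;
    ydot[2] = a_s * p[27] - a_p * fX + R_X;
    ydot[3] = a_s * p[28] - a_p * fL + R_L;
    ydot[4] = a_s * p[29] - a_p * fO;

    /* solubles: out with purge and (liquid-enriched) permeate */
    ydot[5] = a_s * p[30] - a_p * fg - a_m * fg / eps_l + R_g;
    ydot[6] = a_s * p[31] - a_p * fx - a_m * fx / eps_l + R_x;
    ydot[7] = a_s * p[32] - a_p * fsL - a_m * fsL / eps_l + R_sL;

    /* enzyme: own feed stream; purge takes all pools; the membrane passes
     * only the soluble pools (free + sugar- + lignin-inhibited), attenuated
     * by the rejection factor eta_E */
    ydot[8] = a_e * p[33] - a_p * fET -
              a_m * eta_E * MW_E * (cEss + cEsL + cEf) / (rho_T * eps_l);
}
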