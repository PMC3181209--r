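/* Mass-action rate equations of the artificial lac operon network for
 * deSolve's compiled-code interface. One right-hand side serves two modes:
 *
 *   mode 0 (continuum): fixed surface-to-volume ratio, dilution mu applied
 *     to every species except the operator-carrying ones (O, R2O), whose
 *     total is maintained by continuous DNA duplication;
 *   mode 1 (per-cell hybrid): the cell volume grows exponentially from
 *     V0 at segment start, the surface-to-volume ratio follows the rod
 *     geometry, and dilution applies to all species (operator amounts are
 *     restored by discrete duplication/division jumps handled in R).
 *
 * State (nM): MR, R, R2, O, R2O, I, I2R2, MY, Y, YIex.
 * Parms: the 32-entry kinetic/physiology vector shared with the SSA kernel,
 * then mode, AoV_fixed, mu, V0_seg, t0_seg (37 doubles).
 */

#include <R.h>
#include <math.h>

#define N_PARMS 37
static double parms[N_PARMS];

#define k_sMR  parms[0]
#define k_sR   parms[1]
#define k_2R   parms[2]
#define k_m2R  parms[3]
#define k_r    parms[4]
#define k_mr   parms[5]
#define k_dr1  parms[6]
#define k_mdr1 parms[7]
#define k_dr2  parms[8]
#define k_mdr2 parms[9]
#define k_s1MY parms[10]
#define k_s0MY parms[11]
#define k_sY   parms[12]
#define k_p    parms[13]
#define k_mp   parms[14]
#define k_ft   parms[15]
#define ht_um  parms[16]
#define l_MR   parms[17]
#define l_MY   parms[18]
#define l_R    parms[19]
#define l_R2   parms[20]
#define l_Y    parms[21]
#define l_YIex parms[22]
#define l_I2R2 parms[23]
#define I_ex   parms[24]
#define g_rate parms[25]
#define R0     parms[31]
#define MODE      parms[32]
#define AOV_FIXED parms[33]
#define MU        parms[34]
#define V0_SEG    parms[35]
#define T0_SEG    parms[36]

void lac_initmod(void (*odeparms)(int *, double *)) {
  int n = N_PARMS;
  odeparms(&n, parms);
}

void lac_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  double MR = y[0], R = y[1], R2 = y[2], O = y[3], R2O = y[4];
  double I = y[5], I2R2 = y[6], MY = y[7], Y = y[8], YIex = y[9];
  double AoV, mu_op;
  double mu = MU;

  if (MODE < 0.5) {
    AoV = AOV_FIXED;
    mu_op = 0.0;               /* operator exempt from dilution */
  } else {
    double V = V0_SEG * exp(g_rate * (*t - T0_SEG));
    AoV = 2.0 / R0 + (4.0 / 3.0) * M_PI * R0 * R0 / V;
    mu_op = mu;
  }

  double v_dim  = k_2R * R * R - k_m2R * R2;
  double v_rep  = k_r * R2 * O - k_mr * R2O;
  double v_dr1  = k_dr1 * I * I * R2O - k_mdr2 * I2R2 * O;
  double v_dr2  = k_dr2 * I * I * R2 - k_mdr1 * I2R2;
  double v_load = k_p * I_ex * Y - k_mp * YIex;
  double v_ft   = k_ft * YIex;
  double v_pass = ht_um * AoV * (I_ex - I);

  ydot[0] = k_sMR - l_MR * MR - mu * MR;
  ydot[1] = k_sR * MR - 2.0 * v_dim - l_R * R - mu * R;
  ydot[2] = v_dim - v_rep - v_dr2 - l_R2 * R2 - mu * R2;
  ydot[3] = -v_rep + v_dr1 - mu_op * O;
  ydot[4] = v_rep - v_dr1 - mu_op * R2O;
  ydot[5] = -2.0 * v_dr1 - 2.0 * v_dr2 + v_ft + v_pass
            + 2.0 * l_I2R2 * I2R2 - mu * I;
  ydot[6] = v_dr1 + v_dr2 - l_I2R2 * I2R2 - mu * I2R2;
  ydot[7] = k_s1MY * O + k_s0MY * R2O - l_MY * MY - mu * MY;
  ydot[8] = k_sY * MY - v_load + v_ft - l_Y * Y - mu * Y;
  ydot[9] = v_load - v_ft - l_YIex * YIex - mu * YIex;
}
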