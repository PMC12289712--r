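/* Compiled right-hand side of the 15-state erythropoiesis model for use
 * with deSolve.  Drug inhibition is constant within an integration segment
 * (the treatment window is handled by segmenting in R), so the pathway
 * multipliers arrive as parameters.
 *
 * Parameter vector (16):
 *  0 F0      baseline cell flux, 1e9 cells/L/day
 *  1 kPRE    1/day
 *  2 kRBC    1/day
 *  3 kRET    1/day
 *  4 kTOL    1/day
 *  5 pRel    premature-release odds
 *  6 MCH0    pg
 *  7 Hb0     g/L
 *  8 gamma   feedback exponent
 *  9 PRE0    baseline precursors, 1e9/L
 * 10 eMCH    1 - I on hemoglobin synthesis (mechanisms A, D)
 * 11 eRin    1 - I on precursor recruitment (mechanism B)
 * 12 ekPRE   1 - I on precursor differentiation (mechanism C)
 * 13 fbOff   > 0.5: hemoglobin feedback silenced (mechanism D window)
 * 14 fbSign  +1 deficit stimulates / -1 literal suppressive orientation
 * 15 tolFloor relative clamp for TOL2 (fraction of PRE0)
 *
 * State order matches .STATE_NAMES in R/model.R:
 *  0 PRE, 1 TOL1, 2 TOL2, 3 RET_imm_bm, 4 RET_imm_bl, 5 RET_mat_bm,
 *  6 RET_mat_bl, 7-10 RBC1-4, 11-14 Hb1-4
 */

#include <R.h>
#include <math.h>

static double parms[16];

void ery_initmod(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, parms);
}

void ery_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double F0 = parms[0], kPRE = parms[1], kRBC = parms[2],
                 kRET = parms[3], kTOL = parms[4], pRel = parms[5],
                 MCH0 = parms[6], Hb0 = parms[7], gamma = parms[8],
                 PRE0 = parms[9], eMCH = parms[10], eRin = parms[11],
                 ekPRE = parms[12], fbOff = parms[13], fbSign = parms[14],
                 tolFloor = parms[15];
    const double u = 1e-3; /* 1e9 -> 1e12 cells/L; also pg*1e9/L -> g/L */

    double Hbtot = y[11] + y[12] + y[13] + y[14];
    double S = (fbOff > 0.5) ? 1.0
                             : exp(gamma * fbSign * (Hb0 - Hbtot) / Hb0);
    double tol2 = y[2];
    double lo = tolFloor * PRE0;
    if (tol2 < lo) tol2 = lo;
    double M = PRE0 / tol2;

    /* The hemoglobin-driven stimulation S acts on precursor recruitment
     * and on the two bone-marrow -> blood release transitions (earlier
     * and faster release of immature and mature reticulocytes).
     * Maturation transitions keep the baseline rate k_RET. */
    ydot[0] = F0 * S * M * eRin - kPRE * ekPRE * y[0];
    ydot[1] = kTOL * (y[0] - y[1]);
    ydot[2] = kTOL * (y[1] - y[2]);
    ydot[3] = kPRE * ekPRE * y[0]
              - (pRel * S + (1.0 - pRel)) * kRET * y[3];
    ydot[4] = pRel * S * kRET * y[3] - kRET * y[4];
    ydot[5] = (1.0 - pRel) * kRET * y[3] - S * kRET * y[5];
    ydot[6] = kRET * y[4] + S * kRET * y[5] - kRET * y[6];

    double inflow = kRET * y[6] * u; /* 1e12 cells/L/day */
    ydot[7] = inflow - kRBC * y[7];
    ydot[8] = kRBC * (y[7] - y[8]);
    ydot[9] = kRBC * (y[8] - y[9]);
    ydot[10] = kRBC * (y[9] - y[10]);

    ydot[11] = MCH0 * eMCH * kRET * y[6] * u - kRBC * y[11];
    ydot[12] = kRBC * (y[11] - y[12]);
    ydot[13] = kRBC * (y[12] - y[13]);
    ydot[14] = kRBC * (y[13] - y[14]);
}
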