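/* Whole-body PBPK right-hand side for hepatic-uptake (OATP1B1) substrates.
 *
 * Compartments (amounts, ng):
 *   0  venous blood
 *   1  arterial blood
 *   2  lung                          (perfusion-limited, Kp)
 *   3  gut tissue                    (perfusion-limited, Kp)
 *   4  spleen                        (perfusion-limited, Kp)
 *   5  kidney                        (perfusion-limited, Kp)
 *   6  rest of body                  (perfusion-limited, Kp)
 *   7  muscle extracellular          (permeability-limited pair)
 *   8  muscle intracellular
 *   9  adipose extracellular
 *  10  adipose intracellular
 *  11        .. 11+n-1   liver blood, serial sub-units 1..n
 *  11+n      .. 11+2n-1  liver intracellular tissue, sub-units 1..n
 *  11+2n     bile ducts
 *  11+2n+1   GI lumen
 *  11+2n+2   cumulative renal elimination
 *  11+2n+3   cumulative unabsorbed (fecal) loss
 *
 * Liver blood flows through the n sub-units in series; uptake (active +
 * passive), passive efflux and biliary clearances are divided equally across
 * sub-units.  Bile empties continuously into the GI lumen (no gallbladder
 * storage); lumen drug is absorbed into the portal inflow of sub-unit 1 at
 * ka*FaFg and lost to an unabsorbed sink at ka*(1-FaFg).
 *
 * Uptake into tissue acts on unbound plasma concentration (fu_p * C_blood /
 * RB_P); efflux and biliary excretion act on unbound intracellular
 * concentration.  For muscle/adipose the intracellular unbound fraction is
 * fu_p/Kp so the passive-only equilibrium reproduces the tissue Kp.
 *
 * Parameter vector layout must match pbpk_parameter_vector() on the R side.
 */

#include <R.h>

#define NPARMS 45

static double p[NPARMS];

#define N_SUB        ((int) p[0])
#define FU_P         p[1]
#define RBP          p[2]
#define FU_LIVER     p[3]
#define CL_RENAL     p[4]
#define CL_ACT       p[5]
#define CL_BILE      p[6]
#define CL_PASS_LIV  p[7]
#define CL_PASS_MUS  p[8]
#define CL_PASS_ADI  p[9]
#define KA           p[10]
#define FAFG         p[11]
#define KP_LUNG      p[12]
#define KP_GUT       p[13]
#define KP_SPLEEN    p[14]
#define KP_KIDNEY    p[15]
#define KP_REST      p[16]
#define KP_MUSCLE    p[17]
#define KP_ADIPOSE   p[18]
#define V_VEN        p[19]
#define V_ART        p[20]
#define V_LUNG       p[21]
#define V_GUT        p[22]
#define V_SPLEEN     p[23]
#define V_KIDNEY     p[24]
#define V_REST       p[25]
#define V_MUS_EC     p[26]
#define V_MUS_IC     p[27]
#define V_ADI_EC     p[28]
#define V_ADI_IC     p[29]
#define V_LIV_BLOOD  p[30]
#define V_LIV_TISSUE p[31]
#define V_BILE       p[32]
#define Q_CO         p[33]
#define Q_GUT        p[34]
#define Q_SPLEEN     p[35]
#define Q_KIDNEY     p[36]
#define Q_REST       p[37]
#define Q_MUSCLE     p[38]
#define Q_ADIPOSE    p[39]
#define Q_LIVER      p[40]
#define Q_BILE       p[41]
#define INF_RATE     p[42]
#define INF_START    p[43]
#define INF_END      p[44]

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, p);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const int n = N_SUB;
    const int i_lb = 11;            /* first liver blood index      */
    const int i_lt = 11 + n;        /* first liver tissue index     */
    const int i_bile = 11 + 2 * n;
    const int i_lumen = i_bile + 1;
    const int i_renal = i_bile + 2;
    const int i_unabs = i_bile + 3;

    const double c_ven  = y[0] / V_VEN;
    const double c_art  = y[1] / V_ART;
    const double c_lung_out    = y[2] / V_LUNG    * RBP / KP_LUNG;
    const double c_gut_out     = y[3] / V_GUT     * RBP / KP_GUT;
    const double c_spleen_out  = y[4] / V_SPLEEN  * RBP / KP_SPLEEN;
    const double c_kidney_out  = y[5] / V_KIDNEY  * RBP / KP_KIDNEY;
    const double c_rest_out    = y[6] / V_REST    * RBP / KP_REST;
    const double c_mus_ec = y[7] / V_MUS_EC;
    const double c_mus_ic = y[8] / V_MUS_IC;
    const double c_adi_ec = y[9] / V_ADI_EC;
    const double c_adi_ic = y[10] / V_ADI_IC;
    const double c_bile = y[i_bile] / V_BILE;
    const double x_lumen = y[i_lumen];

    const double q_ha = Q_LIVER - Q_GUT - Q_SPLEEN;  /* hepatic artery */
    const double infusion =
        (*t >= INF_START && *t < INF_END) ? INF_RATE : 0.0;

    /* muscle / adipose permeability-limited exchange */
    const double mus_in  = CL_PASS_MUS * FU_P * c_mus_ec / RBP;
    const double mus_out = CL_PASS_MUS * (FU_P / KP_MUSCLE) * c_mus_ic;
    const double adi_in  = CL_PASS_ADI * FU_P * c_adi_ec / RBP;
    const double adi_out = CL_PASS_ADI * (FU_P / KP_ADIPOSE) * c_adi_ic;

    /* liver sub-units in series */
    const double vlb = V_LIV_BLOOD / n;
    const double vlt = V_LIV_TISSUE / n;
    const double cl_upt_sub = (CL_ACT + CL_PASS_LIV) / n;
    const double cl_eff_sub = CL_PASS_LIV / n;
    const double cl_bil_sub = CL_BILE / n;

    double bile_in = 0.0;      /* total biliary excretion flux */
    double c_liver_exit = 0.0; /* blood conc leaving sub-unit n */

    for (int i = 0; i < n; i++) {
        const double c_lb = y[i_lb + i] / vlb;
        const double c_lt = y[i_lt + i] / vlt;
        const double upt = cl_upt_sub * FU_P * c_lb / RBP;
        const double eff = cl_eff_sub * FU_LIVER * c_lt;
        const double bil = cl_bil_sub * FU_LIVER * c_lt;

        double inflow;
        if (i == 0)
            inflow = q_ha * c_art + Q_GUT * c_gut_out +
                     Q_SPLEEN * c_spleen_out + KA * FAFG * x_lumen;
        else
            inflow = Q_LIVER * (y[i_lb + i - 1] / vlb);

        ydot[i_lb + i] = inflow - Q_LIVER * c_lb - upt + eff;
        ydot[i_lt + i] = upt - eff - bil;
        bile_in += bil;
        if (i == n - 1)
            c_liver_exit = c_lb;
    }

    ydot[0] = Q_LIVER * c_liver_exit + Q_KIDNEY * c_kidney_out +
              Q_REST * c_rest_out + Q_MUSCLE * c_mus_ec +
              Q_ADIPOSE * c_adi_ec - Q_CO * c_ven -
              CL_RENAL * c_ven / RBP + infusion;
    ydot[1] = Q_CO * c_lung_out -
              (q_ha + Q_GUT + Q_SPLEEN + Q_KIDNEY + Q_REST +
               Q_MUSCLE + Q_ADIPOSE) * c_art;
    ydot[2] = Q_CO * (c_ven - c_lung_out);
    ydot[3] = Q_GUT * (c_art - c_gut_out);
    ydot[4] = Q_SPLEEN * (c_art - c_spleen_out);
    ydot[5] = Q_KIDNEY * (c_art - c_kidney_out);
    ydot[6] = Q_REST * (c_art - c_rest_out);
    ydot[7] = Q_MUSCLE * (c_art - c_mus_ec) - mus_in + mus_out;
    ydot[8] = mus_in - mus_out;
    ydot[9] = Q_ADIPOSE * (c_art - c_adi_ec) - adi_in + adi_out;
    ydot[10] = adi_in - adi_out;

    ydot[i_bile] = bile_in - Q_BILE * c_bile;
    ydot[i_lumen] = Q_BILE * c_bile - KA * x_lumen;
    ydot[i_renal] = CL_RENAL * c_ven / RBP;
    ydot[i_unabs] = KA * (1.0 - FAFG) * x_lumen;
}
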