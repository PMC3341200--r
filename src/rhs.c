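/* Compiled right-hand side of the MITF-PIAS3-STAT3 network, in the
 * deSolve compiled-model convention.  Must stay in exact agreement with
 * the reference implementation in R/rhs.R (model_rhs); the test suite
 * checks the two against each other and against an independently
 * assembled stoichiometry-matrix oracle.
 *
 * Parameter vector layout (set via initmod): the 30 core constants in
 * the order of core_parameter_names(), followed by the current ERKp and
 * JAKp input levels.
 */
#include <R.h>

static double parms[32];

#define k_Mp73E_plus   parms[0]
#define k_Mp73_minus   parms[1]
#define k_Mp73a_plus   parms[2]
#define k_Mp409_plus   parms[3]
#define k_Mp409_minus  parms[4]
#define k_Mass         parms[5]
#define k_Mdiss        parms[6]
#define k_Mp73ass      parms[7]
#define k_Mp73diss     parms[8]
#define k_Mp409ass     parms[9]
#define k_Mp409diss    parms[10]
#define k_Mppass       parms[11]
#define k_Mppdiss      parms[12]
#define k_Sp_plus      parms[13]
#define k_Sp_minus     parms[14]
#define k_Spass        parms[15]
#define k_Spdiss       parms[16]
#define p_MITF         parms[17]
#define gamma_MITF     parms[18]
#define gamma_MITFp73  parms[19]
#define gamma_MITFp409 parms[20]
#define p_PIAS3        parms[21]
#define gamma_PIAS3    parms[22]
#define p_STAT3        parms[23]
#define gamma_STAT3    parms[24]
#define k_Rp_plus      parms[25]
#define k_Rp_minus     parms[26]
#define ERKp_baseline  parms[27]
#define JAKp_baseline  parms[28]
#define k_u            parms[29]
#define ERKp_in        parms[30]
#define JAKp_in        parms[31]

/* state indices */
#define iMITF   0
#define iM73    1
#define iM409   2
#define iMpp    3
#define iP      4
#define iPM     5
#define iPM73   6
#define iPM409  7
#define iPMpp   8
#define iRSK    9
#define iRSKp  10
#define iS     11
#define iSp    12
#define iPSp   13
#define iR     14

void pias3net_initmod(void (*odeparms)(int *, double *))
{
    int n = 32;
    odeparms(&n, parms);
}

void pias3net_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double erkp = ERKp_in;
    const double jakp = JAKp_in;

    double R = y[iR];
    if (R < 0.0) R = 0.0;
    if (R > 1.0) R = 1.0;

    /* complex degradation: 20% of the mean of the constituents' rates */
    const double gMP   = (gamma_MITF    + gamma_PIAS3) / 10.0;
    const double g73P  = (gamma_MITFp73 + gamma_PIAS3) / 10.0;
    const double g409P = (gamma_MITFp409 + gamma_PIAS3) / 10.0;
    const double gSP   = (gamma_STAT3   + gamma_PIAS3) / 10.0;

    ydot[iMITF] = p_MITF
        - k_Mp73E_plus * y[iMITF] * erkp
        - k_Mp73a_plus * y[iMITF]
        + k_Mp73_minus * y[iM73]
        - k_Mp409_plus * y[iMITF] * y[iRSKp]
        + k_Mp409_minus * y[iM409]
        - k_Mass * y[iMITF] * y[iP]
        + k_Mdiss * y[iPM]
        - gamma_MITF * y[iMITF];

    ydot[iM73] =
        + k_Mp73E_plus * erkp * y[iMITF]
        + k_Mp73a_plus * y[iMITF]
        - k_Mp73_minus * y[iM73]
        - k_Mp409_plus * y[iRSKp] * y[iM73]
        + k_Mp409_minus * y[iMpp]
        - k_Mp73ass * y[iM73] * y[iP]
        + k_Mp73diss * y[iPM73]
        - gamma_MITFp73 * R * y[iM73];

    ydot[iM409] =
        - k_Mp73E_plus * erkp * y[iM409]
        - k_Mp73a_plus * y[iM409]
        + k_Mp73_minus * y[iMpp]
        + k_Mp409_plus * y[iRSKp] * y[iMITF]
        - k_Mp409_minus * y[iM409]
        - k_Mp409ass * y[iM409] * y[iP]
        + k_Mp409diss * y[iPM409]
        - gamma_MITFp409 * y[iM409];

    ydot[iMpp] =
        + k_Mp73E_plus * erkp * y[iM409]
        + k_Mp73a_plus * y[iM409]
        - k_Mp73_minus * y[iMpp]
        + k_Mp409_plus * y[iRSKp] * y[iM73]
        - k_Mp409_minus * y[iMpp]
        - k_Mppass * y[iMpp] * y[iP]
        + k_Mppdiss * y[iPMpp]
        - gamma_MITFp73 * R * y[iMpp]
        - gamma_MITFp409 * y[iMpp];

    ydot[iP] = p_PIAS3
        - k_Mass * y[iP] * y[iMITF] + k_Mdiss * y[iPM]
        - k_Mp73ass * y[iP] * y[iM73] + k_Mp73diss * y[iPM73]
        - k_Mp409ass * y[iP] * y[iM409] + k_Mp409diss * y[iPM409]
        - k_Mppass * y[iP] * y[iMpp] + k_Mppdiss * y[iPMpp]
        - k_Spass * y[iP] * y[iSp] + k_Spdiss * y[iPSp]
        - gamma_PIAS3 * y[iP];

    ydot[iPM] =
        - k_Mp73E_plus * erkp * y[iPM]
        + k_Mp73_minus * y[iPM73]
        - k_Mp73a_plus * y[iPM]
        - k_Mp409_plus * y[iRSKp] * y[iPM]
        + k_Mp409_minus * y[iPM409]
        + k_Mass * y[iMITF] * y[iP]
        - k_Mdiss * y[iPM]
        - gMP * y[iPM];

    ydot[iPM73] =
        + k_Mp73E_plus * erkp * y[iPM]
        - k_Mp73_minus * y[iPM73]
        + k_Mp73a_plus * y[iPM]
        - k_Mp409_plus * y[iRSKp] * y[iPM73]
        + k_Mp409_minus * y[iPMpp]
        + k_Mp73ass * y[iM73] * y[iP]
        - k_Mp73diss * y[iPM73]
        - g73P * R * y[iPM73];

    ydot[iPM409] =
        - k_Mp73E_plus * erkp * y[iPM409]
        + k_Mp73_minus * y[iPMpp]
        - k_Mp73a_plus * y[iPM409]
        + k_Mp409_plus * y[iRSKp] * y[iPM]
        - k_Mp409_minus * y[iPM409]
        + k_Mp409ass * y[iM409] * y[iP]
        - k_Mp409diss * y[iPM409]
        - g409P * y[iPM409];

    ydot[iPMpp] =
        + k_Mp73E_plus * erkp * y[iPM409]
        - k_Mp73_minus * y[iPMpp]
        + k_Mp73a_plus * y[iPM409]
        + k_Mp409_plus * y[iRSKp] * y[iPM73]
        - k_Mp409_minus * y[iPMpp]
        + k_Mppass * y[iMpp] * y[iP]
        - k_Mppdiss * y[iPMpp]
        - g73P * R * y[iPMpp]
        - g409P * y[iPMpp];

    ydot[iRSK] = -k_Rp_plus * y[iRSK] * erkp + k_Rp_minus * y[iRSKp];
    ydot[iRSKp] = -ydot[iRSK];

    ydot[iS] = p_STAT3
        - k_Sp_plus * jakp * y[iS]
        + k_Sp_minus * y[iSp]
        - gamma_STAT3 * y[iS];

    ydot[iSp] =
        + k_Sp_plus * jakp * y[iS]
        - k_Sp_minus * y[iSp]
        - k_Spass * y[iSp] * y[iP]
        + k_Spdiss * y[iPSp]
        - gamma_STAT3 * y[iSp];

    ydot[iPSp] =
        + k_Spass * y[iSp] * y[iP]
        - k_Spdiss * y[iPSp]
        - gSP * y[iPSp];

    /* ubiquitination fraction: tagging, depletion, dilution (a = 1 min) */
    {
        const double term_i = (1.0 - R) * erkp * k_u;
        const double term_ii =
            -gamma_MITFp73 * R * (1.0 - R) / (1.0 - R * gamma_MITFp73);
        const double B = y[iM73] + y[iMpp];
        const double influx = p_MITF - y[iM409] * gamma_MITFp409;
        const double denom = B + influx;
        double A;
        if (denom <= 0.0) {
            A = 1.0;
        } else {
            A = B / denom;
            if (A > 1.0) A = 1.0;
            if (A < 0.0) A = 0.0;
        }
        ydot[iR] = term_i + term_ii - (R - R * A);
    }
}
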