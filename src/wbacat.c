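/* Compiled derivative of the 42-state whole-body oral-absorption model.
 * Mirrors the R reference implementation produced by wb_rhs_compiled();
 * the two are cross-checked in the test suite on random states.
 *
 * Parameter vector layout (see wb_parms_vector() in R/model.R):
 *  0 ger, 1 stomach_volume, 2 csat_st, 3 k_deg_stomach, 4 kt,
 *  5 kd, 6 k_deg_lumen, 7 ka, 8 ksec, 9 kel_colon, 10 colon_volume,
 * 11 csat_co, 12 CLh, 13 CLr,
 * 14..20 vol_si[7], 21..27 csat_si[7],
 * 28 use_rates flag, 29..35 uptake[7] mg/h, 36..42 secretion[7] mg/h,
 * 43..49 q_plain[7], 50..56 vkp_plain[7],
 * 57 q_kid, 58 vk_kid, 59 q_spl, 60 vk_spl, 61 q_pan, 62 vk_pan,
 * 63 q_gut, 64 q_ha, 65 vk_liv, 66 vk_lun, 67 q_lun, 68 qpv, 69 qliv,
 * 70 q_art_off, 71 v_ven, 72 v_art, 73 v_por
 */
#include <R.h>
#include <math.h>

#define NP 74
static double parms[NP];

void wb_acat_init(void (*odeparms)(int *, double *))
{
    int n = NP;
    odeparms(&n, parms);
}

static double soft_gate(double a)
{
    if (a < 0) a = 0;
    return a / (a + 1e-6);
}

static double diss(double kd, double solid, double conc, double csat)
{
    double m = solid > 0 ? solid : 0;
    double f = kd * pow(m, 2.0 / 3.0) * (csat - (conc > 0 ? conc : 0));
    return f > 0 ? f : 0;
}

void wb_acat_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double ger = parms[0], vst = parms[1], csat_st = parms[2],
        kdst = parms[3], kt = parms[4], kd = parms[5], kdl = parms[6],
        ka = parms[7], ksec = parms[8], kel = parms[9], vco = parms[10],
        csat_co = parms[11], clh = parms[12], clr = parms[13];
    const double *vol_si = parms + 14, *csat_si = parms + 21;
    const int use_rates = parms[28] > 0.5;
    const double *urate = parms + 29, *srate = parms + 36;
    const double *q_plain = parms + 43, *vkp = parms + 50;
    const double q_kid = parms[57], vk_kid = parms[58],
        q_spl = parms[59], vk_spl = parms[60], q_pan = parms[61],
        vk_pan = parms[62], q_gut = parms[63], q_ha = parms[64],
        vk_liv = parms[65], vk_lun = parms[66], q_lun = parms[67],
        qpv = parms[68], qliv = parms[69], q_art_off = parms[70],
        v_ven = parms[71], v_art = parms[72], v_por = parms[73];

    double deg, fecal, sec_total = 0, in_sol, in_dis;
    int i;

    /* stomach */
    double ss = y[0], sd = y[1];
    double jst = diss(kd, ss, (sd > 0 ? sd : 0) / vst, csat_st);
    ydot[0] = -ger * ss - jst;
    ydot[1] = jst - ger * sd - kdst * sd;
    deg = kdst * sd;

    /* seven small-intestinal segments */
    in_sol = ger * ss;
    in_dis = ger * sd;
    for (i = 0; i < 7; i++) {
        double sol = y[2 + 2 * i], dis = y[3 + 2 * i], ent = y[18 + i];
        double jd = diss(kd, sol, (dis > 0 ? dis : 0) / vol_si[i],
                         csat_si[i]);
        double up = use_rates ? urate[i] * soft_gate(dis) : ka * dis;
        double sec = use_rates ? srate[i] * soft_gate(ent) : ksec * ent;
        ydot[2 + 2 * i] = in_sol - kt * sol - jd;
        ydot[3 + 2 * i] = in_dis + jd - kt * dis - kdl * dis - up;
        ydot[18 + i] = up - sec;
        deg += kdl * dis;
        sec_total += sec;
        in_sol = kt * sol;
        in_dis = kt * dis;
    }

    /* colon */
    {
        double csol = y[16], cdis = y[17];
        double jc = diss(kd, csol, (cdis > 0 ? cdis : 0) / vco, csat_co);
        ydot[16] = in_sol - jc - kel * csol;
        ydot[17] = in_dis + jc - kel * cdis - kdl * cdis;
        deg += kdl * cdis;
        fecal = kel * (csol + cdis);
    }

    /* systemic circulation */
    {
        double cart = y[26] / v_art, cven = y[25] / v_ven,
            cpor = y[27] / v_por;
        static const int iplain[7] = {29, 30, 31, 32, 33, 34, 39};
        double ven_in = 0, ck, csp, cpa, cli, clung;
        for (i = 0; i < 7; i++) {
            double co = y[iplain[i]] / vkp[i];
            ydot[iplain[i]] = q_plain[i] * (cart - co);
            ven_in += q_plain[i] * co;
        }
        ck = y[35] / vk_kid;
        ydot[35] = q_kid * (cart - ck) - clr * ck;
        ven_in += q_kid * ck;
        csp = y[37] / vk_spl;
        cpa = y[38] / vk_pan;
        ydot[37] = q_spl * (cart - csp);
        ydot[38] = q_pan * (cart - cpa);
        ydot[27] = q_gut * cart + q_spl * csp + q_pan * cpa + sec_total -
            qpv * cpor;
        cli = y[36] / vk_liv;
        ydot[36] = q_ha * cart + qpv * cpor - qliv * cli - clh * cli;
        ven_in += qliv * cli;
        clung = y[28] / vk_lun;
        ydot[28] = q_lun * (cven - clung);
        ydot[25] = ven_in - q_lun * cven;
        ydot[26] = q_lun * clung - q_art_off * cart;
        ydot[40] = clr * ck;
        ydot[41] = deg + fecal + clh * cli;
    }
}
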