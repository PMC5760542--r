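/* Compiled right-hand sides for the meiotic-entry subsystem and the
 * integrated cell-cycle + meiosis model, in the deSolve compiled-model
 * calling convention. Parameter vectors are passed positionally; the order
 * is fixed by the R-side default parameter lists (see parameters.R) and is
 * cross-checked against the reference R implementation in the test suite.
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double pm_mei[61];   /* 57 meiosis params + tor2, pka, phe_on, mpf */
static double pm_int[116];  /* 57 meiosis + 56 cell-cycle params + 3 inputs */

void init_meiosis(void (*odeparms)(int *, double *)) {
  int n = 61;
  odeparms(&n, pm_mei);
}
void init_integrated(void (*odeparms)(int *, double *)) {
  int n = 116;
  odeparms(&n, pm_int);
}

static double hillf(double x, double k, double h) {
  double r;
  if (x <= 0) return 0.0;
  r = pow(x / k, h);
  return r / (1.0 + r);
}

static double gk(double va, double vi, double Ja, double Ji) {
  double b = vi - va + Ja * vi + Ji * va;
  double d = b * b - 4.0 * (vi - va) * va * Ji;
  if (d < 0) d = 0;
  return 2.0 * va * Ji / (b + sqrt(d));
}

/* meiosis parameter indices (order of .meiosis_defaults) */
#define K_IMSTE11 p[0]
#define K_EXSTE11 p[1]
#define B_IMPHE   p[2]
#define B_IMPAT   p[3]
#define H_IMPAT   p[4]
#define B_IMNUT   p[5]
#define B_EXTOR   p[6]
#define IMP_BOOST p[7]
#define PAT_CLAMP p[8]
#define KS_STE11R p[9]
#define KS_STE11A p[10]
#define KS_STE110 p[11]
#define K_MSTE11  p[12]
#define HS        p[13]
#define STE11_ACT p[14]
#define KD_STE11  p[15]
#define J_RST2    p[16]
#define H_RST2    p[17]
#define A_RPOL    p[18]
#define K_RPOL    p[19]
#define J_RPOL    p[20]
#define H_RPOL    p[21]
#define KS_MEI2   p[22]
#define A_MEI2    p[23]
#define J_SMEI2   p[24]
#define H_SMEI2   p[25]
#define KS_MEI2C  p[26]
#define KP_PAT    p[27]
#define KP_TOR    p[28]
#define J_PMEI2   p[29]
#define KDP_MEI2  p[30]
#define J_DPMEI2  p[31]
#define KD_MEI2A  p[32]
#define KD_MEI2P  p[33]
#define W_DMEI2   p[34]
#define B_DPAT    p[35]
#define B_DTOR    p[36]
#define K_SPHE    p[37]
#define J_PHE     p[38]
#define H_PHE     p[39]
#define J_PHEMEI2 p[40]
#define KD_PHE    p[41]
#define PHES_CL   p[42]
#define K_SPM     p[43]
#define J_PM      p[44]
#define H_PM      p[45]
#define KD_PM     p[46]
#define K_SMEI3   p[47]
#define KD_MEI3   p[48]
#define K_AS      p[49]
#define K_DIS     p[50]
#define KD_CPX    p[51]
#define PAT1_T    p[52]
#define J_IPHE    p[53]
#define C_CDK     p[54]
#define J_CDK     p[55]
#define CDK_CL    p[56]

/* shared meiosis derivative block; y[0..7], dy[0..7] */
static void meiosis_block(const double *p, const double *y, double *dy,
                          double tor2, double pka, double phe_on, double mpf) {
  double ste11c = y[0], ste11n = y[1], mei2a = y[2], mei2p = y[3];
  double phes = y[4], mat1pm = y[5], mei3 = y[6], cpx = y[7];
  double phes_eff = (PHES_CL > 0) ? PHES_CL : phes;
  double mei2t = mei2a + mei2p;
  double tf = STE11_ACT * ste11n;
  double pat_free = PAT1_T - cpx; if (pat_free < 0) pat_free = 0;
  double pat_act = pat_free / (1.0 + phes_eff / J_IPHE);
  double rst2 = 1.0 / (1.0 + pow(pka / J_RST2, H_RST2));
  double rpol = A_RPOL + K_RPOL * hillf(mei2t, J_RPOL, H_RPOL);
  double cdk_term = (CDK_CL > 0) ? CDK_CL : C_CDK * (mpf / J_CDK) * (mpf / J_CDK);
  double vcdk = 1.0 / (1.0 + cdk_term);
  double syn_ste11 = KS_STE110 + rpol * vcdk *
    (KS_STE11R * rst2 + KS_STE11A * hillf(tf, K_MSTE11, HS));
  double pat_imp = (PAT_CLAMP > 0) ? PAT_CLAMP : B_IMPAT * pow(pat_act, H_IMPAT);
  double imp = K_IMSTE11 * (1.0 + B_IMPHE * phes_eff + IMP_BOOST) /
    (1.0 + pat_imp + B_IMNUT * tor2 * pka);
  double expo = K_EXSTE11 * (1.0 + B_EXTOR * tor2);
  double syn_mei2 = KS_MEI2 * (A_MEI2 + hillf(tf, J_SMEI2, H_SMEI2)) + KS_MEI2C;
  double vp = (KP_PAT * pat_act + KP_TOR * tor2) * mei2a / (J_PMEI2 + mei2a);
  double vdp = KDP_MEI2 * mei2p / (J_DPMEI2 + mei2p);
  double deg_p = KD_MEI2P * (W_DMEI2 + B_DPAT * pat_act + B_DTOR * tor2);
  double assoc = K_AS * mei3 * pat_free;

  dy[0] = syn_ste11 - imp * ste11c + expo * ste11n - KD_STE11 * ste11c;
  dy[1] = imp * ste11c - expo * ste11n - KD_STE11 * ste11n;
  dy[2] = syn_mei2 - vp + vdp - KD_MEI2A * mei2a;
  dy[3] = vp - vdp - deg_p * mei2p;
  dy[4] = (PHES_CL > 0) ? 0.0 :
    phe_on * K_SPHE * hillf(tf, J_PHE, H_PHE) *
      hillf(mei2t + 1e-12, J_PHEMEI2, 2.0) - KD_PHE * phes;
  dy[5] = K_SPM * hillf(tf, J_PM, H_PM) - KD_PM * mat1pm;
  dy[6] = K_SMEI3 * mat1pm - KD_MEI3 * mei3 - assoc + K_DIS * cpx;
  dy[7] = assoc - K_DIS * cpx - KD_CPX * cpx;
}

void derivs_meiosis(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip) {
  const double *p = pm_mei;
  meiosis_block(p, y, ydot, p[57], p[58], p[59], p[60]);
}

/* cell-cycle parameter indices, offset from the meiosis block */
#define Q(i) q[(i)]
/* order of .cellcycle_defaults:
   0 k1, 1 k2p, 2 k2pp, 3 k2ppp, 4 k3p, 5 k3pp, 6 j3, 7 k4p, 8 k4, 9 j4,
   10 k5p, 11 k5pp, 12 j5, 13 k6, 14 k7, 15 k8, 16 j7, 17 j8, 18 k9, 19 k10,
   20 j9, 21 j10, 22 k11, 23 k12, 24 k12p, 25 k12pp, 26 kdiss, 27 k13, 28 k14,
   29 k15, 30 k16p, 31 k16pp, 32 j15, 33 j16, 34 vawee, 35 viwee, 36 jawee,
   37 jiwee, 38 va25, 39 vi25, 40 ja25, 41 ji25, 42 kweep, 43 kwepp, 44 k25p,
   45 k25pp, 46 mu, 47 kfill_n, 48 kdn, 49 ki_igo, 50 kd_igo, 51 j_igo,
   52 c_pherum1, 53 c_b55g1, 54 div_hi, 55 div_lo */

double cc_mpf(const double *q, double cdc13t, double prempf, double rum1t) {
  double kdiss = Q(26), sig, trim, mpf;
  if (cdc13t <= 1e-12) return 0.0;
  sig = cdc13t + rum1t + kdiss;
  trim = 2.0 * cdc13t * rum1t / (sig + sqrt(sig * sig - 4.0 * cdc13t * rum1t));
  mpf = (cdc13t - prempf) * (cdc13t - trim) / cdc13t;
  return (mpf > 0) ? mpf : 0.0;
}

void derivs_integrated(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip) {
  const double *p = pm_int;        /* meiosis block: indices 0..56 */
  const double *q = pm_int + 57;   /* cell-cycle block: 55 entries  */
  double tor2 = pm_int[113], pka = pm_int[114], phe_on = pm_int[115];
  double cdc13t = y[8], prempf = y[9], ste9 = y[10], slp1t = y[11];
  double slp1 = y[12], iep = y[13], rum1t = y[14], sk = y[15];
  double mass = y[16], npool = y[17], igo1p = y[18];
  double mpf = cc_mpf(q, cdc13t, prempf, rum1t);
  double ext = tor2 * pka;
  double nut = ext + (1.0 - ext) * npool;
  double b55 = 1.0 / (1.0 + igo1p / Q(51));
  double kwee = Q(42) + (Q(43) - Q(42)) * gk(Q(34) * b55, Q(35) * mpf, Q(36), Q(37));
  double k25 = Q(44) + (Q(45) - Q(44)) * gk(Q(38) * mpf, Q(39) * b55, Q(40), Q(41));
  double kdeg = Q(1) + Q(2) * ste9 + Q(3) * slp1;
  double phes_eff = (p[42] > 0) ? p[42] : y[4];
  double fphe = 1.0 / (1.0 + Q(52) * phes_eff);
  double eff = 1.0 + Q(53) * (1.0 - b55);
  double m4, tfsk;

  meiosis_block(p, y, ydot, tor2, pka, phe_on, mpf);

  ydot[8] = Q(0) * mass * nut - kdeg * cdc13t;
  ydot[9] = kwee * (cdc13t - prempf) - k25 * prempf - kdeg * prempf;
  ydot[10] = (Q(4) + Q(5) * slp1) * (1.0 - ste9) / (Q(6) + 1.0 - ste9) -
    (Q(7) * sk * eff + Q(8) * mpf) * ste9 / (Q(9) + ste9);
  m4 = pow(mpf, 4.0);
  ydot[11] = Q(10) + Q(11) * m4 / (pow(Q(12), 4.0) + m4) - Q(13) * slp1t;
  ydot[12] = Q(14) * iep * (slp1t - slp1) / (Q(16) + slp1t - slp1) -
    Q(15) * slp1 / (Q(17) + slp1) - Q(13) * slp1;
  ydot[13] = Q(18) * mpf * (1.0 - iep) / (Q(20) + 1.0 - iep) -
    Q(19) * iep / (Q(21) + iep);
  ydot[14] = Q(22) - (Q(23) + Q(24) * sk * eff + Q(25) * mpf) * fphe * rum1t;
  tfsk = gk(Q(29) * mass * nut, Q(30) + Q(31) * mpf, Q(32), Q(33));
  ydot[15] = Q(27) * tfsk - Q(28) * sk;
  ydot[16] = Q(46) * ext * mass;
  ydot[17] = Q(47) * ext * (1.0 - npool) - Q(48) * (1.0 - ext) * npool;
  ydot[18] = Q(49) * (1.0 - ext) * (1.0 - igo1p) - Q(50) * igo1p;

  if (*neq >= 19 && yout && ip && ip[0] >= 1) yout[0] = mpf;
}

static const R_CMethodDef cMethods[] = {
  {"derivs_meiosis", (DL_FUNC) &derivs_meiosis, 6, NULL},
  {"derivs_integrated", (DL_FUNC) &derivs_integrated, 6, NULL},
  {NULL, NULL, 0, NULL}
};

void R_init_meioswitch(DllInfo *info) {
  R_registerRoutines(info, cMethods, NULL, NULL, NULL);
  R_useDynamicSymbols(info, TRUE);
}
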