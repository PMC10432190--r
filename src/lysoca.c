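/* Compiled right-hand side of the lysosome-extended mouse ventricular
 * myocyte model, in the deSolve compiled-code convention.
 *
 * Units: mV, ms, mM, pL, pA/pF.  The parameter vector layout must match
 * .lysoca_parm_names on the R side; the reference R implementation of the
 * same equations lives in R/rhs.R and the two are tested for equality.
 *
 * Calcium machinery follows the Shannon-style compartmental architecture
 * (junctional cleft / subsarcolemmal rim / bulk cytosol / SR), with a
 * luminal-calcium-gated four-state RyR, forward/reverse SERCA, explicit
 * membrane and cytosolic buffers, and the lysosomal pool (CLC uptake,
 * TPC2 release, NAADP-gated open probability) coupled to the junctional
 * and cytosolic spaces.
 */
#include <R.h>
#include <math.h>

#define NPARMS 99

/* parameter indices (order = .lysoca_parm_names in R/parameters.R) */
enum {
  iCmem, iVmyo, iVsr, iVsl, iVjunc, iVls,
  iTemp, iCao, iNao, iKo, iKi,
  iPCa, ikonfca, ikofffca,
  igto, igkr, igsus, igk1,
  iIbarNCX, iKmCai, iKmCao, iKmNai, iKmNao, iksat, ieta, iKdact,
  igcab, iibarnak, iKmNaip, iKmKo, ignab,
  iVmaxserca, iKmf, iKmr, ihillserca,
  iks, ikoCa, ikom, ikiCa, ikim, iec50SR, iMaxSR, iMinSR, ikleak,
  iJjsl, iJsli,
  iBmaxTnC, ikonTnC, ikoffTnC,
  iBmaxCaM, ikonCaM, ikoffCaM,
  iBmaxSRB, ikonSRB, ikoffSRB,
  iBmaxSLL, iBmaxSLLj, ikonsll, ikoffsll,
  iBmaxSLH, iBmaxSLHj, ikonslh, ikoffslh,
  iBmaxcsqn, ikoncsqn, ikoffcsqn,
  ijclc, ijtpc, ijclcleak, ijtpcleak,
  iPOmax, iPOmean, iPOsd,
  iJlsj, iJlsi, inaadp,
  iuptake_block, irelease_block,
  iiso_ltcc, iiso_ryr, iiso_serca_kmf, iiso_kmnai, iiso_cdi,
  isc_ical, isc_ryr, isc_jclc, isc_jtpc, isc_jclcleak, isc_jtpcleak,
  isc_ncx, isc_serca, isc_to, isc_kr,
  istim_amp, istim_dur, ip1, in1, ip2, in2
};

static double parms[NPARMS];

static const double Frdy = 96485.0;
static const double Rgas = 8314.0;

void lysoca_initmod(void (* odeparms)(int *, double *))
{
  int n = NPARMS;
  odeparms(&n, parms);
}

/* rectangular stimulus from the pacing-segment parameters */
static double stim_current(double t)
{
  double p1 = parms[ip1], p2 = parms[ip2];
  double n1 = parms[in1], n2 = parms[in2];
  double dur = parms[istim_dur];
  double T1 = n1 * p1;
  double phase;
  if (t < T1)
    phase = fmod(t, p1);
  else if (t < T1 + n2 * p2)
    phase = fmod(t - T1, p2);
  else
    return 0.0;
  return (phase < dur) ? -parms[istim_amp] : 0.0;
}

void lysoca_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
  double V = y[0], d = y[1], f = y[2], fcab = y[3];
  double xto = y[4], yto = y[5], xkr = y[6];
  double rR = y[7], rO = y[8], rI = y[9];
  double Caj = y[10], Casl = y[11], Cai = y[12], Casr = y[13], Cals = y[14];
  double Nai = y[15];
  double TnCL = y[16], CaM = y[17], SRB = y[18];
  double SLLj = y[19], SLHj = y[20], SLLsl = y[21], SLHsl = y[22];
  double Csqn = y[23];

  double Cmem = parms[iCmem];
  double Vmyo = parms[iVmyo], Vsr = parms[iVsr], Vsl = parms[iVsl];
  double Vjunc = parms[iVjunc], Vls = parms[iVls];
  double Cao = parms[iCao], Nao = parms[iNao];
  double Ko = parms[iKo], Ki = parms[iKi];

  double FoRT = Frdy / (Rgas * parms[iTemp]);
  double EK = log(Ko / Ki) / FoRT;
  double ENa = log(Nao / Nai) / FoRT;

  /* ---- L-type Ca current (GHK driving force, junctional cleft) ---- */
  double vs = V + 14.5;
  double dss = 1.0 / (1.0 + exp(-vs / 6.0));
  double taud = (fabs(vs) < 1e-4)
    ? dss / (0.035 * 6.0)
    : dss * (1.0 - exp(-vs / 6.0)) / (0.035 * vs);
  double fss = 1.0 / (1.0 + exp((V + 35.06) / 3.6))
    + 0.6 / (1.0 + exp((50.0 - V) / 20.0));
  if (fss > 1.0) fss = 1.0;
  double tauf = 1.0 / (0.0197 * exp(-pow(0.0337 * vs, 2.0)) + 0.02);
  double dfcab = parms[ikonfca] * parms[iiso_cdi] * Caj * (1.0 - fcab)
    - parms[ikofffca] * fcab;
  double z = 2.0 * V * FoRT;
  if (fabs(z) < 1e-6) z = (z >= 0.0) ? 1e-6 : -1e-6;
  double ibarca = parms[iPCa] * parms[iiso_ltcc] * parms[isc_ical]
    * 2.0 * z * Frdy * (0.341 * Caj * exp(z) - 0.341 * Cao) / (exp(z) - 1.0);
  double ICaL = ibarca * d * f * (1.0 - fcab);

  /* ---- K currents (mouse-like repolarisation) ---- */
  double Ito = parms[igto] * parms[isc_to] * xto * yto * (V - EK);
  double xtoss = 1.0 / (1.0 + exp(-(V + 5.0) / 13.0));
  double tauxto = 1.5;
  double ytoss = 1.0 / (1.0 + exp((V + 38.0) / 5.0));
  double tauyto = 8.0 + 40.0 / (1.0 + exp((V + 35.0) / 6.0));

  double rkr = 1.0 / (1.0 + exp((V + 74.0) / 24.0));
  double IKr = parms[igkr] * parms[isc_kr] * xkr * rkr * (V - EK);
  double xkrss = 1.0 / (1.0 + exp(-(V + 10.0) / 5.0));
  double tauxkr = 50.0;

  double Isus = parms[igsus] * (V - EK) / (1.0 + exp(-(V + 15.0) / 8.0));

  double aK1 = 1.02 / (1.0 + exp(0.2385 * (V - EK - 59.215)));
  double bK1 = (0.49124 * exp(0.08032 * (V - EK + 5.476))
                + exp(0.06175 * (V - EK - 594.31)))
    / (1.0 + exp(-0.5143 * (V - EK + 4.753)));
  double IK1 = parms[igk1] * sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);

  /* ---- Na/Ca exchanger (subsarcolemmal) ---- */
  double Ka = 1.0 / (1.0 + pow(parms[iKdact] / Casl, 2.0));
  double s1 = exp(parms[ieta] * V * FoRT) * pow(Nai, 3.0) * Cao;
  double s2 = exp((parms[ieta] - 1.0) * V * FoRT) * pow(Nao, 3.0) * Casl;
  double s3 = parms[iKmCai] * pow(Nao, 3.0)
      * (1.0 + pow(Nai / parms[iKmNai], 3.0))
    + pow(parms[iKmNao], 3.0) * Casl * (1.0 + Casl / parms[iKmCai])
    + parms[iKmCao] * pow(Nai, 3.0)
    + pow(Nai, 3.0) * Cao + pow(Nao, 3.0) * Casl;
  double INCX = parms[iIbarNCX] * parms[isc_ncx] * Ka * (s1 - s2)
    / (s3 * (1.0 + parms[iksat] * exp((parms[ieta] - 1.0) * V * FoRT)));

  /* ---- Na/K pump, backgrounds ---- */
  double sigma = (exp(Nao / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V * FoRT)
                       + 0.0365 * sigma * exp(-V * FoRT));
  double INaK = parms[iibarnak] * fnak * Ko / (Ko + parms[iKmKo])
    / (1.0 + pow(parms[iKmNaip] * parms[iiso_kmnai] / Nai, 4.0));
  double ICab = parms[igcab] * 2.0 * z * Frdy
    * (0.341 * Casl * exp(z) - 0.341 * Cao) / (exp(z) - 1.0);
  double INab = parms[ignab] * (V - ENa);

  /* ---- RyR (luminal-Ca gated 4-state) ---- */
  double kCaSR = parms[iMaxSR] - (parms[iMaxSR] - parms[iMinSR])
    / (1.0 + pow(parms[iec50SR] / Casr, 2.5));
  double koSRCa = parms[ikoCa] * parms[iiso_ryr] / kCaSR;
  double kiSRCa = parms[ikiCa] * kCaSR;
  double RI = 1.0 - rR - rO - rI;
  double drR = (parms[ikim] * RI - kiSRCa * Caj * rR)
    - (koSRCa * Caj * Caj * rR - parms[ikom] * rO);
  double drO = (koSRCa * Caj * Caj * rR - parms[ikom] * rO)
    - (kiSRCa * Caj * rO - parms[ikim] * rI);
  double drI = (kiSRCa * Caj * rO - parms[ikim] * rI)
    - (parms[ikom] * rI - koSRCa * Caj * Caj * RI);
  double JRyR = parms[iks] * parms[isc_ryr] * rO * (Casr - Caj);  /* SR vol units */
  double Jleak = parms[ikleak] * (Casr - Caj);                    /* cyt vol units */

  /* ---- SERCA (forward/reverse) ---- */
  double Kmf = parms[iKmf] * parms[iiso_serca_kmf];
  double hc = parms[ihillserca];
  double fw = pow(Cai / Kmf, hc), rv = pow(Casr / parms[iKmr], hc);
  double JSERCA = parms[iVmaxserca] * parms[isc_serca] * (fw - rv)
    / (1.0 + fw + rv);                                            /* cyt vol units */

  /* ---- lysosome ---- */
  double lg = log10(parms[inaadp] / parms[iPOmean]);
  double PO = parms[iPOmax]
    * exp(-lg * lg / (2.0 * parms[iPOsd] * parms[iPOsd]));
  double gup = parms[ijclc] * parms[isc_jclc] * PO
    + parms[ijclcleak] * parms[isc_jclcleak];
  double grel = parms[ijtpc] * parms[isc_jtpc] * PO
    + parms[ijtpcleak] * parms[isc_jtpcleak];
  double Jlsup = (parms[iuptake_block] > 0.5) ? 0.0 : gup * (Cals - Caj);
  double Jlsrel = (parms[irelease_block] > 0.5) ? 0.0 : grel * (Cals - Cai);
  double Jlsj = parms[iJlsj], Jlsi = parms[iJlsi];

  /* ---- buffers ---- */
  double dTnCL = parms[ikonTnC] * Cai * (parms[iBmaxTnC] - TnCL)
    - parms[ikoffTnC] * TnCL;
  double dCaM = parms[ikonCaM] * Cai * (parms[iBmaxCaM] - CaM)
    - parms[ikoffCaM] * CaM;
  double dSRB = parms[ikonSRB] * Cai * (parms[iBmaxSRB] - SRB)
    - parms[ikoffSRB] * SRB;
  double JCaBi = dTnCL + dCaM + dSRB;
  double BmaxSLLj = parms[iBmaxSLLj] * Vmyo / Vjunc;
  double BmaxSLHj = parms[iBmaxSLHj] * Vmyo / Vjunc;
  double BmaxSLLsl = parms[iBmaxSLL] * Vmyo / Vsl;
  double BmaxSLHsl = parms[iBmaxSLH] * Vmyo / Vsl;
  double dSLLj = parms[ikonsll] * Caj * (BmaxSLLj - SLLj)
    - parms[ikoffsll] * SLLj;
  double dSLHj = parms[ikonslh] * Caj * (BmaxSLHj - SLHj)
    - parms[ikoffslh] * SLHj;
  double dSLLsl = parms[ikonsll] * Casl * (BmaxSLLsl - SLLsl)
    - parms[ikoffsll] * SLLsl;
  double dSLHsl = parms[ikonslh] * Casl * (BmaxSLHsl - SLHsl)
    - parms[ikoffslh] * SLHsl;
  double JCaBj = dSLLj + dSLHj;
  double JCaBsl = dSLLsl + dSLHsl;
  double JCsqn = parms[ikoncsqn] * Casr * (parms[iBmaxcsqn] - Csqn)
    - parms[ikoffcsqn] * Csqn;

  /* ---- conservation ---- */
  double convj = Cmem / (2.0 * Frdy * Vjunc);
  double convsl = Cmem / (2.0 * Frdy * Vsl);
  double convNa = Cmem / (Frdy * Vmyo);
  double Istim = stim_current(*t);

  ydot[0] = -(ICaL + Ito + IKr + Isus + IK1 + INCX + INaK + ICab + INab + Istim);
  ydot[1] = (dss - d) / taud;
  ydot[2] = (fss - f) / tauf;
  ydot[3] = dfcab;
  ydot[4] = (xtoss - xto) / tauxto;
  ydot[5] = (ytoss - yto) / tauyto;
  ydot[6] = (xkrss - xkr) / tauxkr;
  ydot[7] = drR;
  ydot[8] = drO;
  ydot[9] = drI;
  ydot[10] = parms[iJjsl] * (Casl - Caj) / Vjunc - ICaL * convj - JCaBj
    + JRyR * Vsr / Vjunc + Jleak * Vmyo / Vjunc
    + Jlsup * Vls / Vjunc + Jlsj * (Cals - Caj) / Vjunc;
  ydot[11] = parms[iJjsl] * (Caj - Casl) / Vsl
    + parms[iJsli] * (Cai - Casl) / Vsl - JCaBsl
    + 2.0 * convsl * INCX - convsl * ICab;
  ydot[12] = parms[iJsli] * (Casl - Cai) / Vmyo - JSERCA - JCaBi
    + Jlsrel * Vls / Vmyo + Jlsi * (Cals - Cai) / Vmyo;
  ydot[13] = JSERCA * Vmyo / Vsr - JRyR - Jleak * Vmyo / Vsr - JCsqn;
  ydot[14] = Jlsj * (Caj - Cals) / Vls - Jlsup
    + Jlsi * (Cai - Cals) / Vls - Jlsrel;
  ydot[15] = -convNa * (INab + 3.0 * INCX + 3.0 * INaK);
  ydot[16] = dTnCL;
  ydot[17] = dCaM;
  ydot[18] = dSRB;
  ydot[19] = dSLLj;
  ydot[20] = dSLHj;
  ydot[21] = dSLLsl;
  ydot[22] = dSLHsl;
  ydot[23] = JCsqn;

  if (ip[0] >= 7) {
    yout[0] = JSERCA;
    yout[1] = JRyR;
    yout[2] = Jlsup;
    yout[3] = Jlsrel;
    yout[4] = PO;
    yout[5] = INCX;
    yout[6] = Istim;
  }
}
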