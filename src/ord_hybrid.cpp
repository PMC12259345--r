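// Compiled twin of R/model-ord-hybrid.R plus the adaptive Rush-Larsen
// integrator for coupled cell collections. The R implementation is the
// readable reference; tests assert exact agreement of the derivatives.
//
// State layout (38 per cell), 0-based:
//   0 v, 1 nai, 2 nass, 3 ki, 4 kss, 5 cai, 6 cass, 7 cansr, 8 cajsr,
//   9..36 relaxation-form states (m h j mL hL hLp a iF iS ap iFp iSp d ff fs
//   fcaf fcas jca nca ffp fcafp xrf xrs xs1 xs2 xk1 Jrelnp Jrelp), 37 CaMKt.
// Parameter layout (20): gNa gNaL pNaK pNab gKr gKs gto gK1 gKb pCaL gNaCa
//   gpCa pbCa Jrel Jup BmaxSL BmaxSR BmaxCMDN BmaxCSQN BmaxTRPN.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NS = 38;     // states per cell
static const int NG = 28;     // relaxation-form states, indices 9..36
static const int GOFF = 9;    // first gate index
static const int NP = 20;     // scalable parameters

static inline double expm1_safe(double x) {
  double y = std::expm1(x);
  if (std::fabs(y) < 1e-10) y = (y >= 0.0) ? 1e-10 : -1e-10;
  return y;
}

// full right-hand side for one cell; fills deriv[NS], ginf[NG], gtau[NG]
// and returns Iion (A/F, excluding istim and ip)
static double ord_rhs(const double *s, const double *p, double istim,
                      double ip, double *deriv, double *ginf, double *gtau) {
  const double R = 8314.0, Temp = 310.0, F = 96485.0;
  const double nao = 140.0, cao = 1.8, ko = 5.4;
  const double pi0 = 3.14;
  const double L = 0.01, rad = 0.0011;
  const double vcell = 1000.0 * pi0 * rad * rad * L;
  const double Ageo = 2.0 * pi0 * rad * rad + 2.0 * pi0 * rad * L;
  const double Acap = 2.0 * Ageo;
  const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell;
  const double vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

  const double v = s[0], nai = s[1], nass = s[2], ki = s[3], kss = s[4];
  const double cai = s[5], cass = s[6], cansr = s[7], cajsr = s[8];
  const double m = s[9], h = s[10], j = s[11], mL = s[12], hL = s[13],
               hLp = s[14], a = s[15], iF = s[16], iS = s[17], ap = s[18],
               iFp = s[19], iSp = s[20], d = s[21], ff = s[22], fs = s[23],
               fcaf = s[24], fcas = s[25], jca = s[26], nca = s[27],
               ffp = s[28], fcafp = s[29], xrf = s[30], xrs = s[31],
               xs1 = s[32], xs2 = s[33], xk1 = s[34], Jrelnp = s[35],
               Jrelp = s[36], CaMKt = s[37];

  const double gNa = p[0], gNaL = p[1], pNaK = p[2], pNab = p[3], gKr = p[4],
               gKs = p[5], gto = p[6], gK1 = p[7], gKb = p[8], pCaL = p[9],
               gNaCa = p[10], gpCa = p[11], pbCa = p[12], JrelSc = p[13],
               JupB = p[14], BmaxSL = p[15], BmaxSR = p[16],
               BmaxCMDN = p[17], BmaxCSQN = p[18], BmaxTRPN = p[19];

  const double vfrt = v * F / (R * Temp);
  const double vffrt = v * F * F / (R * Temp);

  // CaMK
  const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
  const double CaMKo = 0.05, KmCaM = 0.0015;
  const double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
  const double CaMKa = CaMKb + CaMKt;
  const double dCaMKt = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;
  const double fphos = 1.0 / (1.0 + KmCaMK / CaMKa);

  const double ENa = (R * Temp / F) * std::log(nao / nai);
  const double EK = (R * Temp / F) * std::log(ko / ki);
  const double PKNa = 0.01833;
  const double EKs = (R * Temp / F) *
      std::log((ko + PKNa * nao) / (ki + PKNa * nai));

  // fast INa (ten Tusscher)
  double q = 1.0 + std::exp((-56.86 - v) / 9.03);
  const double minf = 1.0 / (q * q);
  const double am = 1.0 / (1.0 + std::exp((-60.0 - v) / 5.0));
  const double bm = 0.1 / (1.0 + std::exp((v + 35.0) / 5.0)) +
                    0.1 / (1.0 + std::exp((v - 50.0) / 200.0));
  const double taum = am * bm;
  q = 1.0 + std::exp((v + 71.55) / 7.43);
  const double hinf = 1.0 / (q * q);
  double ah, bh, aj, bj;
  if (v >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + std::exp(-(v + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.6 * std::exp(0.057 * v) / (1.0 + std::exp(-0.1 * (v + 32.0)));
  } else {
    ah = 0.057 * std::exp(-(v + 80.0) / 6.8);
    bh = 2.7 * std::exp(0.079 * v) + 3.1e5 * std::exp(0.3485 * v);
    aj = (-2.5428e4 * std::exp(0.2444 * v) -
          6.948e-6 * std::exp(-0.04391 * v)) * (v + 37.78) /
         (1.0 + std::exp(0.311 * (v + 79.23)));
    bj = 0.02424 * std::exp(-0.01052 * v) /
         (1.0 + std::exp(-0.1378 * (v + 40.14)));
  }
  const double tauh = 1.0 / (ah + bh);
  const double jinf = hinf;
  const double tauj = 1.0 / (aj + bj);
  const double INa = gNa * m * m * m * h * j * (v - ENa);

  // late INaL
  const double mLss = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));
  const double tmL = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                            8.552 * std::exp(-(v + 77.42) / 5.955));
  const double hLss = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  const double thL = 200.0;
  const double hLssp = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  const double thLp = 3.0 * thL;
  const double INaL = gNaL * (v - ENa) * mL * ((1.0 - fphos) * hL + fphos * hLp);

  // Ito
  const double ass = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));
  const double ta = 1.0515 /
      (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
       3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
  const double iss = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  const double tiF = 4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                                    0.08004 * std::exp((v + 50.0) / 16.59));
  const double tiS = 23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                                    1.780e-8 * std::exp((v + 114.1) / 8.079));
  const double AiF = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  const double AiS = 1.0 - AiF;
  const double i_to = AiF * iF + AiS * iS;
  const double assp = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));
  const double dti_develop = 1.354 +
      1e-4 / (std::exp((v - 167.4) / 15.89) + std::exp(-(v - 12.23) / 0.2154));
  const double dti_recover = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
  const double tiFp = dti_develop * dti_recover * tiF;
  const double tiSp = dti_develop * dti_recover * tiS;
  const double ip_to = AiF * iFp + AiS * iSp;
  const double Ito = gto * (v - EK) *
      ((1.0 - fphos) * a * i_to + fphos * ap * ip_to);

  // ICaL / ICaNa / ICaK
  const double dss = 1.0 / (1.0 + std::exp(-(v + 3.94) / 4.23));
  const double td = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) +
                                 std::exp(0.09 * (v + 14.0)));
  const double fss = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  const double tff = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                                  0.0045 * std::exp((v + 20.0) / 10.0));
  const double tfs = 1000.0 + 1.0 / (3.5e-5 * std::exp(-(v + 5.0) / 4.0) +
                                     3.5e-5 * std::exp((v + 5.0) / 6.0));
  const double Aff = 0.6, Afs = 0.4;
  const double f = Aff * ff + Afs * fs;
  const double fcass_ = fss;
  const double tfcaf = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                                    0.04 * std::exp((v - 4.0) / 7.0));
  const double tfcas = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                                      0.00012 * std::exp(v / 7.0));
  const double Afcaf = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  const double Afcas = 1.0 - Afcaf;
  const double fca = Afcaf * fcaf + Afcas * fcas;
  const double tjca = 75.0;
  const double tffp = 2.5 * tff;
  const double f_p = Aff * ffp + Afs * fs;
  const double tfcafp = 2.5 * tfcaf;
  const double fca_p = Afcaf * fcafp + Afcas * fcas;
  const double Kmn = 0.002, k2n = 1000.0;
  const double km2n = jca * 1.0;
  double t4 = 1.0 + Kmn / cass; t4 = t4 * t4 * t4 * t4;
  const double anca = 1.0 / (k2n / km2n + t4);
  const double PhiCaL = 4.0 * vffrt * (cass * std::exp(2.0 * vfrt) -
      0.341 * cao) / expm1_safe(2.0 * vfrt);
  const double PhiCaNa = vffrt * (0.75 * nass * std::exp(vfrt) - 0.75 * nao) /
      expm1_safe(vfrt);
  const double PhiCaK = vffrt * (0.75 * kss * std::exp(vfrt) - 0.75 * ko) /
      expm1_safe(vfrt);
  const double PCa = pCaL, PCap = 1.1 * PCa;
  const double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
  const double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
  const double gate_np = f * (1.0 - nca) + jca * fca * nca;
  const double gate_p = f_p * (1.0 - nca) + jca * fca_p * nca;
  const double ICaL = (1.0 - fphos) * PCa * PhiCaL * d * gate_np +
                      fphos * PCap * PhiCaL * d * gate_p;
  const double ICaNa = (1.0 - fphos) * PCaNa * PhiCaNa * d * gate_np +
                       fphos * PCaNap * PhiCaNa * d * gate_p;
  const double ICaK = (1.0 - fphos) * PCaK * PhiCaK * d * gate_np +
                      fphos * PCaKp * PhiCaK * d * gate_p;

  // IKr
  const double xrss = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  const double txrf = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
      4.123e-5 * std::exp(-(v - 47.78) / 20.38));
  const double txrs = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.7) / 7.355) +
      1.128e-5 * std::exp(-(v - 29.74) / 25.94));
  const double Axrf = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
  const double Axrs = 1.0 - Axrf;
  const double xr = Axrf * xrf + Axrs * xrs;
  const double rkr = 1.0 / ((1.0 + std::exp((v + 55.0) / 75.0)) *
                            (1.0 + std::exp((v - 10.0) / 30.0)));
  const double IKr = gKr * std::sqrt(ko / 5.4) * xr * rkr * (v - EK);

  // IKs
  const double xs1ss = 1.0 / (1.0 + std::exp(-(v + 11.6) / 8.932));
  const double txs1 = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.8) +
      0.001292 * std::exp(-(v + 210.0) / 230.0));
  const double xs2ss = xs1ss;
  const double txs2 = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                             0.0193 * std::exp(-(v + 66.54) / 31.0));
  const double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  const double IKs = gKs * KsCa * xs1 * xs2 * (v - EKs);

  // IK1
  const double xk1ss = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                             (1.5692 * ko + 3.8115)));
  const double txk1 = 122.2 / (std::exp(-(v + 127.2) / 20.36) +
                               std::exp((v + 236.8) / 69.33));
  const double rk1 = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));
  const double IK1 = gK1 * std::sqrt(ko) * rk1 * xk1 * (v - EK);

  // INaCa
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
  const double wna = 6e4, wca = 6e4, wnaca = 5e3;
  const double kcaon = 1.5e6, kcaoff = 5e3;
  const double qna = 0.5224, qca = 0.167;
  const double hca = std::exp(qca * vfrt), hna = std::exp(qna * vfrt);
  const double KmCaAct = 150e-6;
  double INaCa_i = 0.0, INaCa_ss = 0.0;
  for (int comp = 0; comp < 2; comp++) {
    const double na = comp == 0 ? nai : nass;
    const double ca = comp == 0 ? cai : cass;
    const double h1 = 1.0 + na / kna3 * (1.0 + hna);
    const double h2 = (na * hna) / (kna3 * h1);
    const double h3 = 1.0 / h1;
    const double h4 = 1.0 + na / kna1 * (1.0 + na / kna2);
    const double h5 = na * na / (h4 * kna1 * kna2);
    const double h6 = 1.0 / h4;
    const double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    const double h8 = nao / (kna3 * hna * h7);
    const double h9 = 1.0 / h7;
    const double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    const double h11 = nao * nao / (h10 * kna1 * kna2);
    const double h12 = 1.0 / h10;
    const double k1 = h12 * cao * kcaon;
    const double k2 = kcaoff;
    const double k3p = h9 * wca;
    const double k3pp = h8 * wnaca;
    const double k3 = k3p + k3pp;
    const double k4p = h3 * wca / hca;
    const double k4pp = h2 * wnaca;
    const double k4 = k4p + k4pp;
    const double k5 = kcaoff;
    const double k6 = h6 * ca * kcaon;
    const double k7 = h5 * h2 * wna;
    const double k8 = h8 * h11 * wna;
    const double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    const double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    const double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    const double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    const double xs = x1 + x2 + x3 + x4;
    const double E1 = x1 / xs, E2 = x2 / xs, E3 = x3 / xs, E4 = x4 / xs;
    const double allo = 1.0 / (1.0 + (KmCaAct / ca) * (KmCaAct / ca));
    const double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    const double JncxCa = E2 * k2 - E1 * k1;
    const double I = allo * (1.0 * JncxNa + 2.0 * JncxCa);
    if (comp == 0) INaCa_i = 0.8 * gNaCa * I; else INaCa_ss = 0.2 * gNaCa * I;
  }

  // INaK
  const double k1p_ = 949.5, k1m = 182.4, k2p_ = 687.2, k2m = 39.4;
  const double k3p_ = 1899.0, k3m = 79300.0, k4p_ = 639.0, k4m = 40.0;
  const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.155;
  const double Knai = Knai0 * std::exp(delta * vfrt / 3.0);
  const double Knao = Knao0 * std::exp((1.0 - delta) * vfrt / 3.0);
  const double Kki = 0.5, Kko = 0.3582;
  const double MgADP = 0.05, MgATP = 9.8, Kmgatp = 1.698e-7;
  const double Hc = 1e-7, eP = 4.2, Khp = 1.698e-7, Knap = 224.0, Kxkur = 292.0;
  const double P = eP / (1.0 + Hc / Khp + nai / Knap + ki / Kxkur);
  double t1 = 1.0 + nai / Knai, t2 = 1.0 + ki / Kki;
  const double di = t1 * t1 * t1 + t2 * t2 - 1.0;
  t1 = 1.0 + nao / Knao; t2 = 1.0 + ko / Kko;
  const double do_ = t1 * t1 * t1 + t2 * t2 - 1.0;
  const double na_r = nai / Knai, ko_r = ko / Kko, nao_r = nao / Knao,
               ki_r = ki / Kki;
  const double a1 = k1p_ * (na_r * na_r * na_r) / di;
  const double b1 = k1m * MgADP;
  const double a2 = k2p_;
  const double b2 = k2m * (nao_r * nao_r * nao_r) / do_;
  const double a3 = k3p_ * (ko_r * ko_r) / do_;
  const double b3 = k3m * P * Hc / (1.0 + MgATP / Kmgatp);
  const double a4 = k4p_ * MgATP / Kmgatp / (1.0 + MgATP / Kmgatp);
  const double b4 = k4m * (ki_r * ki_r) / di;
  const double y1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
  const double y2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
  const double y3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
  const double y4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
  const double ys = y1 + y2 + y3 + y4;
  const double E1n = y1 / ys, E2n = y2 / ys, E3n = y3 / ys, E4n = y4 / ys;
  const double JnakNa = 3.0 * (E1n * a3 - E2n * b3);
  const double JnakK = 2.0 * (E4n * b1 - E3n * a1);
  const double INaK = pNaK * (JnakNa + JnakK);

  // background / pump
  const double xkb = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  const double IKb = gKb * xkb * (v - EK);
  const double INab = pNab * vffrt * (nai * std::exp(vfrt) - nao) /
      expm1_safe(vfrt);
  const double ICab = pbCa * 4.0 * vffrt * (cai * std::exp(2.0 * vfrt) -
      0.341 * cao) / expm1_safe(2.0 * vfrt);
  const double IpCa = gpCa * cai / (0.0005 + cai);

  // subspace diffusion
  const double JdiffNa = (nass - nai) / 2.0;
  const double JdiffK = (kss - ki) / 2.0;
  const double Jdiff = (cass - cai) / 0.2;

  // SR release
  const double bt = 4.75, a_rel = 0.5 * bt;
  const double rel_gate = 1.0 + std::pow(1.5 / cajsr, 8.0);
  const double Jrel_inf = JrelSc * a_rel * (-ICaL) / rel_gate;
  double tau_rel = bt / (1.0 + 0.0123 / cajsr);
  if (tau_rel < 0.001) tau_rel = 0.001;
  const double btp = 1.25 * bt, a_relp = 0.5 * btp;
  const double Jrel_infp = JrelSc * a_relp * (-ICaL) / rel_gate;
  double tau_relp = btp / (1.0 + 0.0123 / cajsr);
  if (tau_relp < 0.001) tau_relp = 0.001;
  const double Jrel = (1.0 - fphos) * Jrelnp + fphos * Jrelp;

  // SR uptake
  const double Jupnp = JupB * cai / (cai + 0.00092);
  const double Jupp = 2.75 * JupB * cai / (cai + 0.00092 - 0.00017);
  const double Jleak = 0.0039375 * cansr / 15.0;
  const double Jup = (1.0 - fphos) * Jupnp + fphos * Jupp - Jleak;
  const double Jtr = (cansr - cajsr) / 100.0;

  const double iion = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs +
      IK1 + INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab;

  // buffered concentration derivatives
  const double kmcmdn = 0.00238, kmtrpn = 0.0005;
  const double KmBSR = 0.00087, KmBSL = 0.0087, kmcsqn = 0.8;
  const double dnai = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) *
      Acap / (F * vmyo) + JdiffNa * vss / vmyo;
  const double dnass = -(ICaNa + 3.0 * INaCa_ss) * Acap / (F * vss) - JdiffNa;
  const double dki = -(Ito + IKr + IKs + IK1 + IKb + istim - 2.0 * INaK) *
      Acap / (F * vmyo) + JdiffK * vss / vmyo;
  const double dkss = -ICaK * Acap / (F * vss) - JdiffK;
  double w1 = kmcmdn + cai, w2 = kmtrpn + cai;
  const double Bcai = 1.0 / (1.0 + BmaxCMDN * kmcmdn / (w1 * w1) +
                             BmaxTRPN * kmtrpn / (w2 * w2));
  const double dcai = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap /
      (2.0 * F * vmyo) - Jup * vnsr / vmyo + Jdiff * vss / vmyo);
  w1 = KmBSR + cass; w2 = KmBSL + cass;
  const double Bcass = 1.0 / (1.0 + BmaxSR * KmBSR / (w1 * w1) +
                              BmaxSL * KmBSL / (w2 * w2));
  const double dcass = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap /
      (2.0 * F * vss) + Jrel * vjsr / vss - Jdiff);
  const double dcansr = Jup - Jtr * vjsr / vnsr;
  w1 = kmcsqn + cajsr;
  const double Bcajsr = 1.0 / (1.0 + BmaxCSQN * kmcsqn / (w1 * w1));
  const double dcajsr = Bcajsr * (Jtr - Jrel);

  // relaxation-form states: inf and tau in state order 9..36
  const double infs[NG] = {
    minf, hinf, jinf, mLss, hLss, hLssp, ass, iss, iss, assp, iss, iss,
    dss, fss, fss, fcass_, fcass_, fcass_, anca * k2n / km2n, fss, fcass_,
    xrss, xrss, xs1ss, xs2ss, xk1ss, Jrel_inf, Jrel_infp
  };
  const double taus[NG] = {
    taum, tauh, tauj, tmL, thL, thLp, ta, tiF, tiS, ta, tiFp, tiSp,
    td, tff, tfs, tfcaf, tfcas, tjca, 1.0 / km2n, tffp, tfcafp,
    txrf, txrs, txs1, txs2, txk1, tau_rel, tau_relp
  };
  for (int g = 0; g < NG; g++) {
    ginf[g] = infs[g];
    gtau[g] = taus[g];
    deriv[GOFF + g] = (infs[g] - s[GOFF + g]) / taus[g];
  }
  deriv[0] = -(iion + istim + ip);
  deriv[1] = dnai; deriv[2] = dnass; deriv[3] = dki; deriv[4] = dkss;
  deriv[5] = dcai; deriv[6] = dcass; deriv[7] = dcansr; deriv[8] = dcajsr;
  deriv[37] = dCaMKt;
  return iion;
}

// [[Rcpp::export]]
List ord_hybrid_rhs_cpp(NumericVector state, NumericVector params,
                        double istim = 0.0, double ip = 0.0) {
  if (state.size() != NS) stop("state must have %d entries", NS);
  if (params.size() != NP) stop("params must have %d entries", NP);
  NumericVector deriv(NS), ginf(NG), gtau(NG);
  double iion = ord_rhs(state.begin(), params.begin(), istim, ip,
                        deriv.begin(), ginf.begin(), gtau.begin());
  return List::create(_["deriv"] = deriv, _["iion"] = iion,
                      _["gate_inf"] = ginf, _["gate_tau"] = gtau);
}

// Adaptive Rush-Larsen / forward-Euler integration of a coupled collection.
//
// state:  NS x nc matrix (columns = cells), modified copy returned
// params: NP x nc matrix
// ip:     per-cell constant perturbation current (A/F)
// edge_a, edge_b: 0-based endpoints of each connection
// edge_w: coupling weight lambda/(1+lambda) * Gi / (Cm*Am) in 1/ms
// stim_mask: per-cell 0/1, which cells receive the stimulus
// t0: absolute start time (ms, stimulus fires at t = k*period)
// t_end: absolute end time
// rec_start: first absolute time to record (Inf = record nothing)
// record_dt: sampling interval (ms)
// returns recorded time, V, Cai (+ ICaL if record_ical) and the final state
// [[Rcpp::export]]
List run_collection_cpp(NumericMatrix state, NumericMatrix params,
                        NumericVector ip, IntegerVector edge_a,
                        IntegerVector edge_b, NumericVector edge_w,
                        NumericVector stim_mask, double stim_amp,
                        double stim_dur, double period, double t0,
                        double t_end, double rec_start, double record_dt,
                        double dt_min, double dt_max, double dv_max,
                        double ca_rel) {
  const int nc = state.ncol();
  if (state.nrow() != NS) stop("state matrix must have %d rows", NS);
  if (params.nrow() != NP || params.ncol() != nc) stop("bad params matrix");
  const int ne = edge_a.size();

  // stability cap from the coupling operator (explicit treatment)
  std::vector<double> wsum(nc, 0.0);
  for (int e = 0; e < ne; e++) {
    wsum[edge_a[e]] += edge_w[e];
    wsum[edge_b[e]] += edge_w[e];
  }
  double wmax = 0.0;
  for (int k = 0; k < nc; k++) wmax = std::max(wmax, wsum[k]);
  double dt_cap = dt_max;
  if (wmax > 0.0) dt_cap = std::min(dt_max, 0.8 / wmax);

  NumericMatrix S = clone(state);
  std::vector<double> deriv(NS * nc), ginf(NG * nc), gtau(NG * nc);
  std::vector<double> coup(nc), iion(nc);

  // recording grid
  std::vector<double> rec_times;
  if (R_finite(rec_start)) {
    for (double tr = rec_start; tr <= t_end + 1e-9; tr += record_dt)
      rec_times.push_back(tr);
  }
  const int nt = rec_times.size();
  NumericMatrix V(nt, nc), CAI(nt, nc);
  int ri = 0;

  double t = t0;
  long nsteps = 0;
  while (t < t_end - 1e-9) {
    // stimulus bookkeeping (avoid fmod: not portable across libm versions)
    double phase = t - period * std::floor(t / period);
    const bool stim_on = phase < stim_dur - 1e-12;
    // coupling term
    std::fill(coup.begin(), coup.end(), 0.0);
    for (int e = 0; e < ne; e++) {
      const double dv = S(0, edge_b[e]) - S(0, edge_a[e]);
      coup[edge_a[e]] += edge_w[e] * dv;
      coup[edge_b[e]] -= edge_w[e] * dv;
    }
    // per-cell RHS and step-size control
    double dt = dt_cap;
    for (int k = 0; k < nc; k++) {
      const double istim = (stim_on && stim_mask[k] != 0.0) ? stim_amp : 0.0;
      iion[k] = ord_rhs(&S(0, k), &params(0, k), istim, ip[k],
                        &deriv[NS * k], &ginf[NG * k], &gtau[NG * k]);
      const double dvk = deriv[NS * k] + coup[k];
      deriv[NS * k] = dvk;
      double lim = dv_max / std::max(std::fabs(dvk), 1e-12);
      const double cass = S(6, k), cajsr = S(8, k);
      lim = std::min(lim, ca_rel * std::max(cass, 1e-6) /
                     std::max(std::fabs(deriv[NS * k + 6]), 1e-12));
      lim = std::min(lim, ca_rel * std::max(cajsr, 1e-4) /
                     std::max(std::fabs(deriv[NS * k + 8]), 1e-12));
      if (lim < dt) dt = lim;
    }
    if (dt < dt_min) dt = dt_min;
    // do not step across stimulus edges, record points or t_end
    double next_edge = stim_on ? (stim_dur - phase) : (period - phase);
    dt = std::min(dt, next_edge);
    dt = std::min(dt, t_end - t);
    if (ri < nt) dt = std::min(dt, rec_times[ri] - t + 1e-12);
    if (dt <= 0) dt = dt_min;

    // advance: Rush-Larsen for relaxation states, forward Euler otherwise
    for (int k = 0; k < nc; k++) {
      double *sk = &S(0, k);
      const double *dk = &deriv[NS * k];
      sk[0] += dt * dk[0];
      for (int c = 1; c <= 8; c++) sk[c] += dt * dk[c];
      sk[37] += dt * dk[37];
      const double *gi = &ginf[NG * k], *gt = &gtau[NG * k];
      for (int g = 0; g < NG; g++) {
        const int idx = GOFF + g;
        sk[idx] = gi[g] + (sk[idx] - gi[g]) * std::exp(-dt / gt[g]);
      }
      // guard strictly positive concentrations
      for (int c = 1; c <= 8; c++) if (sk[c] < 1e-12) sk[c] = 1e-12;
      if (!R_finite(sk[0]))
        stop("integration diverged at t = %.3f ms (cell %d)", t, k + 1);
    }
    t += dt;
    nsteps++;
    while (ri < nt && t >= rec_times[ri] - 1e-9) {
      for (int k = 0; k < nc; k++) {
        V(ri, k) = S(0, k);
        CAI(ri, k) = S(5, k);
      }
      ri++;
    }
  }

  List out = List::create(_["time"] = wrap(rec_times), _["v"] = V,
                          _["cai"] = CAI, _["state"] = S,
                          _["nsteps"] = (double)nsteps);
  return out;
}
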