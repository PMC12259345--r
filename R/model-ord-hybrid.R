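# Hybrid human ventricular ionic model: O'Hara-Rudy (endocardial) currents and
# fluxes with the fast sodium current replaced by the ten Tusscher formulation,
# whose maximal conductance is doubled to calibrate longitudinal conduction
# velocity to ~50 cm/s in well-coupled tissue.
#
# Units: mV, ms, mM, A/F (current densities), mS/uF (conductances).
# The R implementation below is the readable reference; the C++ twin in
# src/ord_hybrid.cpp is used for production runs and is tested for exact
# agreement with this one.

.ord_state_names <- c(
  "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
  "m", "h", "j", "mL", "hL", "hLp", "a", "iF", "iS", "ap", "iFp", "iSp",
  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
  "xrf", "xrs", "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt"
)

# indices (1-based) of states with relaxation (inf/tau) form, eligible for
# Rush-Larsen updates (m..Jrelp); everything else is advanced by forward Euler
.ord_gate_idx <- 10:37

.ord_param_names <- c(
  "gNa", "gNaL", "pNaK", "pNab", "gKr", "gKs", "gto", "gK1", "gKb",
  "pCaL", "gNaCa", "gpCa", "pbCa", "Jrel", "Jup",
  "BmaxSL", "BmaxSR", "BmaxCMDN", "BmaxCSQN", "BmaxTRPN"
)

#' Default parameters of the hybrid ventricular model
#'
#' Returns the named vector of the 20 scalable membrane parameters: maximal
#' conductances (mS/uF), permeabilities, pump/exchanger maxima, the relative
#' SR-release amplitude `Jrel` (unitless multiplier, default 1), the SERCA
#' uptake base rate `Jup` (mM/ms) and the five calcium-buffer totals (mM).
#' Defaults are the published endocardial values of the source models, with
#' `gNa` equal to twice the ten Tusscher conductance (conduction-velocity
#' calibration of the hybrid model).
#'
#' @param subtype cell subtype; only `"endo"` is built in.
#' @return named numeric vector of length 20.
#' @export
ord_hybrid_default_params <- function(subtype = "endo") {
  subtype <- match.arg(subtype)
  c(
    gNa = 2 * 14.838,   # ten Tusscher GNa, doubled
    gNaL = 0.0075,
    pNaK = 30,
    pNab = 3.75e-10,
    gKr = 0.046,
    gKs = 0.0034,
    gto = 0.02,
    gK1 = 0.1908,
    gKb = 0.003,
    pCaL = 1e-4,
    gNaCa = 0.0008,
    gpCa = 0.0005,
    pbCa = 2.5e-8,
    Jrel = 1.0,
    Jup = 0.004375,
    BmaxSL = 1.124,
    BmaxSR = 0.047,
    BmaxCMDN = 0.05,
    BmaxCSQN = 10,
    BmaxTRPN = 0.07
  )
}

#' Initial (unpaced) state of the hybrid ventricular model
#'
#' The crude resting state published with the O'Hara-Rudy code; simulations
#' are pre-paced towards a limit cycle before biomarkers are read, so this
#' only needs to lie in the resting basin. The ten Tusscher sodium gates
#' replace the original fast-INa gates.
#'
#' @return named numeric vector of length 38.
#' @export
ord_hybrid_initial_state <- function() {
  s <- c(
    v = -87, nai = 7, nass = 7, ki = 145, kss = 145,
    cai = 1e-4, cass = 1e-4, cansr = 1.2, cajsr = 1.2,
    m = 0, h = 1, j = 1, mL = 0, hL = 1, hLp = 1,
    a = 0, iF = 1, iS = 1, ap = 0, iFp = 1, iSp = 1,
    d = 0, ff = 1, fs = 1, fcaf = 1, fcas = 1, jca = 1, nca = 0,
    ffp = 1, fcafp = 1, xrf = 0, xrs = 0, xs1 = 0, xs2 = 0, xk1 = 1,
    Jrelnp = 0, Jrelp = 0, CaMKt = 0
  )
  stopifnot(identical(names(s), .ord_state_names))
  s
}

# guarded expm1 for GHK-type driving-force denominators (numerator vanishes
# with the denominator as v -> 0, so clamping is benign)
.expm1_safe <- function(x) {
  y <- expm1(x)
  ifelse(abs(y) < 1e-10, sign(y + (y == 0)) * 1e-10, y)
}

#' Time derivatives of the hybrid ventricular model (reference implementation)
#'
#' Evaluates all membrane currents, intracellular fluxes and state derivatives
#' at one state. Pure function; used as the correctness oracle for the
#' compiled production code and for external-model style integration.
#'
#' @param state named numeric state vector (see [ord_hybrid_initial_state()]).
#' @param params named parameter vector (see [ord_hybrid_default_params()]).
#' @param istim stimulus current density (A/F, negative = depolarizing),
#'   applied to the membrane and booked on potassium as in the source model.
#' @param ip constant perturbation current density (A/F) added to the total
#'   ionic current (membrane equation only).
#' @return list with `deriv` (named vector), `iion` (A/F, excluding `istim`
#'   and `ip`), `currents` (named list, A/F), and the Rush-Larsen data
#'   `gate_inf`, `gate_tau` for the relaxation-form states.
#' @export
ord_hybrid_derivs <- function(state, params, istim = 0, ip = 0) {
  s <- as.list(state)
  p <- as.list(params)

  # physical constants and fixed geometry (source-model cell, pi = 3.14 as in
  # the published code)
  R <- 8314; Temp <- 310; Frdy <- 96485
  nao <- 140; cao <- 1.8; ko <- 5.4
  pi0 <- 3.14
  L <- 0.01; rad <- 0.0011
  vcell <- 1000 * pi0 * rad * rad * L
  Ageo <- 2 * pi0 * rad * rad + 2 * pi0 * rad * L
  Acap <- 2 * Ageo
  vmyo <- 0.68 * vcell; vnsr <- 0.0552 * vcell
  vjsr <- 0.0048 * vcell; vss <- 0.02 * vcell

  v <- s$v
  vfrt <- v * Frdy / (R * Temp)
  vffrt <- v * Frdy * Frdy / (R * Temp)

  # CaMK
  KmCaMK <- 0.15; aCaMK <- 0.05; bCaMK <- 0.00068
  CaMKo <- 0.05; KmCaM <- 0.0015
  CaMKb <- CaMKo * (1 - s$CaMKt) / (1 + KmCaM / s$cass)
  CaMKa <- CaMKb + s$CaMKt
  dCaMKt <- aCaMK * CaMKb * (CaMKb + s$CaMKt) - bCaMK * s$CaMKt
  fp <- 1 / (1 + KmCaMK / CaMKa)  # shared CaMK-phosphorylated fraction

  ENa <- (R * Temp / Frdy) * log(nao / s$nai)
  EK <- (R * Temp / Frdy) * log(ko / s$ki)
  PKNa <- 0.01833
  EKs <- (R * Temp / Frdy) * log((ko + PKNa * nao) / (s$ki + PKNa * s$nai))

  # --- fast INa: ten Tusscher formulation (gNa already includes the 2x) ---
  minf <- 1 / (1 + exp((-56.86 - v) / 9.03))^2
  am <- 1 / (1 + exp((-60 - v) / 5))
  bm <- 0.1 / (1 + exp((v + 35) / 5)) + 0.1 / (1 + exp((v - 50) / 200))
  taum <- am * bm
  hinf <- 1 / (1 + exp((v + 71.55) / 7.43))^2
  if (v >= -40) {
    ah <- 0
    bh <- 0.77 / (0.13 * (1 + exp(-(v + 10.66) / 11.1)))
    aj <- 0
    bj <- 0.6 * exp(0.057 * v) / (1 + exp(-0.1 * (v + 32)))
  } else {
    ah <- 0.057 * exp(-(v + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * v) + 3.1e5 * exp(0.3485 * v)
    aj <- (-2.5428e4 * exp(0.2444 * v) - 6.948e-6 * exp(-0.04391 * v)) *
      (v + 37.78) / (1 + exp(0.311 * (v + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * v) / (1 + exp(-0.1378 * (v + 40.14)))
  }
  tauh <- 1 / (ah + bh)
  jinf <- hinf
  tauj <- 1 / (aj + bj)
  INa <- p$gNa * s$m^3 * s$h * s$j * (v - ENa)

  # --- late INaL (O'Hara-Rudy; tmL reuses the original INa m time constant)
  mLss <- 1 / (1 + exp(-(v + 42.85) / 5.264))
  tmL <- 1 / (6.765 * exp((v + 11.64) / 34.77) + 8.552 * exp(-(v + 77.42) / 5.955))
  hLss <- 1 / (1 + exp((v + 87.61) / 7.488))
  thL <- 200
  hLssp <- 1 / (1 + exp((v + 93.81) / 7.488))
  thLp <- 3 * thL
  INaL <- p$gNaL * (v - ENa) * s$mL * ((1 - fp) * s$hL + fp * s$hLp)

  # --- Ito ---
  ass <- 1 / (1 + exp(-(v - 14.34) / 14.82))
  ta <- 1.0515 / (1 / (1.2089 * (1 + exp(-(v - 18.4099) / 29.3814))) +
                    3.5 / (1 + exp((v + 100) / 29.3814)))
  iss <- 1 / (1 + exp((v + 43.94) / 5.711))
  tiF <- 4.562 + 1 / (0.3933 * exp(-(v + 100) / 100) +
                        0.08004 * exp((v + 50) / 16.59))
  tiS <- 23.62 + 1 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                        1.780e-8 * exp((v + 114.1) / 8.079))
  AiF <- 1 / (1 + exp((v - 213.6) / 151.2))
  AiS <- 1 - AiF
  i_to <- AiF * s$iF + AiS * s$iS
  assp <- 1 / (1 + exp(-(v - 24.34) / 14.82))
  dti_develop <- 1.354 + 1e-4 / (exp((v - 167.4) / 15.89) +
                                   exp(-(v - 12.23) / 0.2154))
  dti_recover <- 1 - 0.5 / (1 + exp((v + 70) / 20))
  tiFp <- dti_develop * dti_recover * tiF
  tiSp <- dti_develop * dti_recover * tiS
  ip_to <- AiF * s$iFp + AiS * s$iSp
  Ito <- p$gto * (v - EK) * ((1 - fp) * s$a * i_to + fp * s$ap * ip_to)

  # --- ICaL / ICaNa / ICaK ---
  dss <- 1 / (1 + exp(-(v + 3.94) / 4.23))
  td <- 0.6 + 1 / (exp(-0.05 * (v + 6)) + exp(0.09 * (v + 14)))
  fss <- 1 / (1 + exp((v + 19.58) / 3.696))
  tff <- 7 + 1 / (0.0045 * exp(-(v + 20) / 10) + 0.0045 * exp((v + 20) / 10))
  tfs <- 1000 + 1 / (3.5e-5 * exp(-(v + 5) / 4) + 3.5e-5 * exp((v + 5) / 6))
  Aff <- 0.6; Afs <- 0.4
  f <- Aff * s$ff + Afs * s$fs
  fcass <- fss
  tfcaf <- 7 + 1 / (0.04 * exp(-(v - 4) / 7) + 0.04 * exp((v - 4) / 7))
  tfcas <- 100 + 1 / (0.00012 * exp(-v / 3) + 0.00012 * exp(v / 7))
  Afcaf <- 0.3 + 0.6 / (1 + exp((v - 10) / 10))
  Afcas <- 1 - Afcaf
  fca <- Afcaf * s$fcaf + Afcas * s$fcas
  tjca <- 75
  tffp <- 2.5 * tff
  f_p <- Aff * s$ffp + Afs * s$fs
  tfcafp <- 2.5 * tfcaf
  fca_p <- Afcaf * s$fcafp + Afcas * s$fcas
  Kmn <- 0.002; k2n <- 1000
  km2n <- s$jca * 1
  anca <- 1 / (k2n / km2n + (1 + Kmn / s$cass)^4)
  dnca <- anca * k2n - s$nca * km2n
  PhiCaL <- 4 * vffrt * (s$cass * exp(2 * vfrt) - 0.341 * cao) /
    .expm1_safe(2 * vfrt)
  PhiCaNa <- 1 * vffrt * (0.75 * s$nass * exp(1 * vfrt) - 0.75 * nao) /
    .expm1_safe(1 * vfrt)
  PhiCaK <- 1 * vffrt * (0.75 * s$kss * exp(1 * vfrt) - 0.75 * ko) /
    .expm1_safe(1 * vfrt)
  PCa <- p$pCaL
  PCap <- 1.1 * PCa
  PCaNa <- 0.00125 * PCa; PCaK <- 3.574e-4 * PCa
  PCaNap <- 0.00125 * PCap; PCaKp <- 3.574e-4 * PCap
  ICaL <- (1 - fp) * PCa * PhiCaL * s$d * (f * (1 - s$nca) + s$jca * fca * s$nca) +
    fp * PCap * PhiCaL * s$d * (f_p * (1 - s$nca) + s$jca * fca_p * s$nca)
  ICaNa <- (1 - fp) * PCaNa * PhiCaNa * s$d * (f * (1 - s$nca) + s$jca * fca * s$nca) +
    fp * PCaNap * PhiCaNa * s$d * (f_p * (1 - s$nca) + s$jca * fca_p * s$nca)
  ICaK <- (1 - fp) * PCaK * PhiCaK * s$d * (f * (1 - s$nca) + s$jca * fca * s$nca) +
    fp * PCaKp * PhiCaK * s$d * (f_p * (1 - s$nca) + s$jca * fca_p * s$nca)

  # --- IKr ---
  xrss <- 1 / (1 + exp(-(v + 8.337) / 6.789))
  txrf <- 12.98 + 1 / (0.3652 * exp((v - 31.66) / 3.869) +
                         4.123e-5 * exp(-(v - 47.78) / 20.38))
  txrs <- 1.865 + 1 / (0.06629 * exp((v - 34.7) / 7.355) +
                         1.128e-5 * exp(-(v - 29.74) / 25.94))
  Axrf <- 1 / (1 + exp((v + 54.81) / 38.21))
  Axrs <- 1 - Axrf
  xr <- Axrf * s$xrf + Axrs * s$xrs
  rkr <- 1 / ((1 + exp((v + 55) / 75)) * (1 + exp((v - 10) / 30)))
  IKr <- p$gKr * sqrt(ko / 5.4) * xr * rkr * (v - EK)

  # --- IKs ---
  xs1ss <- 1 / (1 + exp(-(v + 11.6) / 8.932))
  txs1 <- 817.3 + 1 / (2.326e-4 * exp((v + 48.28) / 17.8) +
                         0.001292 * exp(-(v + 210) / 230))
  xs2ss <- xs1ss
  txs2 <- 1 / (0.01 * exp((v - 50) / 20) + 0.0193 * exp(-(v + 66.54) / 31))
  KsCa <- 1 + 0.6 / (1 + (3.8e-5 / s$cai)^1.4)
  IKs <- p$gKs * KsCa * s$xs1 * s$xs2 * (v - EKs)

  # --- IK1 ---
  xk1ss <- 1 / (1 + exp(-(v + 2.5538 * ko + 144.59) / (1.5692 * ko + 3.8115)))
  txk1 <- 122.2 / (exp(-(v + 127.2) / 20.36) + exp((v + 236.8) / 69.33))
  rk1 <- 1 / (1 + exp((v + 105.8 - 2.6 * ko) / 9.493))
  IK1 <- p$gK1 * sqrt(ko) * rk1 * s$xk1 * (v - EK)

  # --- INaCa (myoplasmic and subspace components) ---
  kna1 <- 15; kna2 <- 5; kna3 <- 88.12; kasymm <- 12.5
  wna <- 6e4; wca <- 6e4; wnaca <- 5e3
  kcaon <- 1.5e6; kcaoff <- 5e3
  qna <- 0.5224; qca <- 0.167
  hca <- exp(qca * vfrt); hna <- exp(qna * vfrt)
  zca <- 2; zna <- 1; zk <- 1
  KmCaAct <- 150e-6
  ncx <- function(na, ca) {
    h1 <- 1 + na / kna3 * (1 + hna)
    h2 <- (na * hna) / (kna3 * h1)
    h3 <- 1 / h1
    h4 <- 1 + na / kna1 * (1 + na / kna2)
    h5 <- na * na / (h4 * kna1 * kna2)
    h6 <- 1 / h4
    h7 <- 1 + nao / kna3 * (1 + 1 / hna)
    h8 <- nao / (kna3 * hna * h7)
    h9 <- 1 / h7
    h10 <- kasymm + 1 + nao / kna1 * (1 + nao / kna2)
    h11 <- nao * nao / (h10 * kna1 * kna2)
    h12 <- 1 / h10
    k1 <- h12 * cao * kcaon
    k2 <- kcaoff
    k3p <- h9 * wca
    k3pp <- h8 * wnaca
    k3 <- k3p + k3pp
    k4p <- h3 * wca / hca
    k4pp <- h2 * wnaca
    k4 <- k4p + k4pp
    k5 <- kcaoff
    k6 <- h6 * ca * kcaon
    k7 <- h5 * h2 * wna
    k8 <- h8 * h11 * wna
    x1 <- k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3)
    x2 <- k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8)
    x3 <- k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3)
    x4 <- k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8)
    E1 <- x1 / (x1 + x2 + x3 + x4)
    E2 <- x2 / (x1 + x2 + x3 + x4)
    E3 <- x3 / (x1 + x2 + x3 + x4)
    E4 <- x4 / (x1 + x2 + x3 + x4)
    allo <- 1 / (1 + (KmCaAct / ca)^2)
    JncxNa <- 3 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp
    JncxCa <- E2 * k2 - E1 * k1
    allo * (zna * JncxNa + zca * JncxCa)
  }
  INaCa_i <- 0.8 * p$gNaCa * ncx(s$nai, s$cai)
  INaCa_ss <- 0.2 * p$gNaCa * ncx(s$nass, s$cass)

  # --- INaK ---
  k1p <- 949.5; k1m <- 182.4; k2p <- 687.2; k2m <- 39.4
  k3p_ <- 1899; k3m <- 79300; k4p_ <- 639; k4m <- 40
  Knai0 <- 9.073; Knao0 <- 27.78; delta <- -0.155
  Knai <- Knai0 * exp(delta * vfrt / 3)
  Knao <- Knao0 * exp((1 - delta) * vfrt / 3)
  Kki <- 0.5; Kko <- 0.3582
  MgADP <- 0.05; MgATP <- 9.8; Kmgatp <- 1.698e-7
  H <- 1e-7; eP <- 4.2; Khp <- 1.698e-7; Knap <- 224; Kxkur <- 292
  P <- eP / (1 + H / Khp + s$nai / Knap + s$ki / Kxkur)
  di <- (1 + s$nai / Knai)^3 + (1 + s$ki / Kki)^2 - 1
  do_ <- (1 + nao / Knao)^3 + (1 + ko / Kko)^2 - 1
  a1 <- k1p * (s$nai / Knai)^3 / di
  b1 <- k1m * MgADP
  a2 <- k2p
  b2 <- k2m * (nao / Knao)^3 / do_
  a3 <- k3p_ * (ko / Kko)^2 / do_
  b3 <- k3m * P * H / (1 + MgATP / Kmgatp)
  a4 <- k4p_ * MgATP / Kmgatp / (1 + MgATP / Kmgatp)
  b4 <- k4m * (s$ki / Kki)^2 / di
  x1 <- a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2
  x2 <- b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4
  x3 <- a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1
  x4 <- b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1
  E1 <- x1 / (x1 + x2 + x3 + x4)
  E2 <- x2 / (x1 + x2 + x3 + x4)
  E3 <- x3 / (x1 + x2 + x3 + x4)
  E4 <- x4 / (x1 + x2 + x3 + x4)
  JnakNa <- 3 * (E1 * a3 - E2 * b3)
  JnakK <- 2 * (E4 * b1 - E3 * a1)
  INaK <- p$pNaK * (zna * JnakNa + zk * JnakK)

  # --- background and pump currents ---
  xkb <- 1 / (1 + exp(-(v - 14.48) / 18.34))
  IKb <- p$gKb * xkb * (v - EK)
  INab <- p$pNab * vffrt * (s$nai * exp(vfrt) - nao) / .expm1_safe(vfrt)
  ICab <- p$pbCa * 4 * vffrt * (s$cai * exp(2 * vfrt) - 0.341 * cao) /
    .expm1_safe(2 * vfrt)
  IpCa <- p$gpCa * s$cai / (0.0005 + s$cai)

  # --- diffusion fluxes between subspace and myoplasm ---
  JdiffNa <- (s$nass - s$nai) / 2
  JdiffK <- (s$kss - s$ki) / 2
  Jdiff <- (s$cass - s$cai) / 0.2

  # --- SR calcium release (RyR), scaled by the relative amplitude p$Jrel ---
  bt <- 4.75
  a_rel <- 0.5 * bt
  Jrel_inf <- p$Jrel * a_rel * (-ICaL) / (1 + (1.5 / s$cajsr)^8)
  tau_rel <- bt / (1 + 0.0123 / s$cajsr)
  if (tau_rel < 0.001) tau_rel <- 0.001
  btp <- 1.25 * bt
  a_relp <- 0.5 * btp
  Jrel_infp <- p$Jrel * a_relp * (-ICaL) / (1 + (1.5 / s$cajsr)^8)
  tau_relp <- btp / (1 + 0.0123 / s$cajsr)
  if (tau_relp < 0.001) tau_relp <- 0.001
  Jrel <- (1 - fp) * s$Jrelnp + fp * s$Jrelp

  # --- SR uptake (SERCA) and translocation; p$Jup is the base maximal rate
  Jupnp <- p$Jup * s$cai / (s$cai + 0.00092)
  Jupp <- 2.75 * p$Jup * s$cai / (s$cai + 0.00092 - 0.00017)
  Jleak <- 0.0039375 * s$cansr / 15
  Jup <- (1 - fp) * Jupnp + fp * Jupp - Jleak
  Jtr <- (s$cansr - s$cajsr) / 100

  iion <- INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
    INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa + ICab

  # --- concentration updates ---
  cmdnmax <- p$BmaxCMDN; kmcmdn <- 0.00238
  trpnmax <- p$BmaxTRPN; kmtrpn <- 0.0005
  BSRmax <- p$BmaxSR; KmBSR <- 0.00087
  BSLmax <- p$BmaxSL; KmBSL <- 0.0087
  csqnmax <- p$BmaxCSQN; kmcsqn <- 0.8

  dnai <- -(INa + INaL + 3 * INaCa_i + 3 * INaK + INab) * Acap / (Frdy * vmyo) +
    JdiffNa * vss / vmyo
  dnass <- -(ICaNa + 3 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa
  dki <- -(Ito + IKr + IKs + IK1 + IKb + istim - 2 * INaK) * Acap /
    (Frdy * vmyo) + JdiffK * vss / vmyo
  dkss <- -ICaK * Acap / (Frdy * vss) - JdiffK
  Bcai <- 1 / (1 + cmdnmax * kmcmdn / (kmcmdn + s$cai)^2 +
                 trpnmax * kmtrpn / (kmtrpn + s$cai)^2)
  dcai <- Bcai * (-(IpCa + ICab - 2 * INaCa_i) * Acap / (2 * Frdy * vmyo) -
                    Jup * vnsr / vmyo + Jdiff * vss / vmyo)
  Bcass <- 1 / (1 + BSRmax * KmBSR / (KmBSR + s$cass)^2 +
                  BSLmax * KmBSL / (KmBSL + s$cass)^2)
  dcass <- Bcass * (-(ICaL - 2 * INaCa_ss) * Acap / (2 * Frdy * vss) +
                      Jrel * vjsr / vss - Jdiff)
  dcansr <- Jup - Jtr * vjsr / vnsr
  Bcajsr <- 1 / (1 + csqnmax * kmcsqn / (kmcsqn + s$cajsr)^2)
  dcajsr <- Bcajsr * (Jtr - Jrel)

  gate_inf <- c(
    m = minf, h = hinf, j = jinf, mL = mLss, hL = hLss, hLp = hLssp,
    a = ass, iF = iss, iS = iss, ap = assp, iFp = iss, iSp = iss,
    d = dss, ff = fss, fs = fss, fcaf = fcass, fcas = fcass, jca = fcass,
    nca = anca * k2n / km2n,
    ffp = fss, fcafp = fcass,
    xrf = xrss, xrs = xrss, xs1 = xs1ss, xs2 = xs2ss, xk1 = xk1ss,
    Jrelnp = Jrel_inf, Jrelp = Jrel_infp
  )
  gate_tau <- c(
    m = taum, h = tauh, j = tauj, mL = tmL, hL = thL, hLp = thLp,
    a = ta, iF = tiF, iS = tiS, ap = ta, iFp = tiFp, iSp = tiSp,
    d = td, ff = tff, fs = tfs, fcaf = tfcaf, fcas = tfcas, jca = tjca,
    nca = 1 / km2n,
    ffp = tffp, fcafp = tfcafp,
    xrf = txrf, xrs = txrs, xs1 = txs1, xs2 = txs2, xk1 = txk1,
    Jrelnp = tau_rel, Jrelp = tau_relp
  )
  # note: nca's inf/tau follow from dnca = anca*k2n - nca*km2n

  deriv <- numeric(length(.ord_state_names))
  names(deriv) <- .ord_state_names
  deriv["v"] <- -(iion + istim + ip)
  deriv["nai"] <- dnai; deriv["nass"] <- dnass
  deriv["ki"] <- dki; deriv["kss"] <- dkss
  deriv["cai"] <- dcai; deriv["cass"] <- dcass
  deriv["cansr"] <- dcansr; deriv["cajsr"] <- dcajsr
  deriv["CaMKt"] <- dCaMKt
  gn <- names(gate_inf)
  deriv[gn] <- (gate_inf - as.numeric(state[gn])) / gate_tau

  list(
    deriv = deriv,
    iion = iion,
    currents = list(
      INa = INa, INaL = INaL, Ito = Ito, ICaL = ICaL, ICaNa = ICaNa,
      ICaK = ICaK, IKr = IKr, IKs = IKs, IK1 = IK1, INaCa_i = INaCa_i,
      INaCa_ss = INaCa_ss, INaK = INaK, INab = INab, IKb = IKb,
      IpCa = IpCa, ICab = ICab
    ),
    gate_inf = gate_inf,
    gate_tau = gate_tau
  )
}
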