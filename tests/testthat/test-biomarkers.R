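# Biomarkers: closed-form fixtures, interpolation consistency, EAD detector
# behavior and the brute-force resampling oracle for APD50.

test_that("trapezoid AP: closed-form APD50 and ToA values", {
  # rise -80 -> +40 over [10, 11]; plateau to 200; fall at -1.2 mV/ms to
  # -80 at 300. Halfway level = -20 mV, crossed at t = 250 on the fall;
  # max upstroke sample starts at t = 10; ToA(-30) on the rise at 10.41667,
  # on the fall at 200 + 70/1.2 = 258.3333.
  tr <- trapezoid_ap()
  expect_equal(apd50(tr$t, tr$v), 250 - 10, tolerance = 1e-6)
  expect_equal(toa(tr$t, tr$v, "depolarization"), 10 + 50 / 120,
               tolerance = 1e-6)
  expect_equal(toa(tr$t, tr$v, "repolarization"), 200 + 70 / 1.2,
               tolerance = 1e-6)
})

test_that("resting traces and subthreshold traces are flagged, not zero", {
  t <- seq(0, 500, by = 0.5)
  v <- rep(-87, length(t)) + 0.01 * sin(t / 50)
  expect_true(is.na(apd50(t, v)))
  expect_true(is.na(toa(t, v, "depolarization")))
  expect_true(is.na(toa(t, v, "repolarization")))
  expect_equal(detect_eads(t, v), 0L)
})

test_that("APD50 and ToA are invariant under time shift and supersampling", {
  pr <- single_run_1hz()
  t <- pr$trace$time; v <- pr$trace$v[, 1]
  a0 <- apd50(t, v); d0 <- toa(t, v, "dep"); r0 <- toa(t, v, "rep")
  expect_equal(apd50(t + 137.5, v), a0)
  expect_equal(toa(t + 137.5, v, "dep"), d0 + 137.5)
  # supersample 5x by linear interpolation
  tf <- seq(min(t), max(t), by = 0.1)
  vf <- approx(t, v, tf)$y
  expect_lt(abs(apd50(tf, vf) - a0), 0.1)
  expect_lt(abs(toa(tf, vf, "dep") - d0), 0.1)
  expect_lt(abs(toa(tf, vf, "rep") - r0), 0.1)
})

test_that("APD50 agrees with the brute-force 0.01 ms resampling oracle", {
  # oracle: evaluate the definition literally on a 0.01 ms linear resample
  # of an independently recorded (finer) trace
  model <- build_ord_hybrid()
  proto <- stimulus_protocol("all_cells", period = 1000, prepace = 12,
                             record_beats = 1)
  coarse <- run_single_cell(model, proto, solve_config(record_dt = 0.5))
  fine <- run_single_cell(model, proto, solve_config(record_dt = 0.25))
  tf <- seq(0, max(fine$trace$time), by = 0.01)
  vf <- approx(fine$trace$time, fine$trace$v[, 1], tf)$y
  dvdt <- diff(vf) / 0.01
  t_up <- tf[which.max(dvdt)]
  thr <- (max(vf) + min(vf)) / 2
  after_peak <- which(tf > tf[which.max(vf)])
  below <- after_peak[vf[after_peak] <= thr]
  oracle <- tf[below[1]] - t_up
  expect_lt(abs(apd50(coarse$trace$time, coarse$trace$v[, 1]) - oracle), 1)
})

test_that("repolarization ToA takes the final downward crossing (EAD case)", {
  # constructed two-crossing fixture: AP dips below -30, rebounds (EAD),
  # then finally repolarizes
  t <- seq(0, 400, by = 0.5)
  v <- rep(-80, length(t))
  v[t >= 10 & t < 200] <- 10
  v[t >= 200 & t < 240] <- -40        # dip below -30
  v[t >= 240 & t < 300] <- -10        # EAD rebound above -30
  v[t >= 300] <- -80                  # final repolarization
  r <- toa(t, v, "repolarization")
  expect_gt(r, 295)                   # last crossing, not the first at ~200
  expect_equal(detect_eads(t, v), 1L)
})

test_that("EAD detector counts rebounds and honors its thresholds", {
  # plateau that sags to -50 mV, rebounds 15 mV, then repolarizes -> 1 EAD
  t <- seq(0, 500, by = 0.5)
  v <- -85 + 125 * (t >= 10) - 90 * pmax(0, pmin((t - 150) / 100, 1)) +
    15 * pmax(0, pmin((t - 260) / 30, 1))
  v[t >= 330] <- approx(c(330, 420), c(v[t == 329.5], -85),
                        t[t >= 330], rule = 2)$y
  expect_equal(detect_eads(t, v), 1L)
  # monotone repolarization -> 0
  tr <- trapezoid_ap()
  expect_equal(detect_eads(tr$t, tr$v), 0L)
  # rebound-threshold sensitivity: a 1.5 mV wiggle counts at 1 mV threshold
  # but not at the default 2 mV or at 5 mV
  v2 <- -85 + 125 * (t >= 10) - 90 * pmax(0, pmin((t - 150) / 100, 1)) +
    1.5 * pmax(0, pmin((t - 260) / 30, 1))
  v2[t >= 330] <- approx(c(330, 420), c(v2[t == 329.5], -85),
                         t[t >= 330], rule = 2)$y
  expect_equal(detect_eads(t, v2, rebound = 1), 1L)
  expect_equal(detect_eads(t, v2, rebound = 2), 0L)
  expect_equal(detect_eads(t, v2, rebound = 5), 0L)
})

test_that("calcium amplitude is max minus min in uM", {
  expect_equal(calcium_amplitude(rep(2e-4, 10)), 0)
  cai <- c(1e-4, 2e-4, 7.5e-4, 3e-4, 1e-4)   # mM
  expect_equal(calcium_amplitude(cai), 0.65)
})

test_that("doubling the L-type conductance increases CaA", {
  model <- build_ord_hybrid()
  proto <- stimulus_protocol("all_cells", period = 1000, prepace = 15,
                             record_beats = 1)
  base <- run_single_cell(model, proto)
  p2 <- model$default_params; p2["pCaL"] <- 2 * p2["pCaL"]
  doubled <- run_single_cell(model, proto, params = p2)
  expect_gt(calcium_amplitude(doubled$trace$cai[, 1]),
            calcium_amplitude(base$trace$cai[, 1]))
})

test_that("dispersion arithmetic, incompleteness flag and CV arithmetic", {
  g <- cell_grid(2, 3)
  tb <- data.frame(cell = 1:6, cell_x = rep(1:2, 3), cell_y = rep(1:3, each = 2),
                   beat = 1,
                   apd50_ms = 200, toa_dep_ms = c(1, 101, 1, 103, 1, 100),
                   toa_rep_ms = c(201, 301, 201, 303, 201, 300),
                   caa_uM = 0.3, ead_count = 0L)
  d <- toa_dispersion(tb, g, column = 2)
  expect_equal(d$max_delta_toa_ms, c(3, 3))
  tb$toa_rep_ms[2] <- NA
  d2 <- toa_dispersion(tb, g, column = 2)
  expect_true(is.na(d2$max_delta_toa_ms[2]))
  expect_true(d2$incomplete[2])

  # CV: ToA difference of 2.0 ms over 10 cells of 100 um -> 50 cm/s
  g2 <- cell_grid(12, 1)
  tb2 <- data.frame(cell = 1:12, cell_x = 1:12, cell_y = 1, beat = 1,
                    apd50_ms = 200, toa_dep_ms = 0.2 * (1:12),
                    toa_rep_ms = 200 + 0.2 * (1:12), caa_uM = 0.3,
                    ead_count = 0L)
  expect_equal(conduction_velocity(tb2, g2, from_col = 1, to_col = 11), 50)
  # wave moving the wrong way -> error
  tb2$toa_dep_ms <- rev(tb2$toa_dep_ms)
  expect_error(conduction_velocity(tb2, g2, 1, 11), "did not travel")
})

test_that("biomarker_table splits beats and matches direct evaluation", {
  model <- build_ord_hybrid()
  proto <- stimulus_protocol("all_cells", period = 1000, prepace = 10,
                             record_beats = 2)
  pr <- run_single_cell(model, proto)
  bt <- biomarker_table(pr$trace)
  expect_equal(nrow(bt), 2)
  sel <- pr$trace$time <= 1000
  expect_equal(bt$apd50_ms[1],
               apd50(pr$trace$time[sel], pr$trace$v[sel, 1]))
  expect_lt(abs(bt$apd50_ms[1] - bt$apd50_ms[2]), 1)  # near-steady pacing
})
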