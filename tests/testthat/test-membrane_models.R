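# Membrane models: hybrid model construction, parameter operations, the
# external-model adapter, and the R-vs-compiled dual-route agreement.

test_that("compiled RHS agrees with the R reference at randomized states", {
  p <- ord_hybrid_default_params()
  s0 <- ord_hybrid_initial_state()
  set.seed(42)
  for (i in 1:8) {
    s <- s0
    if (i > 1) {
      s["v"] <- runif(1, -90, 40)
      s[10:37] <- pmin(pmax(s0[10:37] + runif(28, -0.3, 0.3), 1e-3), 0.999)
      s["cai"] <- runif(1, 5e-5, 1e-3)
      s["cass"] <- runif(1, 5e-5, 5e-3)
      s["cajsr"] <- runif(1, 0.5, 2.5)
      s["cansr"] <- runif(1, 0.5, 3)
      s["nai"] <- runif(1, 4, 12)
      s["ki"] <- runif(1, 120, 150)
    }
    a <- ord_hybrid_derivs(s, p, istim = -20, ip = 0.05)
    b <- sknm:::ord_hybrid_rhs_cpp(s, p, -20, 0.05)
    expect_lt(max(abs(a$deriv - b$deriv) / pmax(abs(a$deriv), 1e-8)), 1e-12)
    expect_equal(a$iion, b$iion, tolerance = 1e-13)
  }
})

test_that("identity scaling leaves iion and rates unchanged", {
  model <- build_ord_hybrid()
  p <- model$default_params
  s <- ord_hybrid_initial_state()
  expect_identical(model$rates(s, p * 1), model$rates(s, p))
  expect_identical(model$iion(s, p * 1), model$iion(s, p))
})

test_that("the unstimulated resting state is a fixed point (quiescence)", {
  # 1000 s free run from the published crude initial state; endpoint
  # derivatives must be < 1e-6 of each variable's dynamic range
  S <- matrix(ord_hybrid_initial_state(), 38, 1)
  res <- sknm:::run_collection_cpp(
    S, matrix(ord_hybrid_default_params(), 20, 1), 0, integer(), integer(),
    numeric(), 0, 0, 1, 1e9, 0, 1e6, Inf, 1, 1e-3, 0.5, 0.2, 0.05)
  s_end <- setNames(res$state[, 1], names(ord_hybrid_initial_state()))
  d <- ord_hybrid_derivs(s_end, ord_hybrid_default_params())
  ranges <- c(150, 10, 10, 150, 150, 1e-3, 1e-2, 3, 3, rep(1, 28), 0.2)
  expect_lt(max(abs(d$deriv) / ranges), 1e-6)
  expect_lt(abs(s_end[["v"]] + 88) , 2)   # resting potential near -88 mV
})

test_that("gates stay in [0,1] and concentrations positive along pacing", {
  pr <- single_run_1hz()
  expect_true(all(pr$trace$cai > 0))
  s_end <- pr$checkpoint$state[, 1]
  names(s_end) <- sknm:::.ord_state_names
  expect_true(all(s_end[sknm:::.ord_gate_idx[1:26]] >= 0 &
                    s_end[sknm:::.ord_gate_idx[1:26]] <= 1))
  expect_true(all(s_end[c("nai", "nass", "ki", "kss", "cai", "cass",
                          "cansr", "cajsr")] > 0))
})

test_that("apply_block scales exactly one parameter and validates input", {
  p <- ord_hybrid_default_params()
  b <- apply_block(p, "gKr", 0.53)
  expect_equal(b[["gKr"]], 0.47 * p[["gKr"]])
  expect_equal(b[names(b) != "gKr"], p[names(p) != "gKr"])
  expect_identical(apply_block(p, "gKr", 0), p)
  expect_equal(apply_block(p, "pCaL", 1)[["pCaL"]], 0)
  expect_error(apply_block(p, "gFoo", 0.5), "gFoo")
  expect_error(apply_block(p, "gKr", 1.2), "\\[0, 1\\]")
  expect_error(apply_block(p, "gKr", -0.1), "\\[0, 1\\]")
})

test_that("apply_block only changes the blocked current's iion term", {
  model <- build_ord_hybrid()
  s <- ord_hybrid_initial_state()
  s["v"] <- -20; s["xrf"] <- 0.5; s["xrs"] <- 0.5
  p <- model$default_params
  full <- ord_hybrid_derivs(s, p)
  half <- ord_hybrid_derivs(s, apply_block(p, "gKr", 0.5))
  expect_equal(half$currents$IKr, 0.5 * full$currents$IKr)
  expect_equal(half$iion - half$currents$IKr,
               full$iion - full$currents$IKr, tolerance = 1e-12)
})

test_that("make_perturbed_type applies the three-parameter phenotype", {
  p <- ord_hybrid_default_params()
  q <- make_perturbed_type(p)
  expect_equal(q[["gKr"]], 0)
  expect_equal(q[["gK1"]], 0.25 * p[["gK1"]])
  expect_equal(q[["pCaL"]], 2 * p[["pCaL"]])
  keep <- setdiff(names(p), c("gKr", "gK1", "pCaL"))
  expect_equal(q[keep], p[keep])
  # documented non-idempotence
  q2 <- make_perturbed_type(q)
  expect_equal(q2[["gK1"]], 0.0625 * p[["gK1"]])
  expect_equal(q2[["pCaL"]], 4 * p[["pCaL"]])
  expect_error(make_perturbed_type(c(gKr = 1, gK1 = 1)), "L-type")
})

test_that("hybrid upstroke is faster than the halved-gNa variant", {
  model <- build_ord_hybrid()
  cfg <- solve_config(record_dt = 0.25)
  proto <- stimulus_protocol("all_cells", period = 1000, prepace = 10,
                             record_beats = 1)
  p1 <- model$default_params
  p2 <- p1; p2["gNa"] <- p2["gNa"] / 2   # the unmodified ten Tusscher gNa
  up <- function(params) {
    pr <- run_single_cell(model, proto, cfg, params = params)
    max(diff(pr$trace$v[, 1])) / cfg$record_dt
  }
  expect_gt(up(p1), up(p2))
})

test_that("external toy model registers and propagates on a 10x1 strand", {
  model <- register_external_model(toy_model_definition())
  expect_s3_class(model, "membrane_model")
  grid <- cell_grid(10, 1)
  coup <- build_coupling(grid, 600)
  proto <- stimulus_protocol("first_column", amplitude = -60, duration = 2,
                             period = 400, prepace = 0, record_beats = 1)
  pr <- run_paced(model, grid, coup, proto,
                  solve_config(dt_min = 0.01, dv_max = 1, record_dt = 1))
  tb <- apply(pr$trace$v, 2, function(v) toa(pr$trace$time, v))
  expect_true(all(is.finite(tb)))
  expect_true(all(diff(tb) > 0))   # wave travels left to right
})

test_that("adapter rejects contract violations", {
  bad <- toy_model_definition()
  bad$state_names <- c("u", "w")
  bad$initial_state <- function() c(u = -80, w = 0)
  expect_error(register_external_model(bad), "membrane potential")
  nofun <- toy_model_definition()
  nofun$rates <- NULL
  expect_error(register_external_model(nofun), "rates")
  nan_def <- toy_model_definition()
  nan_def$rates <- function(state, params, istim = 0, ip = 0)
    c(v = NaN, w = 0)
  expect_error(register_external_model(nan_def), "non-finite")
})

test_that("registering the built-in model through the adapter reproduces it", {
  native <- build_ord_hybrid()
  adapted <- register_external_model(list(
    name = "ord_hybrid", state_names = native$state_names,
    default_params = native$default_params,
    initial_state = native$initial_state, rates = native$rates))
  proto <- stimulus_protocol("all_cells", period = 1000, prepace = 2,
                             record_beats = 1)
  a <- run_single_cell(native, proto)
  b <- run_single_cell(adapted, proto)
  expect_identical(a$trace$v, b$trace$v)
})
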