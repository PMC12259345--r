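# Shared fixtures: a toy excitable model for the external-model contract and
# memoized simulation runs reused across test files.

.memo_env <- new.env(parent = emptyenv())
memo <- function(name, expr) {
  if (!exists(name, .memo_env)) assign(name, force(expr), .memo_env)
  get(name, .memo_env)
}

# Two-variable excitable toy model (cubic activation + linear recovery),
# stated in mV/ms units: rest near -80 mV, peak near +30 mV.
#   dv/dt = k*u*(u - a)*(1 - u)*110 - 110*c2*w + istim_term,  u = (v+80)/110
#   dw/dt = eps*(u - w)
toy_model_definition <- function() {
  k <- 3; a <- 0.15; c2 <- 1; eps <- 0.01
  list(
    name = "toy_cubic",
    state_names = c("v", "w"),
    default_params = c(k = k),
    initial_state = function() c(v = -80, w = 0),
    rates = function(state, params, istim = 0, ip = 0) {
      u <- (state[["v"]] + 80) / 110
      du <- params[["k"]] * u * (u - a) * (1 - u) - c2 * state[["w"]]
      c(v = 110 * du - istim - ip, w = eps * (u - state[["w"]]))
    }
  )
}

# paced single hybrid cell at 1 Hz, modest conditioning, 0.5 ms sampling
single_run_1hz <- function() memo("single_1hz", {
  run_single_cell(build_ord_hybrid(),
                  stimulus_protocol("all_cells", period = 1000, prepace = 20,
                                    record_beats = 1))
})

ead_protocol_params <- function(block, cal_factor = 4) {
  p <- ord_hybrid_default_params()
  p["pCaL"] <- cal_factor * p["pCaL"]
  apply_block(p, "gKr", block)
}

# idealized trapezoidal AP sampled at 0.5 ms: rest -80 until t = 10, linear
# rise to +40 at t = 11, plateau to t = 200, linear fall to -80 at t = 300
trapezoid_ap <- function(dt = 0.5, t_end = 350) {
  t <- seq(0, t_end, by = dt)
  v <- ifelse(t <= 10, -80,
       ifelse(t <= 11, -80 + 120 * (t - 10),
       ifelse(t <= 200, 40,
       ifelse(t <= 300, 40 - 1.2 * (t - 200), -80))))
  list(t = t, v = v)
}
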