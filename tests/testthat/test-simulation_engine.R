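# Simulation engine: RHS assembly, pacing, determinism, checkpointing and
# step-refinement convergence.

test_that("assemble_rhs on a 1x1 grid equals the single-cell derivative", {
  model <- build_ord_hybrid()
  g <- cell_grid(1, 1)
  proto <- stimulus_protocol("all_cells", period = 1000)
  rhs <- assemble_rhs(model, g, NULL, protocol = proto)
  s <- ord_hybrid_initial_state()
  expect_equal(rhs(0.2, as.numeric(s)),
               as.numeric(model$rates(s, model$default_params,
                                      istim = proto$amplitude)))
  expect_equal(rhs(500, as.numeric(s)),
               as.numeric(model$rates(s, model$default_params)))
})

test_that("Gg = 0 makes the assembled system block-diagonal", {
  model <- build_ord_hybrid()
  g <- cell_grid(2, 2)
  coup <- build_coupling(g, 600, Gg = 0)   # all junctions closed
  rhs <- assemble_rhs(model, g, coup)
  set.seed(3)
  states <- lapply(1:4, function(i) {
    s <- ord_hybrid_initial_state(); s["v"] <- runif(1, -85, 0); s
  })
  y <- unlist(states, use.names = FALSE)
  dy <- matrix(rhs(0, y), 38, 4)
  for (k in 1:4)
    expect_equal(dy[, k], as.numeric(model$rates(states[[k]],
                                                 model$default_params)))
})

test_that("compiled coupling matches the reference operator on 2x1", {
  # one adaptive step from a hand-packed state must move v by
  # dt * (membrane + coupling) within first-order accuracy
  model <- build_ord_hybrid()
  g <- cell_grid(2, 1)
  coup <- build_coupling(g, 600)
  s1 <- ord_hybrid_initial_state()
  s2 <- ord_hybrid_initial_state(); s2["v"] <- -60
  S <- cbind(s1, s2)
  dt <- 1e-3
  res <- sknm:::run_collection_cpp(
    S, matrix(model$default_params, 20, 2), c(0, 0),
    as.integer(coup$edges$a - 1), as.integer(coup$edges$b - 1), coup$w,
    c(0, 0), 0, 1, 1e9, 0, dt, Inf, 1, dt, dt, 1e9, 1e9)
  rhs <- assemble_rhs(model, g, coup)
  dy <- matrix(rhs(0, as.numeric(S)), 38, 2)
  expect_equal(res$state[1, ], S[1, ] + dt * dy[1, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("two identical coupled cells stay identical under shared stimulus", {
  model <- build_ord_hybrid()
  g <- cell_grid(2, 1)
  coup <- build_coupling(g, 600)
  proto <- stimulus_protocol("all_cells", period = 1000, prepace = 1,
                             record_beats = 1)
  pr <- run_paced(model, g, coup, proto)
  expect_equal(pr$trace$v[, 1], pr$trace$v[, 2], tolerance = 1e-12)
})

test_that("runs are deterministic and checkpoints are transparent", {
  model <- build_ord_hybrid()
  g <- cell_grid(2, 1)
  coup <- build_coupling(g, 600)
  proto <- stimulus_protocol("first_column", period = 1000, prepace = 3,
                             record_beats = 1)
  a <- run_paced(model, g, coup, proto)
  b <- run_paced(model, g, coup, proto)
  expect_identical(a$trace$v, b$trace$v)

  # (prepace 3, record) == (prepace 1, checkpoint, prepace 2, record)
  p1 <- stimulus_protocol("first_column", period = 1000, prepace = 1,
                          record_beats = 1)
  first <- run_paced(model, g, coup, p1)
  p2 <- stimulus_protocol("first_column", period = 1000, prepace = 1,
                          record_beats = 1)
  resumed <- run_paced(model, g, coup, p2, init = first$checkpoint)
  direct <- run_paced(model, g, coup,
                      stimulus_protocol("first_column", period = 1000,
                                        prepace = 3, record_beats = 1))
  expect_lt(max(abs(resumed$trace$v - direct$trace$v)), 0.5)  # mV
  apd <- function(x) apd50(x$trace$time, x$trace$v[, 2])
  expect_lt(abs(apd(resumed) - apd(direct)), 0.5)             # ms
})

test_that("checkpoints refuse to resume on provenance mismatch", {
  model <- build_ord_hybrid()
  g <- cell_grid(2, 1)
  coup <- build_coupling(g, 600)
  proto <- stimulus_protocol("first_column", period = 1000, prepace = 1)
  chk <- run_paced(model, g, coup, proto)$checkpoint
  wrong_period <- stimulus_protocol("first_column", period = 4000)
  expect_error(run_paced(model, g, coup, wrong_period, init = chk),
               "provenance")
  tampered <- chk
  tampered$state[1, 1] <- tampered$state[1, 1] + 1
  expect_error(run_paced(model, g, coup, proto, init = tampered),
               "checksum")
})

test_that("disconnection equivalence: Gg = 0 equals independent cells", {
  model <- build_ord_hybrid()
  g <- cell_grid(3, 2)
  sp <- variation_spec(4, r = 0.3, seed = 8)
  rz <- realize_variation(sp, g, model$default_params, 600)
  coup <- build_coupling(g, 600, Gg = 0)
  proto <- stimulus_protocol("all_cells", period = 1000, prepace = 2,
                             record_beats = 1)
  tissue <- run_paced(model, g, coup, proto, params = rz$params)
  # the tissue run shares one adaptive step across cells, so traces agree
  # to integration tolerance rather than bitwise
  for (k in c(1, 4, 6)) {
    single <- run_single_cell(model, proto, params = rz$params[, k])
    expect_lt(max(abs(tissue$trace$v[, k] - single$trace$v[, 1])), 1)
    expect_lt(abs(apd50(tissue$trace$time, tissue$trace$v[, k]) -
                    apd50(single$trace$time, single$trace$v[, 1])), 0.2)
  }
})

test_that("halving the step controls changes APD50 by < 0.5 ms", {
  model <- build_ord_hybrid()
  proto <- stimulus_protocol("all_cells", period = 1000, prepace = 15,
                             record_beats = 1)
  coarse <- run_single_cell(model, proto, solve_config())
  fine <- run_single_cell(model, proto, refine_config(solve_config(), 2))
  a1 <- apd50(coarse$trace$time, coarse$trace$v[, 1])
  a2 <- apd50(fine$trace$time, fine$trace$v[, 1])
  expect_lt(abs(a1 - a2), 0.5)
})

test_that("scan_axis returns empty on empty input and captures failures", {
  expect_length(scan_axis(numeric(), function(x) x), 0)
  res <- scan_axis(c(1, -1), function(x) {
    if (x < 0) stop("bad value") else x
  })
  expect_equal(res[["1"]], 1)
  expect_s3_class(res[["-1"]], "scan_failure")
  expect_match(res[["-1"]]$error, "bad value")
})

test_that("trace CSV round-trips through the tidy writer", {
  pr <- single_run_1hz()
  f <- tempfile(fileext = ".csv")
  write_trace_csv(pr$trace, f)
  df <- read.csv(f)
  expect_named(df, c("time_ms", "cell_x", "cell_y", "v_mV", "cai_mM"))
  expect_equal(df$v_mV, as.vector(pr$trace$v))
  meta <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_equal(meta$stimulus$period, 1000)
  unlink(c(f, paste0(f, ".json")))
})
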