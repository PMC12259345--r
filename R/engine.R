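# Pacing, pre-pacing, integration and trace recording for coupled cell
# collections.
#
# The full system (membrane states of every cell plus the coupling term) is
# advanced monolithically by an adaptive-step Rush-Larsen/forward-Euler
# scheme: relaxation-form states are updated exactly against their momentary
# steady state and time constant, everything else by forward Euler, with the
# global step chosen from the fastest membrane potential and subspace-calcium
# motion and capped by the explicit stability bound of the coupling operator.
# Accuracy is controlled by the solve_config step bounds and verified by the
# step-refinement convergence tests.

#' Stimulation protocol
#'
#' @param target `"first_column"` stimulates all cells with minimal x (the
#'   study-protocol planar wave initiation); `"all_cells"` stimulates every cell
#'   (used for uncoupled collections).
#' @param amplitude stimulus current density (A/F); negative = depolarizing.
#'   The default -80 A/F (the source model's own stimulus amplitude) reliably
#'   excites a stimulated column against the electrotonic load at strong
#'   coupling; -53 A/F does not.
#' @param duration stimulus duration (ms).
#' @param period cycle length (ms): 1000 for 1 Hz, 4000 for 0.25 Hz.
#' @param prepace number of unrecorded conditioning beats.
#' @param record_beats number of recorded beats.
#' @param coupled_prepace extra coupled conditioning beats used when
#'   pre-pacing runs uncoupled (see `prepace_mode` of [run_paced()]).
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(target = c("first_column", "all_cells"),
                              amplitude = -80, duration = 1, period = 1000,
                              prepace = 25, record_beats = 1,
                              coupled_prepace = 2) {
  target <- match.arg(target)
  stopifnot(duration > 0, period >= duration, prepace >= 0, record_beats >= 1)
  structure(list(target = target, amplitude = amplitude, duration = duration,
                 period = period, prepace = prepace,
                 record_beats = record_beats,
                 coupled_prepace = coupled_prepace),
            class = "stimulus_protocol")
}

#' Integrator accuracy settings
#'
#' @param dt_min,dt_max smallest/largest allowed step (ms).
#' @param dv_max largest allowed membrane-potential change per step (mV).
#' @param ca_rel largest allowed relative change of the fast calcium
#'   compartments per step.
#' @param record_dt trace sampling interval (ms); keep at or below 1 ms for
#'   biomarker-grade traces.
#' @return object of class `solve_config`.
#' @export
solve_config <- function(dt_min = 1e-3, dt_max = 0.5, dv_max = 0.2,
                         ca_rel = 0.05, record_dt = 0.5) {
  stopifnot(dt_min > 0, dt_max >= dt_min, dv_max > 0, ca_rel > 0,
            record_dt > 0, record_dt <= 1)
  structure(list(dt_min = dt_min, dt_max = dt_max, dv_max = dv_max,
                 ca_rel = ca_rel, record_dt = record_dt),
            class = "solve_config")
}

#' Refine a solve_config by a factor (for convergence checks)
#'
#' @param config a [solve_config()].
#' @param factor refinement factor (> 1 tightens all step controls).
#' @export
refine_config <- function(config, factor = 2) {
  solve_config(dt_min = config$dt_min / factor,
               dt_max = config$dt_max / factor,
               dv_max = config$dv_max / factor,
               ca_rel = config$ca_rel / factor,
               record_dt = config$record_dt)
}

.stim_mask <- function(grid, target) {
  if (target == "all_cells") rep(1, grid$n_cells)
  else as.numeric(grid_coords(grid)$x == 1)
}

.params_matrix <- function(model, params, nc) {
  if (is.null(params)) params <- model$default_params
  if (is.matrix(params)) {
    stopifnot(ncol(params) == nc,
              nrow(params) == length(model$default_params))
    return(params)
  }
  stopifnot(length(params) == length(model$default_params))
  matrix(params, length(params), nc,
         dimnames = list(names(model$default_params), NULL))
}

#' Assemble the full-system right-hand side (reference path)
#'
#' Returns the time-derivative function of the packed state (all states of
#' cell 1, then cell 2, ...): per-cell membrane rates plus the coupling
#' contribution, the stimulus where targeted, and any constant perturbation
#' current. Pure function of `(t, y)`; the compiled integrator implements
#' the identical operator and is tested against this one.
#'
#' @param model a `membrane_model`.
#' @param grid a [cell_grid()].
#' @param coupling a [build_coupling()] result (or `NULL` for no coupling).
#' @param params parameter vector or parameters-x-cells matrix.
#' @param ip per-cell constant perturbation currents (A/F).
#' @param protocol a [stimulus_protocol()] (or `NULL` for no stimulus).
#' @return `function(t, y)` returning `dy/dt`.
#' @export
assemble_rhs <- function(model, grid, coupling = NULL, params = NULL,
                         ip = NULL, protocol = NULL) {
  nc <- grid$n_cells
  ns <- length(model$state_names)
  pm <- .params_matrix(model, params, nc)
  if (is.null(ip)) ip <- rep(0, nc)
  stopifnot(length(ip) == nc)
  mask <- if (is.null(protocol)) rep(0, nc) else .stim_mask(grid, protocol$target)
  vidx <- which(model$state_names == "v")
  function(t, y) {
    if (length(y) != ns * nc) stop("packed state has wrong length")
    Y <- matrix(y, ns, nc)
    istim <- 0
    if (!is.null(protocol)) {
      phase <- t %% protocol$period
      if (phase < protocol$duration) istim <- protocol$amplitude
    }
    dy <- matrix(0, ns, nc)
    for (k in seq_len(nc)) {
      st <- Y[, k]
      names(st) <- model$state_names
      dy[, k] <- model$rates(st, pm[, k], istim * mask[k], ip[k])
    }
    if (!is.null(coupling) && nrow(coupling$edges) > 0)
      dy[vidx, ] <- dy[vidx, ] + coupling_rhs(Y[vidx, ], coupling, grid)
    as.vector(dy)
  }
}

.new_checkpoint <- function(state, beat, model, protocol, nc) {
  structure(list(
    state = state, beat = beat,
    provenance = list(model = model$name, n_cells = nc,
                      period = protocol$period,
                      state_checksum = signif(sum(state^2), 12))
  ), class = "state_checkpoint")
}

.check_resume <- function(chk, model, nc, protocol) {
  pr <- chk$provenance
  if (!identical(pr$model, model$name) || pr$n_cells != nc ||
      pr$period != protocol$period)
    stop("checkpoint provenance mismatch: was (", pr$model, ", ",
         pr$n_cells, " cells, period ", pr$period, " ms)")
  if (signif(sum(chk$state^2), 12) != pr$state_checksum)
    stop("checkpoint state does not match its provenance checksum")
}

.trace_set <- function(time, v, cai, grid, metadata) {
  structure(list(time = time, v = v, cai = cai, grid = grid,
                 metadata = metadata), class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d cells, %d samples (%.1f ms at %.2g ms)\n",
              ncol(x$v), length(x$time), diff(range(x$time)),
              x$metadata$record_dt))
  invisible(x)
}

# generic adaptive forward-Euler integrator for external (R-level) models
.integrate_r_model <- function(model, grid, coupling, pm, ip, mask, protocol,
                               config, S, t0, t_end, rec_start) {
  ns <- nrow(S); nc <- ncol(S)
  vidx <- which(model$state_names == "v")
  rec_times <- if (is.finite(rec_start))
    seq(rec_start, t_end, by = config$record_dt) else numeric()
  V <- matrix(NA_real_, length(rec_times), nc)
  CAI <- NULL
  ci <- which(model$state_names %in% c("cai", "Cai", "ca"))
  if (length(ci) == 1) CAI <- matrix(NA_real_, length(rec_times), nc)
  ri <- 1
  t <- t0
  w <- if (is.null(coupling)) numeric() else coupling$w
  dt_cap <- config$dt_max
  if (length(w) > 0) {
    wsum <- numeric(nc)
    for (e in seq_along(w)) {
      wsum[coupling$edges$a[e]] <- wsum[coupling$edges$a[e]] + w[e]
      wsum[coupling$edges$b[e]] <- wsum[coupling$edges$b[e]] + w[e]
    }
    dt_cap <- min(dt_cap, 0.8 / max(wsum))
  }
  while (t < t_end - 1e-9) {
    phase <- t %% protocol$period
    stim_on <- phase < protocol$duration - 1e-12
    D <- matrix(0, ns, nc)
    for (k in seq_len(nc)) {
      st <- S[, k]
      names(st) <- model$state_names
      D[, k] <- model$rates(st, pm[, k],
                            if (stim_on) protocol$amplitude * mask[k] else 0,
                            ip[k])
    }
    if (!is.null(coupling) && nrow(coupling$edges) > 0)
      D[vidx, ] <- D[vidx, ] + coupling_rhs(S[vidx, ], coupling, grid)
    dt <- min(dt_cap, config$dv_max / max(abs(D[vidx, ]), 1e-12))
    dt <- max(dt, config$dt_min)
    dt <- min(dt, if (stim_on) protocol$duration - phase
              else protocol$period - phase, t_end - t)
    if (ri <= length(rec_times)) dt <- min(dt, rec_times[ri] - t + 1e-12)
    S <- S + dt * D
    t <- t + dt
    while (ri <= length(rec_times) && t >= rec_times[ri] - 1e-9) {
      V[ri, ] <- S[vidx, ]
      if (!is.null(CAI)) CAI[ri, ] <- S[ci, ]
      ri <- ri + 1
    }
  }
  list(time = rec_times, v = V, cai = CAI, state = S)
}

.simulate_span <- function(model, grid, coupling, pm, ip, mask, protocol,
                           config, S, n_beats, record_from_beat = n_beats) {
  t_end <- n_beats * protocol$period
  rec_start <- if (record_from_beat < n_beats)
    record_from_beat * protocol$period else Inf
  edges_empty <- is.null(coupling) || nrow(coupling$edges) == 0
  if (identical(model$builtin, "ord_hybrid")) {
    run_collection_cpp(
      state = S, params = pm, ip = ip,
      edge_a = if (edges_empty) integer() else as.integer(coupling$edges$a - 1),
      edge_b = if (edges_empty) integer() else as.integer(coupling$edges$b - 1),
      edge_w = if (edges_empty) numeric() else coupling$w,
      stim_mask = mask, stim_amp = protocol$amplitude,
      stim_dur = protocol$duration, period = protocol$period,
      t0 = 0, t_end = t_end, rec_start = rec_start,
      record_dt = config$record_dt, dt_min = config$dt_min,
      dt_max = config$dt_max, dv_max = config$dv_max, ca_rel = config$ca_rel)
  } else {
    .integrate_r_model(model, grid, coupling, pm, ip, mask, protocol, config,
                       S, 0, t_end, rec_start)
  }
}

#' Run a paced simulation of a cell collection
#'
#' Conditions the collection with `protocol$prepace` unrecorded beats (either
#' fully coupled, or uncoupled-with-all-cell-stimulus followed by
#' `protocol$coupled_prepace` coupled beats when `prepace_mode = "isolated"`
#' -- the desk-scale shortcut), then records `protocol$record_beats` beats at
#' `config$record_dt` and returns the trace together with a resumable
#' checkpoint at the final beat boundary.
#'
#' @param model a `membrane_model`.
#' @param grid a [cell_grid()].
#' @param coupling a [build_coupling()] result, or `NULL` for fully
#'   disconnected cells.
#' @param protocol a [stimulus_protocol()].
#' @param config a [solve_config()].
#' @param params parameter vector (shared) or parameters-x-cells matrix.
#' @param ip per-cell constant perturbation currents (A/F), default none.
#' @param init `NULL` (model initial state), a state vector/matrix, or a
#'   checkpoint from a previous run (provenance-checked).
#' @param prepace_mode `"coupled"` (default, paper-faithful) or `"isolated"`.
#' @return object of class `paced_run` with `trace` (a `trace_set`) and
#'   `checkpoint`.
#' @export
run_paced <- function(model, grid, coupling, protocol,
                      config = solve_config(), params = NULL, ip = NULL,
                      init = NULL, prepace_mode = c("coupled", "isolated")) {
  prepace_mode <- match.arg(prepace_mode)
  nc <- grid$n_cells
  ns <- length(model$state_names)
  pm <- .params_matrix(model, params, nc)
  if (is.null(ip)) ip <- rep(0, nc)
  stopifnot(length(ip) == nc)
  mask <- .stim_mask(grid, protocol$target)

  beat0 <- 0L
  if (inherits(init, "state_checkpoint")) {
    .check_resume(init, model, nc, protocol)
    S <- init$state
    beat0 <- init$beat
  } else if (is.null(init)) {
    S <- matrix(model$initial_state(), ns, nc)
  } else if (is.matrix(init)) {
    stopifnot(nrow(init) == ns, ncol(init) == nc)
    S <- init
  } else {
    stopifnot(length(init) == ns)
    S <- matrix(init, ns, nc)
  }

  if (prepace_mode == "isolated" && protocol$prepace > 0) {
    iso_proto <- protocol
    iso_proto$target <- "all_cells"
    res <- .simulate_span(model, grid, NULL, pm, ip, rep(1, nc), iso_proto,
                          config, S, protocol$prepace)
    S <- res$state
    n_pre <- protocol$coupled_prepace
  } else {
    n_pre <- protocol$prepace
  }
  n_tot <- n_pre + protocol$record_beats
  res <- .simulate_span(model, grid, coupling, pm, ip, mask, protocol,
                        config, S, n_tot, record_from_beat = n_pre)
  time <- res$time - n_pre * protocol$period
  meta <- list(model = model$name, nx = grid$nx, ny = grid$ny,
               Gg_star = if (!is.null(coupling)) coupling$Gg_star else 0,
               lambda = if (!is.null(coupling)) coupling$lambda else NA,
               stimulus = protocol[c("target", "amplitude", "duration",
                                     "period")],
               prepace = protocol$prepace, prepace_mode = prepace_mode,
               record_dt = config$record_dt,
               scaling_order = "type perturbation -> block -> random scaling")
  trace <- .trace_set(time, res$v, res$cai, grid, meta)
  chk <- .new_checkpoint(res$state, beat0 + n_tot, model, protocol, nc)
  structure(list(trace = trace, checkpoint = chk, metadata = meta),
            class = "paced_run")
}

#' Run a paced single-cell simulation
#'
#' Convenience wrapper around [run_paced()] on a 1 x 1 grid with the
#' all-cells stimulus.
#'
#' @inheritParams run_paced
#' @export
run_single_cell <- function(model, protocol, config = solve_config(),
                            params = NULL, init = NULL) {
  protocol$target <- "all_cells"
  run_paced(model, cell_grid(1, 1), NULL, protocol, config, params,
            init = init)
}

#' Sweep an axis of simulations
#'
#' Runs `run(value)` for every value, capturing failures as explicit records
#' instead of aborting the sweep.
#'
#' @param values axis values (e.g. average conductances in nS).
#' @param run function of one value returning any result.
#' @return named list of class `scan_result`; failed members carry class
#'   `scan_failure` with the error message.
#' @export
scan_axis <- function(values, run) {
  out <- lapply(values, function(v) {
    tryCatch(run(v), error = function(e)
      structure(list(value = v, error = conditionMessage(e)),
                class = "scan_failure"))
  })
  names(out) <- as.character(values)
  structure(out, class = "scan_result", values = values)
}

#' Write a trace as tidy CSV (with a JSON metadata sidecar)
#'
#' Columns: `time_ms, cell_x, cell_y, v_mV, cai_mM`.
#'
#' @param trace a `trace_set`.
#' @param path output CSV path; metadata goes to `paste0(path, ".json")`.
#' @export
write_trace_csv <- function(trace, path) {
  co <- grid_coords(trace$grid)
  nt <- length(trace$time)
  df <- data.frame(
    time_ms = rep(trace$time, times = nrow(co)),
    cell_x = rep(co$x, each = nt),
    cell_y = rep(co$y, each = nt),
    v_mV = as.vector(trace$v)
  )
  if (!is.null(trace$cai)) df$cai_mM <- as.vector(trace$cai)
  utils::write.csv(df, path, row.names = FALSE)
  writeLines(jsonlite::toJSON(trace$metadata, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}
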