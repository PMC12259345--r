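# Per-cell and per-tissue biomarkers: APD50, times of arrival, dispersion,
# conduction velocity, calcium-transient amplitude, EAD detection.
#
# All crossings are linearly interpolated between recorded samples, so the
# default 0.5 ms sampling is sufficient; missing features are flagged NA,
# never silently zero.

# linearly interpolated time where v crosses `thr`, between samples i, i+1
.cross_time <- function(t, v, i, thr) {
  t[i] + (thr - v[i]) * (t[i + 1] - t[i]) / (v[i + 1] - v[i])
}

#' Action potential duration at 50% repolarization
#'
#' Duration from the time of maximum upstroke velocity (finite differences
#' on the recorded grid) to the final interpolated downward crossing of the
#' level halfway between the beat's maximum and minimum potentials after the
#' AP peak. Cells that never fire (maximum dv/dt below `dvdt_floor`) or never
#' repolarize below the halfway level yield `NA`.
#'
#' @param t sample times (ms).
#' @param v membrane potential samples (mV) of one beat.
#' @param dvdt_floor excitation floor for the upstroke (mV/ms).
#' @return APD50 in ms, or `NA` if the beat has no complete AP.
#' @export
apd50 <- function(t, v, dvdt_floor = 5) {
  stopifnot(length(t) == length(v), length(t) >= 3)
  dvdt <- diff(v) / diff(t)
  # earliest sample within float noise of the maximum slope, so that
  # supersampling a piecewise-linear trace cannot shift the upstroke time
  m <- max(dvdt)
  if (!is.finite(m) || m < dvdt_floor) return(NA_real_)
  iu <- which(dvdt >= m - abs(m) * 1e-9)[1]
  t_up <- t[iu]
  vmax <- max(v); vmin <- min(v)
  thr <- (vmax + vmin) / 2
  ipk <- which.max(v)
  down <- which(v[-length(v)] > thr & v[-1] <= thr)
  down <- down[down >= ipk]
  if (length(down) == 0) return(NA_real_)
  t_end <- .cross_time(t, v, down[length(down)], thr)
  t_end - t_up
}

#' Time of arrival of the depolarization or repolarization wave
#'
#' The interpolated time at which the potential crosses `threshold` (-30 mV):
#' first upward crossing for depolarization, last downward crossing within
#' the beat for repolarization (so an EAD-bearing cell reports the arrival of
#' its final repolarization).
#'
#' @param t,v one beat of samples.
#' @param phase `"depolarization"` or `"repolarization"`.
#' @param threshold crossing level (mV).
#' @return time in ms (same clock as `t`), or `NA` if there is no crossing.
#' @export
toa <- function(t, v, phase = c("depolarization", "repolarization"),
                threshold = -30) {
  phase <- match.arg(phase)
  stopifnot(length(t) == length(v), length(t) >= 2)
  n <- length(v)
  if (phase == "depolarization") {
    up <- which(v[-n] < threshold & v[-1] >= threshold)
    if (length(up) == 0) return(NA_real_)
    .cross_time(t, v, up[1], threshold)
  } else {
    down <- which(v[-n] > threshold & v[-1] <= threshold)
    if (length(down) == 0) return(NA_real_)
    .cross_time(t, v, down[length(down)], threshold)
  }
}

#' Calcium-transient amplitude over one beat
#'
#' `max(Cai) - min(Cai)` within the beat window, reported in uM (input mM).
#'
#' @param cai cytosolic calcium samples (mM).
#' @return amplitude in uM.
#' @export
calcium_amplitude <- function(cai) {
  (max(cai) - min(cai)) * 1e3
}

#' Count early afterdepolarizations in one beat
#'
#' An EAD is counted when, after the AP peak and before final repolarization,
#' dv/dt turns from negative to positive while the potential lies inside the
#' detection window, and the potential subsequently rises by at least
#' `rebound` mV before turning down again. Monotone repolarization gives 0.
#'
#' @param t,v one beat of samples.
#' @param window voltage window (mV) in which secondary depolarizations are
#'   scored.
#' @param rebound minimal rise (mV) after the local minimum.
#' @return integer count (0 for subthreshold or resting traces).
#' @export
detect_eads <- function(t, v, window = c(-60, 0), rebound = 2) {
  stopifnot(length(t) == length(v))
  n <- length(v)
  if (n < 4) return(0L)
  ipk <- which.max(v)
  if (ipk >= n - 1) return(0L)
  dv <- diff(v)
  count <- 0L
  i <- ipk + 1
  while (i < n - 1) {
    # local minimum: dv turns from <=0 to >0
    if (dv[i - 1] <= 0 && dv[i] > 0 &&
        v[i] > window[1] && v[i] < window[2]) {
      # find the following local maximum (or end)
      j <- i + 1
      while (j < n && dv[j] > 0) j <- j + 1
      if (v[j] - v[i] >= rebound) {
        count <- count + 1L
        i <- j
      }
    }
    i <- i + 1
  }
  count
}

#' Per-cell biomarker table of a recorded trace
#'
#' Splits the trace into beats by stimulus times and evaluates APD50, the
#' depolarization/repolarization times of arrival, calcium-transient
#' amplitude and EAD count per cell and beat. ToA values are on the beat
#' clock (ms after the beat's stimulus).
#'
#' @param trace a `trace_set` from [run_paced()].
#' @param dvdt_floor excitation floor passed to [apd50()].
#' @param ead_window,ead_rebound EAD detector settings.
#' @return data.frame of class `biomarker_table` with columns `cell`,
#'   `cell_x`, `cell_y`, `beat`, `apd50_ms`, `toa_dep_ms`, `toa_rep_ms`,
#'   `caa_uM`, `ead_count`.
#' @export
biomarker_table <- function(trace, dvdt_floor = 5, ead_window = c(-60, 0),
                            ead_rebound = 2) {
  period <- trace$metadata$stimulus$period
  nb <- max(1L, floor((max(trace$time) + 1e-6) / period))
  co <- grid_coords(trace$grid)
  out <- vector("list", nb * nrow(co))
  idx <- 1
  for (b in seq_len(nb)) {
    sel <- trace$time >= (b - 1) * period - 1e-9 &
      trace$time <= b * period + 1e-9
    tb <- trace$time[sel] - (b - 1) * period
    for (k in seq_len(nrow(co))) {
      vb <- trace$v[sel, k]
      out[[idx]] <- data.frame(
        cell = k, cell_x = co$x[k], cell_y = co$y[k], beat = b,
        apd50_ms = apd50(tb, vb, dvdt_floor),
        toa_dep_ms = toa(tb, vb, "depolarization"),
        toa_rep_ms = toa(tb, vb, "repolarization"),
        caa_uM = if (!is.null(trace$cai))
          calcium_amplitude(trace$cai[sel, k]) else NA_real_,
        ead_count = detect_eads(tb, vb, ead_window, ead_rebound)
      )
      idx <- idx + 1
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("biomarker_table", "data.frame")
  res
}

#' Time-of-arrival dispersion across one grid column
#'
#' Max minus min ToA over all cells sharing the x-index, per phase. A column
#' containing any missing ToA is flagged incomplete (`NA` with attribute).
#'
#' @param table a [biomarker_table()].
#' @param grid the matching [cell_grid()].
#' @param column x-index of the column.
#' @param beat beat to evaluate.
#' @return data.frame with `column`, `phase`, `max_delta_toa_ms`,
#'   `incomplete`.
#' @export
toa_dispersion <- function(table, grid, column, beat = 1) {
  rows <- table[table$cell_x == column & table$beat == beat, ]
  if (nrow(rows) != grid$ny) stop("column ", column, " not fully present")
  disp <- function(x) {
    if (anyNA(x)) NA_real_ else max(x) - min(x)
  }
  data.frame(
    column = column,
    phase = c("depolarization", "repolarization"),
    max_delta_toa_ms = c(disp(rows$toa_dep_ms), disp(rows$toa_rep_ms)),
    incomplete = c(anyNA(rows$toa_dep_ms), anyNA(rows$toa_rep_ms))
  )
}

#' Longitudinal conduction velocity from depolarization times of arrival
#'
#' `CV = (to_col - from_col) * l / mean(delta ToA)` in cm/s, with the columns
#' defaulting to 25% and 75% of the x-extent to stay clear of stimulus and
#' boundary artifacts.
#'
#' @param table a [biomarker_table()].
#' @param grid the matching [cell_grid()].
#' @param from_col,to_col measurement columns (x-indices).
#' @param beat beat to evaluate.
#' @return speed in cm/s.
#' @export
conduction_velocity <- function(table, grid,
                                from_col = max(1L, round(0.25 * grid$nx)),
                                to_col = round(0.75 * grid$nx), beat = 1) {
  if (to_col <= from_col) stop("to_col must exceed from_col")
  t1 <- table$toa_dep_ms[table$cell_x == from_col & table$beat == beat]
  t2 <- table$toa_dep_ms[table$cell_x == to_col & table$beat == beat]
  if (anyNA(t1) || anyNA(t2) || !length(t1) || !length(t2))
    stop("incomplete depolarization ToA in measurement columns")
  dt <- mean(t2) - mean(t1)
  if (dt <= 0) stop("wave did not travel from column ", from_col,
                    " to column ", to_col)
  (to_col - from_col) * grid$l / dt * 1000   # cm/ms -> cm/s
}

#' Dispersion summary over all columns (Fig.-6-style)
#'
#' @param table a [biomarker_table()].
#' @param grid the matching [cell_grid()].
#' @param beat beat to evaluate.
#' @return data.frame with per-column dispersion for both phases plus the
#'   per-run maxima as attribute `maxima`.
#' @export
dispersion_summary <- function(table, grid, beat = 1) {
  rows <- do.call(rbind, lapply(seq_len(grid$nx), function(cx)
    toa_dispersion(table, grid, cx, beat)))
  mx <- stats::aggregate(max_delta_toa_ms ~ phase, rows, max, na.rm = TRUE)
  attr(rows, "maxima") <- mx
  rows
}

#' Write a biomarker table and its dispersion summary to CSV
#'
#' @param table a [biomarker_table()].
#' @param path CSV path for the table; the dispersion summary goes to
#'   `paste0(path, "_dispersion.csv")` when `grid` is given.
#' @param grid optional [cell_grid()] for the dispersion summary.
#' @export
write_biomarkers_csv <- function(table, path, grid = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  if (!is.null(grid))
    utils::write.csv(dispersion_summary(table, grid),
                     paste0(sub("\\.csv$", "", path), "_dispersion.csv"),
                     row.names = FALSE)
  invisible(path)
}
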