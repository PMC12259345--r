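# SKNM tissue geometry and coupling.
#
# Cells are cylinders (length l = 100 um, diameter d = 20 um) packed in l x d
# x d boxes on a 2D grid with 4-connectivity (no diagonals). Each connection
# lumps the myoplasmic resistance of the two half-cells in series with the
# gap-junction conductance (Eq.-3-type series formula); extracellular effects
# are folded into the scalar factor lambda/(1+lambda).
#
# Internal units: cm, mS, uF, mV, ms.

#' Build the geometry of a 2D cell collection
#'
#' @param nx,ny number of cells in the x- (propagation) and y-directions.
#' @return object of class `cell_grid`: cell counts, cylinder geometry
#'   (`l`, `d` in cm), specific capacitance `Cm` (uF/cm2), membrane area
#'   `Am = 2*pi*l*d` (cm2, the factor 2 accounts for membrane folding),
#'   intracellular volume fraction `delta_i = pi/4`, conductivities `sigma_i`
#'   = 4 mS/cm and `sigma_e` = 20 mS/cm, and the connection list `edges`
#'   (x-connections row-major, then y-connections).
#'   Cell k sits at (`x = (k-1) %% nx + 1`, `y = (k-1) %/% nx + 1`).
#' @export
cell_grid <- function(nx, ny) {
  stopifnot(nx >= 1, ny >= 1)
  l <- 100e-4; d <- 20e-4                      # cm
  edges <- list()
  # x-connections, row-major
  ex <- NULL
  if (nx > 1) {
    a <- as.vector(outer(seq_len(nx - 1), (seq_len(ny) - 1) * nx, "+"))
    ex <- data.frame(a = a, b = a + 1, dir = "x", stringsAsFactors = FALSE)
  }
  ey <- NULL
  if (ny > 1) {
    a <- as.vector(outer(seq_len(nx), (seq_len(ny - 1) - 1) * nx, "+"))
    ey <- data.frame(a = a, b = a + nx, dir = "y", stringsAsFactors = FALSE)
  }
  edges <- rbind(ex, ey)
  if (is.null(edges)) edges <- data.frame(a = integer(), b = integer(),
                                          dir = character())
  structure(list(
    nx = nx, ny = ny, n_cells = nx * ny,
    l = l, d = d, Cm = 1, Am = 2 * pi * l * d,
    delta_i = pi / 4, sigma_i = 4, sigma_e = 20,
    edges = edges
  ), class = "cell_grid")
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("cell_grid: %d x %d cells (%d connections)\n",
              x$nx, x$ny, nrow(x$edges)))
  invisible(x)
}

#' Cell coordinates of a grid
#'
#' @param grid a [cell_grid()].
#' @return data.frame with columns `cell`, `x`, `y`.
#' @export
grid_coords <- function(grid) {
  k <- seq_len(grid$n_cells)
  data.frame(cell = k,
             x = (k - 1) %% grid$nx + 1,
             y = (k - 1) %/% grid$nx + 1)
}

#' Geometry of a single cell connection
#'
#' Center distance `L` and cross-sectional area `A` follow from the
#' box-packing consistent with the intracellular volume fraction pi/4:
#' x-connections have `L = l`, `A = d^2`; y-connections `L = d`, `A = l*d`.
#'
#' @param direction `"x"` or `"y"`.
#' @param grid a [cell_grid()].
#' @return list with `direction`, `L` (cm), `A` (cm2).
#' @export
connection_geometry <- function(direction = c("x", "y"), grid = cell_grid(1, 1)) {
  direction <- match.arg(direction)
  if (direction == "x") list(direction = "x", L = grid$l, A = grid$d^2)
  else list(direction = "y", L = grid$d, A = grid$l * grid$d)
}

.ns_to_mS <- 1e-6

#' Intercellular (myoplasm + gap junction) conductance of one connection
#'
#' Series combination of the myoplasmic path and the gap junction:
#' `1 / ( L/(delta_i*A*sigma_i) + 1/Gg )` (mS). A closed gap junction
#' (`Gg = 0`) disconnects the cells.
#'
#' @param geom a [connection_geometry()].
#' @param Gg gap-junction conductance in nS.
#' @param grid the [cell_grid()] supplying `delta_i` and `sigma_i`.
#' @return conductance in mS.
#' @export
intracellular_conductance <- function(geom, Gg, grid = cell_grid(1, 1)) {
  if (any(Gg < 0)) stop("gap junction conductance must be >= 0")
  Gg_mS <- Gg * .ns_to_mS
  r_myo <- geom$L / (grid$delta_i * geom$A * grid$sigma_i)
  ifelse(Gg_mS == 0, 0, 1 / (r_myo + 1 / Gg_mS))
}

#' Extracellular conductance of one connection
#'
#' `(1 - delta_i) * A * sigma_e / L` (mS).
#'
#' @inheritParams intracellular_conductance
#' @return conductance in mS.
#' @export
extracellular_conductance <- function(geom, grid = cell_grid(1, 1)) {
  (1 - grid$delta_i) * geom$A * grid$sigma_e / geom$L
}

#' The scalar coupling constant lambda
#'
#' Computed once per simulation from the average gap-junction conductance and
#' x-direction geometry: `lambda = Ge_x / Gi_x*`, never per connection.
#'
#' @param grid a [cell_grid()].
#' @param Gg_star average gap-junction conductance in nS; must be > 0.
#' @return unitless lambda.
#' @export
lambda_constant <- function(grid, Gg_star) {
  if (length(Gg_star) != 1 || !is.finite(Gg_star) || Gg_star <= 0)
    stop("Gg_star must be a single positive conductance (nS)")
  gx <- connection_geometry("x", grid)
  Gi_x <- intracellular_conductance(gx, Gg_star, grid)
  Ge_x <- extracellular_conductance(gx, grid)
  Ge_x / Gi_x
}

#' Assemble the per-connection coupling of a cell collection
#'
#' @param grid a [cell_grid()].
#' @param Gg_star average gap-junction conductance (nS), used for lambda.
#' @param Gg per-connection gap-junction conductances (nS); a scalar is
#'   recycled (uniform coupling). Order must follow `grid$edges`.
#' @return object of class `coupling_matrix`: `edges` (with `Gg` in nS and
#'   `Gi` in mS), `lambda`, `Gg_star`, and `w`, the ready-to-use edge weight
#'   `lambda/(1+lambda) * Gi / (Cm*Am)` in 1/ms.
#' @export
build_coupling <- function(grid, Gg_star, Gg = Gg_star) {
  ne <- nrow(grid$edges)
  if (length(Gg) == 1) Gg <- rep(Gg, ne)
  if (length(Gg) != ne) stop("need one Gg per connection (", ne, ")")
  if (any(Gg < 0)) stop("gap junction conductances must be >= 0")
  lam <- lambda_constant(grid, Gg_star)
  Gi <- numeric(ne)
  for (dd in c("x", "y")) {
    idx <- grid$edges$dir == dd
    if (any(idx))
      Gi[idx] <- intracellular_conductance(connection_geometry(dd, grid),
                                           Gg[idx], grid)
  }
  w <- lam / (1 + lam) * Gi / (grid$Cm * grid$Am)
  edges <- grid$edges
  edges$Gg <- Gg
  edges$Gi <- Gi
  structure(list(edges = edges, lambda = lam, Gg_star = Gg_star, w = w,
                 CmAm = grid$Cm * grid$Am),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("coupling_matrix: %d connections, Gg* = %g nS, lambda = %.4f\n",
              nrow(x$edges), x$Gg_star, x$lambda))
  invisible(x)
}

#' Coupling contribution to dv/dt (reference implementation)
#'
#' `lambda/((1+lambda)*Cm*Am) * sum_j Gi_jk (v_j - v_k)` per cell, in mV/ms.
#' The compiled integrator applies the same operator; this version exists for
#' direct evaluation and testing.
#'
#' @param v per-cell membrane potentials (mV).
#' @param coupling a [build_coupling()] result.
#' @param grid the matching [cell_grid()].
#' @return per-cell dv/dt contribution (mV/ms).
#' @export
coupling_rhs <- function(v, coupling, grid) {
  if (!all(is.finite(v))) stop("non-finite membrane potentials")
  if (length(v) != grid$n_cells) stop("v must have one entry per cell")
  out <- numeric(length(v))
  a <- coupling$edges$a; b <- coupling$edges$b; w <- coupling$w
  dv <- v[b] - v[a]
  for (e in seq_along(w)) {
    out[a[e]] <- out[a[e]] + w[e] * dv[e]
    out[b[e]] <- out[b[e]] - w[e] * dv[e]
  }
  out
}

#' Serialize a grid and its coupling to JSON
#'
#' @param grid a [cell_grid()]; `coupling` a [build_coupling()] result.
#' @param coupling coupling to serialize.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @export
write_coupling_json <- function(grid, coupling, path = NULL) {
  obj <- list(
    nx = grid$nx, ny = grid$ny,
    l_cm = grid$l, d_cm = grid$d, Cm_uF_cm2 = grid$Cm, Am_cm2 = grid$Am,
    delta_i = grid$delta_i, sigma_i_mS_cm = grid$sigma_i,
    sigma_e_mS_cm = grid$sigma_e,
    Gg_star_nS = coupling$Gg_star, lambda = coupling$lambda,
    edge_order = "x-connections row-major, then y-connections",
    Gg_nS = coupling$edges$Gg
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
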