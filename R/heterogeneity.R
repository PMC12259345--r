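# Seeded generators for cell and gap-junction heterogeneity.
#
# All draws are uniform on the stated intervals. A master seed derives fixed
# substreams for (parameter scalings, perturbation currents, gap variation,
# layout), so enabling one kind of map never shifts another's draws.

.case_table <- list(
  `1` = list(cell = "two_type", gap = FALSE, layout = "random"),
  `2` = list(cell = "two_type", gap = FALSE, layout = "checkerboard"),
  `3` = list(cell = "none", gap = TRUE, layout = NA),
  `4` = list(cell = "parameters", gap = FALSE, layout = NA),
  `5` = list(cell = "parameters", gap = TRUE, layout = NA),
  `6` = list(cell = "perturbation", gap = FALSE, layout = NA)
)

#' Specify a heterogeneity scheme
#'
#' The six variation cases: (1) two cell types, randomly mixed; (2) two cell
#' types, checkerboard; (3) gap-junction variation only; (4) random cell
#' parameter variation; (5) cell parameters plus gap variation; (6) constant
#' perturbation currents.
#'
#' @param case integer 1..6.
#' @param r cell-variation degree in `[0, 1]` (parameter scaling half-width,
#'   or the perturbation-current half-width in A/F for case 6).
#' @param gap_level gap-junction variation half-width (0, 0.25 or 0.5).
#' @param seed master RNG seed.
#' @param type_fraction probability that a cell is perturbed (case 1).
#' @return object of class `variation_spec`.
#' @export
variation_spec <- function(case, r = 0, gap_level = 0, seed = 1,
                           type_fraction = 0.5) {
  case <- as.integer(case)
  if (!case %in% 1:6) stop("case must be 1..6")
  info <- .case_table[[as.character(case)]]
  if (!is.numeric(r) || r < 0 || r > 1)
    stop("r must lie in [0, 1]")
  if (!is.numeric(gap_level) || gap_level < 0 || gap_level >= 1)
    stop("gap_level must lie in [0, 1)")
  if (!info$gap && gap_level != 0)
    stop("case ", case, " has no gap junction variation")
  if (info$cell == "none" && r != 0)
    stop("case ", case, " has no cell variation")
  structure(list(case = case, r = r, gap_level = gap_level, seed = seed,
                 layout = info$layout, type_fraction = type_fraction,
                 cell_variation = info$cell, gap_variation = info$gap),
            class = "variation_spec")
}

# fixed substream derivation, kept below 2^31
.sub_seed <- function(seed, stream) {
  offs <- c(parameters = 101, perturbation = 211, gap = 307, layout = 401)
  as.integer((as.numeric(seed) * 2654435761 + offs[[stream]]) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw per-cell parameter scaling factors (cases 4 and 5)
#'
#' One independent `alpha[i, k]` uniform on `[-1, 1]` per scalable parameter
#' i and cell k; realized parameters are `(1 + r * alpha[i, k]) * p_i*`.
#'
#' @param spec a [variation_spec()] with parameter variation.
#' @param params default (or otherwise adjusted) parameter vector `p*`.
#' @param grid a [cell_grid()].
#' @return object of class `parameter_scaling_map`: `alpha` and the realized
#'   parameter matrix `p` (parameters x cells).
#' @export
draw_parameter_scalings <- function(spec, params, grid) {
  if (spec$cell_variation != "parameters")
    stop("case ", spec$case, " does not use cell parameter variation")
  np <- length(params); nc <- grid$n_cells
  alpha <- .with_seed(.sub_seed(spec$seed, "parameters"),
                      matrix(stats::runif(np * nc, -1, 1), np, nc))
  rownames(alpha) <- names(params)
  p <- (1 + spec$r * alpha) * params
  structure(list(alpha = alpha, p = p, r = spec$r, seed = spec$seed),
            class = "parameter_scaling_map")
}

#' Draw per-cell constant perturbation currents (case 6)
#'
#' `Ip_k = r * alpha_k` with `alpha_k` uniform on `[-1, 1]` A/F; the current
#' is constant in time and added to the total ionic current of cell k.
#'
#' @param spec a [variation_spec()] with case 6.
#' @param grid a [cell_grid()].
#' @return object of class `perturbation_current_map` with `alpha` and `ip`
#'   (A/F) per cell.
#' @export
draw_perturbation_currents <- function(spec, grid) {
  if (spec$cell_variation != "perturbation")
    stop("case ", spec$case, " does not use perturbation currents")
  alpha <- .with_seed(.sub_seed(spec$seed, "perturbation"),
                      stats::runif(grid$n_cells, -1, 1))
  structure(list(alpha = alpha, ip = spec$r * alpha, r = spec$r,
                 seed = spec$seed),
            class = "perturbation_current_map")
}

#' Draw per-connection gap-junction conductances (cases 3 and 5)
#'
#' `Gg_i = (1 + beta_i) * Gg*` with `beta_i` uniform on
#' `[-gap_level, gap_level]`, in the documented connection order.
#'
#' @param spec a [variation_spec()] with gap variation (a zero `gap_level`
#'   yields the uniform coupling `Gg*` everywhere).
#' @param grid a [cell_grid()].
#' @param Gg_star average gap-junction conductance (nS).
#' @return object of class `gap_variation_map` with `beta` and `Gg` (nS).
#' @export
draw_gap_variation <- function(spec, grid, Gg_star) {
  if (spec$gap_level >= 1) stop("gap_level must be < 1")
  ne <- nrow(grid$edges)
  beta <- if (spec$gap_level == 0) rep(0, ne)
  else .with_seed(.sub_seed(spec$seed, "gap"),
                  stats::runif(ne, -spec$gap_level, spec$gap_level))
  structure(list(beta = beta, Gg = (1 + beta) * Gg_star, Gg_star = Gg_star,
                 gap_level = spec$gap_level, seed = spec$seed),
            class = "gap_variation_map")
}

#' Assign the two cell types over the grid (cases 1 and 2)
#'
#' Random layouts mark each cell perturbed independently with probability
#' `type_fraction`; checkerboard layouts assign by parity of `x + y` (the
#' perturbed type where the parity is odd).
#'
#' @param spec a [variation_spec()] with case 1 or 2.
#' @param grid a [cell_grid()].
#' @return integer vector per cell: 0 = healthy, 1 = perturbed; class
#'   `cell_type_layout`.
#' @export
make_two_type_layout <- function(spec, grid) {
  if (spec$cell_variation != "two_type")
    stop("case ", spec$case, " is not a two-cell-type case")
  co <- grid_coords(grid)
  types <- if (spec$layout == "checkerboard") {
    as.integer((co$x + co$y) %% 2 == 1)
  } else {
    .with_seed(.sub_seed(spec$seed, "layout"),
               as.integer(stats::runif(grid$n_cells) < spec$type_fraction))
  }
  structure(types, class = "cell_type_layout", layout = spec$layout)
}

#' Realize all variation maps of a spec as engine inputs
#'
#' Builds the per-cell parameter matrix, perturbation-current vector and
#' per-connection conductances for a spec, starting from base parameters.
#'
#' @param spec a [variation_spec()].
#' @param grid a [cell_grid()].
#' @param base_params base parameter vector (defaults already including any
#'   block or type perturbation shared by all cells).
#' @param Gg_star average gap-junction conductance (nS).
#' @return list with `params` (parameters x cells matrix), `ip` (A/F per
#'   cell), `Gg` (nS per connection), `types` (or NULL) and the raw maps.
#' @export
realize_variation <- function(spec, grid, base_params, Gg_star) {
  nc <- grid$n_cells
  pm <- matrix(base_params, length(base_params), nc,
               dimnames = list(names(base_params), NULL))
  ip <- rep(0, nc)
  Gg <- rep(Gg_star, nrow(grid$edges))
  maps <- list()
  types <- NULL
  if (spec$cell_variation == "parameters" && spec$r > 0) {
    maps$scaling <- draw_parameter_scalings(spec, base_params, grid)
    pm <- maps$scaling$p
  } else if (spec$cell_variation == "perturbation") {
    maps$perturbation <- draw_perturbation_currents(spec, grid)
    ip <- maps$perturbation$ip
  } else if (spec$cell_variation == "two_type") {
    types <- make_two_type_layout(spec, grid)
    maps$layout <- types
    pp <- make_perturbed_type(base_params)
    pm[, types == 1] <- pp
  }
  if (spec$gap_variation) {
    maps$gap <- draw_gap_variation(spec, grid, Gg_star)
    Gg <- maps$gap$Gg
  }
  list(params = pm, ip = ip, Gg = Gg, types = types, maps = maps,
       spec = spec)
}

#' Serialize variation maps to JSON
#'
#' @param realized result of [realize_variation()].
#' @param path optional output file.
#' @export
write_variation_json <- function(realized, path = NULL) {
  sp <- realized$spec
  obj <- list(
    case = sp$case, r = sp$r, gap_level = sp$gap_level, seed = sp$seed,
    layout = sp$layout, type_fraction = sp$type_fraction,
    alpha = if (!is.null(realized$maps$scaling)) realized$maps$scaling$alpha,
    ip_A_per_F = realized$ip,
    beta = if (!is.null(realized$maps$gap)) realized$maps$gap$beta,
    types = if (!is.null(realized$types)) as.integer(realized$types),
    edge_order = "x-connections row-major, then y-connections"
  )
  txt <- jsonlite::toJSON(obj[!vapply(obj, is.null, TRUE)],
                          auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
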