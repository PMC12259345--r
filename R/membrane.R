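# Membrane-model objects: the built-in hybrid ventricular model and the
# adapter contract for externally supplied models (e.g. the adult ventricular
# base model with the Rice contraction model, available from the authors'
# deposit; re-implementing those is out of scope here).

.zenodo_base_model <- "https://doi.org/10.5281/zenodo.15798522"

#' Build the hybrid ventricular membrane model
#'
#' O'Hara-Rudy endocardial currents with the ten Tusscher fast sodium current
#' (conductance doubled). The returned object satisfies the membrane-model
#' contract used by all tissue and biomarker operations: a state template,
#' default parameters, `iion(state, params)` (A/F, outward positive),
#' `rates(state, params)` and `initial_state()`, all pure functions.
#'
#' @param subtype cell subtype; the endocardial variant is built in.
#' @return object of class `membrane_model` with `builtin = "ord_hybrid"`,
#'   which routes tissue simulations through the compiled integrator.
#' @export
build_ord_hybrid <- function(subtype = "endo") {
  subtype <- match.arg(subtype)
  params <- ord_hybrid_default_params(subtype)
  structure(list(
    name = "ord_hybrid",
    subtype = subtype,
    builtin = "ord_hybrid",
    state_names = .ord_state_names,
    scalable = .ord_param_names,
    default_params = params,
    initial_state = ord_hybrid_initial_state,
    rates = function(state, params, istim = 0, ip = 0)
      ord_hybrid_derivs(state, params, istim, ip)$deriv,
    iion = function(state, params)
      ord_hybrid_derivs(state, params)$iion
  ), class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf("membrane_model '%s' (%d states, %d scalable parameters)\n",
              x$name, length(x$state_names), length(x$default_params)))
  invisible(x)
}

#' Block a fraction of one membrane current
#'
#' Multiplies the named maximal conductance/permeability by `1 - fraction`,
#' e.g. `apply_block(p, "gKr", 0.53)` for a 53% IKr block.
#'
#' @param params named parameter vector.
#' @param current name of a scalable parameter.
#' @param fraction blocked proportion in `[0, 1]`.
#' @return modified copy of `params`.
#' @export
apply_block <- function(params, current, fraction) {
  if (!is.character(current) || length(current) != 1 ||
      !(current %in% names(params)))
    stop("unknown current parameter: ", paste(current, collapse = ", "))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      is.na(fraction) || fraction < 0 || fraction > 1)
    stop("block fraction must be in [0, 1]")
  params[current] <- params[current] * (1 - fraction)
  params
}

#' Parameters of the perturbed (long-AP) cell type
#'
#' The second cell type of the two-type layouts: IKr conductance set to zero,
#' IK1 conductance reduced by 75%, L-type calcium conductance doubled. Not
#' idempotent: applying it twice quarters gK1 again and quadruples pCaL.
#'
#' @param params default parameters of a model exposing `gKr`, `gK1` and an
#'   L-type calcium conductance (`pCaL` or `gCaL`).
#' @return modified copy of `params`.
#' @export
make_perturbed_type <- function(params) {
  cal <- intersect(c("pCaL", "gCaL"), names(params))[1]
  need <- c("gKr", "gK1", cal)
  if (any(is.na(need)) || !all(need %in% names(params)))
    stop("model must expose gKr, gK1 and an L-type calcium conductance")
  params["gKr"] <- 0
  params["gK1"] <- 0.25 * params["gK1"]
  params[cal] <- 2 * params[cal]
  params
}

#' Register an external membrane model
#'
#' Adapter for published models that are not re-implemented here (base model,
#' contraction model). The definition must supply the full contract; it is
#' validated at registration and the resulting object participates in tissue
#' and biomarker operations through the generic (R-level) integrator.
#'
#' @param definition list with `name`, `state_names` (must contain `"v"`),
#'   `default_params` (named numeric), `initial_state()` and
#'   `rates(state, params, istim, ip)` returning named derivatives; `iion`
#'   is optional (defaults to `-rates(...)["v"]` at zero stimulus).
#' @return object of class `membrane_model` with `builtin = NA`.
#' @export
register_external_model <- function(definition) {
  d <- definition
  for (f in c("name", "state_names", "default_params", "initial_state",
              "rates"))
    if (is.null(d[[f]])) stop("external model definition lacks '", f, "'")
  if (!("v" %in% d$state_names))
    stop("external model must expose a membrane potential state 'v'")
  s0 <- d$initial_state()
  if (!identical(names(s0), d$state_names))
    stop("initial_state() must return the declared state vector")
  r0 <- d$rates(s0, d$default_params, 0, 0)
  if (!all(is.finite(r0)))
    stop("external model has non-finite rates at its initial state")
  if (is.null(d$iion))
    d$iion <- function(state, params) -d$rates(state, params, 0, 0)[["v"]]
  structure(list(
    name = d$name, subtype = d$subtype %||% NA_character_,
    builtin = if (identical(d$name, "ord_hybrid")) "ord_hybrid" else NA_character_,
    state_names = d$state_names,
    scalable = d$scalable %||% names(d$default_params),
    default_params = d$default_params,
    initial_state = d$initial_state,
    rates = d$rates,
    iion = d$iion
  ), class = "membrane_model")
}

#' Model manifest for provenance
#'
#' @param model a `membrane_model`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
model_manifest <- function(model, path = NULL) {
  obj <- list(model = model$name, subtype = model$subtype,
              state_names = model$state_names,
              parameters = as.list(model$default_params),
              scalable = model$scalable)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
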