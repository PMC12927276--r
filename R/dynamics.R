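#' Network dynamics
#'
#' The whole network advances in synchronous timesteps (explicit Euler,
#' dt = 1). Within a step the stage order is fixed: (1) net input from the
#' previous step's outputs, plus external drive, minus the area's global
#' inhibition; (2) membrane integration with fresh uniform noise in
#' \[-0.5, 0.5\] on every excitatory cell; (3) outputs — binary spikes for
#' e-cells (spike iff `V - alpha * adapt > thresh`), rectified-linear for
#' i-cells; (4) Euler updates of the adaptation, rate-estimate and
#' global-inhibition low-passes. During learning phases the Hebbian rule
#' runs after the traces.
#'
#' @name dynamics
NULL

#' Create a simulation engine for a network
#'
#' Builds the compiled stepping engine holding the network's weights and
#' dynamic state. The engine is a mutable handle: stepping and plasticity
#' update it in place.
#'
#' @param network a [build_network()] result.
#' @param params a [whorf_params()] object (defaults to the network's).
#' @return An object of class `whorf_engine`.
#' @export
as_engine <- function(network, params = network$params) {
  stopifnot(inherits(network, "whorf_network"))
  W <- network$W
  area <- cell_area_ids(network)
  ptr <- cpp_engine_create(W@p, W@i, W@x, network$n_e, area,
                           rep(network$grid_side^2, network$n_areas),
                           engine_params(params))
  structure(list(ptr = ptr, n_e = network$n_e, n_c = 2L * network$n_e,
                 n_areas = network$n_areas, areas = network$areas,
                 grid_side = network$grid_side, params = params),
            class = "whorf_engine")
}

#' @export
print.whorf_engine <- function(x, ...) {
  cat(sprintf("<whorf_engine> %d areas, %d cells\n", x$n_areas, x$n_c))
  invisible(x)
}

#' Read or write the engine's dynamic state
#'
#' The state comprises the membrane potentials `V` (all cells), the
#' per-e-cell adaptation and rate-estimate traces, the per-area global
#' inhibition, and the outputs `phi` of the previous step.
#'
#' @param engine a `whorf_engine`.
#' @return `engine_state()`: a named list of state vectors.
#' @export
engine_state <- function(engine) cpp_engine_state(engine$ptr)

#' @rdname engine_state
#' @param state a named list as returned by `engine_state()`.
#' @export
set_engine_state <- function(engine, state) {
  cpp_engine_set_state(engine$ptr, state$V, state$adapt, state$rate,
                       state$glob, state$phi)
  invisible(engine)
}

#' @rdname engine_state
#' @return `engine_weights()`: the weight values aligned with the
#'   network's sparse-matrix slots.
#' @export
engine_weights <- function(engine) cpp_engine_weights(engine$ptr)

#' Zero-initialized dynamic state for a network
#'
#' @param network a `whorf_network` or `whorf_engine`.
#' @return A named list of zero state vectors.
#' @export
new_state <- function(network) {
  n_e <- network$n_e
  n_c <- if (inherits(network, "whorf_engine")) network$n_c else 2L * n_e
  list(V = numeric(n_c), adapt = numeric(n_e), rate = numeric(n_e),
       glob = numeric(network$n_areas), phi = numeric(n_c))
}

#' Reset membrane potentials
#'
#' The global network reset performed before each trial sets the membrane
#' potential of all e- and i-cells (and hence all outputs) to zero; the
#' adaptation, rate and global-inhibition traces are retained unless
#' `full = TRUE`.
#'
#' @param x a state list (from [new_state()] / [engine_state()]) or a
#'   `whorf_engine` (reset in place).
#' @param full also zero all traces.
#' @return The reset state (or the engine, invisibly).
#' @export
reset_potentials <- function(x, full = FALSE) {
  if (inherits(x, "whorf_engine")) {
    cpp_engine_reset(x$ptr, full)
    return(invisible(x))
  }
  x$V[] <- 0
  x$phi[] <- 0
  if (full) {
    x$adapt[] <- 0
    x$rate[] <- 0
    x$glob[] <- 0
  }
  x
}

#' Run the engine for a number of steps
#'
#' @param engine a `whorf_engine`.
#' @param n_steps steps to run.
#' @param stim optional external drive, one value per e-cell (raw input
#'   units; rescaled by `k1` inside the membrane equation).
#' @param learn apply the Hebbian rule each step.
#' @param tau_favg rate-estimate time constant for this run (learning and
#'   extraction use different values).
#' @param noise draw fresh membrane noise each step.
#' @param noise_matrix optional `n_e x n_steps` matrix of noise values in
#'   \[-0.5, 0.5\], overriding `noise` (used to share a stream with the
#'   reference implementation).
#' @param record `"none"`, `"rates"` (rate estimates per step) or
#'   `"spikes"`.
#' @param gate_threshold,gate_areas optional early-stop rule: stop at the
#'   first step where the global inhibition of every named area is below
#'   the threshold (the inter-stimulus-interval gate).
#' @return A list with `steps` actually run, `hot_steps` (steps where some
#'   area had >90% of its e-cells firing) and, if requested, the
#'   `rates`/`spikes` recording (`n_e x n_steps`).
#' @export
run_steps <- function(engine, n_steps, stim = NULL, learn = FALSE,
                      tau_favg = engine$params$tau_favg_learn,
                      noise = TRUE, noise_matrix = NULL,
                      record = c("none", "rates", "spikes"),
                      gate_threshold = NULL, gate_areas = NULL) {
  record <- match.arg(record)
  rec <- match(record, c("none", "rates", "spikes")) - 1L
  gthr <- if (is.null(gate_threshold)) NA_real_ else gate_threshold
  gar <- if (is.null(gate_areas)) integer(0)
         else match(gate_areas, engine$areas) - 1L
  if (anyNA(gar)) stop("unknown gate area", call. = FALSE)
  out <- cpp_engine_run(engine$ptr, as.integer(n_steps), stim, learn,
                        tau_favg, noise, noise_matrix, rec, gthr, gar)
  names(out)[names(out) == "rates"] <- "rates"
  out
}

#' Advance a state by one synchronous step
#'
#' Functional single-step interface used for small circuits and
#' verification; for long runs use [run_steps()] on a persistent engine.
#'
#' @param engine a `whorf_engine`.
#' @param state a state list.
#' @inheritParams run_steps
#' @param noise_vector optional per-e-cell noise values for this step.
#' @return The updated state list.
#' @export
step_network <- function(engine, state, stim = NULL, learn = FALSE,
                         tau_favg = engine$params$tau_favg_learn,
                         noise = FALSE, noise_vector = NULL) {
  set_engine_state(engine, state)
  nm <- if (!is.null(noise_vector)) matrix(noise_vector, ncol = 1) else NULL
  cpp_engine_run(engine$ptr, 1L, stim, learn, tau_favg, noise, nm, 0L,
                 NA_real_, integer(0))
  engine_state(engine)
}

#' First-order low-pass step
#'
#' The Euler discretization (dt = 1) shared by the adaptation,
#' rate-estimate and global-inhibition traces:
#' `y' = y + (-y + gain * u) / tau`.
#'
#' @param previous current trace value(s).
#' @param input_signal input value(s).
#' @param tau time constant (> 0), in timesteps.
#' @param gain input gain (1 for the rate estimate and global inhibition,
#'   `alpha_adapt` for adaptation).
#' @return The updated trace.
#' @export
lowpass <- function(previous, input_signal, tau, gain = 1) {
  if (any(tau <= 0)) stop("tau must be positive", call. = FALSE)
  previous + (-previous + gain * input_signal) / tau
}
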