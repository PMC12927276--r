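#' Two-threshold Hebbian update for a single synapse
#'
#' Discretized Artola-style learning rule for excitatory-to-excitatory
#' links. With presynaptic rate estimate `r` and postsynaptic membrane
#' potential `v`:
#' \itemize{
#'   \item LTP (`+delta_w`): `r >= theta_pre` and `v >= theta_plus`;
#'   \item homosynaptic LTD (`-delta_w`): `r >= theta_pre` and
#'     `theta_minus <= v < theta_plus`;
#'   \item heterosynaptic LTD (`-delta_w`): `r < theta_zero` (a truly
#'     silent input) and `v >= theta_plus`;
#'   \item otherwise unchanged (including the neutral presynaptic band
#'     `theta_zero <= r < theta_pre` under strong depolarization).
#' }
#' The result is clipped to `[0, w_max]`. All arguments are vectorized.
#'
#' @param pre_rate presynaptic rate estimate(s).
#' @param post_potential postsynaptic membrane potential(s).
#' @param weight current weight(s).
#' @param params a [whorf_params()] object.
#' @return The updated weight(s).
#' @export
hebbian_update <- function(pre_rate, post_potential, weight,
                           params = whorf_params()) {
  pre_on <- pre_rate >= params$theta_pre
  ltp <- pre_on & post_potential >= params$theta_plus
  homo <- pre_on & post_potential >= params$theta_minus &
    post_potential < params$theta_plus
  het <- pre_rate < params$theta_zero & post_potential >= params$theta_plus
  w <- weight + params$delta_w * (ltp - homo - het)
  pmin(pmax(w, 0), params$w_max)
}

#' Apply one plasticity pass to every plastic synapse
#'
#' Updates all excitatory-to-excitatory weights from the current
#' per-cell rate estimates and membrane potentials, exactly as performed
#' once per timestep during learning. Non-plastic projections (e-i, i-e)
#' are untouched.
#'
#' @param network a `whorf_network`.
#' @param state a state list (see [new_state()]).
#' @param params a [whorf_params()] object.
#' @return The network with updated weights.
#' @export
apply_plasticity <- function(network, state, params = network$params) {
  eng <- as_engine(network, params)
  set_engine_state(eng, state)
  cpp_engine_plasticity(eng$ptr)
  out <- network
  out$W@x <- engine_weights(eng)
  out
}
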