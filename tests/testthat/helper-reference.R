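# Scalar reference implementation of the synchronous update and the
# Hebbian rule, written independently of the compiled engine (plain R
# loops over the sparse slots, same stage order and accumulation order).
# Used as the oracle for the engine-equivalence tests on small circuits.

reference_init <- function(network) {
  n_e <- network$n_e
  list(V = numeric(2L * n_e),
       adapt = numeric(n_e),
       rate = numeric(n_e),
       glob = numeric(network$n_areas),
       phi = numeric(2L * n_e))
}

# one synchronous step; returns list(state, x) with updated weights
reference_step <- function(network, state, x, stim = NULL, eta = NULL,
                           learn = FALSE, tau_favg, params) {
  W <- network$W
  p <- W@p; ri <- W@i          # 0-based CSC slots
  n_e <- network$n_e
  n_c <- 2L * n_e
  area <- cell_area_ids_ref(network)          # 1-based area per cell
  if (is.null(stim)) stim <- numeric(n_e)
  if (is.null(eta)) eta <- numeric(n_e)

  # (1) synaptic input accumulated column by column (presynaptic order)
  syn <- numeric(n_c)
  for (y in seq_len(n_c)) {
    o <- state$phi[y]
    if (o == 0) next
    ks <- (p[y] + 1L):p[y + 1L]
    if (p[y + 1L] == p[y]) next
    rows <- ri[ks] + 1L
    syn[rows] <- syn[rows] + x[ks] * o
  }
  # (2) membrane integration; weights are effective couplings, k1
  # rescales the external drive, global inhibition and noise only
  V <- state$V
  for (c in seq_len(n_e)) {
    vin <- syn[c] + params$k1 *
      (stim[c] - params$k_G * state$glob[area[c]] + params$k2 * eta[c])
    V[c] <- V[c] + (-V[c] + vin) / params$tau_e
  }
  for (c in (n_e + 1L):n_c)
    V[c] <- V[c] + (-V[c] + syn[c]) / params$tau_i
  # (3) outputs
  phi <- numeric(n_c)
  for (c in seq_len(n_e))
    phi[c] <- if ((V[c] - params$alpha * state$adapt[c]) > params$thresh) 1 else 0
  for (c in (n_e + 1L):n_c) phi[c] <- max(V[c], 0)
  # (4) traces
  adapt <- state$adapt; rate <- state$rate; glob <- state$glob
  for (c in seq_len(n_e)) {
    adapt[c] <- adapt[c] + (-adapt[c] + params$alpha_adapt * phi[c]) / params$tau_adapt
    rate[c] <- rate[c] + (-rate[c] + phi[c]) / tau_favg
  }
  for (a in seq_len(network$n_areas)) {
    s <- 0
    for (c in seq_len(n_e)) if (area[c] == a && phi[c] != 0) s <- s + 1
    glob[a] <- glob[a] + (-glob[a] + s) / params$tau_glob
  }
  st <- list(V = V, adapt = adapt, rate = rate, glob = glob, phi = phi)
  if (learn)
    x <- reference_plasticity(network, st, x, params)
  list(state = st, x = x)
}

# Eq.7 over every plastic (e->e) entry, in the engine's pass order:
# active-presynaptic columns first, then heterosynaptic rows
reference_plasticity <- function(network, state, x, params) {
  W <- network$W
  p <- W@p; ri <- W@i
  n_e <- network$n_e
  for (pre in seq_len(n_e)) {
    if (state$rate[pre] < params$theta_pre) next
    if (p[pre + 1L] == p[pre]) next
    for (k in (p[pre] + 1L):p[pre + 1L]) {
      post <- ri[k] + 1L
      if (post > n_e) next
      v <- state$V[post]
      if (v >= params$theta_plus)
        x[k] <- min(x[k] + params$delta_w, params$w_max)
      else if (v >= params$theta_minus)
        x[k] <- max(x[k] - params$delta_w, 0)
    }
  }
  for (post in seq_len(n_e)) {
    if (state$V[post] < params$theta_plus) next
    for (pre in seq_len(n_e)) {
      if (state$rate[pre] >= params$theta_zero) next
      if (p[pre + 1L] == p[pre]) next
      ks <- (p[pre] + 1L):p[pre + 1L]
      k <- ks[ri[ks] + 1L == post]
      if (length(k))
        x[k] <- pmax(x[k] - params$delta_w, 0)
    }
  }
  x
}

cell_area_ids_ref <- function(network) {
  a <- rep(seq_len(network$n_areas), each = network$grid_side^2)
  c(a, a)
}

# run both implementations n steps from a zero state under a shared noise
# matrix and return their trajectories
reference_vs_engine <- function(network, params, n_steps, stim = NULL,
                                noise_matrix = NULL, learn = FALSE,
                                tau_favg = params$tau_favg_learn) {
  eng <- as_engine(network, params)
  ref_state <- reference_init(network)
  x <- network$W@x
  traj_ref <- traj_eng <- vector("list", n_steps)
  for (t in seq_len(n_steps)) {
    eta <- if (is.null(noise_matrix)) NULL else noise_matrix[, t]
    out <- reference_step(network, ref_state, x, stim = stim, eta = eta,
                          learn = learn, tau_favg = tau_favg, params = params)
    ref_state <- out$state
    x <- out$x
    nm <- if (is.null(eta)) NULL else matrix(eta, ncol = 1)
    whorfnet:::cpp_engine_run(eng$ptr, 1L, stim, learn, tau_favg, FALSE, nm,
                              0L, NA_real_, integer(0))
    traj_ref[[t]] <- ref_state
    traj_eng[[t]] <- engine_state(eng)
  }
  list(ref = traj_ref, eng = traj_eng, ref_x = x, eng_x = engine_weights(eng))
}
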