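#' Simulation parameters
#'
#' Single authoritative container for every constant of the membrane,
#' adaptation, rate-estimate, global-inhibition and Hebbian plasticity
#' equations, the connectivity kernels, and the protocol constants
#' (stimulation durations, inter-stimulus interval, trial counts).
#' Defaults reproduce the published parameter table of the 12-area
#' frontotemporal-occipital model.
#'
#' @param tau_e,tau_i membrane time constants of excitatory / inhibitory
#'   cells, in simulation timesteps.
#' @param k1 total input rescaling factor (dimensionless).
#' @param dt discretization constant entering the noise-amplitude formula
#'   `k2 = 3 * sqrt(24 / dt)`; only used when `k2` is not given directly.
#' @param k2 noise amplitude. `NULL` (default) computes it from `dt`.
#' @param k_G global inhibition strength.
#' @param thresh spiking threshold (membrane-potential units).
#' @param alpha adaptation strength at the threshold comparison.
#' @param alpha_adapt gain of the adaptation low-pass.
#' @param tau_adapt,tau_glob adaptation and global-inhibition time constants.
#' @param tau_favg_learn,tau_favg_extract rate-estimate time constants:
#'   the slow published default and the fast one used during
#'   cell-assembly extraction / recognition.
#' @param tau_favg_plasticity rate-estimate time constant feeding the
#'   presynaptic-activity test of the Hebbian rule during learning
#'   (default `tau_favg_extract`): with the published adaptation strength
#'   a synaptically driven cell fires at a duty cycle of about one step
#'   in ten, so only a fast estimate can cross `theta_pre` within a
#'   16-step trial and let recruited cells teach their own efferents.
#' @param inp_strength sensorimotor input strength per stimulated cell.
#' @param theta_plus,theta_minus,theta_pre postsynaptic LTP / homosynaptic
#'   LTD and presynaptic activity thresholds of the Hebbian rule.
#' @param theta_zero presynaptic silence threshold for heterosynaptic LTD:
#'   a strongly depolarized postsynaptic cell depresses only in-links whose
#'   presynaptic rate estimate is below `theta_zero`. Presynaptic activity
#'   in the neutral band `[theta_zero, theta_pre)` leaves the weight
#'   unchanged, the classic three-zone reading of the Artola-type rule
#'   (`theta_pre` is the output required for LTP). Setting
#'   `theta_zero = theta_pre` removes the neutral band.
#' @param delta_w learning-rate increment applied per plasticity event.
#' @param w_init_max upper bound of the uniform weight initialization for
#'   plastic excitatory-to-excitatory links.
#' @param w_inhib_max upper bound of the uniform initialization of the
#'   non-plastic local inhibitory loop (excitatory-to-inhibitory and
#'   inhibitory-to-excitatory couplings); sets the strength of local
#'   lateral competition.
#' @param w_max hard upper clip for excitatory weights.
#' @param gamma_ca cell-assembly membership fraction (threshold is
#'   `gamma_ca` times the area's peak rate).
#' @param min_peak_rate minimum per-area peak rate for an area to
#'   contribute assembly members.
#' @param kernel_ee_within,kernel_ee_between,kernel_ie Gaussian link
#'   kernels, each a list with `center_prob`, `sigma` and (odd)
#'   `neighborhood`.
#' @param stim_steps_learn stimulation duration per learning trial (steps).
#' @param isi_steps maximum inter-stimulus interval (steps).
#' @param isi_inhib_threshold global-inhibition value gating early ISI
#'   termination.
#' @param isi_gate_areas area names monitored for the ISI gate.
#' @param stim_steps_recog stimulation duration in recognition runs.
#' @param recog_post_steps post-offset recording window (steps).
#' @param recog_baseline_steps pre-onset baseline window (steps).
#' @param trials_phase1_per_pattern,trials_phase2_per_pairing learning
#'   trials per stimulus type (phase 1) and per color-label pairing
#'   (phase 2).
#' @param n_networks number of network instantiations in a full experiment.
#' @param noise_drive_form form of the fresh uncorrelated drive given to
#'   non-relevant primary areas during learning trials: `"pattern"` (a
#'   new random 22-cell pattern at full input strength each trial) or
#'   `"spread"` (the same total drive spread uniformly at random over all
#'   cells of the area); see [fresh_noise_pattern()].
#' @param torus logical; treat area grids as toroidal when placing
#'   topographic neighborhoods (clipped borders when `FALSE`).
#'
#' @return An object of class `whorf_params` (a validated named list with
#'   the effective `k2` resolved).
#' @seealso [load_params()], [dump_params()]
#' @export
whorf_params <- function(tau_e = 2.5, tau_i = 5, k1 = 0.01, dt = 0.5,
                         k2 = NULL, k_G = 0.73, thresh = 0.18, alpha = 7,
                         alpha_adapt = 1, tau_adapt = 10,
                         tau_favg_learn = 30, tau_favg_extract = 5,
                         tau_favg_plasticity = tau_favg_extract,
                         tau_glob = 12, inp_strength = 700,
                         theta_plus = 0.15, theta_minus = 0.14,
                         theta_pre = 0.15, theta_zero = 0.05,
                         delta_w = 0.008,
                         w_init_max = 0.07, w_inhib_max = 1,
                         w_max = 0.225, gamma_ca = 0.5,
                         min_peak_rate = 0.2,
                         kernel_ee_within = list(center_prob = 0.28, sigma = 6.5, neighborhood = 19L),
                         kernel_ee_between = list(center_prob = 0.15, sigma = 4.5, neighborhood = 19L),
                         kernel_ie = list(center_prob = 0.295, sigma = 2.0, neighborhood = 5L),
                         stim_steps_learn = 16L, isi_steps = 30L,
                         isi_inhib_threshold = 0.55,
                         isi_gate_areas = c("V1", "TO", "AT", "PFL"),
                         stim_steps_recog = 2L, recog_post_steps = 28L,
                         recog_baseline_steps = 10L,
                         trials_phase1_per_pattern = 1000L,
                         trials_phase2_per_pairing = 1000L,
                         n_networks = 16L,
                         noise_drive_form = c("pattern", "spread"),
                         torus = TRUE) {
  noise_drive_form <- match.arg(noise_drive_form)
  p <- list(tau_e = tau_e, tau_i = tau_i, k1 = k1, dt = dt, k2 = k2,
            k_G = k_G, thresh = thresh, alpha = alpha,
            alpha_adapt = alpha_adapt, tau_adapt = tau_adapt,
            tau_favg_learn = tau_favg_learn,
            tau_favg_extract = tau_favg_extract,
            tau_favg_plasticity = tau_favg_plasticity, tau_glob = tau_glob,
            inp_strength = inp_strength, theta_plus = theta_plus,
            theta_minus = theta_minus, theta_pre = theta_pre,
            theta_zero = theta_zero, delta_w = delta_w, w_init_max = w_init_max,
            w_inhib_max = w_inhib_max, w_max = w_max,
            gamma_ca = gamma_ca, min_peak_rate = min_peak_rate,
            kernel_ee_within = kernel_ee_within,
            kernel_ee_between = kernel_ee_between, kernel_ie = kernel_ie,
            stim_steps_learn = as.integer(stim_steps_learn),
            isi_steps = as.integer(isi_steps),
            isi_inhib_threshold = isi_inhib_threshold,
            isi_gate_areas = isi_gate_areas,
            stim_steps_recog = as.integer(stim_steps_recog),
            recog_post_steps = as.integer(recog_post_steps),
            recog_baseline_steps = as.integer(recog_baseline_steps),
            trials_phase1_per_pattern = as.integer(trials_phase1_per_pattern),
            trials_phase2_per_pairing = as.integer(trials_phase2_per_pairing),
            n_networks = as.integer(n_networks),
            noise_drive_form = noise_drive_form, torus = isTRUE(torus))
  if (is.null(p$k2)) p$k2 <- 3 * sqrt(24 / p$dt)
  validate_params(p)
  structure(p, class = "whorf_params")
}

validate_params <- function(p) {
  pos <- c("tau_e", "tau_i", "dt", "tau_adapt", "tau_favg_learn",
           "tau_favg_extract", "tau_favg_plasticity", "tau_glob")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive scalar", call. = FALSE)
  nonneg <- c("k1", "k2", "k_G", "alpha", "alpha_adapt", "inp_strength",
              "delta_w", "w_init_max", "w_inhib_max", "w_max",
              "min_peak_rate")
  for (nm in nonneg)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0)
      stop("parameter '", nm, "' must be a non-negative scalar", call. = FALSE)
  prob <- c("gamma_ca")
  for (nm in prob)
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("parameter '", nm, "' must lie in [0, 1]", call. = FALSE)
  for (nm in c("kernel_ee_within", "kernel_ee_between", "kernel_ie")) {
    k <- p[[nm]]
    if (!is.list(k) || !all(c("center_prob", "sigma", "neighborhood") %in% names(k)))
      stop("kernel '", nm, "' needs center_prob, sigma and neighborhood", call. = FALSE)
    if (k$center_prob < 0 || k$center_prob > 1)
      stop("kernel '", nm, "': center_prob must lie in [0, 1]", call. = FALSE)
    if (k$sigma <= 0)
      stop("kernel '", nm, "': sigma must be positive", call. = FALSE)
    nb <- k$neighborhood
    if (nb != as.integer(nb) || nb < 1 || nb %% 2 != 1)
      stop("kernel '", nm, "': neighborhood must be an odd positive integer", call. = FALSE)
  }
  if (!(p$theta_minus < p$theta_plus))
    stop("theta_minus must be strictly smaller than theta_plus", call. = FALSE)
  if (p$theta_zero < 0 || p$theta_zero > p$theta_pre)
    stop("theta_zero must lie in [0, theta_pre]", call. = FALSE)
  ints <- c("stim_steps_learn", "isi_steps", "stim_steps_recog",
            "recog_post_steps", "recog_baseline_steps",
            "trials_phase1_per_pattern", "trials_phase2_per_pairing",
            "n_networks")
  for (nm in ints)
    if (p[[nm]] < 1) stop("parameter '", nm, "' must be >= 1", call. = FALSE)
  if (!is.character(p$isi_gate_areas) || length(p$isi_gate_areas) < 1)
    stop("isi_gate_areas must name at least one area", call. = FALSE)
  invisible(p)
}

#' Load simulation parameters from a configuration source
#'
#' Reads a YAML or JSON file (or an already-parsed named list), fills every
#' omitted key with the published default, validates the result, and
#' records which keys were overridden in the `"overridden"` attribute.
#' Unknown keys are rejected.
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or a named list.
#' @return A `whorf_params` object.
#' @export
load_params <- function(config = list()) {
  if (is.character(config)) {
    if (length(config) != 1 || !file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    cfg <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      stop("unsupported config format '", ext, "' (use YAML or JSON)",
           call. = FALSE))
    if (is.null(cfg)) cfg <- list()
  } else if (is.list(config)) {
    cfg <- config
  } else {
    stop("config must be a file path or a named list", call. = FALSE)
  }
  known <- names(formals(whorf_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == "")))
    stop("all config entries must be named", call. = FALSE)
  for (nm in c("kernel_ee_within", "kernel_ee_between", "kernel_ie"))
    if (nm %in% names(cfg)) cfg[[nm]] <- as.list(cfg[[nm]])
  p <- do.call(whorf_params, cfg)
  attr(p, "overridden") <- names(cfg)
  p
}

#' Serialize parameters
#'
#' Writes (or returns) the effective configuration as YAML. A round trip
#' through [dump_params()] and [load_params()] is lossless.
#'
#' @param params a `whorf_params` object.
#' @param path optional output file; when `NULL` the YAML text is returned.
#' @return The YAML string, invisibly when written to `path`.
#' @export
dump_params <- function(params, path = NULL) {
  stopifnot(inherits(params, "whorf_params"))
  txt <- yaml::as.yaml(unclass(params), precision = 17L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @export
print.whorf_params <- function(x, ...) {
  cat("<whorf_params>\n")
  cat(sprintf("  membrane: tau_e=%.3g tau_i=%.3g k1=%.3g k2=%.4g thresh=%.3g\n",
              x$tau_e, x$tau_i, x$k1, x$k2, x$thresh))
  cat(sprintf("  adaptation/inhibition: alpha=%.3g tau_adapt=%.3g k_G=%.3g tau_glob=%.3g\n",
              x$alpha, x$tau_adapt, x$k_G, x$tau_glob))
  cat(sprintf("  plasticity: delta_w=%.3g theta_pre=%.3g theta+=%.3g theta-=%.3g w_max=%.3g\n",
              x$delta_w, x$theta_pre, x$theta_plus, x$theta_minus, x$w_max))
  cat(sprintf("  protocol: stim=%d steps, isi<=%d (gate %.2f), %d/%d trials, %d networks\n",
              x$stim_steps_learn, x$isi_steps, x$isi_inhib_threshold,
              x$trials_phase1_per_pattern, x$trials_phase2_per_pairing,
              x$n_networks))
  ov <- attr(x, "overridden")
  if (length(ov)) cat("  overridden:", paste(ov, collapse = ", "), "\n")
  invisible(x)
}

# engine-facing flat parameter list (tau_favg is supplied per run)
engine_params <- function(params) {
  list(tau_e = params$tau_e, tau_i = params$tau_i, k1 = params$k1,
       k2 = params$k2, k_G = params$k_G, thresh = params$thresh,
       alpha = params$alpha, alpha_adapt = params$alpha_adapt,
       tau_adapt = params$tau_adapt, tau_glob = params$tau_glob,
       theta_plus = params$theta_plus, theta_minus = params$theta_minus,
       theta_pre = params$theta_pre, theta_zero = params$theta_zero,
       delta_w = params$delta_w,
       w_max = params$w_max)
}

# evaluate expr with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducibility", call. = FALSE)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else rm(".Random.seed", envir = .GlobalEnv)
  })
  expr
}
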