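#' Color-to-label mapping for a language model
#'
#' The one-label (English-like) mapping pairs both blue shades with word 1
#' and both green shades with word 2. The two-label (Russian-like) mapping
#' gives each blue shade its own word (1 and 2) while both greens share
#' word 3 — mirroring the goluboj/sinij lexical distinction.
#'
#' @param language `"english"` or `"russian"`.
#' @return An object of class `label_mapping`: a named integer vector from
#'   color tag to word index, with the language in attribute `language`.
#' @export
label_mapping <- function(language = c("english", "russian")) {
  language <- match.arg(language)
  map <- switch(language,
    english = c(blue_light = 1L, blue_dark = 1L, green_light = 2L, green_dark = 2L),
    russian = c(blue_light = 1L, blue_dark = 2L, green_light = 3L, green_dark = 3L))
  structure(map, language = language, class = "label_mapping")
}

#' @export
print.label_mapping <- function(x, ...) {
  cat(sprintf("<label_mapping> %s: %s\n", attr(x, "language"),
              paste(names(x), unclass(x), sep = "->", collapse = ", ")))
  invisible(x)
}

#' Randomized trial schedules
#'
#' Phase 1 presents the 7 stimulus types (4 colors, 3 word-form pairs)
#' separately, `n_per` trials each, in a randomized order. Phase 2
#' presents the 4 color-label pairings, `n_per` trials each, randomized.
#'
#' @param n_per trials per stimulus type / pairing.
#' @param seed integer seed for the permutation.
#' @return A character vector of stimulus-type labels, one per trial.
#' @export
phase1_schedule <- function(n_per, seed) {
  types <- c(color_tags(), paste0("word", 1:3))
  with_seed(seed, sample(rep(types, each = n_per)))
}

#' @rdname phase1_schedule
#' @export
phase2_schedule <- function(n_per, seed) {
  with_seed(seed, sample(rep(color_tags(), each = n_per)))
}

area_cell_range <- function(network, area) {
  a <- match(area, network$areas)
  if (is.na(a)) stop("unknown area ", area, call. = FALSE)
  ((a - 1L) * network$grid_side^2 + 1L):(a * network$grid_side^2)
}

# drive vector for one learning trial: driven pattern cells at full input
# strength plus fresh uncorrelated noise drives on the listed areas
build_stim <- function(network, params, patterns_at, noise_areas) {
  stim <- numeric(network$n_e)
  for (p in patterns_at)
    stim[pattern_cells_global(network, p)] <- params$inp_strength
  for (a in noise_areas)
    stim[area_cell_range(network, a)] <-
      stim[area_cell_range(network, a)] +
      fresh_noise_pattern(a, params, network$grid_side^2,
                          form = params$noise_drive_form)
  stim
}

# one learning trial: V-reset, 16 stimulation steps, gated ISI.
# Hot steps (>90% of an area firing) are recorded, not fatal: runaway
# activation spread is a known failure mode of individual networks and
# is handled downstream by the exclusion rule, as in the study design.
run_learning_trial <- function(engine, stim, params) {
  reset_potentials(engine)
  s1 <- run_steps(engine, params$stim_steps_learn, stim = stim,
                  learn = TRUE, tau_favg = params$tau_favg_plasticity)
  s2 <- run_steps(engine, params$isi_steps, learn = TRUE,
                  tau_favg = params$tau_favg_plasticity,
                  gate_threshold = params$isi_inhib_threshold,
                  gate_areas = params$isi_gate_areas)
  c(isi = s2$steps, hot = s1$hot_steps + s2$hot_steps)
}

finish_training <- function(network, engine, diag) {
  out <- network
  out$W@x <- engine_weights(engine)
  attr(out, "diagnostics") <- diag
  out
}

#' Phase 1: perceptual color learning and word-form babbling
#'
#' Presents the 4 color patterns (to V1, with uncorrelated noise drives on
#' A1, M1i and M1L) and the 3 word-form pairs (auditory + articulatory
#' halves simultaneously to A1 and M1i, with noise on V1 and M1L), each
#' stimulus type in `trials_phase1_per_pattern` randomized trials. The
#' membrane potentials are reset before every trial; Hebbian plasticity is
#' active during stimulation and the inter-stimulus interval.
#'
#' @param network a freshly built `whorf_network`.
#' @param patterns a [pattern_set()].
#' @param params a [whorf_params()] object.
#' @param seed integer seed governing trial order, noise drives and
#'   membrane noise.
#' @return The trained network; attribute `"diagnostics"` carries trial
#'   counts and mean realized ISI length.
#' @export
run_phase1 <- function(network, patterns, params = network$params, seed) {
  engine <- as_engine(network, params)
  sched <- phase1_schedule(params$trials_phase1_per_pattern, seed)
  frames <- c(
    lapply(patterns$colors, function(p)
      list(pat = list(p), noise = c("A1", "M1i", "M1L"))),
    stats::setNames(lapply(patterns$words, function(w)
      list(pat = list(w$auditory, w$articulatory), noise = c("V1", "M1L"))),
      paste0("word", 1:3)))
  diag <- with_seed(seed + 1L, {
    stats <- matrix(0, nrow = length(sched), ncol = 2)
    for (t in seq_along(sched)) {
      fr <- frames[[sched[t]]]
      stim <- build_stim(network, params, fr$pat, fr$noise)
      stats[t, ] <- run_learning_trial(engine, stim, params)
    }
    hot_trials <- sum(stats[, 2] > 0)
    if (hot_trials > 0.5 * length(sched))
      stop("sustained activity explosion: ", hot_trials, " of ",
           length(sched), " trials showed near-full-area firing",
           call. = FALSE)
    list(trials = length(sched), mean_isi = mean(stats[, 1]),
         hot_steps = sum(stats[, 2]), hot_trials = hot_trials,
         schedule = table(sched))
  })
  finish_training(network, engine, diag)
}

#' Phase 2: language-specific semantic learning
#'
#' Co-presents each learned color pattern (V1) with its mapped word form
#' (auditory half to A1 and articulatory half to M1i simultaneously), with
#' an uncorrelated noise drive on the non-relevant lateral motor primary
#' (M1L), for `trials_phase2_per_pairing` randomized trials per pairing.
#' Trial mechanics (reset, 16-step stimulation, gated ISI, plasticity)
#' match phase 1.
#'
#' @param network a phase-1 trained `whorf_network` snapshot. The English
#'   and Russian branches of an experiment start from the identical
#'   snapshot; only the mapping differs.
#' @param mapping a [label_mapping()].
#' @inheritParams run_phase1
#' @return The trained network with diagnostics, as in [run_phase1()].
#' @export
run_phase2 <- function(network, patterns, mapping, params = network$params,
                       seed) {
  stopifnot(inherits(mapping, "label_mapping"))
  engine <- as_engine(network, params)
  sched <- phase2_schedule(params$trials_phase2_per_pairing, seed)
  diag <- with_seed(seed + 1L, {
    stats <- matrix(0, nrow = length(sched), ncol = 2)
    words <- numeric(0)
    for (t in seq_along(sched)) {
      tag <- sched[t]
      w <- patterns$words[[mapping[[tag]]]]
      stim <- build_stim(network, params,
                         list(patterns$colors[[tag]], w$auditory,
                              w$articulatory), "M1L")
      stats[t, ] <- run_learning_trial(engine, stim, params)
    }
    hot_trials <- sum(stats[, 2] > 0)
    if (hot_trials > 0.5 * length(sched))
      stop("sustained activity explosion: ", hot_trials, " of ",
           length(sched), " trials showed near-full-area firing",
           call. = FALSE)
    wcount <- table(factor(paste0("word", unclass(mapping)[sched]),
                           levels = paste0("word", 1:3)))
    list(trials = length(sched), mean_isi = mean(stats[, 1]),
         hot_steps = sum(stats[, 2]), hot_trials = hot_trials,
         schedule = table(sched), word_presentations = wcount)
  })
  finish_training(network, engine, diag)
}

#' Cell-assembly reactivation (extraction) trial
#'
#' Stimulates V1 with a learned color pattern for 16 steps with plasticity
#' frozen and no drives to the other primary areas, starting from a fully
#' zeroed state, recording the per-cell rate estimate (time constant
#' `tau_favg_extract`) over a 30-step window anchored at stimulus onset
#' (the 16 stimulation steps and the following 14 steps). Anchoring at
#' onset rather than offset matters under the published adaptation
#' strength: responses are brief bursts, so an offset-anchored window
#' would only ever see their decayed traces.
#'
#' @param network a trained `whorf_network`.
#' @param pattern an `input_pattern` (or an [as_engine()] handle via
#'   `engine`).
#' @param params a [whorf_params()] object.
#' @param noise keep the intrinsic membrane noise on during the probe
#'   (default `TRUE`, as noise is an inherent property of every cell; it
#'   is subthreshold, so an untrained network stays silent either way).
#'   `FALSE` gives a fully deterministic probe of the learned circuitry.
#' @param seed optional seed for the membrane noise (only relevant with
#'   `noise = TRUE`); `NULL` uses the current RNG stream.
#' @param engine optional pre-built engine to reuse (its weights are not
#'   modified).
#' @return A `rate_tensor`: numeric array `n_areas x cells x 30` of rate
#'   estimates, with area dimnames.
#' @export
run_extraction_trial <- function(network, pattern, params = network$params,
                                 noise = TRUE, seed = NULL, engine = NULL) {
  if (is.null(engine)) engine <- as_engine(network, params)
  run <- function() {
    reset_potentials(engine, full = TRUE)
    stim <- numeric(network$n_e)
    stim[pattern_cells_global(network, pattern)] <- params$inp_strength
    on <- run_steps(engine, params$stim_steps_learn, stim = stim,
                    learn = FALSE, tau_favg = params$tau_favg_extract,
                    noise = noise, record = "rates")
    post <- run_steps(engine, 30L - params$stim_steps_learn, learn = FALSE,
                      noise = noise, tau_favg = params$tau_favg_extract,
                      record = "rates")
    cbind(on$rates, post$rates)
  }
  rates <- if (is.null(seed)) run() else with_seed(seed, run())
  as_rate_tensor(rates, network$areas, network$grid_side^2)
}

as_rate_tensor <- function(rates, areas, n_per) {
  n_steps <- ncol(rates)
  arr <- aperm(array(rates, dim = c(n_per, length(areas), n_steps)), c(2, 1, 3))
  dimnames(arr) <- list(areas, NULL, NULL)
  structure(arr, class = "rate_tensor")
}

#' Recognition trial with spike recording
#'
#' Simulates color perception for the neurophysiological proxy: from a
#' fully zeroed state, 10 baseline steps without input, a 2-step V1
#' stimulation, and 28 further steps without input, recording every
#' excitatory spike. Plasticity is frozen.
#'
#' @inheritParams run_extraction_trial
#' @return A `spike_raster`: integer matrix `n_e x 40` with the step time
#'   relative to stimulus onset (-10..29) in attribute `"times"`.
#' @export
run_recognition_trial <- function(network, pattern, params = network$params,
                                  noise = TRUE, seed = NULL, engine = NULL) {
  if (is.null(engine)) engine <- as_engine(network, params)
  run <- function() {
    reset_potentials(engine, full = TRUE)
    stim <- numeric(network$n_e)
    stim[pattern_cells_global(network, pattern)] <- params$inp_strength
    tf <- params$tau_favg_extract
    base <- run_steps(engine, params$recog_baseline_steps, learn = FALSE,
                      tau_favg = tf, noise = noise, record = "spikes")$spikes
    on <- run_steps(engine, params$stim_steps_recog, stim = stim, noise = noise,
                    learn = FALSE, tau_favg = tf, record = "spikes")$spikes
    post <- run_steps(engine, params$recog_post_steps, learn = FALSE,
                      tau_favg = tf, noise = noise, record = "spikes")$spikes
    cbind(base, on, post)
  }
  raster <- if (is.null(seed)) run() else with_seed(seed, run())
  times <- c(seq(-params$recog_baseline_steps, -1L),
             seq(0L, params$stim_steps_recog - 1L),
             seq(params$stim_steps_recog,
                 params$stim_steps_recog + params$recog_post_steps - 1L))
  structure(raster, times = times, areas = network$areas,
            class = "spike_raster")
}

# extraction + recognition + per-model analyses for one trained network
analyze_model <- function(network, patterns, params, seed) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 8))
  engine <- as_engine(network, params)
  tags <- color_tags()
  assemblies <- list()
  act <- matrix(0, network$n_e, length(tags), dimnames = list(NULL, tags))
  rasters <- list()
  for (k in seq_along(tags)) {
    tens <- run_extraction_trial(network, patterns$colors[[tags[k]]], params,
                                 seed = seeds[k], engine = engine)
    assemblies[[tags[k]]] <- extract_assembly(tens, params, tag = tags[k])
    act[, k] <- as.vector(t(rowMeans(unclass(tens), dims = 2)))
    rasters[[tags[k]]] <- run_recognition_trial(
      network, patterns$colors[[tags[k]]], params,
      seed = seeds[4 + k], engine = engine)
  }
  mmn <- list()
  for (col in c("blue", "green")) {
    ca_l <- assemblies[[paste0(col, "_light")]]
    ca_d <- assemblies[[paste0(col, "_dark")]]
    mmn[[paste0(col, "_light")]] <-
      mmn_trace(rasters[[paste0(col, "_light")]], ca_l, ca_d, params,
                target = "light")
    mmn[[paste0(col, "_dark")]] <-
      mmn_trace(rasters[[paste0(col, "_dark")]], ca_l, ca_d, params,
                target = "dark")
  }
  excl <- exclude_network(assemblies, params)
  list(act_vectors = act, assemblies = assemblies, mmn = mmn,
       excluded = excl$excluded, exclusion_reason = excl$reason)
}

#' Run a full multi-network experiment
#'
#' The central driver: builds `n_networks` network instantiations
#' (distinct connectivity seeds, shared input patterns), trains each
#' through phase 1, branches byte-identical copies into the requested
#' language models for phase 2, and runs cell-assembly extraction and
#' recognition for all four color patterns on the perceptual (phase-1)
#' snapshot and on every language branch. Per-network assemblies,
#' activation vectors, mismatch-negativity traces and exclusion flags are
#' collected into a `whorf_experiment` object; see
#' [summary.whorf_experiment()] for the aggregate tables.
#'
#' @param params a [whorf_params()] object; its `n_networks` and trial
#'   counts define the experiment scale.
#' @param seed master seed. Every random choice (connectivity, patterns,
#'   trial order, noise) descends from it via derived sub-seeds.
#' @param models language models to branch (default both).
#' @param keep_networks keep the trained weight matrices in the returned
#'   object (memory-heavy; default `FALSE`).
#' @param progress print per-stage progress lines.
#' @return An object of class `whorf_experiment`.
#' @export
run_experiment <- function(params = whorf_params(), seed,
                           models = c("english", "russian"),
                           keep_networks = FALSE, progress = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  n <- params$n_networks
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max, n * 8L),
                                  nrow = n))
  pat_seed <- with_seed(seed + 1L, sample.int(.Machine$integer.max, 1))
  patterns <- pattern_set(pat_seed)
  results <- stats::setNames(
    rep(list(vector("list", n)), length(models) + 1L),
    c("perceptual", models))
  networks <- vector("list", n)
  kept <- if (keep_networks) list() else NULL
  for (k in seq_len(n)) {
    if (progress) message("network ", k, "/", n, ": build + phase 1")
    net <- build_network(params, seed = seeds[k, 1])
    net1 <- run_phase1(net, patterns, params, seed = seeds[k, 2])
    w1 <- net1$W@x
    networks[[k]] <- list(
      connectivity_seed = seeds[k, 1],
      phase1 = attr(net1, "diagnostics"),
      phase1_checksum = c(n = length(w1), sum = sum(w1),
                          sumsq = sum(w1^2)))
    results$perceptual[[k]] <- analyze_model(net1, patterns, params,
                                             seed = seeds[k, 3])
    for (m in seq_along(models)) {
      if (progress) message("network ", k, "/", n, ": phase 2 (", models[m], ")")
      net2 <- run_phase2(net1, patterns, label_mapping(models[m]), params,
                         seed = seeds[k, 3 + m])
      networks[[k]][[paste0("phase2_", models[m])]] <- attr(net2, "diagnostics")
      results[[models[m]]][[k]] <- analyze_model(net2, patterns, params,
                                                 seed = seeds[k, 5 + m])
      if (keep_networks) kept[[paste(models[m], k, sep = "_")]] <- net2
    }
    if (keep_networks) kept[[paste("phase1", k, sep = "_")]] <- net1
  }
  structure(list(params = params, seed = seed, patterns = patterns,
                 models = c("perceptual", models), n_networks = n,
                 networks = networks, results = results,
                 kept_networks = kept),
            class = "whorf_experiment")
}

#' @export
print.whorf_experiment <- function(x, ...) {
  cat(sprintf("<whorf_experiment> %d networks x models {%s}, seed %d\n",
              x$n_networks, paste(x$models, collapse = ", "), x$seed))
  for (m in x$models) {
    excl <- vapply(x$results[[m]], `[[`, logical(1), "excluded")
    cat(sprintf("  %-10s %d/%d networks retained\n", m,
                sum(!excl), length(excl)))
  }
  cat("use summary() for dissimilarity / neuron-type / MMN tables\n")
  invisible(x)
}
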