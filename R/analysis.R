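#' Region groupings used in the analyses
#'
#' @return A named list of area-name vectors: the visual, auditory and
#'   articulatory systems, the four multimodal hubs, and the 10 relevant
#'   regions (all areas except the lateral motor PML and M1L, which
#'   receive no direct input in the color protocols).
#' @export
region_groupings <- function() {
  list(visual = c("V1", "TO", "AT"),
       auditory = c("A1", "AB", "PB"),
       articulatory = c("PFi", "PMi", "M1i"),
       hubs = hub_areas(),
       all_relevant = setdiff(area_names(), c("PML", "M1L")))
}

#' Extract a cell assembly from an extraction-trial recording
#'
#' Per area, the threshold is `gamma` times the peak rate estimate over
#' all cells and all 30 post-stimulation steps; a cell is a member iff its
#' rate reaches the threshold at any step. Areas whose peak stays below
#' `min_peak_rate` contribute no members. The default `gamma` is 0.5; the
#' 20%-of-peak responsiveness rule corresponds to `gamma = 0.2`, and
#' members under `gamma = 0.5` are always a subset of those under a
#' smaller `gamma`.
#'
#' @param rate_tensor a `rate_tensor` from [run_extraction_trial()].
#' @param params a [whorf_params()] object.
#' @param gamma membership fraction (default `params$gamma_ca`).
#' @param tag optional stimulus tag stored on the assembly.
#' @return An object of class `cell_assembly`: per-area member index sets
#'   and peak rates.
#' @export
extract_assembly <- function(rate_tensor, params = whorf_params(),
                             gamma = params$gamma_ca, tag = NULL) {
  arr <- unclass(rate_tensor)
  areas <- dimnames(arr)[[1]]
  members <- list()
  peaks <- numeric(length(areas))
  names(peaks) <- areas
  for (a in seq_along(areas)) {
    m <- arr[a, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = dim(arr)[3])
    cellmax <- apply(m, 1, max)
    peaks[a] <- max(cellmax)
    members[[areas[a]]] <-
      if (peaks[a] < params$min_peak_rate) integer(0)
      else which(cellmax >= gamma * peaks[a])
  }
  structure(list(tag = tag, members = members, peaks = peaks,
                 gamma = gamma, n_per = dim(arr)[2]),
            class = "cell_assembly")
}

#' @export
print.cell_assembly <- function(x, ...) {
  sizes <- vapply(x$members, length, integer(1))
  cat(sprintf("<cell_assembly>%s gamma=%.2g, %d members: %s\n",
              if (is.null(x$tag)) "" else paste0(" ", x$tag), x$gamma,
              sum(sizes),
              paste(names(sizes)[sizes > 0], sizes[sizes > 0],
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Per-region activation vectors
#'
#' Converts an extraction recording into the unthresholded activation
#' vectors used for representational similarity analysis: per region, the
#' per-cell mean rate estimate over the 30 post-stimulation steps.
#'
#' @inheritParams extract_assembly
#' @return A numeric matrix `cells x areas` with area column names.
#' @export
activation_vectors <- function(rate_tensor) {
  arr <- unclass(rate_tensor)
  out <- t(rowMeans(arr, dims = 2))
  colnames(out) <- dimnames(arr)[[1]]
  out
}

#' Representational dissimilarity matrix over the four color stimuli
#'
#' Euclidean distances between per-region activation vectors. For a
#' multi-region grouping the default collapses by averaging the
#' per-region distance matrices (`mode = "mean"`); `mode = "concat"`
#' instead measures distance over the concatenated vectors.
#'
#' @param vectors_by_stimulus a named list with one `cells x areas` matrix
#'   (see [activation_vectors()]) per stimulus; all four color stimuli
#'   must be present.
#' @param grouping character vector of region names to collapse.
#' @param mode `"mean"` or `"concat"`.
#' @return A symmetric `4 x 4` matrix of class `rdm` with zero diagonal.
#' @export
compute_rdm <- function(vectors_by_stimulus, grouping = region_groupings()$all_relevant,
                        mode = c("mean", "concat")) {
  mode <- match.arg(mode)
  tags <- color_tags()
  if (!all(tags %in% names(vectors_by_stimulus)))
    stop("missing stimulus: ",
         paste(setdiff(tags, names(vectors_by_stimulus)), collapse = ", "),
         call. = FALSE)
  vs <- vectors_by_stimulus[tags]
  areas <- colnames(vs[[1]])
  if (!all(grouping %in% areas))
    stop("grouping references unknown region(s)", call. = FALSE)
  if (mode == "concat") {
    m <- vapply(vs, function(v) as.vector(v[, grouping]),
                numeric(nrow(vs[[1]]) * length(grouping)))
    out <- as.matrix(stats::dist(t(m)))
  } else {
    per <- lapply(grouping, function(a) {
      m <- vapply(vs, function(v) v[, a], numeric(nrow(vs[[1]])))
      as.matrix(stats::dist(t(m)))
    })
    out <- Reduce(`+`, per) / length(per)
  }
  dimnames(out) <- list(tags, tags)
  structure(out, class = c("rdm", "matrix"))
}

# global e-cell indices of an assembly's members over given regions
assembly_global <- function(ca, regions, areas) {
  idx <- integer(0)
  for (a in regions) {
    m <- ca$members[[a]]
    if (length(m))
      idx <- c(idx, (match(a, areas) - 1L) * ca$n_per + m)
  }
  idx
}

#' Shared / unique neuron decomposition for a shade pair
#'
#' Per region: shared neurons belong to the assemblies of both shades of
#' a color, unique neurons to exactly one. Sharedness is
#' `shared / (shared + unique) * 100`.
#'
#' @param ca_light,ca_dark `cell_assembly` objects for the two shades.
#' @param grouping optional region subset; when given, a `(combined)` row
#'   with summed counts is appended.
#' @return A data.frame with columns `region`, `shared`, `unique_light`,
#'   `unique_dark`, `unique` and `sharedness` (percent, `NA` when both
#'   assemblies are empty in a region).
#' @export
count_shared_unique <- function(ca_light, ca_dark, grouping = NULL) {
  regions <- names(ca_light$members)
  if (!identical(regions, names(ca_dark$members)))
    stop("assemblies come from different architectures", call. = FALSE)
  if (!is.null(grouping)) regions <- intersect(regions, grouping)
  rows <- lapply(regions, function(a) {
    l <- ca_light$members[[a]]; d <- ca_dark$members[[a]]
    s <- length(intersect(l, d))
    ul <- length(setdiff(l, d)); ud <- length(setdiff(d, l))
    data.frame(region = a, shared = s, unique_light = ul, unique_dark = ud,
               unique = ul + ud, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(grouping)) {
    tot <- data.frame(region = "(combined)", shared = sum(out$shared),
                      unique_light = sum(out$unique_light),
                      unique_dark = sum(out$unique_dark),
                      unique = sum(out$unique), stringsAsFactors = FALSE)
    out <- rbind(out, tot)
  }
  denom <- out$shared + out$unique
  out$sharedness <- ifelse(denom > 0, 100 * out$shared / denom, NA_real_)
  out
}

#' Unique-response (mismatch-negativity proxy) trace
#'
#' From a recognition-trial spike raster and the two shade assemblies of
#' a color: per timestep, `Rtot` counts spikes among the cells assembled
#' by the presented shade, `Rshared` spikes among cells assembled by both
#' shades, and `uniqueR = Rtot - Rshared` isolates the response of the
#' shade-specific neurons. Counts are summed over the 10 relevant regions
#' by default; set `per_area = TRUE` to retain area-resolved traces.
#'
#' @param raster a `spike_raster` from [run_recognition_trial()].
#' @param ca_light,ca_dark the shade assemblies (from extraction).
#' @param params a [whorf_params()] object.
#' @param target which shade the raster's stimulus was.
#' @param regions regions to sum over (default the 10 relevant regions).
#' @param per_area return a named list of per-region traces instead.
#' @return A data.frame with columns `time`, `Rtot`, `Rshared`, `uniqueR`
#'   of class `mmn_trace`; attribute `"window"` holds the times of the
#'   10-step statistics window starting 2 steps after stimulus offset.
#' @export
mmn_trace <- function(raster, ca_light, ca_dark, params = whorf_params(),
                      target = c("light", "dark"),
                      regions = region_groupings()$all_relevant,
                      per_area = FALSE) {
  target <- match.arg(target)
  areas <- attr(raster, "areas")
  times <- attr(raster, "times")
  if (per_area) {
    out <- lapply(stats::setNames(nm = regions), function(a)
      mmn_trace(raster, ca_light, ca_dark, params, target, regions = a))
    return(out)
  }
  ca_t <- if (target == "light") ca_light else ca_dark
  tot_idx <- assembly_global(ca_t, regions, areas)
  shared <- lapply(names(ca_light$members), function(a)
    intersect(ca_light$members[[a]], ca_dark$members[[a]]))
  names(shared) <- names(ca_light$members)
  ca_s <- ca_t
  ca_s$members <- shared
  sh_idx <- assembly_global(ca_s, regions, areas)
  rtot <- if (length(tot_idx)) colSums(raster[tot_idx, , drop = FALSE])
          else numeric(ncol(raster))
  rsh <- if (length(sh_idx)) colSums(raster[sh_idx, , drop = FALSE])
         else numeric(ncol(raster))
  out <- data.frame(time = times, Rtot = rtot, Rshared = rsh,
                    uniqueR = rtot - rsh)
  offset <- params$stim_steps_recog  # first post-stimulation time
  window <- times[times >= offset + 1L & times <= offset + 10L]
  structure(out, window = window, target = target,
            class = c("mmn_trace", "data.frame"))
}

#' Mean unique response over the statistics window
#'
#' @param trace an `mmn_trace`.
#' @return Mean `uniqueR` across the 10-step post-offset window.
#' @export
mmn_window_mean <- function(trace) {
  w <- attr(trace, "window")
  mean(trace$uniqueR[trace$time %in% w])
}

#' Flag networks with merged or runaway assemblies
#'
#' A network is excluded when any two color assemblies that should stay
#' distinct exceed a Jaccard-overlap ceiling over the relevant regions,
#' or when a single stimulus recruits more than a ceiling fraction of any
#' area's e-cells — the operational reading of assembly merging and
#' excessive activation spread.
#'
#' @param assemblies a named list of the four color `cell_assembly`s.
#' @param params a [whorf_params()] object.
#' @param jaccard_ceiling maximum tolerated Jaccard overlap (default 0.8).
#' @param recruit_ceiling maximum tolerated fraction of an area recruited
#'   by one stimulus (default 0.5).
#' @param regions regions over which the Jaccard overlap is measured.
#' @return `exclude_network()`: list with `excluded`, `reason` and the
#'   pairwise `jaccard` matrix.
#' @export
exclude_network <- function(assemblies, params = whorf_params(),
                            jaccard_ceiling = 0.8, recruit_ceiling = 0.5,
                            regions = region_groupings()$all_relevant) {
  tags <- names(assemblies)
  areas <- names(assemblies[[1]]$members)
  n_per <- assemblies[[1]]$n_per
  sets <- lapply(assemblies, assembly_global, regions = regions,
                 areas = areas)
  n <- length(sets)
  jac <- matrix(0, n, n, dimnames = list(tags, tags))
  reason <- NULL
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) { jac[a, b] <- 1; next }
    u <- length(union(sets[[a]], sets[[b]]))
    jac[a, b] <- if (u == 0) 0 else length(intersect(sets[[a]], sets[[b]])) / u
  }
  over <- which(jac > jaccard_ceiling & upper.tri(jac), arr.ind = TRUE)
  if (nrow(over))
    reason <- paste0("assembly merge: ", tags[over[1, 1]], "/",
                     tags[over[1, 2]], " Jaccard ",
                     signif(jac[over[1, , drop = FALSE]], 3))
  for (tg in tags) for (a in areas) {
    frac <- length(assemblies[[tg]]$members[[a]]) / n_per
    if (frac > recruit_ceiling) {
      reason <- c(reason, paste0("activation spread: ", tg, " recruits ",
                                 round(100 * frac), "% of ", a))
      break
    }
  }
  list(excluded = !is.null(reason),
       reason = if (is.null(reason)) NA_character_ else reason[1],
       jaccard = jac)
}

#' @rdname exclude_network
#' @param results_per_network a list, one element per network, each a
#'   named list of four color `cell_assembly`s.
#' @param ... passed on to `exclude_network()`.
#' @return `exclude_networks()`: a logical exclusion flag per network,
#'   with reasons in attribute `"reason"`.
#' @export
exclude_networks <- function(results_per_network, ...) {
  res <- lapply(results_per_network, exclude_network, ...)
  structure(vapply(res, `[[`, logical(1), "excluded"),
            reason = vapply(res, `[[`, character(1), "reason"))
}

# per-stimulus activation-vector list (cells x areas) for one model result
act_vector_list <- function(model_result, areas, n_per) {
  act <- model_result$act_vectors
  lapply(stats::setNames(nm = colnames(act)), function(tag)
    matrix(act[, tag], nrow = n_per, ncol = length(areas),
           dimnames = list(NULL, areas)))
}

#' Per-network shade-pair dissimilarities
#'
#' For every model type and network, the Euclidean dissimilarity between
#' the light and dark shade representations of blue and of green, under a
#' region grouping.
#'
#' @param experiment a `whorf_experiment`.
#' @param grouping a grouping name from [region_groupings()] or a
#'   character vector of areas.
#' @param mode collapse mode, see [compute_rdm()].
#' @return A data.frame with columns `model`, `network`, `color`, `value`,
#'   `retained`.
#' @export
pair_dissimilarity <- function(experiment, grouping = "all_relevant",
                               mode = "mean") {
  if (length(grouping) == 1 && grouping %in% names(region_groupings()))
    grouping <- region_groupings()[[grouping]]
  areas <- area_names()
  n_per <- experiment$results[[1]][[1]]$assemblies[[1]]$n_per
  rows <- list()
  for (m in experiment$models) {
    for (k in seq_len(experiment$n_networks)) {
      r <- experiment$results[[m]][[k]]
      vs <- act_vector_list(r, areas, n_per)
      rdm <- compute_rdm(vs, grouping, mode)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, network = k,
        color = c("blue", "green"),
        value = c(rdm["blue_light", "blue_dark"],
                  rdm["green_light", "green_dark"]),
        retained = !r$excluded, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-region sharedness for a color, averaged over retained networks
#'
#' @param experiment a `whorf_experiment`.
#' @param model model type (`"perceptual"`, `"english"`, `"russian"`).
#' @param color `"blue"` or `"green"`.
#' @param regions regions to report (default the 10 relevant regions).
#' @return A data.frame with `region`, mean `sharedness` (percent) across
#'   retained networks, and `n` (networks contributing a defined value).
#' @export
sharedness_by_region <- function(experiment, model, color = "blue",
                                 regions = region_groupings()$all_relevant) {
  res <- experiment$results[[model]]
  keep <- !vapply(res, `[[`, logical(1), "excluded")
  if (!sum(keep))
    return(data.frame(region = regions, sharedness = NA_real_, n = 0L,
                      stringsAsFactors = FALSE))
  per_net <- lapply(res[keep], function(r) {
    cs <- count_shared_unique(r$assemblies[[paste0(color, "_light")]],
                              r$assemblies[[paste0(color, "_dark")]])
    cs$sharedness[match(regions, cs$region)]
  })
  m <- do.call(cbind, per_net)
  data.frame(region = regions,
             sharedness = rowMeans(m, na.rm = TRUE),
             n = rowSums(!is.na(m)), stringsAsFactors = FALSE)
}

#' Aggregate experiment tables
#'
#' Computes, over retained networks: mean and sd of the blue/green
#' shade-pair dissimilarities per region grouping; shared and unique
#' neuron counts per grouping and color; per-region sharedness; and the
#' mean unique-response (mismatch-negativity proxy) per color with the
#' blue-minus-green contrast per model.
#'
#' @param object a `whorf_experiment`.
#' @param ... unused.
#' @return An object of class `summary.whorf_experiment`.
#' @export
summary.whorf_experiment <- function(object, ...) {
  groupings <- region_groupings()
  diss <- list(); types <- list(); mmn <- list()
  for (g in names(groupings)) {
    pd <- pair_dissimilarity(object, g)
    pd$grouping <- g
    diss[[g]] <- pd
  }
  diss <- do.call(rbind, diss)
  kept <- diss[diss$retained, ]
  if (nrow(kept) == 0)
    stop("all networks excluded in every model type", call. = FALSE)
  diss_sum <- stats::aggregate(value ~ model + grouping + color, kept,
                               function(v) c(mean = mean(v), sd = stats::sd(v)))
  diss_sum <- cbind(diss_sum[1:3], as.data.frame(diss_sum$value))
  for (m in object$models) {
    res <- object$results[[m]]
    keep <- !vapply(res, `[[`, logical(1), "excluded")
    for (g in names(groupings)) {
      for (col in c("blue", "green")) {
        cnt <- vapply(res[keep], function(r) {
          cs <- count_shared_unique(r$assemblies[[paste0(col, "_light")]],
                                    r$assemblies[[paste0(col, "_dark")]],
                                    grouping = groupings[[g]])
          tot <- cs[cs$region == "(combined)", ]
          c(tot$shared, tot$unique)
        }, numeric(2))
        if (!sum(keep)) cnt <- matrix(NA_real_, 2, 0)
        types[[length(types) + 1L]] <- data.frame(
          model = m, grouping = g, color = col,
          shared = mean(cnt[1, ]), unique = mean(cnt[2, ]),
          shared_sd = stats::sd(cnt[1, ]), unique_sd = stats::sd(cnt[2, ]),
          n = sum(keep), stringsAsFactors = FALSE)
      }
    }
    if (sum(keep)) {
      umeans <- vapply(res[keep], function(r)
        vapply(r$mmn, mmn_window_mean, numeric(1)), numeric(4))
      blue <- colMeans(umeans[c("blue_light", "blue_dark"), , drop = FALSE])
      green <- colMeans(umeans[c("green_light", "green_dark"), , drop = FALSE])
    } else {
      blue <- green <- NA_real_
    }
    mmn[[m]] <- data.frame(model = m, blue = mean(blue), green = mean(green),
                           contrast = mean(blue - green),
                           contrast_sd = stats::sd(blue - green),
                           n = sum(keep), stringsAsFactors = FALSE)
  }
  retained <- vapply(object$models, function(m)
    sum(!vapply(object$results[[m]], `[[`, logical(1), "excluded")),
    integer(1))
  structure(list(dissimilarity = diss_sum,
                 dissimilarity_networks = diss,
                 neuron_types = do.call(rbind, types),
                 sharedness = lapply(
                   stats::setNames(nm = object$models), function(m)
                     list(blue = sharedness_by_region(object, m, "blue"),
                          green = sharedness_by_region(object, m, "green"))),
                 mmn = do.call(rbind, mmn),
                 retained = retained,
                 n_networks = object$n_networks),
            class = "summary.whorf_experiment")
}

#' @export
print.summary.whorf_experiment <- function(x, ...) {
  cat("Retained networks:",
      paste(names(x$retained), x$retained, sep = "=", collapse = ", "),
      "of", x$n_networks, "\n\n")
  cat("Shade-pair dissimilarity (mean over retained networks):\n")
  d <- x$dissimilarity[x$dissimilarity$grouping == "all_relevant", ]
  print(d, row.names = FALSE, digits = 4)
  cat("\nShared/unique neurons (all relevant regions):\n")
  t <- x$neuron_types[x$neuron_types$grouping == "all_relevant", ]
  print(t[, c("model", "color", "shared", "unique", "n")],
        row.names = FALSE, digits = 4)
  cat("\nUnique-response (MMN proxy) window means:\n")
  print(x$mmn, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Descriptive repeated-measures ANOVA on shade-pair dissimilarities
#'
#' Convenience wrapper over [stats::aov()] with a network-level error
#' stratum, contrasting model type and color on per-network shade-pair
#' dissimilarities. Descriptive only: small desk-scale experiments do not
#' license the published inferential statistics.
#'
#' @param experiment a `whorf_experiment`.
#' @param grouping region grouping (see [pair_dissimilarity()]).
#' @param models model types to contrast (default the two language models).
#' @return The `summary()` of the fitted `aov` object.
#' @export
anova_dissimilarity <- function(experiment, grouping = "all_relevant",
                                models = c("english", "russian")) {
  d <- pair_dissimilarity(experiment, grouping)
  d <- d[d$retained & d$model %in% models, ]
  d$model <- factor(d$model); d$color <- factor(d$color)
  d$network <- factor(d$network)
  summary(stats::aov(value ~ model * color + Error(network / (model * color)),
                     data = d))
}

#' Plot experiment results
#'
#' Draws the collapsed representational dissimilarity matrix per model
#' type and a boxplot of per-network blue/green shade-pair
#' dissimilarities.
#'
#' @param x a `whorf_experiment`.
#' @param grouping region grouping to display.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.whorf_experiment <- function(x, grouping = "all_relevant", ...) {
  models <- x$models
  old <- graphics::par(mfrow = c(1, length(models) + 1), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old))
  areas <- area_names()
  gr <- region_groupings()[[grouping]]
  n_per <- x$results[[1]][[1]]$assemblies[[1]]$n_per
  for (m in models) {
    res <- x$results[[m]]
    keep <- !vapply(res, `[[`, logical(1), "excluded")
    rdms <- lapply(res[keep], function(r)
      compute_rdm(act_vector_list(r, areas, n_per), gr))
    rdm <- Reduce(`+`, rdms) / length(rdms)
    graphics::image(seq_len(4), seq_len(4), t(rdm[4:1, ]),
                    col = grDevices::hcl.colors(24, "Blues", rev = TRUE),
                    axes = FALSE, xlab = "", ylab = "",
                    main = paste0(m, " RDM (", grouping, ")"))
    graphics::axis(1, 1:4, colnames(rdm), las = 2, cex.axis = 0.7)
    graphics::axis(2, 1:4, rev(rownames(rdm)), las = 2, cex.axis = 0.7)
  }
  d <- pair_dissimilarity(x, grouping)
  d <- d[d$retained, ]
  graphics::boxplot(value ~ color + model, data = d, las = 2,
                    ylab = "shade-pair dissimilarity", xlab = "",
                    main = "blue vs green by model")
  invisible(x)
}

#' Export result tables and a run manifest
#'
#' Writes tidy CSVs (per-network dissimilarities, neuron-type summaries,
#' per-region sharedness, MMN window means) and a JSON manifest (seed,
#' model list, exclusion flags, effective parameters) to a directory.
#'
#' @param experiment a `whorf_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(experiment)
  utils::write.csv(s$dissimilarity_networks,
                   file.path(dir, "dissimilarity_per_network.csv"),
                   row.names = FALSE)
  utils::write.csv(s$neuron_types, file.path(dir, "neuron_types.csv"),
                   row.names = FALSE)
  sh <- do.call(rbind, lapply(names(s$sharedness), function(m)
    do.call(rbind, lapply(names(s$sharedness[[m]]), function(col)
      cbind(model = m, color = col, s$sharedness[[m]][[col]])))))
  utils::write.csv(sh, file.path(dir, "sharedness.csv"), row.names = FALSE)
  utils::write.csv(s$mmn, file.path(dir, "mmn_window_means.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = experiment$seed, models = experiment$models,
    n_networks = experiment$n_networks,
    pattern_seed = experiment$patterns$seed,
    excluded = lapply(stats::setNames(nm = experiment$models), function(m)
      vapply(experiment$results[[m]], `[[`, logical(1), "excluded")),
    params = unclass(experiment$params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_pattern_set(experiment$patterns, file.path(dir, "patterns.json"))
  invisible(dir)
}
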