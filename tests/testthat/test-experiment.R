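test_that("a miniature experiment produces all model types reproducibly", {
  p <- whorf_params(n_networks = 1L)
  p$trials_phase1_per_pattern <- 2L
  p$trials_phase2_per_pairing <- 2L
  exp1 <- run_experiment(p, seed = 301)
  expect_s3_class(exp1, "whorf_experiment")
  # perceptual snapshot plus both language branches per instantiation
  expect_setequal(exp1$models, c("perceptual", "english", "russian"))
  for (m in exp1$models) {
    r <- exp1$results[[m]][[1]]
    expect_named(r$assemblies, color_tags())
    expect_equal(dim(r$act_vectors), c(12L * 625L, 4L))
    expect_named(r$mmn, c("blue_light", "blue_dark",
                          "green_light", "green_dark"))
    expect_type(r$excluded, "logical")
  }
  # language branches descend from the identical phase-1 snapshot
  expect_length(exp1$networks[[1]]$phase1_checksum, 3L)
  # and the whole experiment is reproducible from the master seed
  exp2 <- run_experiment(p, seed = 301)
  expect_identical(exp1$results$russian[[1]]$act_vectors,
                   exp2$results$russian[[1]]$act_vectors)
  expect_identical(exp1$networks[[1]]$phase1_checksum,
                   exp2$networks[[1]]$phase1_checksum)
})

# deterministic hand-built experiment for the aggregation layer
fake_experiment <- function(n_networks = 2) {
  n_e <- 12L * 625L
  mk_result <- function(k, shift) {
    act <- matrix(0, n_e, 4, dimnames = list(NULL, color_tags()))
    # V1 block differs between shades by `shift`, greens identical
    act[1:20, "blue_light"] <- 1
    act[1:20 + shift, "blue_dark"] <- 1
    act[51:70, c("green_light", "green_dark")] <- 1
    assemblies <- list(
      blue_light = toy_assembly(list(V1 = 1:20)),
      blue_dark = toy_assembly(list(V1 = 1:20 + shift)),
      green_light = toy_assembly(list(V1 = 51:70)),
      green_dark = toy_assembly(list(V1 = 51:70)))
    for (tag in color_tags()) {
      mem <- assemblies[[tag]]$members$V1
      full <- stats::setNames(rep(list(integer(0)), 12), area_names())
      full$V1 <- mem
      assemblies[[tag]]$members <- full
    }
    tr <- data.frame(time = c(-10:-1, 0:1, 2:29), Rtot = 0, Rshared = 0,
                     uniqueR = shift)
    attr(tr, "window") <- 3:12
    class(tr) <- c("mmn_trace", "data.frame")
    mmn <- stats::setNames(rep(list(tr), 4), color_tags())
    list(act_vectors = act, assemblies = assemblies, mmn = mmn,
         excluded = FALSE, exclusion_reason = NA_character_)
  }
  results <- list(
    perceptual = lapply(1:n_networks, mk_result, shift = 5),
    english = lapply(1:n_networks, mk_result, shift = 5),
    russian = lapply(1:n_networks, mk_result, shift = 10))
  structure(list(params = whorf_params(n_networks = n_networks),
                 seed = 1, patterns = pattern_fixture(),
                 models = c("perceptual", "english", "russian"),
                 n_networks = n_networks,
                 networks = vector("list", n_networks),
                 results = results, kept_networks = NULL),
            class = "whorf_experiment")
}

test_that("summary aggregates dissimilarity, neuron types and MMN correctly", {
  ex <- fake_experiment()
  s <- summary(ex)
  # one dissimilarity row per model x grouping x color
  expect_equal(nrow(s$dissimilarity),
               length(ex$models) * length(region_groupings()) * 2L)
  # the russian blue pair is built more dissimilar than the english one
  d <- s$dissimilarity[s$dissimilarity$grouping == "all_relevant", ]
  blue_ru <- d$mean[d$model == "russian" & d$color == "blue"]
  blue_en <- d$mean[d$model == "english" & d$color == "blue"]
  expect_gt(blue_ru, blue_en)
  # identical green patterns -> zero dissimilarity everywhere
  expect_equal(d$mean[d$color == "green"], rep(0, 3))
  # neuron types: english blue shares 15 of 25, russian blue 10 of 30
  nt <- s$neuron_types[s$neuron_types$grouping == "all_relevant", ]
  expect_equal(nt$shared[nt$model == "english" & nt$color == "blue"], 15)
  expect_equal(nt$unique[nt$model == "english" & nt$color == "blue"], 10)
  expect_equal(nt$shared[nt$model == "russian" & nt$color == "blue"], 10)
  expect_equal(nt$unique[nt$model == "russian" & nt$color == "blue"], 20)
  # MMN window means flow through
  expect_equal(s$mmn$blue[s$mmn$model == "russian"], 10)
  expect_equal(s$mmn$contrast[s$mmn$model == "russian"], 0)
  expect_equal(s$retained[["russian"]], 2L)
})

test_that("symmetric inputs give identical blue and green summaries", {
  ex <- fake_experiment()
  # rebuild with blue patterns mirroring the greens exactly
  for (m in ex$models) for (k in seq_along(ex$results[[m]])) {
    r <- ex$results[[m]][[k]]
    r$act_vectors[, "blue_light"] <- r$act_vectors[, "green_light"]
    r$act_vectors[, "blue_dark"] <- r$act_vectors[, "green_dark"]
    r$assemblies$blue_light <- r$assemblies$green_light
    r$assemblies$blue_dark <- r$assemblies$green_dark
    ex$results[[m]][[k]] <- r
  }
  s <- summary(ex)
  d <- s$dissimilarity
  expect_equal(d$mean[d$color == "blue"], d$mean[d$color == "green"])
  nt <- s$neuron_types
  expect_equal(nt$shared[nt$color == "blue"], nt$shared[nt$color == "green"])
})

test_that("result export writes tidy tables and a manifest", {
  ex <- fake_experiment()
  dir <- withr::local_tempdir()
  write_results(ex, dir)
  expect_true(file.exists(file.path(dir, "dissimilarity_per_network.csv")))
  expect_true(file.exists(file.path(dir, "neuron_types.csv")))
  expect_true(file.exists(file.path(dir, "sharedness.csv")))
  expect_true(file.exists(file.path(dir, "mmn_window_means.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 1L)
  expect_equal(man$n_networks, 2L)
  ps <- read_pattern_set(file.path(dir, "patterns.json"))
  expect_equal(ps$seed, ex$patterns$seed)
})
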