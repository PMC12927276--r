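test_that("assembly extraction applies the gamma and peak-rate rules", {
  p <- whorf_params()
  # hand-built tensor: 2 areas, 4 cells, 5 steps
  tens <- toy_tensor(n_areas = 2, n_cells = 4, n_steps = 5)
  # area 1 (V1): peak 0.4 at cell 1; cell 2 peaks at 0.19
  tens[1, 1, 3] <- 0.4
  tens[1, 2, 4] <- 0.19
  # area 2 (TO): peak below min_peak_rate -> contributes nothing
  tens[2, , ] <- 0.15
  ca5 <- extract_assembly(tens, p, gamma = 0.5)
  expect_equal(ca5$members$V1, 1L)            # 0.19 < 0.5 * 0.4
  expect_length(ca5$members$TO, 0L)           # peak 0.15 < 0.2
  ca2 <- extract_assembly(tens, p, gamma = 0.2)
  expect_equal(ca2$members$V1, c(1L, 2L))     # 0.19 >= 0.2 * 0.4
  # membership threshold is inclusive: a cell exactly at gamma * peak is in
  tens[1, 3, 2] <- 0.2
  expect_true(3L %in% extract_assembly(tens, p, gamma = 0.5)$members$V1)
  expect_equal(whorf_params()$gamma_ca, 0.5)  # published default

  # all-zero tensor -> empty assembly
  ca0 <- extract_assembly(toy_tensor(), p)
  expect_true(all(vapply(ca0$members, length, 1L) == 0L))
})

test_that("membership is monotone in gamma", {
  p <- whorf_params()
  set.seed(5)
  for (i in 1:10) {
    tens <- toy_tensor(n_areas = 3, n_cells = 30, n_steps = 8)
    tens[] <- runif(length(tens))
    hi <- extract_assembly(tens, p, gamma = 0.5)
    lo <- extract_assembly(tens, p, gamma = 0.2)
    for (a in names(hi$members))
      expect_true(all(hi$members[[a]] %in% lo$members[[a]]))
  }
})

test_that("activation vectors are per-cell window means", {
  tens <- toy_tensor(n_areas = 2, n_cells = 3, n_steps = 4)
  set.seed(2)
  tens[] <- runif(length(tens))
  av <- activation_vectors(tens)
  expect_equal(dim(av), c(3L, 2L))
  # naive loop oracle
  for (a in 1:2) for (c in 1:3)
    expect_equal(unname(av[c, a]), mean(tens[a, c, ]))
  # constant trace and zero tensor
  tens[] <- 0.3
  expect_true(all(activation_vectors(tens) == 0.3))
  tens[] <- 0
  expect_true(all(activation_vectors(tens) == 0))
})

test_that("RDMs are Euclidean, symmetric, and collapse correctly", {
  mk <- function(v1, to = rep(0, 5)) {
    m <- cbind(V1 = v1, TO = to)
    m
  }
  zeros <- rep(0, 5)
  vs <- list(blue_light = mk(zeros), blue_dark = mk(c(3, 4, 0, 0, 0)),
             green_light = mk(zeros), green_dark = mk(zeros))
  rdm <- compute_rdm(vs, grouping = "V1")
  expect_equal(rdm["blue_light", "blue_dark"], 5)      # 3-4-5 triangle
  expect_equal(rdm["green_light", "green_dark"], 0)    # identical -> 0
  expect_true(isSymmetric(unclass(rdm)))
  expect_equal(unname(diag(rdm)), rep(0, 4))

  # mean mode averages per-region distances; concat uses joint space
  vs2 <- list(blue_light = mk(zeros, zeros),
              blue_dark = mk(c(3, 4, 0, 0, 0), c(0, 0, 5, 0, 0)),
              green_light = mk(zeros, zeros), green_dark = mk(zeros, zeros))
  rdm_mean <- compute_rdm(vs2, grouping = c("V1", "TO"), mode = "mean")
  expect_equal(rdm_mean["blue_light", "blue_dark"], (5 + 5) / 2)
  rdm_cat <- compute_rdm(vs2, grouping = c("V1", "TO"), mode = "concat")
  expect_equal(rdm_cat["blue_light", "blue_dark"], sqrt(25 + 25))

  expect_error(compute_rdm(vs[1:3], grouping = "V1"), "missing stimulus")

  # metric properties on random inputs
  set.seed(9)
  vr <- lapply(stats::setNames(nm = names(vs)), function(n)
    matrix(runif(20), 10, 2, dimnames = list(NULL, c("V1", "TO"))))
  r <- compute_rdm(vr, grouping = c("V1", "TO"))
  expect_true(all(r >= 0))
  expect_true(isSymmetric(unclass(r)))
  expect_equal(unname(diag(r)), rep(0, 4))
})

test_that("shared/unique decomposition follows the set arithmetic", {
  ca_l <- toy_assembly(list(V1 = c(1L, 2L, 3L), TO = integer(0)))
  ca_d <- toy_assembly(list(V1 = c(3L, 4L), TO = integer(0)))
  cs <- count_shared_unique(ca_l, ca_d)
  v1 <- cs[cs$region == "V1", ]
  expect_equal(v1$shared, 1L)
  expect_equal(v1$unique, 3L)
  expect_equal(v1$sharedness, 25)
  expect_true(is.na(cs$sharedness[cs$region == "TO"]))

  # disjoint -> 0%; identical -> 100%
  d1 <- count_shared_unique(toy_assembly(list(V1 = 1:5)),
                            toy_assembly(list(V1 = 6:9)))
  expect_equal(d1$sharedness, 0)
  d2 <- count_shared_unique(toy_assembly(list(V1 = 1:5)),
                            toy_assembly(list(V1 = 1:5)))
  expect_equal(d2$sharedness, 100)

  # grouping totals are sums over regions
  ca_l2 <- toy_assembly(list(V1 = 1:3, TO = 1:2, AT = integer(0)))
  ca_d2 <- toy_assembly(list(V1 = 2:4, TO = 3:4, AT = integer(0)))
  cs2 <- count_shared_unique(ca_l2, ca_d2, grouping = c("V1", "TO"))
  tot <- cs2[cs2$region == "(combined)", ]
  expect_equal(tot$shared, 2L)       # {2,3} in V1, none in TO
  expect_equal(tot$unique, 6L)
  expect_equal(tot$sharedness, 100 * 2 / 8)
})

test_that("the unique-response trace subtracts the shared response", {
  p <- whorf_params()
  # toy raster over the full 12-area layout, 2 areas used
  n_e <- 12L * 625L
  raster <- matrix(0L, n_e, 40)
  times <- c(-10:-1, 0:1, 2:29)
  attr(raster, "times") <- times
  attr(raster, "areas") <- area_names()
  # light CA: V1 cells 1..10; dark CA: V1 cells 6..15 (shared 6..10)
  ca_l <- toy_assembly(list(V1 = 1:10))
  ca_d <- toy_assembly(list(V1 = 6:15))
  # at one post-stimulation step, all light members spike (Rtot 10,
  # Rshared 5 -> uniqueR 5); craft a 10/4 step too
  raster[1:10, 20] <- 1L
  raster[c(1:6, 7:9, 10), 21] <- 1L
  raster[6:9, 21] <- 1L  # idempotent; keeps shared spikes at 4 below
  raster[, 22] <- 0L
  raster[1:10, 22] <- 1L
  raster[10:15, 23] <- 1L
  tr <- mmn_trace(raster, ca_l, ca_d, p, target = "light")
  expect_s3_class(tr, "mmn_trace")
  i20 <- which(tr$time == times[20])
  expect_equal(tr$Rtot[i20], 10)
  expect_equal(tr$Rshared[i20], 5)
  expect_equal(tr$uniqueR[i20], 5)
  expect_true(all(tr$uniqueR >= 0))
  # identical responsive sets -> uniqueR identically zero
  tr0 <- mmn_trace(raster, ca_l, ca_l, p, target = "light")
  expect_true(all(tr0$uniqueR == 0))
  # statistics window: 10 steps starting 2 after stimulus offset
  expect_length(attr(tr, "window"), 10L)
  expect_equal(min(attr(tr, "window")), p$stim_steps_recog + 1L)
  # explicit example: Rtot 10, Rshared 4 -> uniqueR 6
  raster2 <- raster; raster2[, ] <- 0L
  raster2[1:10, 25] <- 1L
  raster2[11:15, 25] <- 0L
  ca_d2 <- toy_assembly(list(V1 = c(7:10, 16:21)))
  tr2 <- mmn_trace(raster2, ca_l, ca_d2, p, target = "light")
  i25 <- which(tr2$time == times[25])
  expect_equal(tr2$Rtot[i25], 10)
  expect_equal(tr2$Rshared[i25], 4)
  expect_equal(tr2$uniqueR[i25], 6)
})

test_that("network exclusion flags merged assemblies and runaway spread", {
  p <- whorf_params()
  # two assemblies with Jaccard 0.9 over the relevant regions
  a <- toy_assembly(list(V1 = 1:100, AT = 1:50))
  b <- toy_assembly(list(V1 = c(1:95, 101:105), AT = c(1:40, 51:60)))
  mk4 <- function(a, b) list(blue_light = a, blue_dark = a,
                             green_light = b, green_dark = b)
  ex <- exclude_network(list(blue_light = a, blue_dark = b,
                             green_light = toy_assembly(list(V1 = 200:220)),
                             green_dark = toy_assembly(list(V1 = 230:250))), p)
  expect_true(ex$excluded)
  expect_match(ex$reason, "merge")
  expect_gt(ex$jaccard["blue_light", "blue_dark"], 0.8)

  # well-separated assemblies are retained
  sep <- list(blue_light = toy_assembly(list(V1 = 1:30)),
              blue_dark = toy_assembly(list(V1 = 25:55)),
              green_light = toy_assembly(list(V1 = 100:130)),
              green_dark = toy_assembly(list(V1 = 125:155)))
  expect_false(exclude_network(sep, p)$excluded)

  # one stimulus recruiting 400/625 cells of an area is flagged
  big <- sep
  big$blue_light <- toy_assembly(list(V1 = 1:400))
  ex2 <- exclude_network(big, p)
  expect_true(ex2$excluded)
  expect_match(ex2$reason, "spread")

  # vectorized form
  flags <- exclude_networks(list(sep, big), p)
  expect_equal(as.vector(flags), c(FALSE, TRUE))
})
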