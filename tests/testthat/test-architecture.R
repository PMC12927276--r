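test_that("the default macro-graph has 12 areas, streams, hubs and jumps", {
  g <- default_connectivity_graph()
  expect_setequal(unique(c(g$from, g$to)), area_names())
  expect_length(area_names(), 12L)

  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- key(g$from, g$to)
  # within-stream adjacency
  for (pair in list(c("V1", "TO"), c("TO", "AT"), c("PFL", "PML"),
                    c("PML", "M1L"), c("A1", "AB"), c("AB", "PB"),
                    c("PFi", "PMi"), c("PMi", "M1i")))
    expect_true(key(pair[1], pair[2]) %in% edges)
  # hub subgraph is complete: all 6 pairs among AT, PFL, PB, PFi
  hubs <- c("AT", "PFL", "PB", "PFi")
  hub_pairs <- utils::combn(hubs, 2)
  expect_true(all(key(hub_pairs[1, ], hub_pairs[2, ]) %in% edges))
  # jumping links primary -> hub
  for (pair in list(c("V1", "AT"), c("M1L", "PFL"), c("A1", "PB"),
                    c("M1i", "PFi")))
    expect_true(key(pair[1], pair[2]) %in% edges)
  # reciprocity by construction: directed expansion has both directions
  d <- whorfnet:::directed_edges(g)
  expect_true(all(paste(d$to, d$from) %in% paste(d$from, d$to)))
  expect_equal(nrow(d), 2L * nrow(g))
})

test_that("graph validation rejects malformed graphs", {
  bad <- data.frame(from = "V1", to = "V1", class = "adjacent")
  expect_error(whorfnet:::validate_graph(bad, area_names()), "self-loops")
  dup <- data.frame(from = c("V1", "TO"), to = c("TO", "V1"),
                    class = "adjacent")
  expect_error(whorfnet:::validate_graph(dup, area_names()), "duplicate")
  unk <- data.frame(from = "V1", to = "XX", class = "adjacent")
  expect_error(whorfnet:::validate_graph(unk, area_names()), "unknown")
})

test_that("kernel probabilities follow the clipped Gaussian", {
  p <- whorf_params()
  expect_equal(kernel_probability(c(0, 0), "ee_within", p), 0.28)
  expect_equal(kernel_probability(c(0, 0), "ee_between", p), 0.15)
  expect_equal(kernel_probability(c(0, 0), "ie", p), 0.295)
  expect_equal(kernel_probability(c(3, 4), "ee_within", p),
               0.28 * exp(-25 / (2 * 6.5^2)))
  expect_equal(kernel_probability(c(-2, 1), "ie", p),
               0.295 * exp(-5 / (2 * 2^2)))
  # clipped to zero outside the neighborhood square
  expect_equal(kernel_probability(c(10, 0), "ee_within", p), 0)
  expect_equal(kernel_probability(c(0, 10), "ee_between", p), 0)
  expect_equal(kernel_probability(c(3, 0), "ie", p), 0)
})

test_that("a default network instantiates 15,000 cells with sign-correct synapses", {
  p <- whorf_params()
  net <- build_network(p, seed = 1)
  expect_equal(2L * net$n_e, 15000L)
  expect_equal(net$n_e, 12L * 625L)
  expect_equal(dim(net$W), c(15000L, 15000L))

  n_e <- net$n_e
  W <- net$W
  ij <- Matrix::which(W != 0, arr.ind = TRUE)
  x <- W@x[W@x != 0]
  pre_is_i <- ij[, 2] > n_e
  expect_true(all(x[pre_is_i] <= 0))         # i -> e negative
  expect_true(all(x[!pre_is_i] >= 0))        # e -> e and e -> i non-negative
  expect_true(all(ij[pre_is_i, 1] <= n_e))   # i-cells project to e only
  ee <- !pre_is_i & ij[, 1] <= n_e
  expect_true(all(x[ee] <= p$w_init_max))
  expect_false(any(ij[, 1] == ij[, 2]))      # no self links
})

test_that("builds are reproducible from the seed and require one", {
  p <- whorf_params()
  n1 <- build_network(p, seed = 5)
  n2 <- build_network(p, seed = 5)
  n3 <- build_network(p, seed = 6)
  expect_identical(n1$W@x, n2$W@x)
  expect_identical(n1$W@i, n2$W@i)
  expect_false(identical(n1$W@x, n3$W@x))
  expect_error(build_network(p), "seed")
})

test_that("between-area links exist only for pairs in the macro-graph", {
  p <- toy_params(kernel_ee_within = list(center_prob = 0.5, sigma = 2, neighborhood = 3L),
                  kernel_ee_between = list(center_prob = 0.5, sigma = 2, neighborhood = 3L),
                  kernel_ie = list(center_prob = 0.5, sigma = 2, neighborhood = 3L))
  areas <- area_names()[1:3]
  g <- structure(data.frame(from = "V1", to = "TO", class = "adjacent",
                            stringsAsFactors = FALSE),
                 class = c("connectivity_graph", "data.frame"))
  net <- build_network(p, seed = 2, graph = g, areas = areas, grid_side = 5)
  n_per <- 25L
  blk <- function(a, b) # e-block weight count from area a to area b
    Matrix::nnzero(net$W[(b - 1) * n_per + 1:n_per, (a - 1) * n_per + 1:n_per])
  expect_gt(blk(1, 2), 0)  # V1 -> TO sampled
  expect_gt(blk(2, 1), 0)  # reciprocal direction sampled
  expect_equal(blk(1, 3), 0)  # V1 -> AT not in graph
  expect_equal(blk(3, 1), 0)
  expect_equal(blk(2, 3), 0)
})

test_that("realized link frequencies match the kernel (Monte Carlo)", {
  p <- whorf_params()
  areas <- area_names()[1]
  g <- structure(data.frame(from = character(0), to = character(0),
                            class = character(0), stringsAsFactors = FALSE),
                 class = c("connectivity_graph", "data.frame"))
  # count within-area e->e links at offset (1, 0) across seeds
  n_links <- 0L
  n_builds <- 30L
  for (s in seq_len(n_builds)) {
    net <- build_network(p, seed = 1000 + s, graph = g, areas = areas)
    n_e <- net$n_e
    ij <- Matrix::which(net$W[1:n_e, 1:n_e] != 0, arr.ind = TRUE)
    pre_rc <- cbind((ij[, 2] - 1) %/% 25, (ij[, 2] - 1) %% 25)
    post_rc <- cbind((ij[, 1] - 1) %/% 25, (ij[, 1] - 1) %% 25)
    ddr <- (post_rc[, 1] - pre_rc[, 1]) %% 25
    ddc <- (post_rc[, 2] - pre_rc[, 2]) %% 25
    n_links <- n_links + sum(ddr == 0 & ddc == 1)
  }
  n_trials <- n_builds * 625L
  p_hat <- n_links / n_trials
  p_true <- 0.28 * exp(-1 / (2 * 6.5^2))
  se <- sqrt(p_true * (1 - p_true) / n_trials)
  expect_lt(abs(p_hat - p_true), 4 * se)

  # total within-area link count across all offsets
  exp_total <- 625 * sum(vapply(-9:9, function(dx) sum(vapply(-9:9, function(dy) {
    if (dx == 0 && dy == 0) return(0)
    0.28 * exp(-(dx^2 + dy^2) / (2 * 6.5^2))
  }, 1)), 1))
  net <- build_network(p, seed = 77, graph = g, areas = areas)
  tot <- Matrix::nnzero(net$W[1:625, 1:625])
  expect_lt(abs(tot - exp_total) / exp_total, 0.05)
})
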