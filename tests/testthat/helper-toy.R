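# Small-circuit builders for fast deterministic tests.

# parameters scaled for toy grids: tiny neighborhoods, no noise surprises
toy_params <- function(...) {
  defaults <- list(
    kernel_ee_within = list(center_prob = 0.9, sigma = 2, neighborhood = 1L),
    kernel_ee_between = list(center_prob = 0.9, sigma = 2, neighborhood = 1L),
    kernel_ie = list(center_prob = 0.9, sigma = 2, neighborhood = 1L))
  do.call(whorf_params, utils::modifyList(defaults, list(...)))
}

# random small network: n_areas areas on a g x g grid, chain-connected
toy_network <- function(seed, n_areas = 2, g = 2, params = toy_params()) {
  areas <- area_names()[seq_len(n_areas)]
  graph <- if (n_areas >= 2)
    data.frame(from = areas[-n_areas], to = areas[-1],
               class = "adjacent", stringsAsFactors = FALSE)
  else
    data.frame(from = character(0), to = character(0),
               class = character(0), stringsAsFactors = FALSE)
  class(graph) <- c("connectivity_graph", "data.frame")
  build_network(params, seed = seed, graph = graph, areas = areas,
                grid_side = g)
}

# network with explicitly given e/i weight matrix (post x pre, signed)
manual_network <- function(W, n_areas, grid_side, params = toy_params()) {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  areas <- area_names()[seq_len(n_areas)]
  graph <- data.frame(from = character(0), to = character(0),
                      class = character(0), stringsAsFactors = FALSE)
  class(graph) <- c("connectivity_graph", "data.frame")
  structure(list(W = W, areas = areas, grid_side = as.integer(grid_side),
                 n_e = n_areas * grid_side^2, n_areas = n_areas,
                 graph = graph, seed = 0L, params = params),
            class = "whorf_network")
}

# a single isolated e-cell (one 1x1 area, no synapses)
isolated_cell <- function(params = toy_params()) {
  manual_network(matrix(0, 2, 2), n_areas = 1, grid_side = 1,
                 params = params)
}

# hand-built extraction tensor: areas x cells x steps from a list of
# per-area cell traces (named by area index)
toy_tensor <- function(n_areas = 2, n_cells = 4, n_steps = 5, fill = 0) {
  arr <- array(fill, dim = c(n_areas, n_cells, n_steps))
  dimnames(arr) <- list(area_names()[seq_len(n_areas)], NULL, NULL)
  structure(arr, class = "rate_tensor")
}

# minimal cell_assembly from per-area member lists
toy_assembly <- function(members, n_per = 625L, tag = NULL, gamma = 0.5) {
  areas <- names(members)
  peaks <- stats::setNames(rep(1, length(areas)), areas)
  structure(list(tag = tag, members = members, peaks = peaks,
                 gamma = gamma, n_per = n_per),
            class = "cell_assembly")
}
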