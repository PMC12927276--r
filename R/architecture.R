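#' The 12-area frontotemporal-occipital architecture
#'
#' The model comprises twelve cortical areas, each a 25 x 25 grid of
#' excitatory cells with twin inhibitory cells: a ventral visual stream
#' (V1, TO, AT), a lateral motor stream (PFL, PML, M1L), an auditory
#' stream (A1, AB, PB) and an articulatory stream (PFi, PMi, M1i). The
#' four multimodal hub areas (AT, PFL, PB, PFi) are fully interconnected;
#' adjacent areas within a stream are linked, and each stream carries a
#' non-adjacent jumping link between its primary area and its hub.
#'
#' @name architecture
NULL

#' @rdname architecture
#' @return `area_names()`: the canonical area ordering used throughout.
#' @export
area_names <- function() {
  c("V1", "TO", "AT", "PFL", "PML", "M1L",
    "A1", "AB", "PB", "PFi", "PMi", "M1i")
}

#' @rdname architecture
#' @return `area_roles()`: a data.frame tagging each area as
#'   primary/secondary/hub and with its system.
#' @export
area_roles <- function() {
  data.frame(
    area = area_names(),
    role = c("primary", "secondary", "hub", "hub", "secondary", "primary",
             "primary", "secondary", "hub", "hub", "secondary", "primary"),
    system = c("visual", "visual", "visual", "lateral-motor", "lateral-motor",
               "lateral-motor", "auditory", "auditory", "auditory",
               "articulatory", "articulatory", "articulatory"),
    stringsAsFactors = FALSE)
}

hub_areas <- function() c("AT", "PFL", "PB", "PFi")
primary_areas <- function() c("V1", "M1L", "A1", "M1i")

#' Default between-area connectivity graph
#'
#' Returns the default macro-graph: within-stream adjacent links, a
#' complete graph over the four hubs, and within-stream jumping links
#' (primary to hub). Links are undirected pairs; reciprocal projections
#' are sampled for both directions.
#'
#' @return An object of class `connectivity_graph`: a data.frame with
#'   columns `from`, `to` and `class` (`adjacent`, `hub-hub`, `jumping`).
#' @export
default_connectivity_graph <- function() {
  adj <- rbind(c("V1", "TO"), c("TO", "AT"), c("PFL", "PML"),
               c("PML", "M1L"), c("A1", "AB"), c("AB", "PB"),
               c("PFi", "PMi"), c("PMi", "M1i"))
  hubs <- t(utils::combn(hub_areas(), 2))
  jump <- rbind(c("V1", "AT"), c("M1L", "PFL"), c("A1", "PB"),
                c("M1i", "PFi"))
  g <- data.frame(from = c(adj[, 1], hubs[, 1], jump[, 1]),
                  to = c(adj[, 2], hubs[, 2], jump[, 2]),
                  class = rep(c("adjacent", "hub-hub", "jumping"),
                              c(nrow(adj), nrow(hubs), nrow(jump))),
                  stringsAsFactors = FALSE)
  validate_graph(g, area_names())
  structure(g, class = c("connectivity_graph", "data.frame"))
}

validate_graph <- function(g, areas) {
  stopifnot(is.data.frame(g), all(c("from", "to") %in% names(g)))
  if (!all(c(g$from, g$to) %in% areas))
    stop("graph references unknown areas: ",
         paste(setdiff(c(g$from, g$to), areas), collapse = ", "), call. = FALSE)
  if (any(g$from == g$to)) stop("graph must not contain self-loops", call. = FALSE)
  key <- apply(cbind(pmin(g$from, g$to), pmax(g$from, g$to)), 1, paste, collapse = "|")
  if (anyDuplicated(key)) stop("duplicate area pair in graph", call. = FALSE)
  invisible(g)
}

# expand undirected pairs into a fixed-order directed edge list
directed_edges <- function(graph) {
  data.frame(from = c(rbind(graph$from, graph$to)),
             to = c(rbind(graph$to, graph$from)),
             stringsAsFactors = FALSE)
}

#' Gaussian link-probability kernel
#'
#' Probability that a synapse is created between two topographically
#' aligned cells at grid offset `offset`, under one of the three kernels:
#' `p = center_prob * exp(-(dx^2 + dy^2) / (2 sigma^2))` inside the
#' (square) neighborhood and 0 outside it.
#'
#' @param offset integer pair `c(dx, dy)`.
#' @param kind one of `"ee_within"`, `"ee_between"`, `"ie"`.
#' @param params a [whorf_params()] object.
#' @return The link probability.
#' @export
kernel_probability <- function(offset, kind = c("ee_within", "ee_between", "ie"),
                               params = whorf_params()) {
  kind <- match.arg(kind)
  k <- params[[paste0("kernel_", kind)]]
  h <- (k$neighborhood - 1) / 2
  dx <- offset[1]; dy <- offset[2]
  if (abs(dx) > h || abs(dy) > h) return(0)
  k$center_prob * exp(-(dx^2 + dy^2) / (2 * k$sigma^2))
}

#' Instantiate a network
#'
#' Samples the sparse topographic synapses of one network instantiation:
#' within-area excitatory links (19 x 19 neighborhood, Gaussian with
#' center probability 0.28, sigma 6.5), between-area excitatory links for
#' every pair in the macro-graph (0.15, sigma 4.5), and the local
#' excitatory/inhibitory loop per cell (5 x 5 neighborhood, 0.295, sigma
#' 2.0; the inhibitory-to-excitatory weights enter the net input with a
#' negative sign). Excitatory weights are drawn uniformly from
#' `[0, w_init_max]`; only excitatory-to-excitatory links are plastic.
#'
#' @param params a [whorf_params()] object.
#' @param seed mandatory integer seed; two builds with the same seed are
#'   identical.
#' @param graph a `connectivity_graph` (default [default_connectivity_graph()]).
#' @param areas character vector of area names (default the 12-area model).
#' @param grid_side side of the square e-cell grid per area (default 25).
#' @return An object of class `whorf_network`: weights as a
#'   `Matrix::dgCMatrix` over all cells (e-cells first, then i-cells,
#'   area-major) plus layout metadata.
#' @export
build_network <- function(params = whorf_params(), seed,
                          graph = default_connectivity_graph(),
                          areas = area_names(), grid_side = 25L) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducibility", call. = FALSE)
  grid_side <- as.integer(grid_side)
  validate_graph(graph, areas)
  nb_max <- max(params$kernel_ee_within$neighborhood,
                params$kernel_ee_between$neighborhood,
                params$kernel_ie$neighborhood)
  if (params$torus && grid_side < nb_max)
    stop("toroidal grids need grid_side >= the largest kernel neighborhood (",
         nb_max, ")", call. = FALSE)
  n_areas <- length(areas)
  n_per <- grid_side^2
  n_e <- n_areas * n_per
  n_c <- 2L * n_e
  ed <- directed_edges(graph)
  ef <- match(ed$from, areas) - 1L
  et <- match(ed$to, areas) - 1L
  trip <- with_seed(seed, cpp_sample_network(
    n_areas, grid_side, ef, et,
    list(ee_within = params$kernel_ee_within,
         ee_between = params$kernel_ee_between,
         ie = params$kernel_ie),
    params$w_init_max, params$w_inhib_max, params$torus))
  W <- Matrix::sparseMatrix(i = trip$i + 1L, j = trip$j + 1L, x = trip$x,
                            dims = c(n_c, n_c))
  structure(list(W = W, areas = areas, grid_side = grid_side,
                 n_e = n_e, n_areas = n_areas, graph = graph,
                 seed = seed, params = params),
            class = "whorf_network")
}

#' @export
print.whorf_network <- function(x, ...) {
  nnz <- length(x$W@x)
  cat(sprintf("<whorf_network> %d areas x (%d e + %d i cells) = %d cells, %d synapses (seed %d)\n",
              x$n_areas, x$grid_side^2, x$grid_side^2,
              2L * x$n_e, nnz, x$seed))
  invisible(x)
}

# 0-based area id per cell (e-cells then i-cells, area-major)
cell_area_ids <- function(network) {
  a <- rep(seq_len(network$n_areas) - 1L, each = network$grid_side^2)
  c(a, a)
}

# global e-cell indices (1-based) of a pattern's cells in its area
pattern_cells_global <- function(network, pattern) {
  a <- match(pattern$area, network$areas)
  if (is.na(a)) stop("pattern targets unknown area ", pattern$area, call. = FALSE)
  (a - 1L) * network$grid_side^2 + pattern$cells
}

#' Synapse count summaries per projection class
#'
#' @param network a `whorf_network`.
#' @return A data.frame with link counts for within-area e-e, between-area
#'   e-e, e-i and i-e projections.
#' @export
synapse_summary <- function(network) {
  W <- network$W
  n_e <- network$n_e
  area <- cell_area_ids(network)
  ij <- Matrix::which(W != 0, arr.ind = TRUE)
  post <- ij[, 1]; pre <- ij[, 2]
  cls <- ifelse(pre <= n_e & post <= n_e,
                ifelse(area[pre] == area[post], "ee_within", "ee_between"),
                ifelse(pre <= n_e, "ei", "ie"))
  as.data.frame(table(class = cls), stringsAsFactors = FALSE)
}
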