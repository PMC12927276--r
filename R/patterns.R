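#' Synthetic sensorimotor stimulation patterns
#'
#' The model is trained on binary activation patterns over the 625 e-cells
#' of a primary area: four color patterns presented to V1 and three
#' word-form pattern pairs presented to A1 (auditory) and M1i
#' (articulatory). Each pattern activates 22 cells (3.5% of an area). The
#' color patterns carry a prescribed similarity structure: the two shades
#' of one color share `round(0.228 * 22) = 5` cells, while any blue/green
#' pair shares `round(0.05 * 22) = 1` cell; word patterns are pairwise
#' disjoint within their area.
#'
#' @name patterns
NULL

color_tags <- function() c("blue_light", "blue_dark", "green_light", "green_dark")

new_input_pattern <- function(area, cells, tag, n_cells = 625L) {
  cells <- sort(as.integer(cells))
  stopifnot(all(cells >= 1), all(cells <= n_cells), !anyDuplicated(cells))
  structure(list(area = area, cells = cells, tag = tag, n_cells = n_cells),
            class = "input_pattern")
}

#' @export
print.input_pattern <- function(x, ...) {
  cat(sprintf("<input_pattern> %s -> %s (%d cells of %d)\n",
              x$tag, x$area, length(x$cells), x$n_cells))
  invisible(x)
}

#' Generate the four color patterns
#'
#' Constructs 22-cell patterns over V1 for light/dark blue and light/dark
#' green. The two shades of a color share `within_shared` cells; each
#' blue/green shade pair shares `between_shared` cells drawn from cells
#' outside the within-color overlaps, so the four-set Venn structure stays
#' simple.
#'
#' @param seed integer seed; the same seed yields identical patterns, so
#'   all simulated learners can be given the same input world.
#' @param n_active active cells per pattern (default 22).
#' @param n_cells cells in the target area (default 625).
#' @param within_shared cells shared between the two shades of one color
#'   (default `round(0.228 * n_active)`).
#' @param between_shared cells shared between each blue/green shade pair
#'   (default `round(0.05 * n_active)`).
#' @return A named list of four `input_pattern` objects.
#' @export
generate_color_patterns <- function(seed, n_active = 22L, n_cells = 625L,
                                    within_shared = round(0.228 * n_active),
                                    between_shared = round(0.05 * n_active)) {
  n_active <- as.integer(n_active)
  within_shared <- as.integer(within_shared)
  between_shared <- as.integer(between_shared)
  n_unique <- n_active - within_shared - 2L * between_shared
  if (n_unique < 0)
    stop("infeasible overlap request: within_shared + 2*between_shared > n_active",
         call. = FALSE)
  need <- 2L * within_shared + 4L * between_shared + 4L * n_unique
  if (need > n_cells)
    stop("infeasible overlap request: construction needs ", need,
         " distinct cells but the area has ", n_cells, call. = FALSE)
  with_seed(seed, {
    pool <- sample.int(n_cells, need)
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    blue_core <- take(within_shared)   # shared by the two blues
    green_core <- take(within_shared)  # shared by the two greens
    # one bridge cell per blue/green shade pair (between_shared of them)
    bridge <- list(ll = take(between_shared), ld = take(between_shared),
                   dl = take(between_shared), dd = take(between_shared))
    u <- replicate(4, take(n_unique), simplify = FALSE)
    sets <- list(
      blue_light = c(blue_core, bridge$ll, bridge$ld, u[[1]]),
      blue_dark = c(blue_core, bridge$dl, bridge$dd, u[[2]]),
      green_light = c(green_core, bridge$ll, bridge$dl, u[[3]]),
      green_dark = c(green_core, bridge$ld, bridge$dd, u[[4]]))
    lapply(stats::setNames(nm = names(sets)), function(tag)
      new_input_pattern("V1", sets[[tag]], tag, n_cells))
  })
}

#' Generate the three word-form pattern pairs
#'
#' Each word form is a pair of 22-cell patterns, one over the auditory
#' primary area (A1) and one over the articulatory primary area (M1i).
#' Within an area the three patterns are pairwise disjoint, the strongest
#' reading of word forms without structural similarity.
#'
#' @inheritParams generate_color_patterns
#' @return A list of three elements, each a list with `auditory` and
#'   `articulatory` `input_pattern` objects.
#' @export
generate_word_patterns <- function(seed, n_active = 22L, n_cells = 625L) {
  n_active <- as.integer(n_active)
  if (3L * n_active > n_cells)
    stop("cannot place 3 disjoint patterns of ", n_active, " cells in ",
         n_cells, call. = FALSE)
  with_seed(seed, {
    aud <- matrix(sample.int(n_cells, 3L * n_active), nrow = 3L)
    art <- matrix(sample.int(n_cells, 3L * n_active), nrow = 3L)
    lapply(1:3, function(w) list(
      auditory = new_input_pattern("A1", aud[w, ], paste0("word", w, "_aud"), n_cells),
      articulatory = new_input_pattern("M1i", art[w, ], paste0("word", w, "_art"), n_cells)))
  })
}

#' Build the full pattern set
#'
#' @param seed integer seed shared by color and word construction.
#' @inheritParams generate_color_patterns
#' @return An object of class `pattern_set` with elements `colors` (four
#'   `input_pattern`s), `words` (three auditory/articulatory pairs) and
#'   `seed`.
#' @export
pattern_set <- function(seed, n_active = 22L, n_cells = 625L) {
  structure(list(colors = generate_color_patterns(seed, n_active, n_cells),
                 words = generate_word_patterns(seed + 1L, n_active, n_cells),
                 seed = seed, n_active = as.integer(n_active),
                 n_cells = as.integer(n_cells)),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> seed %d: 4 color patterns (V1), 3 word pairs (A1/M1i), %d cells each\n",
              x$seed, x$n_active))
  ov <- overlap_matrix(x)
  cat("  color overlap matrix (cells):\n")
  print(ov)
  invisible(x)
}

#' Overlap matrix of the four color patterns
#'
#' @param x a `pattern_set` or list of `input_pattern`s.
#' @return A symmetric integer matrix of pairwise shared-cell counts with
#'   the pattern sizes on the diagonal.
#' @export
overlap_matrix <- function(x) {
  pats <- if (inherits(x, "pattern_set")) x$colors else x
  n <- length(pats)
  m <- matrix(0L, n, n, dimnames = list(names(pats), names(pats)))
  for (a in seq_len(n)) for (b in seq_len(n))
    m[a, b] <- length(intersect(pats[[a]]$cells, pats[[b]]$cells))
  m
}

#' Fresh uncorrelated drive for a non-relevant primary area
#'
#' During learning, primary areas that are not carrying the trial's
#' stimulus receive a variable noise input that changes at each learning
#' event. The default form is a freshly drawn random `n_active`-cell
#' binary pattern at full input strength — structurally matched to the
#' learned stimuli, so the drive exerts the intended decorrelating
#' pressure without depolarizing most of the area at once. The `"spread"`
#' alternative distributes the same total budget
#' (`n_active * inp_strength`) uniformly at random over all cells.
#' Draws consume the current RNG stream, so trials within a seeded run
#' are reproducible.
#'
#' @param area name of the primary area receiving the drive.
#' @param params a [whorf_params()] object.
#' @param n_cells cells in the area.
#' @param n_active nominal pattern size fixing the total budget.
#' @param form `"pattern"` (default) or `"spread"`.
#' @return A numeric drive vector of length `n_cells` whose entries sum to
#'   `n_active * inp_strength`.
#' @export
fresh_noise_pattern <- function(area, params, n_cells = 625L,
                                n_active = 22L, form = c("pattern", "spread")) {
  form <- match.arg(form)
  total <- n_active * params$inp_strength
  if (form == "spread") {
    u <- stats::runif(n_cells)
    drive <- u * (total / sum(u))
  } else {
    drive <- numeric(n_cells)
    drive[sample.int(n_cells, n_active)] <- params$inp_strength
  }
  attr(drive, "area") <- area
  drive
}

#' Write or read a pattern set as JSON
#'
#' Serializes the exact stimuli of a run (areas, cell indices, tags, seed)
#' so they can be re-loaded bit-exactly.
#'
#' @param x a `pattern_set`.
#' @param path output / input file.
#' @return `write_pattern_set` returns `path` invisibly;
#'   `read_pattern_set` returns a `pattern_set`.
#' @export
write_pattern_set <- function(x, path) {
  stopifnot(inherits(x, "pattern_set"))
  flat <- list(seed = x$seed, n_active = x$n_active, n_cells = x$n_cells,
               colors = lapply(x$colors, function(p)
                 list(area = p$area, tag = p$tag, cells = p$cells)),
               words = lapply(x$words, function(w) lapply(w, function(p)
                 list(area = p$area, tag = p$tag, cells = p$cells))))
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pattern_set
#' @export
read_pattern_set <- function(path) {
  flat <- jsonlite::read_json(path)
  n_cells <- as.integer(flat$n_cells)
  unpack <- function(p)
    new_input_pattern(p$area, unlist(p$cells), p$tag, n_cells)
  colors <- lapply(stats::setNames(nm = names(flat$colors)), function(nm)
    unpack(flat$colors[[nm]]))
  words <- lapply(flat$words, function(w) lapply(w, unpack))
  structure(list(colors = colors, words = words,
                 seed = as.integer(flat$seed),
                 n_active = as.integer(flat$n_active), n_cells = n_cells),
            class = "pattern_set")
}
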