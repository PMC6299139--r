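#' Bond state between two adjacent tiles
#'
#' Tracks the progress of an invader through one migration segment of a bond:
#' `branch_position = 0` means the original (cover) tile is fully bound on
#' this segment, `branch_position = n_segments` means the invader has fully
#' migrated through it. Corner crossings are single-step segments.
#'
#' @param toehold_bound Is the toehold of this bond currently hybridized?
#' @param branch_position Integer in `0..n_segments`.
#' @param segment_class `"edge"` or `"corner"`.
#' @param n_segments Number of migration steps in this segment (corners: 1).
#' @return An object of class `bond_state`.
#' @export
bond_state <- function(toehold_bound = FALSE, branch_position = 0L,
                       segment_class = c("edge", "corner"), n_segments = 1L) {
  segment_class <- match.arg(segment_class)
  if (segment_class == "corner" && n_segments != 1L)
    stop("corner segments have exactly 1 migration step")
  branch_position <- as.integer(branch_position)
  if (branch_position < 0L || branch_position > n_segments)
    stop("branch_position must lie in [0, ", n_segments, "]")
  structure(list(toehold_bound = isTRUE(toehold_bound),
                 branch_position = branch_position,
                 segment_class = segment_class,
                 n_segments = as.integer(n_segments)),
            class = "bond_state")
}

# direction helpers: grid is (row, col), row-major, 0-based; N decreases row.
.dir_offset <- function(edge) {
  switch(edge, N = c(-1L, 0L), E = c(0L, 1L), S = c(1L, 0L), W = c(0L, -1L),
         stop("edge must be one of N, E, S, W"))
}
.opposite_edge <- function(edge) {
  c(N = "S", E = "W", S = "N", W = "E")[[edge]]
}
.coord_key <- function(rc) paste0(rc[1L], ",", rc[2L])

#' Multi-tile complex
#'
#' A complex of origami tiles on an integer grid with bonds between
#' grid-adjacent tiles. Each bond records which domain labels it currently
#' engages (a bound neighbor may hybridize a branch domain without engaging
#' a toehold at the same junction -- that is how toehold sequestering is
#' represented structurally).
#'
#' @param tiles List of placements `list(row =, col =, tile = tile_type)`.
#' @param bonds List of `list(from = c(row, col), to = c(row, col),
#'   engages = c(labels), state = bond_state())`.
#' @return An object of class `complex_species` with a `canonical_key` field.
#' @export
complex_species <- function(tiles, bonds = list()) {
  if (length(tiles) == 0L) stop("a complex must contain at least one tile")
  occ <- new.env(parent = emptyenv())
  for (p in tiles) {
    if (!inherits(p$tile, "tile_type")) stop("each placement needs a tile_type")
    k <- .coord_key(c(p$row, p$col))
    if (!is.null(occ[[k]])) stop("two tiles placed at grid position ", k)
    occ[[k]] <- p$tile$name
  }
  for (b in bonds) {
    d <- abs(b$from - b$to)
    if (!(sum(d) == 1L && all(d %in% 0:1)))
      stop("bond between non-adjacent grid positions ",
           .coord_key(b$from), " and ", .coord_key(b$to))
    if (is.null(occ[[.coord_key(b$from)]]) || is.null(occ[[.coord_key(b$to)]]))
      stop("bond references an empty grid position")
    if (is.null(b$state)) b$state <- bond_state(toehold_bound = FALSE)
  }
  x <- structure(list(tiles = tiles, bonds = bonds, canonical_key = NA_character_),
                 class = "complex_species")
  x$canonical_key <- canonical_key(x)
  x
}

#' Canonical identity key of a complex
#'
#' Two complexes that are equal as labeled grids (same tile names at the same
#' relative positions with the same bonds) receive byte-identical keys,
#' independently of construction order or absolute grid offset. Substituting
#' any single tile changes the key.
#'
#' @param x A [complex_species()].
#' @return A string key.
#' @export
canonical_key <- function(x) {
  stopifnot(inherits(x, "complex_species"))
  rows <- vapply(x$tiles, function(p) p$row, numeric(1))
  cols <- vapply(x$tiles, function(p) p$col, numeric(1))
  r0 <- min(rows); c0 <- min(cols)
  placed <- vapply(seq_along(x$tiles), function(i) {
    sprintf("%d,%d=%s", rows[i] - r0, cols[i] - c0, x$tiles[[i]]$tile$name)
  }, character(1))
  bstr <- vapply(x$bonds, function(b) {
    a <- c(b$from[1L] - r0, b$from[2L] - c0)
    z <- c(b$to[1L] - r0, b$to[2L] - c0)
    ends <- sort(c(.coord_key(a), .coord_key(z)))
    sprintf("%s~%s:%s", ends[1L], ends[2L],
            paste(sort(b$engages), collapse = "+"))
  }, character(1))
  paste0("[", paste(sort(placed), collapse = ";"), "|",
         paste(sort(bstr), collapse = ";"), "]")
}

#' Is a receiving toehold accessible?
#'
#' A toehold initiates invader binding only when its staples are not
#' currently hybridized to a bound neighbor tile. A toehold on a free outer
#' edge is accessible; a toehold whose label is engaged by the bond to an
#' adjacent tile is sequestered until that tile is displaced. A neighbor
#' bound only through other domain labels (e.g. a branch domain at the same
#' junction) does not sequester the toehold.
#'
#' @param complex A [complex_species()].
#' @param at Grid coordinate `c(row, col)` of the tile carrying the toehold.
#' @param edge Which edge of that tile (`"N"`, `"E"`, `"S"`, `"W"`).
#' @return TRUE when the toehold can bind an invader.
#' @export
toehold_accessible <- function(complex, at, edge) {
  stopifnot(inherits(complex, "complex_species"))
  keys <- vapply(complex$tiles, function(p) .coord_key(c(p$row, p$col)), character(1))
  i <- match(.coord_key(at), keys)
  if (is.na(i)) stop("no tile at grid position ", .coord_key(at))
  tile <- complex$tiles[[i]]$tile
  segs <- tile$edges[[edge]]
  th <- Filter(function(s) inherits(s, "toehold_spec"), segs)
  if (length(th) == 0L)
    stop("tile ", tile$name, " has no toehold on edge ", edge)
  labels <- vapply(th, function(s) s$label, character(1))
  nb <- at + .dir_offset(edge)
  for (b in complex$bonds) {
    pair <- c(.coord_key(b$from), .coord_key(b$to))
    if (setequal(pair, c(.coord_key(at), .coord_key(nb)))) {
      if (any(labels %in% b$engages)) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.complex_species <- function(x, ...) {
  cat(sprintf("<complex: %d tiles, %d bonds>\n  key: %s\n",
              length(x$tiles), length(x$bonds), x$canonical_key))
  invisible(x)
}
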