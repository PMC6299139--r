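#' Toehold domain specification
#'
#' A toehold on a tile edge is a small set of edge staples whose short
#' single-stranded sticky ends initiate binding of an invader tile. Its
#' strength is set by the total number of paired nucleotides,
#' `n_staples * sticky_nt`. "Giving" toeholds carry nucleotide extensions
#' (invader side); "receiving" toeholds carry the matching truncations.
#' A giving toehold reacts only with a receiving toehold of the same label.
#'
#' @param n_staples Integer number of edge staples in the toehold (0--4).
#' @param sticky_nt Integer nucleotides per sticky end (0--5).
#' @param polarity `"giving"` or `"receiving"`.
#' @param label Complementarity label; matching is by label, never by sequence.
#' @return An object of class `toehold_spec`.
#' @examples
#' th <- toehold_spec(4, 2)
#' toehold_total_nt(th)  # 8
#' @export
toehold_spec <- function(n_staples, sticky_nt, polarity = c("giving", "receiving"),
                         label = "t") {
  polarity <- match.arg(polarity)
  n_staples <- as.integer(n_staples)
  sticky_nt <- as.integer(sticky_nt)
  if (is.na(n_staples) || n_staples < 0L || n_staples > 4L)
    stop("n_staples must be an integer in 0..4, got ", n_staples)
  if (is.na(sticky_nt) || sticky_nt < 0L || sticky_nt > 5L)
    stop("sticky_nt must be an integer in 0..5, got ", sticky_nt)
  structure(list(n_staples = n_staples, sticky_nt = sticky_nt,
                 polarity = polarity, label = label),
            class = "toehold_spec")
}

#' Total toehold strength in nucleotides
#'
#' The dissociation kinetics of a tile toehold depend on the total number of
#' paired nucleotides, the product of staple count and sticky-end length, so
#' that e.g. a 5-nt 2-staple toehold (10 nt) is comparable in strength to a
#' 2-nt 4-staple toehold (8 nt).
#'
#' @param spec A [toehold_spec()].
#' @return Integer total nucleotides.
#' @export
toehold_total_nt <- function(spec) {
  stopifnot(inherits(spec, "toehold_spec"))
  spec$n_staples * spec$sticky_nt
}

#' Branch migration domain specification
#'
#' The branch migration domain is the run of edge staples over which an
#' invader progressively competes with a bound cover tile for a base tile's
#' edge. The continuous design uses 7 staples, all present; coded domains
#' (used in 3x3 arrays) use a subset of 9 staple positions (6 present) to
#' gain domain-level specificity, at the cost of slower migration.
#'
#' @param n_staples Number of staple positions in the domain.
#' @param code Presence mask (logical or 0/1) over staple positions; default
#'   all present. A valid code never leaves more than 2 consecutive positions
#'   absent (see [validate_edge_code()]).
#' @param label Complementarity label.
#' @return An object of class `branch_domain_spec`; its `coded` field is TRUE
#'   when any position is absent.
#' @export
branch_domain_spec <- function(n_staples = 7L, code = rep(1L, n_staples),
                               label = "b") {
  n_staples <- as.integer(n_staples)
  code <- as.integer(as.logical(code))
  if (length(code) != n_staples)
    stop("code mask length (", length(code), ") != n_staples (", n_staples, ")")
  chk <- validate_edge_code(code)
  if (!chk$valid)
    stop("invalid edge code: run of ", chk$run_length,
         " absent staples starting at position ", chk$run_start)
  structure(list(n_staples = n_staples, code = code,
                 coded = any(code == 0L), label = label),
            class = "branch_domain_spec")
}

#' Validate an edge staple code
#'
#' Edge domains may be encoded by leaving out a subset of staple positions,
#' but to preserve domain continuity no more than 2 staples may be absent in
#' a row.
#'
#' @param code Presence mask (logical or 0/1), length >= 1.
#' @return A list with `valid` (logical) and, when invalid, `run_start`
#'   (1-based position of the first violating run) and `run_length`.
#' @examples
#' validate_edge_code(c(1, 1, 0, 1, 1, 0, 1, 1, 1))$valid  # TRUE
#' validate_edge_code(c(1, 0, 0, 0, 1, 1, 1, 1, 1))$valid  # FALSE
#' @export
validate_edge_code <- function(code) {
  if (length(code) < 1L) stop("edge code mask must have length >= 1")
  code <- as.integer(as.logical(code))
  if (anyNA(code)) stop("edge code mask contains NA")
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- which(r$values == 0L & r$lengths > 2L)
  if (length(bad) == 0L)
    list(valid = TRUE, run_start = NA_integer_, run_length = NA_integer_)
  else
    list(valid = FALSE, run_start = starts[bad[1L]],
         run_length = r$lengths[bad[1L]])
}

#' Tile type
#'
#' A square DNA origami tile with four edges (ordered N, E, S, W, clockwise),
#' each carrying zero or more domain segments (toeholds and/or branch
#' migration domains). The display label (X, O, smile, frown, line, plain)
#' is the AFM-readout pattern of double-stranded staple extensions and has
#' no kinetic effect. Fluorophore/quencher modifications are recorded as
#' (edge, position) placements.
#'
#' @param name Tile name (used in species bookkeeping).
#' @param edges Named list with entries `N`, `E`, `S`, `W`, each a list of
#'   [toehold_spec()] / [branch_domain_spec()] segments (possibly empty).
#' @param display_label Decorative pattern name; metadata only.
#' @param fluor_mods Optional list of `list(kind = "F"|"Q", edge, position)`.
#' @return An object of class `tile_type`.
#' @export
tile_type <- function(name, edges = NULL, display_label = "plain",
                      fluor_mods = NULL) {
  if (is.null(edges)) edges <- list(N = list(), E = list(), S = list(), W = list())
  if (!identical(sort(names(edges)), sort(c("N", "E", "S", "W"))))
    stop("edges must be a named list with exactly N, E, S, W")
  edges <- edges[c("N", "E", "S", "W")]
  for (e in names(edges)) {
    for (seg in edges[[e]]) {
      if (!inherits(seg, "toehold_spec") && !inherits(seg, "branch_domain_spec"))
        stop("edge ", e, " of tile ", name,
             " contains a segment that is neither a toehold nor a branch domain")
    }
  }
  if (!is.null(fluor_mods)) {
    for (m in fluor_mods) {
      if (!m$kind %in% c("F", "Q")) stop("fluor_mods kind must be 'F' or 'Q'")
      if (!m$edge %in% c("N", "E", "S", "W")) stop("fluor_mods edge must be N/E/S/W")
      nseg <- length(edges[[m$edge]])
      if (m$position < 1L || (nseg > 0L && m$position > nseg))
        stop("fluor_mods position ", m$position, " does not reference an existing ",
             "segment on edge ", m$edge, " of tile ", name)
    }
  }
  structure(list(name = name, edges = edges, display_label = display_label,
                 fluor_mods = fluor_mods),
            class = "tile_type")
}

#' @export
print.toehold_spec <- function(x, ...) {
  cat(sprintf("<toehold %s: %d staples x %d nt = %d nt, label '%s'>\n",
              x$polarity, x$n_staples, x$sticky_nt, x$n_staples * x$sticky_nt,
              x$label))
  invisible(x)
}

#' @export
print.branch_domain_spec <- function(x, ...) {
  cat(sprintf("<branch domain: %d staples [%s]%s, label '%s'>\n",
              x$n_staples, paste(x$code, collapse = ""),
              if (x$coded) " (coded)" else "", x$label))
  invisible(x)
}
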