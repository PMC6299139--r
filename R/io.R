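# Structured-text (JSON) serialization of system specifications. Objects of
# the package's S3 classes are tagged with ".class" and named/long atomic
# vectors with ".vec" so that load -> save -> load is the identity.

.io_classes <- c("system_spec", "displacement_pathway", "toehold_spec",
                 "branch_domain_spec", "tile_type", "complex_species",
                 "bond_state")

.tile_encode <- function(x) {
  if (inherits(x, .io_classes)) {
    out <- lapply(unclass(x), .tile_encode)
    c(list(.class = class(x)[1L]), out)
  } else if (is.data.frame(x)) {
    list(.class = "data.frame",
         columns = lapply(as.list(x), .tile_encode))
  } else if (is.atomic(x) && !is.null(x) &&
             (length(x) != 1L || !is.null(names(x)))) {
    list(.vec = class(x)[1L],
         names = if (is.null(names(x))) NULL else as.list(names(x)),
         values = as.list(unname(x)))
  } else if (is.list(x)) {
    lapply(x, .tile_encode)
  } else x
}

.tile_decode <- function(x) {
  if (is.list(x) && !is.null(x$.class)) {
    cls <- x$.class
    if (cls == "data.frame") {
      cols <- lapply(x$columns, .tile_decode)
      return(as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE))
    }
    body <- lapply(x[setdiff(names(x), ".class")], .tile_decode)
    return(structure(body, class = cls))
  }
  if (is.list(x) && !is.null(x$.vec)) {
    v <- unlist(x$values)
    if (length(x$values) == 0L)
      v <- vector(mode = if (x$.vec == "numeric") "numeric" else x$.vec, 0L)
    v <- switch(x$.vec, integer = as.integer(v), numeric = as.numeric(v),
                character = as.character(v), logical = as.logical(v), v)
    if (!is.null(x$names)) names(v) <- unlist(x$names)
    return(v)
  }
  if (is.list(x)) return(lapply(x, .tile_decode))
  x
}

#' Read/write a system specification as JSON
#'
#' The full specification (species with compositions and structural grids,
#' pathways, leaks, extra reactions, observables, dosing) is serialized as
#' JSON-compatible structured text; `read_system_spec(write_system_spec(x))`
#' is the identity.
#'
#' @param system A [system_spec()].
#' @param path File path.
#' @return `read_system_spec` returns a [system_spec()];
#'   `write_system_spec` returns `path` invisibly.
#' @export
write_system_spec <- function(system, path) {
  stopifnot(inherits(system, "system_spec"))
  jsonlite::write_json(.tile_encode(system), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_system_spec
#' @export
read_system_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- .tile_decode(x)
  if (!inherits(out, "system_spec")) stop("file does not contain a system_spec")
  # revalidate through the constructor (also restores canonical keys)
  system_spec(out$species, out$pathways, out$leaks, out$extra_reactions,
              out$observables, out$dosing, preset = out$preset)
}
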