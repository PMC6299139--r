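#' Kinetic rate parameters of the three-step tile displacement model
#'
#' Tile displacement is modeled in three steps: reversible bimolecular
#' toehold binding, exponential-in-nucleotides toehold dissociation, and
#' unimolecular branch migration through a chain of edge and corner
#' segments. The fields are:
#'
#' * `k_bind_per_M_s`: named vector of bimolecular binding rates by
#'   sticky-end length (names `"1"`, `"2"`, `"5"` nucleotides). Tile binding
#'   is 10--100x slower than strand-displacement hybridization depending on
#'   the sticky-end length, so this is a lookup rather than a formula.
#' * `k_diss0_per_s`: toehold dissociation rate extrapolated to zero
#'   toehold nucleotides (stacking-bond contributions are absorbed here).
#' * `b_per_nt`: per-nucleotide dissociation decay factor (> 1);
#'   `k_diss(n) = k_diss0 * b^-n`.
#' * `k_disp_per_s`: branch migration rate through one uncoded edge segment.
#' * `corner_factor`: slowdown of a migration step across a 90-degree tile
#'   corner (default 100).
#' * `code_factor`: slowdown of migration through a coded branch domain
#'   (default 25). When a corner step lies in a coded domain both factors
#'   apply multiplicatively.
#' * `k_leak_per_M_s`: effective bimolecular rate of zero-toehold (spurious)
#'   invasion.
#' * `k_dimer_per_M_s`: rate of spurious invader--invader dimerization.
#'
#' @param k_bind_per_M_s Named numeric vector, M^-1 s^-1.
#' @param k_diss0_per_s Numeric, s^-1.
#' @param b_per_nt Numeric > 1, dimensionless.
#' @param k_disp_per_s Numeric, s^-1.
#' @param corner_factor,code_factor Numeric >= 1, dimensionless.
#' @param k_leak_per_M_s,k_dimer_per_M_s Numeric, M^-1 s^-1.
#' @return An object of class `rate_params`.
#' @seealso [default_rate_params()] for the calibrated default set.
#' @export
rate_params <- function(k_bind_per_M_s = c(`1` = 4.5e4, `2` = 4.5e5, `5` = 4.5e5),
                        k_diss0_per_s = 0.02 * 24^4,
                        b_per_nt = 24,
                        k_disp_per_s = 0.025,
                        corner_factor = 100,
                        code_factor = 25,
                        k_leak_per_M_s = 55,
                        k_dimer_per_M_s = 1e6) {
  if (is.null(names(k_bind_per_M_s)) || any(!nzchar(names(k_bind_per_M_s))))
    stop("k_bind_per_M_s must be named by sticky-end length in nt")
  stopifnot(all(k_bind_per_M_s >= 0), k_diss0_per_s >= 0, k_disp_per_s >= 0,
            k_leak_per_M_s >= 0, k_dimer_per_M_s >= 0)
  if (!(b_per_nt > 1)) stop("b_per_nt must be > 1")
  if (corner_factor < 1) stop("corner_factor must be >= 1")
  if (code_factor < 1) stop("code_factor must be >= 1")
  structure(list(k_bind_per_M_s = k_bind_per_M_s,
                 k_diss0_per_s = k_diss0_per_s,
                 b_per_nt = b_per_nt,
                 k_disp_per_s = k_disp_per_s,
                 corner_factor = corner_factor,
                 code_factor = code_factor,
                 k_leak_per_M_s = k_leak_per_M_s,
                 k_dimer_per_M_s = k_dimer_per_M_s),
            class = "rate_params")
}

#' Default calibrated rate-parameter set
#'
#' The shipped `"fig1e"` set is calibrated so that the model reproduces the
#' measured behavior of tile displacement at 25 C: a maximum effective rate
#' of 4.5e5 M^-1 s^-1 for the strongest (8-nt) toehold, an 18-fold rate
#' difference between the 2-nt 4-staple and 1-nt 4-staple pathways, a
#' binding/displacement regime crossover near 50 nM, a >= 5 order-of-
#' magnitude dynamic range across nonzero toeholds, and a zero-toehold leak
#' of ~3.8% completion at 48 h for 2 nM complex with 4 nM invader. The
#' per-nucleotide dissociation factor b = 24 corresponds to about 1.9
#' kcal/mol of pairing free energy per nucleotide at 25 C.
#'
#' @param set Name of the parameter set; only `"fig1e"` ships.
#' @return A [rate_params()] object.
#' @examples
#' p <- default_rate_params()
#' k_effective(k_bind(p, 2), k_dissociation(8, p), p$k_disp_per_s)  # ~4.5e5
#' @export
default_rate_params <- function(set = "fig1e") {
  if (!identical(set, "fig1e")) stop("unknown parameter set: ", set)
  rate_params()
}

#' Binding rate for a sticky-end length
#'
#' @param params A [rate_params()].
#' @param sticky_nt Sticky-end length in nucleotides (must be a tabulated
#'   length, by default 1, 2 or 5).
#' @return Bimolecular rate in M^-1 s^-1.
#' @export
k_bind <- function(params, sticky_nt) {
  key <- as.character(as.integer(sticky_nt))
  if (!key %in% names(params$k_bind_per_M_s))
    stop("no binding rate tabulated for sticky-end length ", sticky_nt,
         " nt (have: ", paste(names(params$k_bind_per_M_s), collapse = ", "), ")")
  unname(params$k_bind_per_M_s[[key]])
}

#' Toehold dissociation rate
#'
#' Dissociation decreases exponentially with the total number of toehold
#' nucleotides: `k_diss(n) = k_diss0 * b^-n`.
#'
#' @param n_nt Total toehold nucleotides (staples x sticky-end length), >= 0.
#' @param params A [rate_params()].
#' @return Rate in s^-1, strictly decreasing in `n_nt`.
#' @export
k_dissociation <- function(n_nt, params) {
  if (any(n_nt < 0)) stop("n_nt must be >= 0")
  params$k_diss0_per_s * params$b_per_nt^(-n_nt)
}

#' Effective bimolecular displacement rate
#'
#' Reduction of the reversible-bind-then-displace scheme in the
#' low-concentration (binding-limited) regime:
#' `k_eff = k_bind * k_disp_path / (k_diss + k_disp_path)`.
#' Bounded above by `k_bind`; approaches `k_bind * k_disp_path / k_diss`
#' in the pre-equilibrium limit of a weak toehold.
#'
#' @param k_bind Bimolecular binding rate, M^-1 s^-1.
#' @param k_diss Toehold dissociation rate, s^-1.
#' @param k_disp_path Effective first-passage rate of the full migration
#'   path, s^-1 (see [path_rate()]).
#' @return Effective bimolecular rate, M^-1 s^-1.
#' @export
k_effective <- function(k_bind, k_diss, k_disp_path) {
  stopifnot(k_bind >= 0, k_diss >= 0, k_disp_path >= 0)
  if (k_diss + k_disp_path == 0)
    stop("k_effective undefined: k_diss + k_disp_path = 0")
  k_bind * k_disp_path / (k_diss + k_disp_path)
}

#' Migration rate of a single segment
#'
#' One branch-migration step proceeds at the edge rate `k_disp`, divided by
#' `corner_factor` for a corner crossing and by `code_factor` for a coded
#' branch domain; both slowdowns apply when both conditions hold.
#'
#' @param params A [rate_params()].
#' @param class `"edge"` or `"corner"`.
#' @param coded Does the step lie in a coded branch domain?
#' @return Rate in s^-1.
#' @export
segment_rate <- function(params, class = c("edge", "corner"), coded = FALSE) {
  class <- match.arg(class)
  r <- params$k_disp_per_s
  if (class == "corner") r <- r / params$corner_factor
  if (isTRUE(coded)) r <- r / params$code_factor
  r
}

#' Effective first-passage rate of a migration path
#'
#' The inverse of the mean first-passage time of a sequential chain of
#' migration steps, each an exponential step at its [segment_rate()]:
#' `1 / sum(1 / r_i)`. A single uncoded edge segment returns `k_disp`
#' exactly; a chain of n identical steps at rate r returns `r / n`. Corner
#' crossings dominate the passage time, which is why displacement paths with
#' more corners are slower overall.
#'
#' @param segments Nonempty list of `list(class = "edge"|"corner",
#'   coded = TRUE/FALSE)`.
#' @param params A [rate_params()].
#' @return Rate in s^-1.
#' @export
path_rate <- function(segments, params) {
  if (length(segments) == 0L) stop("segment list must be nonempty")
  rates <- vapply(segments, function(s)
    segment_rate(params, s$class, isTRUE(s$coded)), numeric(1))
  1 / sum(1 / rates)
}

#' Binding/displacement regime crossover concentration
#'
#' The invader concentration at which the pseudo-first-order binding flux
#' `k_bind * c` equals the displacement path rate. Below it the reaction is
#' binding-limited (rate grows with concentration); above it the
#' unimolecular displacement limits the overall rate and added invader
#' saturates.
#'
#' @param k_bind Bimolecular binding rate, M^-1 s^-1 (> 0).
#' @param k_disp_path Migration path rate, s^-1.
#' @return Concentration in M.
#' @export
regime_crossover <- function(k_bind, k_disp_path) {
  if (k_bind <= 0) stop("k_bind must be > 0")
  if (k_disp_path < 0) stop("k_disp_path must be >= 0")
  k_disp_path / k_bind
}

#' Effective displacement rate of a toehold configuration
#'
#' Convenience composition of the three-step reduction for one displacement
#' pathway: binding at the toehold's sticky-end rate, dissociation at its
#' total-nucleotide rate, migration through `segments`.
#'
#' @param params A [rate_params()].
#' @param toehold A [toehold_spec()].
#' @param segments Migration path (default: one uncoded edge segment).
#' @return Effective bimolecular rate, M^-1 s^-1.
#' @export
toehold_k_eff <- function(params, toehold,
                          segments = list(list(class = "edge", coded = FALSE))) {
  n <- toehold_total_nt(toehold)
  k_effective(k_bind(params, toehold$sticky_nt),
              k_dissociation(n, params),
              path_rate(segments, params))
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>\n")
  cat("  k_bind (/M/s) by sticky nt:",
      paste(sprintf("%s nt: %.3g", names(x$k_bind_per_M_s), x$k_bind_per_M_s),
            collapse = ", "), "\n")
  cat(sprintf("  k_diss(n) = %.4g * %.3g^-n /s\n", x$k_diss0_per_s, x$b_per_nt))
  cat(sprintf("  k_disp = %.3g /s; corner / %g, coded / %g\n",
              x$k_disp_per_s, x$corner_factor, x$code_factor))
  cat(sprintf("  leak = %.3g /M/s; dimerization = %.3g /M/s\n",
              x$k_leak_per_M_s, x$k_dimer_per_M_s))
  invisible(x)
}

# -- flat get/set by dotted name, used by the fitter and the CLI ------------

.param_flat_names <- function(params) {
  c(paste0("k_bind_per_M_s.", names(params$k_bind_per_M_s)),
    "k_diss0_per_s", "b_per_nt", "k_disp_per_s", "corner_factor",
    "code_factor", "k_leak_per_M_s", "k_dimer_per_M_s")
}

.param_get <- function(params, name) {
  if (startsWith(name, "k_bind_per_M_s.")) {
    key <- sub("^k_bind_per_M_s\\.", "", name)
    if (!key %in% names(params$k_bind_per_M_s)) stop("unknown parameter: ", name)
    return(unname(params$k_bind_per_M_s[[key]]))
  }
  if (!name %in% names(params)) stop("unknown parameter: ", name)
  params[[name]]
}

.param_set <- function(params, name, value) {
  if (startsWith(name, "k_bind_per_M_s.")) {
    key <- sub("^k_bind_per_M_s\\.", "", name)
    if (!key %in% names(params$k_bind_per_M_s)) stop("unknown parameter: ", name)
    params$k_bind_per_M_s[[key]] <- value
  } else {
    if (!name %in% names(params)) stop("unknown parameter: ", name)
    params[[name]] <- value
  }
  params
}

#' Read/write rate parameters as JSON
#'
#' Units are explicit in the field names (`*_per_M_s`, `*_per_s`).
#'
#' @param params A [rate_params()].
#' @param path File path.
#' @return `read_rate_params` returns a [rate_params()]; `write_rate_params`
#'   returns `path` invisibly.
#' @export
write_rate_params <- function(params, path) {
  stopifnot(inherits(params, "rate_params"))
  x <- unclass(params)
  x$k_bind_per_M_s <- as.list(x$k_bind_per_M_s)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rate_params
#' @export
read_rate_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  kb <- unlist(x$k_bind_per_M_s)
  rate_params(k_bind_per_M_s = kb,
              k_diss0_per_s = x$k_diss0_per_s,
              b_per_nt = x$b_per_nt,
              k_disp_per_s = x$k_disp_per_s,
              corner_factor = x$corner_factor,
              code_factor = x$code_factor,
              k_leak_per_M_s = x$k_leak_per_M_s,
              k_dimer_per_M_s = x$k_dimer_per_M_s)
}
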