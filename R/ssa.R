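# Exact stochastic simulation (Gillespie direct method) at integer copy
# numbers, the stochastic counterpart of simulate_ode for small volumes.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a reaction network stochastically (exact SSA)
#'
#' Samples one exact trajectory of the network's Markov jump process by the
#' Gillespie direct method. Concentrations are converted to integer copy
#' numbers through the reaction volume: `copies = conc_nM * 1e-9 * N_A * V`.
#' Bimolecular propensities are `k n1 n2 / Omega` (distinct reactants) or
#' `k n (n - 1) / Omega` (identical), with `Omega = 1e-9 * N_A * V`
#' copies per nM, which reproduces the deterministic flux in the
#' large-copy-number limit. Tile counts are conserved exactly in integers.
#' When the total propensity reaches zero before `t_max` the simulation
#' terminates normally with the final state held.
#'
#' @param network A [enumerate_network()] result.
#' @param params Optional [rate_params()] to re-rate the network.
#' @param volume_L Reaction volume in liters. Alternatively give
#'   `copies_at_nM = c(copies, nM)` is not supported; choose the volume as
#'   `copies_target / (conc_nM * 1e-9 * 6.02214076e23)`.
#' @param t_max End time in seconds.
#' @param seed Integer seed; a fixed seed reproduces the event list exactly.
#'   The caller's RNG state is left untouched.
#' @param t_grid Optional recording grid (default 201 points); the state is
#'   recorded by forward-filling event intervals.
#' @return A `tile_trajectory` data frame of copy numbers on `t_grid`, with
#'   `meta` including the seed, volume and number of events.
#' @export
simulate_ssa <- function(network, params = NULL, volume_L, t_max, seed,
                         t_grid = NULL) {
  stopifnot(inherits(network, "reaction_network"), volume_L > 0, t_max > 0)
  if (!is.null(params)) network <- network_rates(network, params)
  omega <- 1e-9 * 6.02214076e23 * volume_L  # copies per nM
  su <- .ode_setup(network)                 # k already nM-based
  n0 <- round(network$species$conc_nM * omega)
  if (any(network$species$conc_nM > 0 & n0 < 1))
    stop("volume too small: an occupied species has < 1 copy")
  if (is.null(t_grid)) t_grid <- seq(0, t_max, length.out = 201L)
  nrx <- length(su$k)
  # propensity constants in events/s: uni k*n; bi k/omega*n1*n2
  kc <- su$k
  bi <- su$r2 > 0L
  kc[bi] <- kc[bi] / omega
  ident <- bi & (su$r1 == su$r2)
  # per-reaction sparse state updates (indices + deltas)
  upd <- lapply(seq_len(nrx), function(j) {
    col <- su$S[, j]
    idx <- which(col != 0)
    list(idx = idx, d = col[idx])
  })
  .with_seed(seed, {
    n <- as.numeric(n0)
    t <- 0
    ngrid <- length(t_grid)
    rec <- matrix(0, nrow = ngrid, ncol = length(n))
    gi <- 1L
    nev <- 0L
    r1 <- su$r1; r2 <- su$r2
    repeat {
      a <- kc * n[r1]
      a[bi] <- a[bi] * n[r2[bi]]
      if (any(ident))
        a[ident] <- kc[ident] * n[r1[ident]] * (n[r1[ident]] - 1)
      a0 <- sum(a)
      t_next <- if (a0 <= 0) Inf else t - log(stats::runif(1L)) / a0
      while (gi <= ngrid && t_grid[gi] < t_next) {
        rec[gi, ] <- n
        gi <- gi + 1L
      }
      if (gi > ngrid || t_next > t_max) break
      t <- t_next
      j <- 1L
      u <- stats::runif(1L) * a0
      acc <- a[1L]
      while (acc < u && j < nrx) { j <- j + 1L; acc <- acc + a[j] }
      uj <- upd[[j]]
      n[uj$idx] <- n[uj$idx] + uj$d
      nev <- nev + 1L
    }
    while (gi <= ngrid) { rec[gi, ] <- n; gi <- gi + 1L }
    out <- data.frame(time_s = t_grid)
    for (i in seq_along(su$keys)) out[[su$keys[i]]] <- rec[, i]
    structure(out, class = c("tile_trajectory", "data.frame"),
              meta = list(solver = "ssa-direct", seed = seed,
                          volume_L = volume_L, omega = omega, events = nev,
                          unit = "copies", preset = network$preset),
              compositions = network$compositions,
              observables = network$observables)
  })
}

#' Reaction volume giving a target copy number
#'
#' Convenience for SSA studies: the volume at which `conc_nM` corresponds to
#' `copies` molecules.
#'
#' @param copies Target copy number.
#' @param conc_nM Concentration that should map to `copies`.
#' @return Volume in liters.
#' @export
volume_for_copies <- function(copies, conc_nM) {
  stopifnot(copies > 0, conc_nM > 0)
  copies / (conc_nM * 1e-9 * 6.02214076e23)
}
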