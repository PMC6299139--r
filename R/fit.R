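# Rate-parameter fitting, competitive completion curves and effective-rate
# ratios.

#' Fit rate parameters to completion trajectories
#'
#' Weighted least squares over one or more experimental conditions
#' simultaneously (a global fit): every condition shares one parameter set,
#' which is how a single set of rate constants is made to explain all
#' toehold variants at once. Each condition supplies a system specification
#' and an observed completion series; the residual is the pointwise
#' difference between the simulated and observed completions, weighted
#' uniformly over time points (plate-reader noise is approximately
#' homoscedastic after normalization; pass `weights` to override).
#' Positive parameters are optimized on a log10 scale with
#' [minpack.lm::nls.lm] (Levenberg--Marquardt). Networks are enumerated
#' once per condition and re-rated per iteration, so the fit is
#' deterministic given identical inputs and starting point.
#'
#' @param data List of conditions, each `list(system = system_spec,
#'   time_s = numeric, observed = numeric, observable = name or index)`
#'   (observable defaults to the first).
#' @param params Starting [rate_params()].
#' @param free Character vector of parameter names to fit, e.g.
#'   `c("k_bind_per_M_s.2", "k_disp_per_s")`; the remaining parameters stay
#'   frozen. An empty `free` returns the residual report only.
#' @param lower,upper Optional named bounds (natural scale).
#' @param weights Optional list of per-condition weight vectors.
#' @return An object of class `tile_fit`: `params` (fitted [rate_params()]),
#'   `estimates` (named vector), `rms` (residual root-mean-square),
#'   `converged`, `status` (solver message), `niter`.
#' @export
fit_rates <- function(data, params = default_rate_params(), free,
                      lower = NULL, upper = NULL, weights = NULL) {
  stopifnot(length(data) >= 1L)
  nets <- lapply(data, function(d) enumerate_network(d$system, params))
  obs_idx <- lapply(data, function(d) d$observable %||% 1L)
  get_resid <- function(p) {
    unlist(lapply(seq_along(data), function(i) {
      d <- data[[i]]
      net <- network_rates(nets[[i]], p)
      traj <- simulate_ode(net, t_grid = d$time_s)
      sim <- observe(traj, obs_idx[[i]])
      w <- if (is.null(weights)) 1 else sqrt(weights[[i]])
      (sim - d$observed) * w
    }))
  }
  if (length(free) == 0L) {
    r <- get_resid(params)
    return(structure(list(params = params, estimates = numeric(0),
                          rms = sqrt(mean(r^2)), converged = TRUE,
                          status = "no free parameters; residual report only",
                          niter = 0L), class = "tile_fit"))
  }
  start <- vapply(free, function(nm) .param_get(params, nm), numeric(1))
  if (any(start <= 0)) stop("free parameters must start positive (log scale)")
  lo <- vapply(free, function(nm)
    if (!is.null(lower) && nm %in% names(lower)) log10(lower[[nm]]) else -Inf,
    numeric(1))
  hi <- vapply(free, function(nm)
    if (!is.null(upper) && nm %in% names(upper)) log10(upper[[nm]]) else Inf,
    numeric(1))
  fn <- function(lg) {
    p <- params
    for (i in seq_along(free)) p <- .param_set(p, free[i], 10^lg[i])
    get_resid(p)
  }
  res <- minpack.lm::nls.lm(par = log10(start), lower = lo, upper = hi,
                            fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-10, ptol = 1e-10))
  est <- stats::setNames(10^res$par, free)
  p_hat <- params
  for (nm in free) p_hat <- .param_set(p_hat, nm, est[[nm]])
  converged <- res$info %in% 1:4
  structure(list(params = p_hat, estimates = est,
                 rms = sqrt(mean(res$fvec^2)), converged = converged,
                 status = res$message, niter = res$niter),
            class = "tile_fit")
}

#' @export
print.tile_fit <- function(x, ...) {
  cat(sprintf("<tile_fit> %s (rms %.4g, %d iterations)\n",
              if (x$converged) "converged" else "NOT CONVERGED",
              x$rms, x$niter))
  if (length(x$estimates))
    for (nm in names(x$estimates))
      cat(sprintf("  %-22s %.6g\n", nm, x$estimates[[nm]]))
  invisible(x)
}

#' Write a fit report as structured text
#'
#' @param fit A `tile_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(list(
    converged = fit$converged, status = fit$status, rms = fit$rms,
    niter = fit$niter, estimates = as.list(fit$estimates)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Competitive completion levels versus invader concentration
#'
#' Simulates the competitive system over a sweep of invader multiples and
#' reports both products' completion at the horizon. The fast pathway's
#' product rises roughly linearly with invader until it saturates; the slow
#' pathway's product is sigmoidal with its threshold at the fast complex's
#' concentration (the fast reaction consumes the invader first and thereby
#' thresholds the slow one).
#'
#' @param params A [rate_params()].
#' @param multiples Invader concentrations as multiples of 1x (= 2 nM).
#' @param horizon_h Readout time in hours.
#' @param fast_nM,slow_nM Complex concentrations.
#' @return Data frame `multiple`, `fast`, `slow` (completions at horizon).
#' @export
completion_curve <- function(params = default_rate_params(),
                             multiples = seq(0.2, 3, by = 0.2),
                             horizon_h = 24, fast_nM = 2, slow_nM = 2) {
  stopifnot(all(multiples >= 0), horizon_h > 0)
  rows <- lapply(multiples, function(m) {
    sys <- make_competitive(invader_multiple = m, fast_nM = fast_nM,
                            slow_nM = slow_nM)
    cc <- simulate_system(sys, params, hours = horizon_h, dt_s = 360)
    data.frame(multiple = m, fast = cc$fast[nrow(cc)],
               slow = cc$slow[nrow(cc)])
  })
  do.call(rbind, rows)
}

#' Ratio of effective displacement rates of two toehold configurations
#'
#' In the low-concentration (binding-limited) regime the ratio of
#' [k_effective()] values; at a stated invader concentration, the ratio of
#' the full three-step mean-first-passage rates
#' `a * m / (a + d + m)` with `a = k_bind * c` (which reduces to the
#' k_eff ratio as `c -> 0`). Both are exposed because "overall rate" can
#' reasonably mean either.
#'
#' @param params A [rate_params()].
#' @param toehold_a,toehold_b [toehold_spec()]s to compare (a over b).
#' @param concentration Optional invader concentration in M; `NULL` (the
#'   default) compares low-concentration effective rates.
#' @param segments Migration path (shared by both configurations).
#' @return Dimensionless rate ratio.
#' @export
effective_rate_ratio <- function(params, toehold_a, toehold_b,
                                 concentration = NULL,
                                 segments = list(list(class = "edge",
                                                      coded = FALSE))) {
  m <- path_rate(segments, params)
  one <- function(th) {
    a_bind <- k_bind(params, th$sticky_nt)
    d <- k_dissociation(toehold_total_nt(th), params)
    if (is.null(concentration)) k_effective(a_bind, d, m)
    else {
      a <- a_bind * concentration
      a * m / (a + d + m)
    }
  }
  denom <- one(toehold_b)
  if (denom == 0) stop("denominator toehold has zero effective rate")
  one(toehold_a) / denom
}

#' Threshold concentration of the competitive system
#'
#' The fast pathway consumes invader first, so the slow product only forms
#' once the invader exceeds the fast complex's capacity: the fast reaction
#' acts as a concentration threshold. This estimates that threshold from a
#' [completion_curve()] sweep as the (interpolated) invader multiple at
#' half-maximal slow-product completion, minus the slow pathway's own
#' stoichiometric half-capacity (the midpoint of a capacity-limited
#' titration sits half a capacity above its onset). Raising the fast
#' complex's concentration shifts the threshold proportionally.
#'
#' @param curve Data frame from [completion_curve()].
#' @param slow_nM Slow complex concentration used in the sweep.
#' @param one_x_nM The 1x concentration (2 nM).
#' @return Threshold in invader multiples of 1x.
#' @export
competitive_threshold <- function(curve, slow_nM = 2, one_x_nM = 2) {
  s <- curve$slow
  half <- (min(s) + max(s)) / 2
  i <- which(s >= half)[1L]
  if (is.na(i) || i == 1L) stop("sweep does not bracket the half-maximum")
  m_half <- curve$multiple[i - 1L] +
    (half - s[i - 1L]) / (s[i] - s[i - 1L]) *
      (curve$multiple[i] - curve$multiple[i - 1L])
  m_half - slow_nM / (2 * one_x_nM)
}
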