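# Synthetic plate-reader and count data with the statistical structure of
# tile-displacement experiments, so the full analysis chain (normalization,
# fitting, yield estimation) is testable without instrument data.

#' Plate-reader noise model
#'
#' Raw signal is `baseline + scale * completion + drift_per_hour * t_h` plus
#' additive Gaussian noise with standard deviation `additive_sd * scale`.
#' Additive Gaussian noise approximates plate-reader fluorescence at fixed
#' gain; shot noise is deliberately not modeled.
#'
#' @param additive_sd Noise standard deviation as a fraction of full scale.
#' @param baseline Raw units at completion 0.
#' @param scale Raw units per unit completion (> 0).
#' @param drift_per_hour Linear drift in raw units per hour.
#' @param seed Integer seed recorded into generated plates.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.01, baseline = 100, scale = 1000,
                        drift_per_hour = 0, seed = 1L) {
  stopifnot(additive_sd >= 0, scale > 0)
  structure(list(additive_sd = additive_sd, baseline = baseline,
                 scale = scale, drift_per_hour = drift_per_hour,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a synthetic fluorescence plate
#'
#' Simulates the system's completion observable, maps completion to raw
#' units through the noise model, and emits sample wells plus the two
#' control wells used for normalization: a negative control (the initial
#' structure without invader, completion 0) and a positive control (the
#' pre-annealed target structure, completion 1). Default sampling mirrors
#' the plate reader: one point every 3 min over 48 h. Reproducible by seed;
#' the caller's RNG state is untouched.
#'
#' @param system A [system_spec()].
#' @param params A [rate_params()].
#' @param noise A [noise_model()].
#' @param hours,dt_s Sampling horizon and spacing.
#' @param observable Which observable to emit (name or index).
#' @param n_replicates Number of sample wells.
#' @return A [plate_data()] whose channel records the seed
#'   (`meta`-style suffix) and with attribute `"true_completion"` holding
#'   the noise-free simulated series.
#' @export
generate_plate <- function(system, params = default_rate_params(),
                           noise = noise_model(), hours = 48, dt_s = 180,
                           observable = 1L, n_replicates = 1L) {
  cc <- simulate_system(system, params, hours = hours, dt_s = dt_s)
  obs_names <- setdiff(names(cc), "time_s")
  nm <- if (is.numeric(observable)) obs_names[observable] else observable
  comp <- cc[[nm]]
  t_h <- cc$time_s / 3600
  raw_of <- function(completion, eps) {
    noise$baseline + noise$scale * completion +
      noise$drift_per_hour * t_h + eps
  }
  npt <- length(comp)
  .with_seed(noise$seed, {
    eps <- function() stats::rnorm(npt, 0, noise$additive_sd * noise$scale)
    wells <- list()
    roles <- character(0)
    for (i in seq_len(n_replicates)) {
      w <- sprintf("sample_%d", i)
      wells[[w]] <- raw_of(comp, eps())
      roles[w] <- "sample"
    }
    wells[["neg"]] <- raw_of(0, eps()); roles["neg"] <- "negative_control"
    wells[["pos"]] <- raw_of(1, eps()); roles["pos"] <- "positive_control"
    out <- plate_data(cc$time_s, wells, roles,
                      channel = sprintf("synthetic(seed=%d)", noise$seed))
    attr(out, "true_completion") <- comp
    out
  })
}

#' Generate a synthetic structure-count table
#'
#' Binomial draw of product counts among `n` imaged structures, matching
#' the Bernoulli treatment of count-based yields.
#'
#' @param true_p True product probability in `[0, 1]`.
#' @param n Total number of structures (>= 1).
#' @param seed Integer seed.
#' @return `list(n_product, n_total)`.
#' @export
generate_counts <- function(true_p, n, seed = 1L) {
  stopifnot(true_p >= 0, true_p <= 1, n >= 1)
  .with_seed(seed, list(n_product = stats::rbinom(1L, n, true_p),
                        n_total = as.integer(n)))
}
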