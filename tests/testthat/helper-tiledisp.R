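# shared helpers for the suite

final_completion <- function(cc, col = 2L) cc[[col]][nrow(cc)]

half_completion_time <- function(cc, col = 2L) {
  i <- which(cc[[col]] >= 0.5)[1L]
  if (is.na(i)) Inf else cc$time_s[i]
}

# coarse grid to keep routine tests fast; acceptance tests use finer grids
quick_sim <- function(sys, params = default_rate_params(), hours = 48,
                      dt_s = 900) {
  simulate_system(sys, params, hours = hours, dt_s = dt_s)
}
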