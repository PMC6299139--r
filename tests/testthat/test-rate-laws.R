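test_that("dissociation is exponential in toehold nucleotides", {
  p <- rate_params(k_diss0_per_s = 10, b_per_nt = 2)
  expect_equal(k_dissociation(0, p), 10)            # exponent 0
  expect_equal(k_dissociation(3, p), 1.25)          # 10 * 2^-3
  expect_equal(k_dissociation(8, p) / k_dissociation(4, p), 2^-4)
  expect_error(k_dissociation(-1, p), ">= 0")
  d <- default_rate_params()
  expect_true(all(diff(k_dissociation(0:12, d)) < 0))  # strictly decreasing
})

test_that("the effective-rate reduction has the right limits", {
  expect_equal(k_effective(1e5, 0, 0.025), 1e5)          # binding-limited max
  expect_equal(k_effective(1e5, 0.025, 0.025), 5e4)      # symmetric point
  # pre-equilibrium limit: k_bind * k_disp / k_diss
  expect_equal(k_effective(1e5, 250, 0.025), 1e5 * 0.025 / 250.025)
  expect_error(k_effective(1e5, 0, 0), "undefined")
  expect_error(k_effective(-1, 1, 1))
})

test_that("path rate is the inverse mean first-passage time of the chain", {
  p <- default_rate_params()
  expect_equal(path_rate(list(list(class = "edge", coded = FALSE)), p),
               p$k_disp_per_s)  # single uncoded edge segment, exactly
  # chain of n identical steps at rate r -> r / n
  seg <- list(class = "edge", coded = FALSE)
  expect_equal(path_rate(rep(list(seg), 4), p), p$k_disp_per_s / 4)
  expect_error(path_rate(list(), p), "nonempty")
})

test_that("path rate matches an independent ODE first-passage oracle", {
  # oracle: integrate occupancy of a linear chain of exponential steps and
  # accumulate the mean passage time as the integral of 1 - F(t)
  p <- default_rate_params()
  segs <- list(list(class = "edge", coded = TRUE),
               list(class = "corner", coded = TRUE),
               list(class = "edge", coded = FALSE),
               list(class = "corner", coded = FALSE))
  rates <- vapply(segs, function(s) segment_rate(p, s$class, s$coded),
                  numeric(1))
  n <- length(rates)
  deriv <- function(t, y, parms) {
    occ <- y[seq_len(n)]
    flux_in <- c(0, rates[-n] * occ[-n])
    # last state accumulates the survival probability: MFPT = integral of S(t)
    list(c(flux_in - rates * occ, sum(occ)))
  }
  tmax <- 60 / min(rates)
  sol <- deSolve::lsoda(c(1, rep(0, n - 1L), 0),
                        seq(0, tmax, length.out = 2000L), deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  mfpt_oracle <- unname(sol[nrow(sol), n + 2L])
  expect_equal(path_rate(segs, p), 1 / mfpt_oracle, tolerance = 1e-4)
})

test_that("corner-heavy paths are slower but extra corners dominate edges", {
  p <- default_rate_params()
  corner_path <- list(list(class = "edge", coded = TRUE),
                      list(class = "corner", coded = TRUE))
  edge_path <- c(rep(list(list(class = "edge", coded = TRUE)), 3),
                 rep(list(list(class = "corner", coded = TRUE)), 2))
  expect_gt(path_rate(corner_path, p), path_rate(edge_path, p))
  # monotone nonincreasing in segment count and in each slowdown factor
  seg <- list(class = "corner", coded = TRUE)
  r <- vapply(1:5, function(n) path_rate(rep(list(seg), n), p), numeric(1))
  expect_true(all(diff(r) < 0))
  p2 <- rate_params(corner_factor = 200)
  expect_lt(path_rate(corner_path, p2), path_rate(corner_path, p))
  p3 <- rate_params(code_factor = 50)
  expect_lt(path_rate(corner_path, p3), path_rate(corner_path, p))
})

test_that("regime crossover separates binding- and displacement-limited", {
  expect_equal(regime_crossover(4.5e5, 0), 0)      # always displacement-limited
  # stated crossover near 50 nM implies k_disp_path = 2.25e-2 /s
  expect_equal(regime_crossover(4.5e5, 2.25e-2), 50e-9)
  expect_equal(regime_crossover(9e5, 2.25e-2), 25e-9)  # doubling k_bind halves it
  expect_error(regime_crossover(0, 1), "> 0")
  # the default parameter set crosses over near 50 nM
  p <- default_rate_params()
  cross <- regime_crossover(k_bind(p, 2), p$k_disp_per_s)
  expect_gt(cross, 40e-9); expect_lt(cross, 70e-9)
})

test_that("effective rates are monotone in toehold strength, capped by binding", {
  p <- default_rate_params()
  seg <- list(list(class = "edge", coded = FALSE))
  ke <- vapply(1:8, function(n)
    k_effective(k_bind(p, 2), k_dissociation(n, p), path_rate(seg, p)),
    numeric(1))
  expect_true(all(diff(ke) > 0))
  expect_true(all(ke <= k_bind(p, 2)))
})

test_that("binding lookup rejects untabulated sticky-end lengths", {
  p <- default_rate_params()
  expect_equal(k_bind(p, 2), 4.5e5)
  expect_error(k_bind(p, 3), "tabulated")
})

test_that("rate parameters validate, serialize and expose flat access", {
  expect_error(rate_params(b_per_nt = 1), "> 1")
  expect_error(rate_params(corner_factor = 0.5), ">= 1")
  p <- default_rate_params()
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_rate_params(p, f)
  p2 <- read_rate_params(f)
  expect_equal(p2, p)
  p3 <- .param_set(p, "k_bind_per_M_s.2", 1e5)
  expect_equal(.param_get(p3, "k_bind_per_M_s.2"), 1e5)
  expect_equal(.param_get(p3, "k_disp_per_s"), p$k_disp_per_s)
  expect_error(.param_get(p, "nope"), "unknown parameter")
})
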