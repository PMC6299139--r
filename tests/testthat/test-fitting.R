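make_test_plate <- function(sample, neg, pos, t = seq(0, 999 * 60, by = 60)) {
  plate_data(t, list(s1 = sample, neg = neg, pos = pos),
             c(s1 = "sample", neg = "negative_control",
               pos = "positive_control"))
}

test_that("normalization maps controls to 0 and 1", {
  n <- 1000
  t <- seq(0, (n - 1) * 60, by = 60)
  neg <- rep(100, n)
  pos <- rep(1100, n)
  ramp <- 100 + 1000 * seq(0, 1, length.out = n)
  pl <- make_test_plate(neg, neg, pos, t)
  expect_equal(max(abs(normalize_plate(pl)$s1)), 0)
  pl2 <- make_test_plate(pos, neg, pos, t)
  out2 <- normalize_plate(pl2)
  expect_equal(out2$s1[n], 1)
  pl3 <- make_test_plate(ramp, neg, pos, t)
  expect_equal(normalize_plate(pl3)$s1, seq(0, 1, length.out = n))
})

test_that("a sample below the negative control supplies its own 0% level", {
  n <- 100
  t <- seq(0, (n - 1) * 60, by = 60)
  neg <- rep(100, n)
  pos <- rep(1100, n)
  low <- c(rep(80, 5), seq(80, 1100, length.out = n - 5))
  out <- normalize_plate(make_test_plate(low, neg, pos, t))
  expect_equal(mean(out$s1[1:5]), 0)  # starts at exactly 0
  high <- c(seq(100, 1200, length.out = n - 5), rep(1200, 5))
  out2 <- normalize_plate(make_test_plate(high, neg, pos, t))
  expect_equal(mean(out2$s1[(n - 4):n]), 1)
})

test_that("normalization is invariant under common positive affine maps", {
  n <- 200
  t <- seq(0, (n - 1) * 60, by = 60)
  neg <- 100 + 5 * sin(seq_len(n) / 7)
  pos <- 1100 + 5 * cos(seq_len(n) / 11)
  smp <- 100 + 1000 * (1 - exp(-seq_len(n) / 40)) + 3 * sin(seq_len(n) / 5)
  base <- normalize_plate(make_test_plate(smp, neg, pos, t))
  tf <- normalize_plate(make_test_plate(3.7 * smp + 250, 3.7 * neg + 250,
                                        3.7 * pos + 250, t))
  expect_equal(tf$s1, base$s1, tolerance = 1e-12)
})

test_that("inverted or short controls are rejected", {
  n <- 100
  t <- seq(0, (n - 1) * 60, by = 60)
  expect_error(normalize_plate(make_test_plate(rep(1, n), rep(500, n),
                                               rep(100, n), t)),
               "inverted")
  expect_error(plate_data(1:3, list(a = 1:3), c(a = "sample")),
               "negative")
  short <- make_test_plate(rep(1, 4), rep(0, 4), rep(2, 4), t = 1:4)
  expect_error(normalize_plate(short), ">= 5")
})

test_that("the Bernoulli yield formula reproduces published count pairs", {
  y <- yield_estimate(1, 12)
  expect_equal(round(100 * y$p, 1), 8.3)
  expect_equal(round(100 * y$se, 1), 2.3)
  # every (p, se) pair recoverable from printed counts, at display precision
  cases <- list(list(10, 12, 83.3, 9.8),   # sequential, 2x2 product
                list(19, 21, 90.5, 6.1),   # sequential, pair product
                list(17, 25, 68.0, 7.7),   # cooperative
                list(29, 37, 78.4, 6.0),   # 3x3 corner
                list(19, 36, 52.8, 6.0))   # 3x3 edge
  for (cs in cases) {
    y <- yield_estimate(cs[[1]], cs[[2]])
    expect_equal(round(100 * y$p, 1), cs[[3]])
    expect_equal(round(100 * y$se, 1), cs[[4]])
  }
})

test_that("yield edge cases and the textbook alternative", {
  expect_equal(yield_estimate(0, 20)$se, 0)
  expect_equal(yield_estimate(20, 20)$se, 0)
  expect_equal(yield_estimate(20, 20)$p, 1)
  expect_error(yield_estimate(3, 0), ">= 1")
  expect_error(yield_estimate(5, 3), "<=")
  # the printed convention is deliberately not the textbook SE
  y <- yield_estimate(1, 12)
  expect_equal(yield_se_binomial(y$p, 12), sqrt(y$p * (1 - y$p) / 12))
  expect_gt(yield_se_binomial(y$p, 12), y$se)
})

test_that("zero-noise synthetic data is recovered to solver tolerance", {
  truth <- default_rate_params()
  conds <- list(c(4, 2), c(1, 2))
  data <- lapply(conds, function(yx) {
    sys <- make_basic_displacement(yx[1], yx[2])
    cc <- simulate_system(sys, truth, hours = 48, dt_s = 900)
    list(system = sys, time_s = cc$time_s, observed = cc$completion)
  })
  start <- .param_set(truth, "k_bind_per_M_s.2", 3e5)
  start <- .param_set(start, "k_disp_per_s", 0.06)
  fit <- fit_rates(data, start, free = c("k_bind_per_M_s.2", "k_disp_per_s"))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["k_bind_per_M_s.2"]] / 4.5e5 - 1), 1e-3)
  expect_lt(abs(fit$estimates[["k_disp_per_s"]] / 0.025 - 1), 1e-3)
  expect_lt(fit$rms, 1e-5)
})

test_that("fitting with all parameters frozen reports residuals only", {
  truth <- default_rate_params()
  sys <- make_basic_displacement(4, 2)
  cc <- simulate_system(sys, truth, hours = 12, dt_s = 1800)
  fit <- fit_rates(list(list(system = sys, time_s = cc$time_s,
                             observed = cc$completion)),
                   truth, free = character(0))
  expect_true(fit$converged)
  expect_length(fit$estimates, 0)
  expect_lt(fit$rms, 1e-8)
  expect_equal(fit$params, truth)
})

test_that("effective rate ratios behave at both concentration regimes", {
  p <- default_rate_params()
  th <- toehold_spec(4, 2)
  expect_equal(effective_rate_ratio(p, th, th), 1)
  expect_equal(effective_rate_ratio(p, th, toehold_spec(4, 1)), 18,
               tolerance = 1e-4)
  # at 2 nM the three-step passage rates give a similar contrast
  r2nM <- effective_rate_ratio(p, th, toehold_spec(4, 1),
                               concentration = 2e-9)
  expect_gt(r2nM, 10); expect_lt(r2nM, 26)
})

test_that("fit reports serialize to structured text", {
  truth <- default_rate_params()
  sys <- make_basic_displacement(4, 2)
  cc <- simulate_system(sys, truth, hours = 6, dt_s = 1800)
  fit <- fit_rates(list(list(system = sys, time_s = cc$time_s,
                             observed = cc$completion)),
                   truth, free = character(0))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_fit_report(fit, f)
  rep <- jsonlite::read_json(f)
  expect_true(rep$converged)
  expect_lt(rep$rms, 1e-8)
})
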