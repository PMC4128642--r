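test_that("simulate -> fit -> convert round-trips Pf at the standard shock", {
  m <- default_model()   # 1.4 M -> 1.75 M
  for (pf_true in c(3.31e-4, 7.43e-4, 9.65e-4)) {
    fit <- fit_single_exponential(model_trace(pf_true, m))
    pf <- pf_from_rate(fit, m)
    expect_equal(as.numeric(pf), pf_true, tolerance = 1e-3)
  }
})

test_that("linearized conversion is the closed-form constant", {
  m <- default_model()
  fit <- fit_single_exponential(model_trace(4.3e-4, m))
  pf1 <- as.numeric(pf_from_rate(fit, m, method = "linearized"))
  expect_equal(pf1,
               fit$k * (m$v0 * (1 - m$beta) / m$area) *
                 m$osm_in0 / (m$vw * m$osm_out^2))
  # linear in k: doubling the rate doubles the permeability
  fit2 <- fit
  fit2$k <- 2 * fit$k
  expect_equal(as.numeric(pf_from_rate(fit2, m, method = "linearized")),
               2 * pf1)
})

test_that("linearized-conversion bias shrinks with the shock size", {
  pf_true <- 4.3e-4
  bias <- vapply(c(1.25, 1.10, 1.02), function(ratio) {
    m <- gentle_model(ratio)
    fit <- fit_single_exponential(model_trace(pf_true, m))
    abs(as.numeric(pf_from_rate(fit, m, method = "linearized")) / pf_true - 1)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("hand-computed spherical conversion (beta = 0)", {
  # sphere r = 2.5 um, beta = 0: Pf = k * (r/3) * osm_in0 / (vw * osm_out^2)
  m <- cell_model(radius_um = 2.5, beta = 0)
  r_cm <- 2.5e-4
  k <- 0.5
  by_hand <- k * (r_cm / 3) * 1.4e-3 / (18 * (1.75e-3)^2)
  fit <- structure(list(k = k, times = seq(0, 10, length.out = 100),
                        dead_time = 0, temperature = 296.15),
                   class = "aq_expfit")
  expect_equal(as.numeric(pf_from_rate(fit, m, method = "linearized")),
               by_hand, tolerance = 1e-12)
})

test_that("estimate_pf summarizes replicates with a sample SD", {
  m <- default_model()
  tr <- model_trace(7.43e-4, m)
  res <- estimate_pf(rep(list(tr), 10), m)
  expect_s3_class(res, "aq_pf")
  expect_equal(res$pf_sd, 0)
  expect_equal(res$n_traces, 10)
  expect_equal(res$pf_mean, as.numeric(pf_from_rate(
    fit_single_exponential(tr), m)), tolerance = 1e-9)
})

test_that("noisy replicate ensembles recover the true Pf", {
  m <- default_model()
  pf_true <- 9.65e-4
  traces <- lapply(1:10, function(s)
    model_trace(pf_true, m, noise_sd = 0.02, seed = 400 + s))
  res <- estimate_pf(traces, m)
  expect_lt(abs(res$pf_mean / pf_true - 1), 0.05)
  expect_gt(res$pf_sd, 0)
  # SD uses the n-1 denominator
  expect_equal(res$pf_sd, sd(res$pf_values))
})

test_that("failed traces are excluded with a warning", {
  m <- default_model()
  good <- model_trace(7.43e-4, m)
  flat <- aq_trace(good$times, rep(1, length(good$times)), label = "flat")
  expect_warning(res <- estimate_pf(list(good, flat, good), m),
                 "excluded")
  expect_equal(res$n_traces, 2)
  expect_error(suppressWarnings(estimate_pf(list(flat), m)),
               "all traces failed")
})

test_that("mixed-temperature ensembles are rejected", {
  m <- default_model()
  t1 <- model_trace(5e-4, m, temperature = 296.15)
  t2 <- model_trace(5e-4, m, temperature = 310.15)
  expect_error(estimate_pf(list(t1, t2), m), "temperature")
})
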