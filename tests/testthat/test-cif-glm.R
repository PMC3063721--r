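test_that("design columns are lagged indicators in the single-bin-window case", {
  # N = 1, R = 1, W = delta: the only history column is the target's own
  # indicator lagged by one bin
  ens <- simulate_ensemble(spec_poisson(1), 300, seed = 7)
  b <- bin_spikes(ens)
  hw <- history_windows(0.001, 1, 0.001)
  fd <- build_design(b, 1, hw)
  y <- b$counts[1, ]
  expect_equal(fd$design[, 1], rep(1, length(fd$response)))
  expect_equal(fd$design[, 2], y[seq_len(length(y) - 1)])
  expect_equal(fd$response, y[-1])
})

test_that("excluding a source removes its columns structurally", {
  ens <- simulate_ensemble(spec_poisson(2), 500, seed = 8)
  b <- bin_spikes(ens)
  hw <- history_windows(0.002, 3, 0.001)
  fd_red <- build_design(b, 1, hw, excluded = 1) # drop self-history
  expect_identical(ncol(fd_red$design), 1L + 3L)
  expect_identical(unique(fd_red$col_map$source[-1]), 2L)
  expect_error(build_design(b, 1, hw, excluded = 5), "out of range")
})

test_that("excluding a silent source leaves the remaining columns unchanged", {
  ens <- simulate_ensemble(spec_poisson(2), 500, seed = 9)
  spk <- tibble::as_tibble(ens) |> dplyr::filter(.data$neuron_id == 1)
  ens3 <- spike_ensemble(spk, t_start = 0, t_end = 0.5, n_neurons = 3) # neurons 2,3 silent
  b <- bin_spikes(ens3)
  hw <- history_windows(0.002, 2, 0.001)
  full <- build_design(b, 1, hw)
  red <- build_design(b, 1, hw, excluded = 3)
  kept <- full$col_map$col[is.na(full$col_map$source) | full$col_map$source != 3]
  expect_equal(unname(full$design[, kept]), unname(red$design))
})

test_that("the likelihood of a silent response under constant intensity is -K*lambda*delta", {
  # all-zero response with lambda*delta = 0.018 over 100,000 fittable bins
  ens <- spike_ensemble(
    tibble::tibble(neuron_id = 1, spike_time_s = 0.0005),
    t_start = 0, t_end = 100.001, n_neurons = 2
  )
  b <- bin_spikes(ens, 0.001)
  hw <- history_windows(0.001, 1, 0.001)
  fd <- build_design(b, 2, hw) # neuron 2 is silent; 100,000 fittable bins
  expect_identical(length(fd$response), 100000L)
  model <- mk_model(log(0.018), matrix(0, 2, 1), hw, target = 2, baseline_only = TRUE)
  expect_equal(log_likelihood(model, fd), -1800, tolerance = 1e-12)
})

test_that("log-likelihood matches the per-bin brute-force oracle", {
  spec <- spec_pair()
  ens <- simulate_ensemble(spec, 400, seed = 10)
  b <- bin_spikes(ens)
  hw <- history_windows(0.002, 2, 0.001)
  m <- fit_cif(b, 1, hw)
  fd <- build_design(b, 1, hw)
  expect_equal(log_likelihood(m, fd), bf_loglik(b, m), tolerance = 1e-9)
  expect_equal(m$loglik, bf_loglik(b, m), tolerance = 1e-9)
  # baseline-only model evaluated the same way
  m0 <- fit_cif(b, 1, hw, baseline_only = TRUE)
  expect_equal(m0$loglik, bf_loglik(b, m0), tolerance = 1e-9)
})

test_that("the baseline-only maximum-likelihood rate is the mean spike count per bin", {
  ens <- simulate_ensemble(spec_poisson(1, rate = 25), 4000, seed = 12)
  b <- bin_spikes(ens)
  hw <- history_windows(0.002, 2, 0.001)
  m0 <- fit_cif(b, 1, hw, baseline_only = TRUE)
  fd <- build_design(b, 1, hw)
  expect_equal(exp(m0$beta0), mean(fd$response), tolerance = 1e-8)
})

test_that("the fitter agrees with stats::glm on the same design", {
  spec <- spec_pair()
  ens <- simulate_ensemble(spec, 3000, seed = 13)
  b <- bin_spikes(ens)
  hw <- history_windows(0.002, 2, 0.001)
  fd <- build_design(b, 1, hw)
  m <- fit_cif(b, 1, hw, design = fd)
  ref <- stats::glm.fit(fd$design, fd$response, family = stats::poisson())
  expect_equal(unname(c(m$beta0, as.vector(t(m$gamma)))), unname(ref$coefficients),
    tolerance = 1e-6
  )
  ll_ref <- sum(fd$response * log(ref$fitted.values) - ref$fitted.values)
  expect_equal(m$loglik, ll_ref, tolerance = 1e-8)
})

test_that("a silent target is a degenerate response", {
  ens <- spike_ensemble(
    tibble::tibble(neuron_id = 1, spike_time_s = 0.0005),
    t_start = 0, t_end = 0.2, n_neurons = 2
  )
  b <- bin_spikes(ens)
  expect_error(fit_cif(b, 2, history_windows(0.002, 2)), "Degenerate response")
})

test_that("re-optimised reduced models never beat the full model", {
  set.seed(14)
  spec <- spec_pair(cross = c(1, 0.6), self1 = c(-0.6, -0.4))
  for (seed in c(21, 22, 23)) {
    ens <- simulate_ensemble(spec, 4000, seed = seed)
    b <- bin_spikes(ens)
    hw <- history_windows(0.002, 2, 0.001)
    full <- fit_cif(b, 1, hw)
    for (j in 1:2) {
      red <- fit_cif(b, 1, hw, excluded = j)
      expect_lte(red$loglik, full$loglik + 1e-6 * abs(full$loglik))
    }
  }
})

test_that("coefficients are recovered within three standard errors", {
  # correctly specified generator (window-aligned kernels, no refractoriness):
  # the joint three-sigma box should cover the truth in nearly every run
  cross <- c(0.8, 0.5)
  self1 <- c(-0.5, -0.3)
  spec <- spec_pair(cross = cross, self1 = self1)
  truth <- c(log(18 * 0.001), self1, cross)
  hw <- history_windows(0.002, 2, 0.001)
  hits <- 0L
  n_runs <- 12L
  for (r in seq_len(n_runs)) {
    ens <- simulate_ensemble(spec, 30000, seed = 300 + r)
    m <- fit_cif(bin_spikes(ens), 1, hw)
    est <- c(m$beta0, as.vector(t(m$gamma)))
    se <- c(m$se_beta0, as.vector(t(m$se_gamma)))
    if (all(abs(est - truth) <= 3 * se)) hits <- hits + 1L
  }
  expect_gte(hits, 10L)
})

test_that("AIC selection returns a single candidate unchanged and prefers the true order", {
  spec <- spec_pair(cross = c(1.2, 0.8), self1 = c(-0.6, -0.4))
  ens <- simulate_ensemble(spec, 20000, seed = 31)
  b <- bin_spikes(ens)
  expect_identical(as.integer(select_order_aic(b, 1, 0.002, candidates = 4L)), 4L)
  # generator has R_true = 2 with strong coefficients: modal selection is 2
  picks <- vapply(1:8, function(r) {
    ensr <- simulate_ensemble(spec, 15000, seed = 400 + r)
    as.integer(select_order_aic(bin_spikes(ensr), 1, 0.002, candidates = 1:4))
  }, integer(1))
  expect_identical(as.integer(names(which.max(table(picks)))), 2L)
})

test_that("AIC equals -2 logLik + 2 p on the candidate table", {
  ens <- simulate_ensemble(spec_pair(), 8000, seed = 41)
  b <- bin_spikes(ens)
  sel <- select_order_aic(b, 1, 0.002, candidates = 1:3)
  tab <- attr(sel, "aic_table")
  expect_equal(tab$aic, -2 * tab$loglik + 2 * (1 + 2 * tab$R))
  m <- fit_cif(b, 1, history_windows(0.002, 2))
  expect_equal(AIC(m), -2 * m$loglik + 2 * m$n_params)
})

test_that("fitted models serialise to JSON and back", {
  ens <- simulate_ensemble(spec_pair(), 3000, seed = 51)
  b <- bin_spikes(ens)
  hw <- history_windows(0.002, 2, 0.001)
  m <- fit_cif(b, 1, hw, excluded = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_cif_json(m, path)
  back <- read_cif_json(path)
  expect_equal(back$beta0, m$beta0)
  expect_equal(back$gamma, m$gamma, ignore_attr = TRUE)
  expect_identical(back$excluded, m$excluded)
  fd <- build_design(b, 1, hw, excluded = 2)
  expect_equal(log_likelihood(back, fd), m$loglik, tolerance = 1e-9)
})
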