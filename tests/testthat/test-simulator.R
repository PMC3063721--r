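test_that("simulation is fully determined by spec, length and seed", {
  spec <- preset_network("ninenet")
  a <- simulate_ensemble(spec, 3000, seed = 100)
  b <- simulate_ensemble(spec, 3000, seed = 100)
  c <- simulate_ensemble(spec, 3000, seed = 101)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
  expect_error(simulate_ensemble(spec, 3000), "mandatory")
})

test_that("an uncoupled neuron fires at its nominal spontaneous rate", {
  ens <- simulate_ensemble(spec_poisson(1, rate = 18), 100000, seed = 110)
  rate <- nrow(ens) / 100
  se3 <- 3 * sqrt(100000 * 0.018 * 0.982) / 100 # three binomial sigmas in Hz
  expect_lt(abs(rate - 18), se3)
})

test_that("the refractory rule vetoes spikes in adjacent bins", {
  spec <- preset_network("ninenet") # all nine neurons self-coupled, so all refractory
  b <- bin_spikes(simulate_ensemble(spec, 30000, seed = 111))
  adjacency <- sum(b$counts[, -1] == 1L & b$counts[, -ncol(b$counts)] == 1L)
  expect_identical(adjacency, 0L)
  # with refractoriness off the same network does produce adjacent spikes
  spec$refractory_neurons <- integer(0)
  b2 <- bin_spikes(simulate_ensemble(spec, 30000, seed = 111))
  adjacency2 <- sum(b2$counts[, -1] == 1L & b2$counts[, -ncol(b2$counts)] == 1L)
  expect_gt(adjacency2, 0L)
})

test_that("an inhibitory edge lowers the target's conditional rate after trigger spikes", {
  edges <- tibble::tibble(
    trigger = 2L, target = 1L,
    lags = list(c(-2, -2, -2))
  )
  spec <- network_spec(2, edges, baseline_rate = 25, refractory = 0, name = "inh")
  b <- bin_spikes(simulate_ensemble(spec, 100000, seed = 112))
  y <- b$counts[1, ]
  trig <- which(b$counts[2, ] == 1L)
  after <- unique(pmin(c(trig + 1, trig + 2, trig + 3), length(y)))
  cond_rate <- mean(y[after])
  expect_lt(cond_rate, mean(y) * 0.6)
})

test_that("presets satisfy their declared wiring constraints", {
  nine <- preset_network("ninenet")
  expect_identical(nrow(nine$edges), 30L)
  sign_of <- vapply(nine$edges$lags, function(l) sign(sum(l)), numeric(1))
  for (i in 1:9) {
    inc <- nine$edges$target == i
    n_inh <- sum(inc & sign_of < 0)
    n_exc <- sum(inc & sign_of > 0)
    expect_identical(n_inh, 2L) # two inhibitory inputs counting self-inhibition
    expect_true(any(nine$edges$trigger == i & nine$edges$target == i & sign_of < 0))
    expect_true(n_exc %in% 1:2) # one or two excitatory inputs
  }
  # cross-assembly kernels are the long ones; they target neurons 1,3,4,5,8,9
  assembly <- rep(1:3, each = 3)
  cross <- assembly[nine$edges$trigger] != assembly[nine$edges$target]
  expect_true(all(lengths(nine$edges$lags[cross]) == 6L))
  expect_setequal(unique(nine$edges$target[cross]), c(1L, 3L, 4L, 5L, 8L, 9L))

  for (nm in c("density8", "density16", "density32", "density64")) {
    spec <- preset_network(nm)
    expect_identical(nrow(spec$edges), as.integer(sub("density", "", nm)))
  }
  d8 <- preset_network("density8")
  # neuron 9 has no interactions at all: a homogeneous Poisson unit, exempt
  # from the refractory rule
  expect_false(9L %in% c(d8$edges$trigger, d8$edges$target))
  expect_false(9L %in% d8$refractory_neurons)

  h5 <- preset_network("hidden5")
  expect_identical(h5$hidden, c(4L, 5L))
  obs <- simulate_ensemble(h5, 2000, seed = 113)
  expect_identical(attr(obs, "n_neurons"), 3L)
  all5 <- simulate_ensemble(h5, 2000, seed = 113, include_hidden = TRUE)
  expect_identical(attr(all5, "n_neurons"), 5L)
  # observed neurons are unaffected by dropping the hidden ones
  expect_identical(
    dplyr::filter(tibble::as_tibble(all5), .data$neuron_id <= 3),
    tibble::as_tibble(obs),
    ignore_attr = TRUE
  )
})

test_that("all presets generate plausible stationary rates", {
  for (nm in c("ninenet", "density8", "density16", "density32", "density64", "hidden5")) {
    ens <- simulate_ensemble(preset_network(nm), 20000, seed = 120, include_hidden = TRUE)
    rates <- tibble::as_tibble(ens) |>
      dplyr::count(.data$neuron_id) |>
      dplyr::pull(.data$n) / 20
    expect_true(all(rates > 1 & rates < 200), label = nm)
  }
})

test_that("ground-truth matrices reflect the edge signs and hidden marginalisation", {
  h5 <- preset_network("hidden5")
  full <- truth_matrix(h5, observed_only = FALSE)
  expect_identical(dim(full), c(5L, 5L))
  expect_identical(full[1, 4], 1L) # hidden feedback loop
  expect_identical(full[4, 1], 1L)
  obs <- truth_matrix(h5)
  expect_identical(dim(obs), c(3L, 3L))
  expect_equal(unname(diag(obs)), c(-1L, -1L, -1L)) # direct self-couplings are inhibitory
  expect_identical(obs[1, 2], 1L)
  expect_identical(obs[1, 3], -1L)
})

test_that("infinite-SNR noise reproduces the noiseless simulation exactly", {
  spec <- preset_network("ninenet")
  base <- simulate_ensemble(spec, 4000, seed = 130)
  noisy_inf <- simulate_ensemble(add_log_cif_noise(spec, Inf), 4000, seed = 130)
  expect_identical(tibble::as_tibble(base), tibble::as_tibble(noisy_inf))
})

test_that("the realised log-intensity noise power matches the requested SNR", {
  spec <- add_log_cif_noise(spec_poisson(2, rate = 18), 10)
  n_bins <- 100000L
  seed <- 131L
  ens <- simulate_ensemble(spec, n_bins, seed = seed)
  expect_s3_class(ens, "spike_ensemble")
  # reconstruct the injected noise from its dedicated stream and compare
  # realised power against the (constant) unperturbed log-intensity power
  p_signal <- log(18 * 0.001)^2
  sigma <- sqrt(p_signal / 10^(10 / 10))
  set.seed(seed + 499979L)
  noise <- matrix(rnorm(2 * n_bins), nrow = 2) * sigma
  realised_db <- 10 * log10(p_signal / mean(noise^2))
  expect_lt(abs(realised_db - 10), 0.5)
  # at 0 dB the perturbation power equals the signal power
  sigma0 <- sqrt(p_signal / 10^(0 / 10))
  expect_equal(sigma0^2, p_signal)
})

test_that("noise at a finite SNR changes the spike pattern but not the thinning stream", {
  spec <- spec_poisson(1, rate = 18)
  a <- simulate_ensemble(spec, 20000, seed = 132)
  # at 0 dB the noise std is ~|log(0.018)|, so clamping is expected and silenced
  b <- suppressWarnings(simulate_ensemble(add_log_cif_noise(spec, 0), 20000, seed = 132))
  expect_false(identical(nrow(a), nrow(b)) && identical(a$spike_time_s, b$spike_time_s))
  # heavy noise raises the realised rate (exp of symmetric noise has mean > 1)
  expect_gt(nrow(b), nrow(a))
})

test_that("intensity clamping is counted and reported", {
  edges <- tibble::tibble(trigger = 1L, target = 2L, lags = list(rep(5, 4)))
  spec <- network_spec(2, edges, baseline_rate = 150, refractory = 0, name = "hot")
  expect_warning(simulate_ensemble(spec, 5000, seed = 133), "clamped")
})

test_that("the Monte-Carlo FDR experiment summarises false positives per level", {
  spec <- spec_poisson(3)
  res <- mc_fdr_experiment(spec,
    n_replicates = 4, levels = c(0.05, 0.2), seed = 140,
    n_bins = 4000, orders = rep(2L, 3)
  )
  expect_s3_class(res, "mc_fdr_result")
  expect_identical(nrow(res), 2L)
  expect_true(all(res$observed_fdr >= 0 & res$observed_fdr <= 1))
  det <- attr(res, "details")
  expect_identical(nrow(det), 8L)
  # under the global null every detection is a false positive
  expect_true(all(det$false_positives == det$detected))
})

test_that("network specifications round-trip through JSON", {
  spec <- preset_network("hidden5")
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(spec, path)
  back <- read_network_json(path)
  expect_equal(back$edges, spec$edges)
  expect_identical(back$hidden, spec$hidden)
  expect_identical(back$refractory_neurons, spec$refractory_neurons)
  expect_equal(back$baseline_rate, spec$baseline_rate)
  expect_identical(
    tibble::as_tibble(simulate_ensemble(back, 2000, seed = 7)),
    tibble::as_tibble(simulate_ensemble(spec, 2000, seed = 7))
  )
})
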