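# Small generative networks used across tests.

no_edges <- function() tibble::tibble(trigger = integer(), target = integer(), lags = list())

# N independent homogeneous Poisson neurons (no history, no refractoriness)
spec_poisson <- function(N, rate = 18, delta = 0.001) {
  network_spec(N, no_edges(), baseline_rate = rate, delta = delta, refractory = 0, name = "poisson")
}

# kernels aligned to the analysis windows: one coefficient per window of
# width W, repeated over the bins of that window, so the fitted model with
# the same (W, R) is correctly specified
window_kernel <- function(gammas, W = 0.002, delta = 0.001) {
  rep(gammas, each = as.integer(round(W / delta)))
}

# two neurons, neuron 2 drives neuron 1 with window-aligned coefficients;
# optional window-aligned self-kernels, refractoriness off so the GLM is
# exactly correctly specified
spec_pair <- function(cross = c(0.8, 0.5), self1 = c(-0.5, -0.3),
                      rate = 18, W = 0.002, delta = 0.001) {
  edges <- tibble::tibble(
    trigger = c(2L, 1L),
    target = c(1L, 1L),
    lags = list(window_kernel(cross, W, delta), window_kernel(self1, W, delta))
  )
  network_spec(2, edges, baseline_rate = rate, delta = delta, refractory = 0, name = "pair")
}
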