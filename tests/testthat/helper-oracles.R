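# Independent brute-force reference implementations used to validate the
# vectorised/matrix code paths. Deliberately naive: per-event and per-bin
# loops, no shared code with the package internals.

# counts of `source`'s spikes in the R causal windows before 0-based bin k,
# by looping over the source's spike bins
bf_window_counts <- function(binned, source, k, W, R) {
  w <- as.integer(round(W / binned$delta))
  spike_bins <- which(binned$counts[source, ] == 1L) - 1L # 0-based
  vapply(seq_len(R), function(r) {
    lo <- k - r * w
    hi <- k - (r - 1L) * w
    sum(spike_bins >= lo & spike_bins < hi)
  }, numeric(1))
}

# discrete point-process log-likelihood by a per-bin loop over the fittable
# range, reconstructing the linear predictor from window counts
bf_loglik <- function(binned, model) {
  w <- model$hw$w
  R <- model$hw$R
  K <- ncol(binned$counts)
  kmin <- R * w
  total <- 0
  for (k in kmin:(K - 1L)) {
    eta <- model$beta0
    if (!model$baseline_only) {
      for (jj in seq_along(model$sources)) {
        cnt <- bf_window_counts(binned, model$sources[jj], k, model$hw$W, R)
        eta <- eta + sum(model$gamma[jj, ] * cnt)
      }
    }
    y <- binned$counts[model$target, k + 1L]
    total <- total + y * max(eta, log(1e-12)) - exp(eta)
  }
  total
}

# KS statistic against uniform quantiles (k - 0.5)/n by explicit loop
bf_ks_stat <- function(z) {
  z <- sort(z)
  n <- length(z)
  worst <- 0
  for (k in seq_len(n)) {
    worst <- max(worst, abs(z[k] - (k - 0.5) / n))
  }
  worst
}

# construct a cif_model by hand (for closed-form likelihood/sign checks)
mk_model <- function(beta0, gamma, hw, target, delta = 0.001, excluded = NULL,
                     baseline_only = FALSE) {
  gamma <- as.matrix(gamma)
  sources <- as.integer(rownames(gamma) %||% seq_len(nrow(gamma)))
  structure(
    list(
      target = as.integer(target), beta0 = beta0, gamma = gamma,
      se_beta0 = NA_real_, se_gamma = gamma * NA_real_,
      sources = sources, excluded = excluded, hw = hw, delta = delta,
      loglik = NA_real_, n_params = 1L + length(gamma),
      n_bins_fit = NA_integer_, n_spikes_fit = NA_integer_,
      converged = TRUE, iterations = 0L, baseline_only = baseline_only
    ),
    class = "cif_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
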