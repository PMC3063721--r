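#' Ground-truth generative network specification
#'
#' Describes the network that generates ensemble spike trains: every neuron
#' fires as a Bernoulli approximation of a point process whose log intensity
#' is a baseline plus, for each incoming edge, lagged contributions of the
#' trigger neuron's recent spikes. Edge kernels are per-bin lag coefficient
#' vectors (element `l` multiplies the trigger's spike indicator `l` bins
#' back); vectors may differ in length between edges (short within-assembly
#' kernels, long cross-assembly kernels). The baseline satisfies
#' `exp(beta0) = baseline_rate * delta` at zero history.
#'
#' @param n_neurons Number of neurons.
#' @param edges A data frame with columns `trigger`, `target` and `lags`
#'   (list column of numeric lag-coefficient vectors).
#' @param baseline_rate Spontaneous rate in spikes/s (default 18).
#' @param delta Simulation bin width in seconds (default 1 ms).
#' @param refractory Absolute refractory period in seconds (default 1 ms;
#'   `0` disables). A neuron cannot fire while a spike of its own lies in the
#'   previous `ceiling(refractory/delta)` bins.
#' @param refractory_neurons Indices subject to the refractory rule. Defaults
#'   to the neurons that have a self-edge, so that a neuron declared to have
#'   no self-interaction is a genuinely history-free (homogeneous Poisson)
#'   unit.
#' @param hidden Indices of hidden neurons: they take part in the generation
#'   but are dropped (and the rest relabelled) from the returned ensemble
#'   unless requested.
#' @param noise_snr_db Optional signal-to-noise ratio (dB) of i.i.d. Gaussian
#'   perturbations added per neuron and bin to the log intensity; see
#'   [add_log_cif_noise()].
#' @param name Label used in outputs.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_neurons, edges, baseline_rate = 18, delta = 0.001,
                         refractory = 0.001, refractory_neurons = NULL,
                         hidden = integer(0), noise_snr_db = NULL, name = "custom") {
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 1L) abort("`n_neurons` must be >= 1.")
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("trigger", "target", "lags") %in% names(edges)))
  edges$trigger <- as.integer(edges$trigger)
  edges$target <- as.integer(edges$target)
  if (nrow(edges)) {
    if (any(edges$trigger < 1 | edges$trigger > n_neurons | edges$target < 1 | edges$target > n_neurons)) {
      abort("Edge endpoints out of range.")
    }
    bad <- !purrr::map_lgl(edges$lags, ~ is.numeric(.x) && length(.x) >= 1)
    if (any(bad)) abort("Each edge needs a non-empty numeric lag-coefficient vector.")
  }
  hidden <- as.integer(hidden)
  if (any(hidden < 1 | hidden > n_neurons)) abort("`hidden` indices out of range.")
  if (length(hidden) >= n_neurons) abort("At least one neuron must be observable.")
  self_coupled <- unique(edges$trigger[edges$trigger == edges$target])
  refractory_neurons <- as.integer(refractory_neurons %||% self_coupled)
  structure(
    list(
      n_neurons = n_neurons,
      baseline_rate = baseline_rate,
      delta = delta,
      edges = edges,
      refractory = refractory,
      refractory_neurons = refractory_neurons,
      hidden = hidden,
      noise_snr_db = noise_snr_db,
      name = name
    ),
    class = "network_spec"
  )
}

#' @method print network_spec
#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec '%s': %d neurons (%d hidden), %d edges, baseline %g Hz, delta %g s, refractory %g s%s>\n",
    x$name, x$n_neurons, length(x$hidden), nrow(x$edges), x$baseline_rate,
    x$delta, x$refractory,
    if (is.null(x$noise_snr_db)) "" else sprintf(", log-CIF noise %g dB", x$noise_snr_db)
  ))
  invisible(x)
}

#' Built-in benchmark networks
#'
#' * `"ninenet"` - nine neurons in three three-neuron assemblies. Within each
#'   assembly every neuron excites its successor (`[1, 2, 2]`) and is
#'   inhibited by it (`[-0.8, -0.6, -0.3]`); all neurons self-inhibit
#'   (`[-0.6, -0.5, -0.4]`). Longer cross-assembly kernels
#'   (`[0 0 0 1 2 1]` excitatory, `[0 0 0 -0.8 -0.9 -0.5]` inhibitory) give
#'   six neurons (1, 3, 4, 5, 8, 9) an input from another assembly, so every
#'   neuron has exactly two inhibitory inputs counting self-inhibition and
#'   one or two excitatory inputs.
#' * `"density8"`, `"density16"`, `"density32"`, `"density64"` - nine-neuron
#'   variants with 8, 16, 32 and 64 interactions (self-interactions counted),
#'   used for false-discovery-rate calibration; the sparse variants contain
#'   history-free homogeneous-Poisson neurons.
#' * `"hidden5"` - five neurons of which only 1-3 are observable; hidden
#'   neurons 4 and 5 each form a positive feedback loop with neuron 1 through
#'   the long excitatory kernel `[0 0 1 2 2 1]`.
#'
#' @param name Preset name.
#' @return A [network_spec()].
#' @export
preset_network <- function(name) {
  dir <- system.file("extdata", "networks", package = "ppgranger")
  valid <- sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
  if (!name %in% valid) {
    abort(sprintf(
      "Unknown network preset '%s'. Valid presets: %s.",
      name, paste(sort(valid), collapse = ", ")
    ))
  }
  read_network_json(file.path(dir, paste0(name, ".json")))
}

#' Read and write network specifications as JSON
#'
#' @param path File path.
#' @return `read_network_json()` returns a [network_spec()].
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  edges <- tibble::tibble(
    trigger = purrr::map_int(doc$edges, ~ as.integer(.x$trigger)),
    target = purrr::map_int(doc$edges, ~ as.integer(.x$target)),
    lags = purrr::map(doc$edges, ~ as.numeric(unlist(.x$lags)))
  )
  network_spec(
    n_neurons = doc$n_neurons,
    edges = edges,
    baseline_rate = doc$baseline_rate_hz %||% 18,
    delta = doc$delta_s %||% 0.001,
    refractory = doc$refractory_s %||% 0.001,
    refractory_neurons = if (!is.null(doc$refractory_neurons)) unlist(doc$refractory_neurons),
    hidden = as.integer(unlist(doc$hidden_neurons %||% list())),
    noise_snr_db = doc$noise_snr_db,
    name = doc$name %||% sub("\\.json$", "", basename(path))
  )
}

#' @rdname read_network_json
#' @param spec A [network_spec()].
#' @export
write_network_json <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  doc <- list(
    name = spec$name,
    n_neurons = spec$n_neurons,
    baseline_rate_hz = spec$baseline_rate,
    delta_s = spec$delta,
    refractory_s = spec$refractory,
    refractory_neurons = spec$refractory_neurons,
    hidden_neurons = spec$hidden,
    noise_snr_db = spec$noise_snr_db,
    edges = purrr::pmap(spec$edges, function(trigger, target, lags) {
      list(trigger = trigger, target = target, lags = as.list(lags))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Add Gaussian noise to the log conditional intensity of a generator
#'
#' Perturbs `log(lambda * delta)` with i.i.d. zero-mean Gaussian noise,
#' independently per neuron and bin. The per-neuron variance is set so that
#' `10*log10(P_signal/sigma^2) = snr_db`, where `P_signal` is the uncentred
#' time-average power of that neuron's unperturbed log intensity (measured on
#' a noiseless pass with the same seed). Noise draws come from a separate
#' random stream, so the thinning draws are identical with and without noise
#' and the infinite-SNR limit reproduces the noiseless simulation exactly.
#'
#' @param spec A [network_spec()].
#' @param snr_db Signal-to-noise ratio in dB (`Inf` disables).
#' @return The spec with the noise level set.
#' @export
add_log_cif_noise <- function(spec, snr_db) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.numeric(snr_db) || length(snr_db) != 1 || is.na(snr_db)) abort("`snr_db` must be a number.")
  spec$noise_snr_db <- snr_db
  spec
}

# Core thinning loop. Returns the spike matrix, per-neuron uncentred power of
# the unperturbed log intensity, and the count of clamped bins.
.sim_core <- function(spec, n_bins, U, noise = NULL) {
  N <- spec$n_neurons
  b0 <- log(spec$baseline_rate * spec$delta)
  Lmax <- if (nrow(spec$edges)) max(lengths(spec$edges$lags)) else 1L
  drive <- matrix(0, N, n_bins + Lmax + 1L)
  spk <- matrix(0L, N, n_bins)
  out_t <- vector("list", N) # targets per trigger
  out_l <- vector("list", N) # lag kernels per trigger
  if (nrow(spec$edges)) {
    for (e in seq_len(nrow(spec$edges))) {
      j <- spec$edges$trigger[e]
      out_t[[j]] <- c(out_t[[j]], spec$edges$target[e])
      out_l[[j]] <- c(out_l[[j]], spec$edges$lags[e])
    }
  }
  m <- if (spec$refractory > 0) as.integer(ceiling(spec$refractory / spec$delta - 1e-9)) else 0L
  refr <- logical(N)
  refr[spec$refractory_neurons] <- TRUE
  last <- rep.int(-1e9, N)
  power <- numeric(N)
  clamped <- 0L
  for (k in seq_len(n_bins)) {
    eta0 <- b0 + drive[, k]
    power <- power + eta0 * eta0
    eta <- if (is.null(noise)) eta0 else eta0 + noise[, k]
    lam <- exp(eta)
    over <- lam > 1
    if (any(over)) {
      clamped <- clamped + sum(over)
      lam[over] <- 1
    }
    s <- U[, k] < lam
    if (m > 0L) s <- s & !(refr & (k - last <= m))
    if (any(s)) {
      idx <- which(s)
      spk[idx, k] <- 1L
      for (j in idx) {
        tg <- out_t[[j]]
        if (!is.null(tg)) {
          lg <- out_l[[j]]
          for (q in seq_along(tg)) {
            L <- length(lg[[q]])
            drive[tg[q], (k + 1L):(k + L)] <- drive[tg[q], (k + 1L):(k + L)] + lg[[q]]
          }
        }
      }
      last[idx] <- k
    }
  }
  list(spikes = spk, power = power / n_bins, clamped = clamped)
}

#' Simulate ensemble spike trains from a generative network
#'
#' Per-bin Bernoulli thinning of the log-linear conditional intensity: at
#' every bin each neuron's `lambda * delta` is computed from the baseline and
#' the lagged spike history along its incoming edges (plus optional log-
#' intensity noise), clamped to `[0, 1]`, and compared against an independent
#' uniform draw; absolute refractoriness vetoes spikes in adjacent bins for
#' refractory neurons. The same `(spec, n_bins, seed)` always yields the same
#' output, and the thinning draws do not depend on the noise setting.
#'
#' @param spec A [network_spec()].
#' @param n_bins Number of simulation bins.
#' @param seed Integer seed (mandatory: simulations are always reproducible).
#' @param include_hidden If `TRUE`, hidden neurons are kept in the returned
#'   ensemble; by default they are dropped and the observed neurons are
#'   relabelled `1..n_observed` in index order.
#' @return A [spike_ensemble()] over `[0, n_bins * delta)` with spikes placed
#'   at their bin centres. The fraction of clamped bins is attached as the
#'   `clamp_fraction` attribute (a warning is raised above 1%).
#' @export
simulate_ensemble <- function(spec, n_bins, seed, include_hidden = FALSE) {
  stopifnot(inherits(spec, "network_spec"))
  n_bins <- as.integer(n_bins)
  Ls <- if (nrow(spec$edges)) max(lengths(spec$edges$lags)) else 0L
  if (n_bins <= Ls) abort("`n_bins` must exceed the deepest edge kernel.")
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory: simulations must be reproducible.")
  seed <- as.integer(seed)
  N <- spec$n_neurons
  set.seed(seed)
  U <- matrix(runif(N * n_bins), nrow = N)
  noise <- NULL
  snr <- spec$noise_snr_db
  if (!is.null(snr) && is.finite(snr)) {
    pilot <- .sim_core(spec, n_bins, U, noise = NULL)
    sigma <- sqrt(pilot$power / 10^(snr / 10))
    set.seed(seed + 499979L)
    noise <- matrix(rnorm(N * n_bins), nrow = N) * sigma
  }
  run <- .sim_core(spec, n_bins, U, noise = noise)
  clamp_fraction <- run$clamped / (N * n_bins)
  if (clamp_fraction > 0.01) {
    warn(sprintf("%.2f%% of bins had lambda*delta clamped to 1; rates may be distorted.", 100 * clamp_fraction))
  }
  keep <- if (include_hidden) seq_len(N) else setdiff(seq_len(N), spec$hidden)
  spk <- run$spikes[keep, , drop = FALSE]
  nz <- which(spk == 1L, arr.ind = TRUE)
  ens <- spike_ensemble(
    tibble::tibble(
      neuron_id = as.integer(nz[, 1]),
      spike_time_s = (nz[, 2] - 0.5) * spec$delta
    ),
    t_start = 0, t_end = n_bins * spec$delta, n_neurons = length(keep)
  )
  attr(ens, "clamp_fraction") <- clamp_fraction
  attr(ens, "seed") <- seed
  attr(ens, "network") <- spec$name
  ens
}

#' Ground-truth signed connectivity of a generative network
#'
#' Entry `[j, i]` is the sign of the summed lag kernel of edge `j -> i`
#' (`0` when absent). With `observed_only = TRUE` (default) hidden neurons
#' are dropped and the matrix relabelled like the simulated ensemble.
#'
#' @param spec A [network_spec()].
#' @param observed_only Drop hidden neurons?
#' @return Integer matrix, triggers in rows.
#' @export
truth_matrix <- function(spec, observed_only = TRUE) {
  N <- spec$n_neurons
  M <- matrix(0L, N, N)
  if (nrow(spec$edges)) {
    for (e in seq_len(nrow(spec$edges))) {
      M[spec$edges$trigger[e], spec$edges$target[e]] <- as.integer(sign(sum(spec$edges$lags[[e]])))
    }
  }
  if (observed_only && length(spec$hidden)) {
    keep <- setdiff(seq_len(N), spec$hidden)
    M <- M[keep, keep, drop = FALSE]
  }
  dimnames(M) <- list(trigger = seq_len(nrow(M)), target = seq_len(ncol(M)))
  M
}

#' Monte-Carlo verification of false-discovery-rate control
#'
#' Repeatedly simulates a ground-truth network, runs the full inference
#' pipeline (order selection and pairwise deviance tests with
#' Benjamini-Hochberg correction), and compares significant pairs with the
#' generator's edge set. The observed FDR at each level is the average over
#' replicates of `false positives / detected`, replicates with no detection
#' contributing zero.
#'
#' @param spec A [network_spec()] (its edges are the ground truth).
#' @param n_replicates Number of independent data sets.
#' @param levels Nominal FDR levels to test.
#' @param seed Base seed; replicate `r` uses `seed + r - 1`.
#' @param n_bins Bins per replicate.
#' @param W History-window duration for the fitted models, seconds.
#' @param candidates Candidate history orders for AIC selection.
#' @param orders Optional fixed per-neuron orders (skips selection).
#' @return A tibble of class `mc_fdr_result`: one row per level with
#'   `observed_fdr`, its Monte-Carlo standard error, and means of detected
#'   and false-positive counts. Per-replicate details are in the `details`
#'   attribute.
#' @export
mc_fdr_experiment <- function(spec, n_replicates = 20, levels = c(0.01, 0.05, 0.1),
                              seed = 1, n_bins = 100000, W = 0.002,
                              candidates = 1:6, orders = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  truth <- truth_matrix(spec) != 0L
  details <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    details[[r]] <- tryCatch(
      {
        ens <- simulate_ensemble(spec, n_bins, seed = seed + r - 1L)
        binned <- bin_spikes(ens, spec$delta)
        res <- infer_network(binned, W = W, orders = orders, candidates = candidates, q = max(levels))
        P <- p_matrix(res)
        purrr::map_dfr(levels, function(q) {
          mask <- fdr_correct(P, q)
          detected <- sum(mask)
          fp <- sum(mask & !truth)
          tibble::tibble(
            replicate = r, level = q, detected = detected, false_positives = fp,
            fdr = if (detected > 0) fp / detected else 0
          )
        })
      },
      error = function(e) {
        warn(sprintf("Replicate %d failed (%s); skipped.", r, conditionMessage(e)))
        NULL
      }
    )
  }
  details <- purrr::compact(details)
  if (length(details) < n_replicates / 2) abort("More than half of the replicates failed.")
  det <- dplyr::bind_rows(details)
  out <- det |>
    dplyr::group_by(level = .data$level) |>
    dplyr::summarise(
      observed_fdr = mean(.data$fdr),
      mc_se = stats::sd(.data$fdr) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      mean_detected = mean(.data$detected),
      mean_false_positives = mean(.data$false_positives),
      .groups = "drop"
    )
  structure(
    out,
    details = det, network = spec$name,
    class = c("mc_fdr_result", class(tibble::tibble()))
  )
}

#' @method print mc_fdr_result
#' @export
print.mc_fdr_result <- function(x, ...) {
  cat(sprintf(
    "<mc_fdr_result: network '%s', %d replicate(s)>\n",
    attr(x, "network"), max(x$n_replicates)
  ))
  NextMethod()
}
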