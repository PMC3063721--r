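#' Time-rescaled interspike intervals of a fitted intensity model
#'
#' By the time-rescaling theorem, if the fitted conditional intensity is the
#' true one, the integrals `tau = integral of lambda(t) dt` over successive
#' interspike intervals are independent unit-rate exponentials, so
#' `z = 1 - exp(-tau)` are uniform on `[0, 1)`. In discrete time the integral
#' is the sum of `lambda_k * delta` over the bins strictly after the previous
#' spike through the spike bin. Agreement with uniformity is summarised by a
#' Kolmogorov-Smirnov statistic against the uniform quantiles `(k - 0.5)/n`,
#' with the 95% band `1.36/sqrt(n)` for `n > 35` (a finite-sample corrected
#' constant for smaller `n`).
#'
#' @param model A [fit_cif()] model for the target neuron.
#' @param binned The [bin_spikes()] data it was fitted to.
#' @return An object of class `rescaled_times`: sorted `z`, interval count
#'   `n`, `ks_stat`, the 95% `bound`, and `within_95`.
#' @export
rescale_times <- function(model, binned) {
  stopifnot(inherits(model, "cif_model"), inherits(binned, "binned_ensemble"))
  fd <- build_design(binned, model$target, model$hw, excluded = model$excluded)
  mu <- exp(.cif_eta(model, fd))
  y <- fd$response
  spikes <- which(y == 1L)
  if (length(spikes) < 2) abort("Time rescaling needs at least 2 spikes in the fittable range.")
  M <- cumsum(mu)
  tau <- M[spikes[-1]] - M[spikes[-length(spikes)]]
  z <- sort(1 - exp(-tau))
  new_rescaled_times(z, model$target)
}

new_rescaled_times <- function(z, target = NA_integer_) {
  n <- length(z)
  u <- (seq_len(n) - 0.5) / n
  ks <- max(abs(z - u))
  bound <- ks_bound_95(n)
  structure(
    list(
      z = z, n = n, ks_stat = ks, bound = bound,
      within_95 = ks <= bound, target = target
    ),
    class = "rescaled_times"
  )
}

#' 95% Kolmogorov-Smirnov acceptance bound
#'
#' `1.36/sqrt(n)` for `n > 35`; for small samples the Stephens finite-sample
#' correction `1.36/(sqrt(n) + 0.12 + 0.11/sqrt(n))` is used.
#' @param n Number of rescaled intervals.
#' @export
ks_bound_95 <- function(n) {
  if (n > 35) 1.36 / sqrt(n) else 1.36 / (sqrt(n) + 0.12 + 0.11 / sqrt(n))
}

#' @method print rescaled_times
#' @export
print.rescaled_times <- function(x, ...) {
  cat(sprintf(
    "<rescaled_times: n = %d, KS = %.4f, 95%% bound = %.4f -> %s>\n",
    x$n, x$ks_stat, x$bound, if (x$within_95) "pass" else "FAIL"
  ))
  invisible(x)
}

#' @method tidy rescaled_times
#' @export
tidy.rescaled_times <- function(x, ...) {
  tibble::tibble(
    model_quantile = x$z,
    uniform_quantile = (seq_len(x$n) - 0.5) / x$n
  )
}

#' Kolmogorov-Smirnov goodness-of-fit summary
#'
#' @param rescaled A [rescale_times()] result.
#' @return One-row tibble: neuron, interval count, KS statistic, 95% bound
#'   and pass flag.
#' @export
ks_report <- function(rescaled) {
  stopifnot(inherits(rescaled, "rescaled_times"))
  tibble::tibble(
    neuron = rescaled$target,
    n = rescaled$n,
    ks_stat = rescaled$ks_stat,
    bound = rescaled$bound,
    pass = rescaled$within_95
  )
}

#' KS plot of rescaled times against the uniform reference
#'
#' The 45-degree line is perfect agreement; dashed lines are the 95%
#' acceptance band of the KS statistic.
#' @param object A [rescale_times()] result.
#' @param ... Unused.
#' @method autoplot rescaled_times
#' @export
autoplot.rescaled_times <- function(object, ...) {
  df <- tidy(object)
  b <- object$bound
  ggplot2::ggplot(df, ggplot2::aes(x = .data$uniform_quantile, y = .data$model_quantile)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = c(-b, b), linetype = "dashed") +
    ggplot2::geom_step(colour = "#d73027") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "uniform quantiles", y = "rescaled-time quantiles",
      subtitle = sprintf("neuron %s: KS = %.3f (95%% bound %.3f)", object$target, object$ks_stat, b)
    ) +
    ggplot2::theme_minimal()
}

#' Per-neuron KS goodness-of-fit table for full ensemble models
#'
#' Fits (or reuses) the full conditional-intensity model of each neuron and
#' reports its time-rescaling KS summary.
#'
#' @param binned A [bin_spikes()] result.
#' @param orders Integer vector of per-target history orders.
#' @param W Window duration in seconds.
#' @return Tibble with one row per neuron (see [ks_report()]).
#' @export
gof_table <- function(binned, orders, W = 0.002) {
  N <- nrow(binned$counts)
  orders <- as.integer(orders)
  if (length(orders) != N) abort("`orders` must give one history order per neuron.")
  purrr::map_dfr(seq_len(N), function(i) {
    hw <- history_windows(W, orders[i], binned$delta)
    res <- tryCatch(
      ks_report(rescale_times(fit_cif(binned, i, hw), binned)),
      error = function(e) {
        tibble::tibble(neuron = i, n = NA_integer_, ks_stat = NA_real_, bound = NA_real_, pass = NA)
      }
    )
    res
  })
}
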