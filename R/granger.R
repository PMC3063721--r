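#' Point-process log-likelihood ratio between nested intensity models
#'
#' The causal influence of a trigger neuron on a target is quantified by
#' `logLik(reduced) - logLik(full)`, where the reduced model re-optimises the
#' target's conditional intensity after structurally excluding the trigger's
#' history. The ratio is non-positive up to solver tolerance; values within
#' `1e-6 * |logLik(full)|` above zero are clipped to zero, larger positive
#' values signal a failed re-fit and raise an error.
#'
#' @param full,reduced [fit_cif()] models for the same target and windows;
#'   `reduced` must exclude exactly one source that `full` includes.
#' @param fit_data_full,fit_data_reduced Optional [build_design()] data; when
#'   supplied, log-likelihoods are re-evaluated from the data instead of
#'   taken from the stored fits.
#' @return Scalar log-likelihood ratio, `<= 0`.
#' @export
log_likelihood_ratio <- function(full, reduced, fit_data_full = NULL, fit_data_reduced = NULL) {
  stopifnot(inherits(full, "cif_model"), inherits(reduced, "cif_model"))
  if (!is.null(full$excluded) || is.null(reduced$excluded)) {
    abort("Models are not nested: `full` must include all sources and `reduced` exclude exactly one.")
  }
  if (full$target != reduced$target || full$hw$R != reduced$hw$R || full$hw$w != reduced$hw$w) {
    abort("Models are not nested: target or history windows differ.")
  }
  if (!full$converged || !reduced$converged) {
    abort("Both models must have converged.")
  }
  ll_full <- if (is.null(fit_data_full)) full$loglik else log_likelihood(full, fit_data_full)
  ll_red <- if (is.null(fit_data_reduced)) reduced$loglik else log_likelihood(reduced, fit_data_reduced)
  llr <- ll_red - ll_full
  tol <- 1e-6 * (abs(ll_full) + 1)
  if (llr > tol) {
    abort(sprintf("Log-likelihood ratio %.3g > 0 beyond tolerance: the reduced re-fit failed.", llr))
  }
  min(llr, 0)
}

#' Sign of a trigger neuron's averaged influence on a target
#'
#' The excitatory/inhibitory character of an interaction is the sign of the
#' unweighted mean of the full model's history coefficients for the trigger.
#' For self-interactions the first window's coefficient is omitted from the
#' mean, because the absolute refractory period forces it negative regardless
#' of the neuron's net self-coupling (with `R = 1` nothing would remain, so
#' the sole coefficient is used). A mean of exactly zero maps to `+1` with a
#' message.
#'
#' @param full A converged full [fit_cif()] model.
#' @param trigger Trigger neuron index.
#' @return `+1` or `-1`.
#' @export
causal_sign <- function(full, trigger) {
  stopifnot(inherits(full, "cif_model"))
  if (!is.null(full$excluded)) abort("`causal_sign` needs the full model, not a reduced one.")
  pos <- match(trigger, full$sources)
  if (is.na(pos)) abort("`trigger` is not a source of this model.")
  cf <- full$gamma[pos, ]
  if (trigger == full$target && length(cf) > 1) cf <- cf[-1]
  m <- mean(cf)
  if (m == 0) {
    inform("Averaged influence is exactly zero; sign defaults to +1.")
    return(1)
  }
  if (m > 0) 1 else -1
}

#' Signed Granger causality measure
#'
#' Combines the magnitude of the log-likelihood ratio with the interaction
#' sign: `Gamma = sign * (-llr)`. Positive values indicate an excitatory
#' influence of the trigger on the target, negative values an inhibitory one,
#' zero no detected interaction.
#'
#' @param llr Log-likelihood ratio (`<= 0`), from [log_likelihood_ratio()].
#' @param sign `+1` or `-1`, from [causal_sign()].
#' @return The signed causality strength.
#' @export
causality_measure <- function(llr, sign) {
  if (llr > 1e-6) abort("`llr` must be <= 0.")
  if (!sign %in% c(-1, 1)) abort("`sign` must be -1 or +1.")
  sign * (-min(llr, 0))
}

#' Chi-squared test of a deviance difference
#'
#' The deviance difference between the full and reduced models equals
#' `-2 * llr` and is asymptotically chi-squared with degrees of freedom equal
#' to the number of excluded coefficients (the target's history order `R`)
#' when the null of no influence holds.
#'
#' @param llr Log-likelihood ratio (`<= 0`).
#' @param dof Degrees of freedom (number of excluded coefficients), `>= 1`.
#' @return Upper-tail p-value.
#' @export
deviance_test <- function(llr, dof) {
  dof <- as.integer(dof)
  if (is.na(dof) || dof < 1L) abort("`dof` must be an integer >= 1.")
  if (llr > 1e-6) abort("Negative deviance difference beyond tolerance: the reduced re-fit failed.")
  stat <- max(-2 * llr, 0)
  pchisq(stat, df = dof, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up rejection mask
#'
#' Sorts the finite p-values ascending, finds the largest rank `i` with
#' `p_(i) <= i * q / m` (`m` = number of finite p-values, self-tests
#' included), and rejects all hypotheses with smaller-or-equal ranks. `NA`
#' entries (failed fits) are ignored and never rejected.
#'
#' @param p_values Numeric vector or matrix of p-values, possibly with `NA`.
#' @param q Target false-discovery-rate level, in `(0, 1)`.
#' @return Logical rejection mask of the same shape as `p_values`.
#' @export
fdr_correct <- function(p_values, q) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) abort("`q` must lie in (0, 1).")
  p <- as.vector(p_values)
  reject <- rep(FALSE, length(p))
  fin <- which(is.finite(p))
  m <- length(fin)
  if (m > 0) {
    ord <- order(p[fin])
    ps <- p[fin][ord]
    below <- which(ps <= seq_len(m) * q / m)
    if (length(below)) reject[fin[ord[seq_len(max(below))]]] <- TRUE
  }
  if (is.matrix(p_values)) {
    reject <- matrix(reject, nrow = nrow(p_values), dimnames = dimnames(p_values))
  }
  reject
}

#' Infer the directed causal network of an ensemble
#'
#' Runs the full pairwise analysis: for every target neuron a full
#' conditional-intensity model over the whole ensemble's history is fitted
#' (order selected by AIC unless supplied); for every ordered pair
#' (trigger -> target), including self-pairs, the trigger's history is
#' structurally excluded, the model re-optimised, and the log-likelihood
#' ratio converted into a signed causality strength, a deviance difference
#' and a chi-squared p-value with `dof = R_target`. Benjamini-Hochberg
#' correction at level `q` over all ordered pairs then yields a trichotomous
#' connectivity map: `+1` excitatory, `-1` inhibitory, `0` none, `NA` for
#' pairs whose fit failed (failures never abort the rest of the matrix).
#'
#' @param binned A [bin_spikes()] result.
#' @param W History-window duration in seconds (default 2 ms).
#' @param orders Optional integer vector of per-target history orders; when
#'   `NULL` they are selected by [select_order_aic()] over `candidates`.
#' @param candidates Candidate orders for AIC selection.
#' @param q False-discovery-rate level (default 0.05).
#' @return A tibble of class `causality_result` with one row per ordered pair:
#'   `trigger`, `target`, `gamma` (signed strength), `deviance`, `dof`,
#'   `p_value`, `q_value` (BH-adjusted), `significant`, `connectivity`.
#'   Attributes carry the per-target `orders`, `q`, `W`, `delta` and the AIC
#'   selection tables.
#' @export
infer_network <- function(binned, W = 0.002, orders = NULL, candidates = 1:10, q = 0.05) {
  stopifnot(inherits(binned, "binned_ensemble"))
  N <- nrow(binned$counts)
  selection <- NULL
  if (is.null(orders)) {
    sel <- purrr::map(seq_len(N), function(i) select_order_aic(binned, i, W, candidates))
    orders <- purrr::map_int(sel, as.integer)
    selection <- purrr::map(sel, attr, "aic_table")
  }
  orders <- as.integer(orders)
  if (length(orders) != N) abort("`orders` must give one history order per neuron.")
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    R <- orders[i]
    hw <- history_windows(W, R, binned$delta)
    fd <- build_design(binned, i, hw)
    y <- fd$response
    Xs <- Matrix::Matrix(fd$design, sparse = TRUE)
    full <- tryCatch(.fit_pp_glm(Xs, y), error = function(e) NULL)
    full_ok <- !is.null(full) && full$converged && sum(y) >= 1
    gamma_full <- if (full_ok) matrix(full$coefficients[-1], nrow = N, byrow = TRUE) else NULL
    out <- tibble::tibble(
      trigger = seq_len(N), target = i,
      gamma = NA_real_, deviance = NA_real_, dof = R, p_value = NA_real_
    )
    if (full_ok) {
      for (j in seq_len(N)) {
        cols <- setdiff(seq_len(ncol(Xs)), 1L + (j - 1L) * R + seq_len(R))
        red <- tryCatch(.fit_pp_glm(Xs[, cols, drop = FALSE], y), error = function(e) NULL)
        if (is.null(red) || !red$converged) next
        llr <- red$loglik - full$loglik
        if (llr > 1e-6 * (abs(full$loglik) + 1)) next # failed re-fit: leave NA
        llr <- min(llr, 0)
        cf <- gamma_full[j, ]
        if (j == i && R > 1) cf <- cf[-1]
        sgn <- if (mean(cf) >= 0) 1 else -1
        out$gamma[j] <- sgn * (-llr)
        out$deviance[j] <- -2 * llr
        out$p_value[j] <- pchisq(-2 * llr, df = R, lower.tail = FALSE)
      }
    }
    rows[[i]] <- out
  }
  res <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$target, .data$trigger)
  rej <- fdr_correct(res$p_value, q)
  res$q_value <- .bh_adjust(res$p_value)
  res$significant <- rej
  res$connectivity <- dplyr::case_when(
    is.na(res$p_value) ~ NA_real_,
    !rej ~ 0,
    res$gamma >= 0 ~ 1,
    TRUE ~ -1
  )
  structure(
    res,
    orders = orders, q = q, W = W, delta = binned$delta,
    n_neurons = N, n_bins = ncol(binned$counts),
    selection = selection,
    class = c("causality_result", class(tibble::tibble()))
  )
}

# BH adjusted p-values over the finite entries (NA preserved)
.bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  fin <- which(is.finite(p))
  if (length(fin)) out[fin] <- stats::p.adjust(p[fin], method = "BH")
  out
}

#' @method print causality_result
#' @export
print.causality_result <- function(x, ...) {
  cat(sprintf(
    "<causality_result: %d neurons, q = %g, %d significant link(s), orders = %s>\n",
    attr(x, "n_neurons"), attr(x, "q"), sum(x$significant, na.rm = TRUE),
    paste(attr(x, "orders"), collapse = ",")
  ))
  NextMethod()
}

#' @method tidy causality_result
#' @export
tidy.causality_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance causality_result
#' @export
glance.causality_result <- function(x, ...) {
  tibble::tibble(
    n_neurons = attr(x, "n_neurons"),
    q = attr(x, "q"),
    n_tests = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_excitatory = sum(x$connectivity == 1, na.rm = TRUE),
    n_inhibitory = sum(x$connectivity == -1, na.rm = TRUE),
    n_failed = sum(is.na(x$p_value))
  )
}

.result_matrix <- function(x, col) {
  N <- attr(x, "n_neurons")
  M <- matrix(NA_real_, N, N, dimnames = list(trigger = seq_len(N), target = seq_len(N)))
  M[cbind(x$trigger, x$target)] <- x[[col]]
  M
}

#' Matrix views of a causality result
#'
#' Rows are trigger neurons, columns targets.
#' @param x A [infer_network()] result.
#' @return A numeric matrix.
#' @export
gamma_matrix <- function(x) .result_matrix(x, "gamma")

#' @rdname gamma_matrix
#' @export
deviance_matrix <- function(x) .result_matrix(x, "deviance")

#' @rdname gamma_matrix
#' @export
p_matrix <- function(x) .result_matrix(x, "p_value")

#' @rdname gamma_matrix
#' @export
connectivity_matrix <- function(x) .result_matrix(x, "connectivity")

#' Heat-map of an inferred causal network
#'
#' @param object A [infer_network()] result.
#' @param type `"connectivity"` (trichotomous map) or `"gamma"` (signed
#'   strengths).
#' @param ... Unused.
#' @return A ggplot object; triggers on the y-axis (top-down), targets on the
#'   x-axis.
#' @method autoplot causality_result
#' @export
autoplot.causality_result <- function(object, type = c("connectivity", "gamma"), ...) {
  type <- match.arg(type)
  df <- tibble::as_tibble(object)
  df$trigger_f <- factor(df$trigger, levels = rev(seq_len(attr(object, "n_neurons"))))
  df$target_f <- factor(df$target)
  if (type == "connectivity") {
    df$class <- factor(
      dplyr::case_when(
        is.na(df$connectivity) ~ "failed",
        df$connectivity > 0 ~ "excitatory",
        df$connectivity < 0 ~ "inhibitory",
        TRUE ~ "none"
      ),
      levels = c("excitatory", "inhibitory", "none", "failed")
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$target_f, y = .data$trigger_f, fill = .data$class)) +
      ggplot2::geom_tile(colour = "grey30") +
      ggplot2::scale_fill_manual(
        values = c(excitatory = "#d73027", inhibitory = "#4575b4", none = "#66bd63", failed = "grey80"),
        drop = FALSE, name = NULL
      ) +
      ggplot2::labs(x = "target neuron", y = "trigger neuron") +
      ggplot2::coord_fixed() +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$target_f, y = .data$trigger_f, fill = .data$gamma)) +
      ggplot2::geom_tile(colour = "grey30") +
      ggplot2::scale_fill_gradient2(low = "#4575b4", mid = "white", high = "#d73027", name = "Gamma") +
      ggplot2::labs(x = "target neuron", y = "trigger neuron") +
      ggplot2::coord_fixed() +
      ggplot2::theme_minimal()
  }
}

#' Write the matrices of a causality result as CSV files
#'
#' Writes `gamma.csv`, `deviance.csv`, `p_values.csv` and `connectivity.csv`
#' (rows triggers, columns targets, neuron-id headers; connectivity entries
#' are -1/0/1 integers with `NA` for failed fits).
#'
#' @param x A [infer_network()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_causality_csv <- function(x, dir) {
  stopifnot(inherits(x, "causality_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  emit <- function(M, name, integerish = FALSE) {
    df <- as.data.frame(M)
    names(df) <- paste0("target_", seq_len(ncol(M)))
    if (integerish) df[] <- lapply(df, function(v) ifelse(is.na(v), NA_integer_, as.integer(v)))
    df <- cbind(trigger = seq_len(nrow(M)), df)
    readr::write_csv(tibble::as_tibble(df), file.path(dir, name), na = "NA")
  }
  emit(gamma_matrix(x), "gamma.csv")
  emit(deviance_matrix(x), "deviance.csv")
  emit(p_matrix(x), "p_values.csv")
  emit(connectivity_matrix(x), "connectivity.csv", integerish = TRUE)
  invisible(dir)
}
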