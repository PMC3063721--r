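#' Design matrix and response for one target neuron's history GLM
#'
#' Lays out the covariates of the log-linear conditional-intensity model: an
#' intercept plus, for every included source neuron, the spike counts in its
#' `R` causal history windows of width `W` (see [window_counts()]). Rows are
#' the fittable bins, i.e. those with a complete `R*W` history; the first
#' `R*W/delta` bins are excluded. With `excluded` set, the named source
#' contributes no columns at all: the reduced model is structurally smaller,
#' not a zeroed copy.
#'
#' @param binned A [bin_spikes()] result.
#' @param target Target neuron index (the response).
#' @param hw A [history_windows()] specification.
#' @param excluded Optional index of one source neuron whose history is left
#'   out (may equal `target` to drop self-history).
#' @param kmin Optional 0-based first fittable bin; defaults to `R*W/delta`.
#'   Supply a larger value to put models of different order on a common
#'   fittable range.
#'
#' @return A list of class `cif_fit_data`: `response` (0/1 vector), `design`
#'   (dense matrix, first column the intercept), `bins` (0-based bin index of
#'   each row), `col_map` (tibble mapping columns to source/window), plus the
#'   call geometry (`target`, `excluded`, `hw`).
#' @export
build_design <- function(binned, target, hw, excluded = NULL, kmin = NULL) {
  stopifnot(inherits(binned, "binned_ensemble"), inherits(hw, "history_windows"))
  N <- nrow(binned$counts)
  K <- ncol(binned$counts)
  if (target < 1 || target > N) abort("`target` out of range.")
  if (!is.null(excluded) && (excluded < 1 || excluded > N)) abort("`excluded` source index out of range.")
  w <- hw$w
  R <- hw$R
  kmin <- as.integer(kmin %||% (R * w))
  if (kmin < R * w) abort("`kmin` leaves bins with incomplete history.")
  if (K <= kmin) abort("Too few bins: need more bins than R*W/delta.")
  ks <- (kmin + 1L):K # 1-based columns of the count matrix
  sources <- setdiff(seq_len(N), excluded)
  X <- matrix(0, nrow = length(ks), ncol = 1L + length(sources) * R)
  X[, 1] <- 1
  for (jj in seq_along(sources)) {
    S <- c(0, cumsum(binned$counts[sources[jj], ]))
    for (r in seq_len(R)) {
      X[, 1L + (jj - 1L) * R + r] <- S[ks - (r - 1L) * w] - S[ks - r * w]
    }
  }
  col_map <- tibble::tibble(
    col = seq_len(ncol(X)),
    source = c(NA_integer_, rep(sources, each = R)),
    window = c(NA_integer_, rep(seq_len(R), times = length(sources)))
  )
  structure(
    list(
      response = binned$counts[target, ks],
      design = X,
      bins = ks - 1L,
      col_map = col_map,
      target = as.integer(target),
      excluded = if (is.null(excluded)) NULL else as.integer(excluded),
      hw = hw,
      delta = binned$delta
    ),
    class = "cif_fit_data"
  )
}

# Discrete point-process log-likelihood sum(y*log(mu) - mu) with mu = lambda*delta
# floored at `guard` inside the log. The o(delta) multi-spike term vanishes for
# 0/1 responses and is dropped.
.pp_loglik <- function(eta, y, guard = 1e-12) {
  mu <- exp(eta)
  sum(y * pmax(eta, log(guard)) - mu)
}

# Fisher-scoring/IRLS for the log-link count regression. Deterministic start:
# intercept at log(mean response), history coefficients at zero. Step-halving
# keeps the likelihood ascent monotone; |coef| > cap flags non-convergence
# (practical separation guard).
.fit_pp_glm <- function(X, y, tol = 1e-8, maxit = 100L, cap = 30, guard = 1e-12) {
  p <- ncol(X)
  # all-zero history columns (e.g. a silent source) carry no information and
  # would make the Fisher matrix singular; fit without them and report a
  # zero coefficient
  nnz <- if (inherits(X, "sparseMatrix")) diff(X@p) else colSums(X != 0)
  keep <- c(TRUE, nnz[-1] > 0)
  if (!all(keep)) {
    sub <- .fit_pp_glm(X[, keep, drop = FALSE], y, tol, maxit, cap, guard)
    beta <- se <- numeric(p)
    beta[keep] <- sub$coefficients
    se[keep] <- sub$se
    se[!keep] <- NA_real_
    return(list(
      coefficients = beta, loglik = sub$loglik, se = se,
      converged = sub$converged, iterations = sub$iterations
    ))
  }
  beta <- c(log(max(mean(y), guard)), rep(0, p - 1L))
  eta <- drop(X %*% beta)
  ll <- .pp_loglik(eta, y, guard)
  converged <- FALSE
  it <- 0L
  fail <- FALSE
  while (it < maxit) {
    it <- it + 1L
    mu <- exp(eta)
    g <- drop(Matrix::crossprod(X, y - mu))
    H <- as.matrix(Matrix::crossprod(X, X * mu))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      fail <- TRUE
      break
    }
    # step-halving line search on the log-likelihood
    ok <- FALSE
    for (h in 0:12) {
      cand <- beta + step / 2^h
      eta_c <- drop(X %*% cand)
      ll_c <- .pp_loglik(eta_c, y, guard)
      if (is.finite(ll_c) && ll_c >= ll - 1e-10) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      fail <- TRUE
      break
    }
    delta_ll <- ll_c - ll
    beta <- cand
    eta <- eta_c
    ll <- ll_c
    if (abs(delta_ll) < tol * (abs(ll) + 1e-10)) {
      converged <- TRUE
      break
    }
  }
  se <- rep(NA_real_, p)
  if (!fail) {
    H <- as.matrix(Matrix::crossprod(X, X * exp(eta)))
    Hi <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
    if (!is.null(Hi)) se <- sqrt(pmax(diag(Hi), 0))
  }
  list(
    coefficients = beta, loglik = ll, se = se,
    converged = converged && !fail && max(abs(beta)) < cap,
    iterations = it
  )
}

#' Fit the conditional-intensity GLM for one target neuron
#'
#' Maximises the discrete point-process likelihood of the target's spike
#' train under the log-linear conditional-intensity model: `log(lambda[k] *
#' delta) = beta0 + sum over sources j and windows r of gamma[j, r] *
#' count[j, r, k]`. Fitting is Fisher scoring (equivalently IRLS for the
#' canonical log link) from a deterministic start (`beta0 = log` mean rate,
#' history coefficients zero), to relative tolerance `1e-8`. A reduced model
#' (`excluded` set) re-optimises all remaining coefficients; the excluded
#' source's coefficients are structurally absent.
#'
#' @inheritParams build_design
#' @param design Optionally, a precomputed [build_design()] result consistent
#'   with the other arguments (saves rebuilding in loops).
#' @param baseline_only If `TRUE`, fit only the intercept (all history columns
#'   suppressed); the maximum-likelihood baseline is then the mean spike count
#'   per bin. The fittable range is still that implied by `hw`, so the fit is
#'   comparable with history models.
#'
#' @return An object of class `cif_model`: coefficients (`beta0`, `gamma` as
#'   a sources-by-windows matrix), standard errors, the maximised
#'   log-likelihood, parameter count, convergence flag, and geometry.
#' @export
fit_cif <- function(binned, target, hw, excluded = NULL, design = NULL,
                    baseline_only = FALSE) {
  fd <- design %||% build_design(binned, target, hw, excluded = excluded)
  stopifnot(inherits(fd, "cif_fit_data"))
  y <- fd$response
  if (sum(y) < 1) {
    abort(sprintf("Degenerate response: target neuron %d has no spikes in the fittable range.", fd$target))
  }
  X <- fd$design
  col_map <- fd$col_map
  if (baseline_only) {
    X <- X[, 1, drop = FALSE]
    col_map <- col_map[1, ]
  }
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  fit <- .fit_pp_glm(Xs, y)
  sources <- col_map$source[-1]
  R <- fd$hw$R
  gamma <- matrix(fit$coefficients[-1], ncol = R, byrow = TRUE)
  gamma_se <- matrix(fit$se[-1], ncol = R, byrow = TRUE)
  rownames(gamma) <- rownames(gamma_se) <- unique(sources)
  structure(
    list(
      target = fd$target,
      beta0 = fit$coefficients[1],
      gamma = gamma,
      se_beta0 = fit$se[1],
      se_gamma = gamma_se,
      sources = unique(sources),
      excluded = fd$excluded,
      hw = fd$hw,
      delta = fd$delta,
      loglik = fit$loglik,
      n_params = length(fit$coefficients),
      n_bins_fit = length(y),
      n_spikes_fit = sum(y),
      converged = fit$converged,
      iterations = fit$iterations,
      baseline_only = baseline_only
    ),
    class = "cif_model"
  )
}

#' @method print cif_model
#' @export
print.cif_model <- function(x, ...) {
  cat(sprintf(
    "<cif_model: target %d, R = %d, W = %g s%s, logLik = %.2f, %d params%s>\n",
    x$target, x$hw$R, x$hw$W,
    if (!is.null(x$excluded)) sprintf(", excluding source %d", x$excluded) else "",
    x$loglik, x$n_params,
    if (x$converged) "" else ", NOT CONVERGED"
  ))
  invisible(x)
}

# full coefficient vector in design-column order
.cif_coef <- function(model) {
  if (model$baseline_only) {
    return(model$beta0)
  }
  c(model$beta0, as.vector(t(model$gamma)))
}

# linear predictor (log of lambda*delta) of a model on its fit data
.cif_eta <- function(model, fit_data) {
  same_excl <- identical(
    if (is.null(model$excluded)) NULL else as.integer(model$excluded),
    if (is.null(fit_data$excluded)) NULL else as.integer(fit_data$excluded)
  )
  if (!same_excl || !identical(model$hw$R, fit_data$hw$R) || !identical(model$hw$w, fit_data$hw$w)) {
    abort("`model` and `fit_data` disagree on history windows or exclusion.")
  }
  X <- if (model$baseline_only) fit_data$design[, 1, drop = FALSE] else fit_data$design
  drop(X %*% .cif_coef(model))
}

#' Discrete point-process log-likelihood of a fitted model
#'
#' Evaluates `sum_k [dN_k * log(lambda_k * delta) - lambda_k * delta]` over
#' the fittable bins, the discrete-time form of the point-process likelihood
#' for at most one spike per bin. `lambda_k * delta` is floored at `1e-12`
#' inside the logarithm.
#'
#' @param model A [fit_cif()] result.
#' @param fit_data The [build_design()] data the model applies to (same
#'   target, windows and exclusion).
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(model, fit_data) {
  stopifnot(inherits(model, "cif_model"), inherits(fit_data, "cif_fit_data"))
  .pp_loglik(.cif_eta(model, fit_data), fit_data$response)
}

#' @export
logLik.cif_model <- function(object, ...) {
  structure(object$loglik,
    df = object$n_params, nobs = object$n_bins_fit,
    class = "logLik"
  )
}

#' @method tidy cif_model
#' @export
tidy.cif_model <- function(x, ...) {
  R <- x$hw$R
  est <- tibble::tibble(
    term = c("(baseline)", sprintf("src%d_w%d", rep(x$sources, each = R), rep(seq_len(R), length(x$sources)))),
    source = c(NA_integer_, rep(x$sources, each = R)),
    window = c(NA_integer_, rep(seq_len(R), length(x$sources))),
    estimate = .cif_coef(x),
    std.error = c(x$se_beta0, as.vector(t(x$se_gamma)))
  )
  if (x$baseline_only) est[1, ] else est
}

#' @method glance cif_model
#' @export
glance.cif_model <- function(x, ...) {
  tibble::tibble(
    target = x$target, R = x$hw$R, W = x$hw$W,
    logLik = x$loglik, AIC = -2 * x$loglik + 2 * x$n_params,
    n_params = x$n_params, n_bins = x$n_bins_fit, n_spikes = x$n_spikes_fit,
    converged = x$converged
  )
}

#' @export
AIC.cif_model <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$n_params
}

#' Select the history order by Akaike's information criterion
#'
#' Fits the target's conditional-intensity model at each candidate order `R`
#' and picks the one minimising `AIC = -2 logL + 2 p` with `p = 1 + N*R`
#' parameters. All candidates are evaluated on the common fittable range
#' implied by the largest candidate, so their likelihoods are comparable;
#' ties break toward the smaller order.
#'
#' @inheritParams build_design
#' @param W Window duration in seconds.
#' @param candidates Integer vector of candidate orders.
#' @return The selected order (integer) with an `"aic_table"` attribute: a
#'   tibble of candidate, log-likelihood, AIC and convergence flag.
#' @export
select_order_aic <- function(binned, target, W, candidates = 1:10) {
  candidates <- sort(unique(as.integer(candidates)))
  if (!length(candidates) || any(candidates < 1L)) abort("`candidates` must be positive integers.")
  N <- nrow(binned$counts)
  Rmax <- max(candidates)
  hw_max <- history_windows(W, Rmax, binned$delta)
  fd <- build_design(binned, target, hw_max)
  y <- fd$response
  if (sum(y) < 1) abort(sprintf("Degenerate response: target neuron %d has no spikes in the fittable range.", target))
  Xs <- Matrix::Matrix(fd$design, sparse = TRUE)
  rows <- purrr::map(candidates, function(R) {
    cols <- c(1L, 1L + rep((seq_len(N) - 1L) * Rmax, each = R) + seq_len(R))
    fit <- tryCatch(.fit_pp_glm(Xs[, cols, drop = FALSE], y), error = function(e) NULL)
    if (is.null(fit)) {
      warn(sprintf("Candidate R = %d failed to fit for target %d; skipped.", R, target))
      return(tibble::tibble(R = R, loglik = NA_real_, aic = NA_real_, converged = FALSE))
    }
    if (!fit$converged) {
      warn(sprintf("Candidate R = %d did not converge for target %d; skipped.", R, target))
    }
    tibble::tibble(
      R = R, loglik = fit$loglik,
      aic = -2 * fit$loglik + 2 * length(cols),
      converged = fit$converged
    )
  })
  tab <- dplyr::bind_rows(rows)
  ok <- tab$converged & is.finite(tab$aic)
  if (!any(ok)) abort(sprintf("All candidate orders failed for target %d.", target))
  chosen <- tab$R[ok][which.min(tab$aic[ok])]
  structure(as.integer(chosen), aic_table = tab)
}

#' Serialise a fitted conditional-intensity model to JSON
#'
#' @param model A [fit_cif()] result.
#' @param path Output file.
#' @return `path`, invisibly; `read_cif_json()` returns the reconstructed
#'   `cif_model`.
#' @export
write_cif_json <- function(model, path) {
  stopifnot(inherits(model, "cif_model"))
  doc <- list(
    target = model$target,
    W = model$hw$W, R = model$hw$R, delta = model$delta,
    excluded = model$excluded,
    beta0 = model$beta0,
    sources = model$sources,
    gamma = apply(model$gamma, 1, identity, simplify = FALSE),
    loglik = model$loglik,
    n_params = model$n_params,
    n_bins_fit = model$n_bins_fit,
    n_spikes_fit = model$n_spikes_fit,
    converged = model$converged,
    baseline_only = model$baseline_only
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cif_json
#' @export
read_cif_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  gamma <- do.call(rbind, doc$gamma)
  rownames(gamma) <- doc$sources
  structure(
    list(
      target = as.integer(doc$target),
      beta0 = doc$beta0,
      gamma = gamma,
      se_beta0 = NA_real_,
      se_gamma = matrix(NA_real_, nrow(gamma), ncol(gamma)),
      sources = as.integer(doc$sources),
      excluded = if (is.null(doc$excluded)) NULL else as.integer(doc$excluded),
      hw = history_windows(doc$W, doc$R, doc$delta),
      delta = doc$delta,
      loglik = doc$loglik,
      n_params = as.integer(doc$n_params),
      n_bins_fit = as.integer(doc$n_bins_fit),
      n_spikes_fit = as.integer(doc$n_spikes_fit),
      converged = doc$converged,
      iterations = NA_integer_,
      baseline_only = isTRUE(doc$baseline_only)
    ),
    class = "cif_model"
  )
}
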