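#' Ensemble spike trains as a tidy event table
#'
#' Builds a validated ensemble of spike trains from a two-column table of
#' events. The ensemble is the event-time (point-process) representation of
#' `n_neurons` simultaneously recorded neurons over the observation interval
#' `[t_start, t_end)`; all downstream modelling starts from it.
#'
#' @param spikes A data frame with columns `neuron_id` (positive integers,
#'   labelling neurons `1..n_neurons`) and `spike_time_s` (event times in
#'   seconds). Rows may be in any order; times must be strictly increasing
#'   within each neuron.
#' @param t_start,t_end Observation interval bounds in seconds. Every spike
#'   must lie in `[t_start, t_end)`. `t_end` defaults to the smallest
#'   millisecond boundary past the last spike.
#' @param n_neurons Number of neurons in the ensemble. Defaults to the largest
#'   `neuron_id` present; pass explicitly when trailing neurons are silent.
#'
#' @return A tibble of class `spike_ensemble` with columns `neuron_id` and
#'   `spike_time_s`, sorted by neuron then time, carrying `t_start`, `t_end`
#'   and `n_neurons` attributes.
#' @seealso [bin_spikes()], [read_spike_csv()]
#' @export
#' @examples
#' spike_ensemble(
#'   data.frame(neuron_id = c(1, 1, 2), spike_time_s = c(0.002, 0.015, 0.0071)),
#'   t_start = 0, t_end = 0.1
#' )
spike_ensemble <- function(spikes, t_start = 0, t_end = NULL, n_neurons = NULL) {
  spikes <- tibble::as_tibble(spikes)
  if (!setequal(names(spikes), c("neuron_id", "spike_time_s"))) {
    abort(paste0(
      "`spikes` must have exactly the columns `neuron_id` and `spike_time_s`, not: ",
      paste(names(spikes), collapse = ", ")
    ))
  }
  spikes$neuron_id <- as.integer(spikes$neuron_id)
  spikes$spike_time_s <- as.double(spikes$spike_time_s)
  if (nrow(spikes) > 0 && any(spikes$neuron_id < 1L)) {
    abort("`neuron_id` must be a positive integer label.")
  }
  n_neurons <- as.integer(n_neurons %||% if (nrow(spikes)) max(spikes$neuron_id) else 0L)
  if (n_neurons < 1L) {
    abort("An ensemble needs at least one neuron; got an empty table and no `n_neurons`.")
  }
  if (nrow(spikes) > 0 && max(spikes$neuron_id) > n_neurons) {
    abort("`neuron_id` exceeds `n_neurons`.")
  }
  if (is.null(t_end)) {
    t_end <- if (nrow(spikes)) ceiling((max(spikes$spike_time_s) + 1e-9) * 1e3) / 1e3 else t_start + 1e-3
  }
  if (!(t_end > t_start)) abort("`t_end` must exceed `t_start`.")
  spikes <- dplyr::arrange(spikes, .data$neuron_id, .data$spike_time_s)
  if (nrow(spikes)) {
    if (any(spikes$spike_time_s < t_start | spikes$spike_time_s >= t_end)) {
      abort("All spike times must lie in [t_start, t_end).")
    }
    dup <- spikes |>
      dplyr::group_by(.data$neuron_id) |>
      dplyr::summarise(bad = any(diff(.data$spike_time_s) <= 0), .groups = "drop")
    if (any(dup$bad)) {
      abort(paste0(
        "Spike times must be strictly increasing within each neuron; offending neuron(s): ",
        paste(dup$neuron_id[dup$bad], collapse = ", ")
      ))
    }
  }
  new_spike_ensemble(spikes, t_start, t_end, n_neurons)
}

new_spike_ensemble <- function(spikes, t_start, t_end, n_neurons) {
  structure(
    spikes,
    t_start = as.double(t_start),
    t_end = as.double(t_end),
    n_neurons = as.integer(n_neurons),
    class = c("spike_ensemble", class(tibble::tibble()))
  )
}

#' @method print spike_ensemble
#' @export
print.spike_ensemble <- function(x, ...) {
  cat(sprintf(
    "<spike_ensemble: %d neurons, %d spikes, t = [%g, %g) s>\n",
    attr(x, "n_neurons"), nrow(x), attr(x, "t_start"), attr(x, "t_end")
  ))
  NextMethod()
}

#' @method glance spike_ensemble
#' @export
glance.spike_ensemble <- function(x, ...) {
  dur <- attr(x, "t_end") - attr(x, "t_start")
  tibble::tibble(
    n_neurons = attr(x, "n_neurons"),
    n_spikes = nrow(x),
    t_start = attr(x, "t_start"),
    t_end = attr(x, "t_end"),
    mean_rate_hz = nrow(x) / attr(x, "n_neurons") / dur
  )
}

#' Discretise an ensemble into per-bin spike indicators
#'
#' Partitions the observation interval into `K` bins of width `delta` and
#' marks, for each neuron, whether a spike occurred in each bin. Bins are
#' half-open and 0-based: bin `k` covers `[t_start + k*delta,
#' t_start + (k+1)*delta)`, so a spike exactly on a boundary belongs to the
#' later bin. The bin width is meant to be small enough that a neuron spikes
#' at most once per bin; two same-neuron spikes in one bin are an error
#' unless `collapse_duplicates = TRUE`.
#'
#' @param x A [spike_ensemble()].
#' @param delta Bin width in seconds (default 1 ms). The observation interval
#'   must be a whole number of bins (to rounding tolerance).
#' @param collapse_duplicates If `TRUE`, multiple same-neuron spikes falling
#'   in one bin are collapsed to a single indicator with a warning reporting
#'   how many events were dropped; if `FALSE` (default), this is an error
#'   naming the neuron and bin.
#'
#' @return An object of class `binned_ensemble`: a list with `counts` (an
#'   `n_neurons x K` 0/1 integer matrix), `delta`, `t_start` and `neuron_ids`.
#' @export
bin_spikes <- function(x, delta = 0.001, collapse_duplicates = FALSE) {
  stopifnot(inherits(x, "spike_ensemble"))
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    abort("`delta` must be a single positive number of seconds.")
  }
  t_start <- attr(x, "t_start")
  t_end <- attr(x, "t_end")
  kf <- (t_end - t_start) / delta
  K <- round(kf)
  if (K < 1 || abs(kf - K) > 1e-6 * max(1, K)) {
    abort("(t_end - t_start) must be an integer number of bins of width `delta`.")
  }
  N <- attr(x, "n_neurons")
  counts <- matrix(0L, nrow = N, ncol = K)
  if (nrow(x)) {
    bin <- floor((x$spike_time_s - t_start) / delta)
    bin[bin >= K] <- K - 1 # guards float round-up at the right edge
    idx <- cbind(x$neuron_id, bin + 1)
    dup <- duplicated(idx)
    if (any(dup)) {
      first_bad <- which(dup)[1]
      if (!collapse_duplicates) {
        abort(sprintf(
          "Neuron %d has more than one spike in bin %d (t = [%g, %g) s); use `collapse_duplicates = TRUE` to keep one spike per bin.",
          idx[first_bad, 1], idx[first_bad, 2] - 1L,
          t_start + (idx[first_bad, 2] - 1L) * delta,
          t_start + idx[first_bad, 2] * delta
        ))
      }
      warn(sprintf("Collapsed %d spike(s) that shared a bin with an earlier spike.", sum(dup)))
      idx <- idx[!dup, , drop = FALSE]
    }
    counts[idx] <- 1L
  }
  structure(
    list(
      counts = counts, delta = delta, t_start = t_start,
      neuron_ids = seq_len(N)
    ),
    class = "binned_ensemble"
  )
}

#' @method print binned_ensemble
#' @export
print.binned_ensemble <- function(x, ...) {
  cat(sprintf(
    "<binned_ensemble: %d neurons x %d bins, delta = %g s, %d spikes>\n",
    nrow(x$counts), ncol(x$counts), x$delta, sum(x$counts)
  ))
  invisible(x)
}

#' @describeIn bin_spikes Long-format view of the non-empty bins.
#' @param ... Unused.
#' @method tidy binned_ensemble
#' @export
tidy.binned_ensemble <- function(x, ...) {
  nz <- which(x$counts == 1L, arr.ind = TRUE)
  tibble::tibble(
    neuron_id = as.integer(nz[, 1]),
    bin = as.integer(nz[, 2] - 1L),
    time_s = x$t_start + (nz[, 2] - 1L) * x$delta
  ) |>
    dplyr::arrange(.data$neuron_id, .data$bin)
}

#' History-window geometry for the spiking-history GLM
#'
#' The spiking history that enters the conditional-intensity model is the
#' count of each source neuron's spikes in `R` non-overlapping causal windows
#' of duration `W` immediately preceding the current bin. `R` is the model's
#' spike (history) order: `R * W` seconds of history per source neuron.
#'
#' @param W Window duration in seconds; must be a positive integer multiple
#'   of `delta`.
#' @param R Number of windows (the GLM spike order), `>= 1`.
#' @param delta Bin width in seconds the windows will be laid over.
#' @return A list of class `history_windows` with elements `W`, `R` and `w`
#'   (the window width in bins).
#' @export
history_windows <- function(W, R, delta = 0.001) {
  if (!is.numeric(W) || length(W) != 1 || W <= 0) abort("`W` must be a positive duration in seconds.")
  R <- as.integer(R)
  if (is.na(R) || R < 1L) abort("`R` must be an integer >= 1.")
  w <- W / delta
  if (abs(w - round(w)) > 1e-6) abort("`W` must be an integer multiple of `delta`.")
  structure(list(W = W, R = R, w = as.integer(round(w))), class = "history_windows")
}

#' Spike counts of a source neuron in the causal history windows of one bin
#'
#' For bin `k` (0-based) with left edge `t_k`, window `r` (`r = 1..R`) covers
#' the half-open interval `[t_k - r*W, t_k - (r-1)*W)`: the windows tile the
#' `R*W` seconds strictly before the bin and never include the bin itself.
#'
#' @param binned A [bin_spikes()] result.
#' @param source Source neuron index.
#' @param k 0-based bin index; must satisfy `k >= R*W/delta` so that the full
#'   history is available.
#' @param hw A [history_windows()] specification (its `delta` must match).
#' @return Numeric vector of `R` window counts, most recent window first.
#' @export
window_counts <- function(binned, source, k, hw) {
  stopifnot(inherits(binned, "binned_ensemble"), inherits(hw, "history_windows"))
  if (source < 1 || source > nrow(binned$counts)) abort("`source` out of range.")
  w <- hw$w
  if (k < hw$R * w) {
    abort(sprintf("Bin k = %d has incomplete history: need k >= R*W/delta = %d.", k, hw$R * w))
  }
  row <- binned$counts[source, ]
  vapply(seq_len(hw$R), function(r) {
    lo <- k - r * w # 0-based, inclusive
    hi <- k - (r - 1L) * w # 0-based, exclusive
    sum(row[(lo + 1L):hi])
  }, numeric(1))
}

#' Read and write ensemble spike trains as CSV
#'
#' The on-disk format is a two-column CSV (`neuron_id`, `spike_time_s`, header
#' required, times in seconds) optionally preceded by `#`-prefixed metadata
#' lines recording `t_start`, `t_end` and `n_neurons`, which allow silent
#' neurons and the exact observation interval to round-trip.
#'
#' @param path File path.
#' @param t_start,t_end,n_neurons Optional overrides when the file carries no
#'   metadata lines; see [spike_ensemble()].
#' @return `read_spike_csv()` returns a [spike_ensemble()];
#'   `write_spike_csv()` returns `path` invisibly.
#' @export
read_spike_csv <- function(path, t_start = NULL, t_end = NULL, n_neurons = NULL) {
  header <- readLines(path, n = 50L, warn = FALSE)
  meta <- grep("^#", header, value = TRUE)
  get_meta <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "\\s*=\\s*"), meta, value = TRUE)
    if (!length(ln)) NULL else as.numeric(sub(paste0("^#\\s*", key, "\\s*=\\s*"), "", ln[1]))
  }
  t_start <- t_start %||% get_meta("t_start")
  t_end <- t_end %||% get_meta("t_end")
  n_neurons <- n_neurons %||% get_meta("n_neurons")
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  if (!setequal(names(df), c("neuron_id", "spike_time_s"))) {
    abort(paste0(
      "Spike CSV must have exactly the columns `neuron_id,spike_time_s`; found: ",
      paste(names(df), collapse = ", ")
    ))
  }
  if (nrow(df) == 0 && is.null(n_neurons)) {
    abort("Spike CSV contains no events and no `n_neurons` metadata: an ensemble must have at least one neuron.")
  }
  # sortedness within neuron is validated (not repaired) on read
  bad <- df |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(bad = is.unsorted(.data$spike_time_s, strictly = TRUE), .groups = "drop")
  if (any(bad$bad)) {
    abort(paste0(
      "Spike times are not strictly increasing within neuron(s): ",
      paste(bad$neuron_id[bad$bad], collapse = ", ")
    ))
  }
  spike_ensemble(df, t_start = t_start %||% 0, t_end = t_end, n_neurons = n_neurons)
}

#' @rdname read_spike_csv
#' @param x A [spike_ensemble()].
#' @param comments Extra `#` metadata lines (without the leading `#`) to
#'   record provenance, e.g. the generator seed.
#' @export
write_spike_csv <- function(x, path, comments = character()) {
  stopifnot(inherits(x, "spike_ensemble"))
  meta <- c(
    sprintf("# t_start=%.17g", attr(x, "t_start")),
    sprintf("# t_end=%.17g", attr(x, "t_end")),
    sprintf("# n_neurons=%d", attr(x, "n_neurons")),
    if (length(comments)) paste0("# ", comments)
  )
  body <- readr::format_csv(tibble::as_tibble(x))
  writeLines(c(meta, sub("\n$", "", body)), path)
  invisible(path)
}

#' Export a binned ensemble as a dense neurons-by-bins CSV
#'
#' Debug/interchange format: one row per neuron, one column per bin.
#' @param binned A [bin_spikes()] result.
#' @param path Output file.
#' @export
write_binned_csv <- function(binned, path) {
  stopifnot(inherits(binned, "binned_ensemble"))
  df <- as.data.frame(binned$counts)
  names(df) <- paste0("bin", seq_len(ncol(df)) - 1L)
  df <- cbind(neuron_id = binned$neuron_ids, df)
  readr::write_csv(tibble::as_tibble(df), path)
  invisible(path)
}
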