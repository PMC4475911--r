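#' Raised-cosine spike-history basis in logarithmic time
#'
#' Builds overlapping raised-cosine bumps whose centers are evenly spaced in
#' log(lag + offset), so early lags (refractory/recovery structure) are
#' resolved finely and later lags coarsely.  Each function peaks at 1 and has
#' contiguous support inside lags 1..`window_ms`.
#'
#' @param n_basis Number of basis functions (default 10).
#' @param window_ms History window in ms (default 100).
#' @param first_peak_ms,last_peak_ms Lags (ms) of the first and last basis
#'   peaks.  The log-time offset is derived from these.
#' @return An object of class `history_basis`: a `window_ms` x `n_basis`
#'   matrix (rows = lags 1..window in ms) with attribute `centers_ms`.
#' @export
#' @examples
#' b <- raised_cosine_basis()
#' attr(b, "centers_ms")
raised_cosine_basis <- function(n_basis = 10, window_ms = 100,
                                first_peak_ms = 2, last_peak_ms = 80) {
  if (n_basis < 1) abort("n_basis must be >= 1")
  if (window_ms < n_basis) abort("window_ms must be >= n_basis")
  if (first_peak_ms < 1 || last_peak_ms > window_ms ||
      first_peak_ms >= last_peak_ms) {
    abort("need 1 <= first_peak_ms < last_peak_ms <= window_ms")
  }
  off <- 1 # log-time offset (ms); compresses the first few lags
  u <- function(t) log(t + off)
  centers <- seq(u(first_peak_ms), u(last_peak_ms), length.out = max(n_basis, 2))
  if (n_basis == 1) centers <- centers[1]
  dc <- if (n_basis > 1) centers[2] - centers[1] else (u(last_peak_ms) - u(first_peak_ms))
  lags <- seq_len(window_ms)
  B <- matrix(0, window_ms, n_basis)
  for (j in seq_len(n_basis)) {
    arg <- (u(lags) - centers[j]) * pi / (2 * dc)
    v <- 0.5 * (1 + cos(pmax(pmin(arg, pi), -pi)))
    B[, j] <- v / max(v) # unit peak on the sampled lag grid
  }
  structure(B,
            class = c("history_basis", "matrix", "array"),
            centers_ms = exp(centers) - off,
            window_ms = window_ms)
}

#' @export
print.history_basis <- function(x, ...) {
  cat(sprintf("<history_basis: %d raised-cosine functions over %d ms; peaks at %s ms>\n",
              ncol(x), attr(x, "window_ms"),
              paste(signif(attr(x, "centers_ms"), 3), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.history_basis <- function(x, ...) {
  tibble(
    lag_ms = rep(seq_len(nrow(x)), ncol(x)),
    basis  = rep(seq_len(ncol(x)), each = nrow(x)),
    value  = as.vector(unclass(x))
  )
}

#' Spike-history design columns
#'
#' Convolves the unit's own spike train with each history basis function.
#' Column j at bin t is `sum_tau basis[tau, j] * y[t - tau]` over lags
#' `tau = 1..window`; the current bin is strictly excluded, so the features
#' never see the spike they are used to predict.
#'
#' @param y Spike train: 0/1 vector at 1 ms or a `binned_spikes` object.
#' @param basis A [raised_cosine_basis()].
#' @return A tibble with `t_ms` and columns `hist_01` ... `hist_<n>`.
#' @export
history_columns <- function(y, basis = raised_cosine_basis()) {
  y <- as_spike_vector(y)
  H <- hist_conv_cpp(spike_index0(y), unclass(basis), length(y))
  colnames(H) <- sprintf("hist_%02d", seq_len(ncol(H)))
  out <- as_tibble(H)
  out <- dplyr::bind_cols(tibble(t_ms = seq_along(y) - 1), out)
  out
}
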