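#' Assemble and z-score a point-process design matrix
#'
#' Concatenates labeled feature blocks (tibbles sharing a `t_ms` column) into
#' a numeric design matrix, optionally restricted to a row subset, and
#' z-scores every column.  Standardization statistics are taken from the data
#' itself (training) or from `stats_from` (so test data are scored on the
#' training scale).  Zero-variance columns are dropped with a warning since
#' they carry no information and break standardization.
#'
#' @param blocks A named list of feature tibbles (names become column groups,
#'   e.g. `lfp`, `kin`, `hist`), or a single tibble.
#' @param rows Optional integer row subset (e.g. the usable bins of a
#'   session).  Defaults to all rows.
#' @param stats_from A `pp_design` or `ppglm` whose per-column mean/sd should
#'   be used instead of the data's own.
#' @param scale If `FALSE`, skip standardization (internal fast paths
#'   standardize per fold themselves).
#' @return An object of class `pp_design`: list with elements `X` (matrix),
#'   `info` (tibble: column, group, mean, sd), `t_ms`, `scaled`.
#' @export
assemble_design <- function(blocks, rows = NULL, stats_from = NULL,
                            scale = TRUE) {
  raw <- assemble_matrix(blocks)
  M <- raw$M
  rows <- rows %||% seq_len(nrow(M))
  M <- M[rows, , drop = FALSE]
  if (anyNA(M) || any(!is.finite(M))) {
    abort("non-finite feature values in the selected rows; restrict `rows` to the usable span")
  }
  info <- raw$info
  if (is.null(stats_from)) {
    m <- colMeans(M)
    s <- apply(M, 2, sd)
    keep <- s > 0
    if (!all(keep)) {
      warn(sprintf("dropping %d zero-variance column(s): %s",
                   sum(!keep), paste(info$column[!keep], collapse = ", ")))
      M <- M[, keep, drop = FALSE]
      info <- info[keep, ]
      m <- m[keep]; s <- s[keep]
    }
  } else {
    st <- design_stats(stats_from)
    idx <- match(info$column, st$column)
    if (anyNA(idx)) {
      keep <- !is.na(idx)
      M <- M[, keep, drop = FALSE]
      info <- info[keep, ]
      idx <- idx[keep]
    }
    m <- st$mean[idx]
    s <- st$sd[idx]
  }
  info$mean <- m
  info$sd <- s
  if (scale && ncol(M) > 0) {
    M <- sweep(sweep(M, 2, m, "-"), 2, s, "/")
  }
  structure(list(X = M, info = info, t_ms = raw$t_ms[rows], scaled = scale),
            class = "pp_design")
}

# Bind blocks into one unscaled matrix with column/group bookkeeping.
assemble_matrix <- function(blocks) {
  if (is.data.frame(blocks)) blocks <- list(x = blocks)
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    names(blocks) <- paste0("block", seq_along(blocks))
  }
  t0 <- blocks[[1]]$t_ms
  cols <- list(); grp <- character(0)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if ("t_ms" %in% names(b)) {
      if (length(b$t_ms) != length(t0) || any(b$t_ms != t0, na.rm = TRUE)) {
        abort("feature blocks do not share a time base")
      }
      b <- b[setdiff(names(b), "t_ms")]
    }
    for (cn in names(b)) cols[[cn]] <- b[[cn]]
    grp <- c(grp, rep(nm, ncol(b)))
  }
  M <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, length(t0), 0)
  list(M = M, info = tibble(column = names(cols) %||% character(0), group = grp),
       t_ms = t0)
}

design_stats <- function(x) {
  if (inherits(x, "pp_design")) return(x$info)
  if (inherits(x, "ppglm")) return(x$info)
  abort("`stats_from` must be a pp_design or ppglm object")
}

#' @export
print.pp_design <- function(x, ...) {
  cat(sprintf("<pp_design: %d bins x %d features (%s)%s>\n",
              nrow(x$X), ncol(x$X),
              paste(unique(x$info$group), collapse = "+"),
              if (x$scaled) ", z-scored" else ""))
  invisible(x)
}

#' Penalized negative log-likelihood and gradient
#'
#' The model is a discrete-time point process: the probability of a spike in
#' a 1 ms bin is `lambda_t * Delta` with
#' `ln(lambda_t) = mu + A . X_t`.  This returns the per-sample penalized
#' negative log-likelihood
#' `-(1/T) sum_t [Y_t ln(lambda_t Delta) - lambda_t Delta] + alpha ||A||^2`
#' (the baseline `mu` is not penalized) and its exact gradient.
#'
#' @param mu Baseline log-rate (log spikes/s).
#' @param A Weight vector aligned to the design columns.
#' @param design A `pp_design` (z-scored) or plain matrix.
#' @param y Spike train (0/1 per bin) matching the design rows.
#' @param alpha L2 penalty (>= 0).
#' @param delta Bin width in seconds (default 1e-3).
#' @return List with `value`, `grad_mu`, `grad_A`.
#' @export
penalized_nll <- function(mu, A, design, y, alpha = 0, delta = 1e-3) {
  X <- design_X(design)
  y <- as_spike_vector(y)
  if (nrow(X) != length(y)) abort("design and spike train lengths differ")
  if (alpha < 0) abort("alpha must be >= 0")
  eta <- mu + drop(X %*% A)
  if (any(!is.finite(eta))) {
    abort(sprintf("non-finite intensity at bin %d", which(!is.finite(eta))[1]))
  }
  r <- pp_nll_grad_cpp(X, spike_index0(y), mu, A, alpha, delta)
  list(value = r$f, grad_mu = r$gmu, grad_A = drop(r$g))
}

design_X <- function(design) {
  if (inherits(design, "pp_design")) design$X else as.matrix(design)
}

# Shared optimizer: L-BFGS-B on (mu, A) with analytic gradient and a cached
# joint evaluation so optim's separate fn/gr calls cost one pass.  `evfun`
# computes the penalized NLL and gradient; the double- and single-precision
# matrix backends plug in here.
fit_core_driver <- function(evfun, p, init_mu, init_A, tol, maxit,
                            on_cap = c("error", "warn")) {
  on_cap <- match.arg(on_cap)
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  nev <- 0L
  ev <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
    r <- evfun(par)
    nev <<- nev + 1L
    cache$par <- par
    cache$val <- r
    r
  }
  fn <- function(par) ev(par)$f
  gr <- function(par) { r <- ev(par); c(r$gmu, r$g) }
  par0 <- c(init_mu, init_A)
  if (p == 0) {
    return(list(mu = init_mu, A = numeric(0), nll = fn(par0),
                converged = TRUE, evals = 1L, ncap = 0L))
  }
  o <- optim(par0, fn, gr, method = "L-BFGS-B",
             control = list(maxit = maxit, factr = tol / .Machine$double.eps))
  converged <- o$convergence == 0
  # 1: iteration cap; 52: line-search failure, i.e. no further progress at
  # the working precision -- both leave a usable iterate for the caller to
  # accept (scoring fits) or reject (strict fits check `converged`)
  if (!converged && !(o$convergence %in% c(1, 52))) {
    abort(sprintf("point-process fit failed (code %d: %s) after %d evaluations",
                  o$convergence, o$message %||% "", nev))
  }
  ncap <- ev(o$par)$ncap
  if (ncap > 0) {
    msg <- sprintf("intensity cap (1e4 spikes/s) active at %d bins of the solution", ncap)
    if (on_cap == "error") abort(msg) else warn(msg)
  }
  list(mu = o$par[1], A = o$par[-1], nll = o$value, converged = converged,
       evals = nev, ncap = ncap)
}

fit_core <- function(X, spk0, alpha, init_mu, init_A, delta, tol, maxit,
                     on_cap = c("error", "warn")) {
  fit_core_driver(
    function(par) pp_nll_grad_cpp(X, spk0, par[1], par[-1], alpha, delta),
    ncol(X), init_mu, init_A, tol, maxit, on_cap)
}

# Single-precision backend with on-the-fly standardization, for the inner
# model-selection fits.
fit_core_std_f32 <- function(xptr, p, spk0, alpha, init_mu, init_A, delta,
                             tol, maxit, m, s, on_cap = "warn") {
  fit_core_driver(
    function(par) pp_nll_grad_std_f32(xptr, spk0, par[1], par[-1], alpha,
                                      delta, m, s),
    p, init_mu, init_A, tol, maxit, on_cap)
}

#' Fit an L2-regularized point-process GLM
#'
#' Minimizes the penalized negative log-likelihood (see [penalized_nll()])
#' over `(mu, A)`.  The objective is convex (exponential-family log link plus
#' quadratic penalty), so the optimum is unique whenever the design has full
#' column rank or `alpha > 0`; it is found by quasi-Newton (L-BFGS) iteration
#' with the analytic gradient, stopping when the relative objective change
#' falls below `tol`.  With no covariates the closed-form maximum-likelihood
#' baseline `mu = ln(mean(Y)/Delta)` is returned directly.
#'
#' @inheritParams penalized_nll
#' @param init Optional warm start: a `ppglm` or list with `mu` and `A`.
#' @param tol Relative objective-change convergence tolerance.
#' @param maxit Iteration cap.
#' @param on_cap What to do if the overflow guard (intensity capped at 1e4
#'   spikes/s) is active at the solution.
#' @return An object of class `ppglm` with elements `mu`, `coef` (named),
#'   `alpha`, `info` (column labels, groups and z-scoring statistics),
#'   `nll`, `delta`, `n`, `n_spikes`.
#' @export
fit_ppglm <- function(design, y, alpha = 0, init = NULL, delta = 1e-3,
                      tol = 1e-9, maxit = 1000, on_cap = "error") {
  X <- design_X(design)
  y <- as_spike_vector(y)
  if (nrow(X) != length(y)) abort("design and spike train lengths differ")
  if (alpha < 0) abort("alpha must be >= 0")
  spk0 <- spike_index0(y)
  mu0 <- log(max(mean(y), 1 / (2 * length(y))) / delta)
  if (ncol(X) == 0) {
    fit <- list(mu = mu0, A = numeric(0),
                nll = exp(mu0) * delta - mean(y) * (mu0 + log(delta)),
                converged = TRUE, evals = 0L)
  } else {
    if (inherits(init, "ppglm")) init <- list(mu = init$mu, A = init$coef)
    init_mu <- if (is.null(init)) mu0 else init$mu
    init_A <- if (is.null(init)) numeric(ncol(X)) else init$A
    fit <- fit_core(X, spk0, alpha, init_mu, init_A, delta, tol, maxit, on_cap)
    if (!fit$converged) {
      abort(sprintf("point-process fit did not converge within %d iterations (nll %.6g, %d evaluations)",
                    maxit, fit$nll, fit$evals))
    }
  }
  info <- if (inherits(design, "pp_design")) design$info else
    tibble(column = colnames(X) %||% sprintf("x%d", seq_len(ncol(X))),
           group = "x", mean = 0, sd = 1)
  coefs <- fit$A
  names(coefs) <- info$column
  structure(list(mu = fit$mu, coef = coefs, alpha = alpha, info = info,
                 nll = fit$nll, delta = delta, n = length(y),
                 n_spikes = sum(y), converged = fit$converged,
                 evals = fit$evals),
            class = "ppglm")
}

#' @export
print.ppglm <- function(x, ...) {
  cat(sprintf("<ppglm: %d features, alpha = %g, baseline %.2f spikes/s, %d spikes in %d bins>\n",
              length(x$coef), x$alpha, exp(x$mu), x$n_spikes, x$n))
  invisible(x)
}

#' Conditional intensity of a fitted model
#'
#' Evaluates `lambda_t = exp(mu + A . X_t)` (spikes/s) on a design whose
#' columns match the model.  Assemble the design with
#' `assemble_design(..., stats_from = model)` so test data are standardized
#' with the training statistics.
#'
#' @param model A `ppglm`.
#' @param design A `pp_design` or matrix with matching columns.
#' @return Numeric vector of intensities (spikes/s), one per row.
#' @export
conditional_intensity <- function(model, design) {
  X <- design_X(design)
  if (inherits(design, "pp_design")) {
    if (!identical(design$info$column, model$info$column)) {
      abort("design columns do not match the model's feature labels")
    }
  } else if (!is.null(colnames(X)) &&
             !identical(colnames(X), model$info$column)) {
    abort("design columns do not match the model's feature labels")
  }
  if (ncol(X) != length(model$coef)) {
    abort("design width does not match the model")
  }
  drop(pp_prob_cpp(X, model$mu, model$coef, model$delta)) / model$delta
}

#' @export
#' @rdname conditional_intensity
#' @param object,... S3 method arguments; `type = "prob"` returns the per-bin
#'   spike probability `lambda_t * Delta` instead of the rate.
#' @param type `"intensity"` (spikes/s) or `"prob"` (per-bin probability).
predict.ppglm <- function(object, design, type = c("intensity", "prob"), ...) {
  type <- match.arg(type)
  lam <- conditional_intensity(object, design)
  if (type == "prob") lam * object$delta else lam
}

#' Preferred phase and modulation depth of a band's phase tuning
#'
#' The cosine/sine phase pair of a narrow band realizes cosine tuning
#' `a cos(theta0 - phase)`; this recovers the preferred phase
#' `theta0 = atan2(w_sin, w_cos)` and depth `a = sqrt(w_cos^2 + w_sin^2)`
#' from the fitted weights after undoing the z-score scaling.
#'
#' @param model A fitted `ppglm`.
#' @param band Band name (must be a narrow band with phase columns).
#' @return A tibble with `band`, `theta0` (radians) and `depth`.
#' @export
preferred_phase <- function(model, band) {
  cn <- paste0(band, c("_cos", "_sin"))
  if (!all(cn %in% model$info$column)) {
    abort(sprintf("model has no phase features for band '%s'", band))
  }
  i <- match(cn, model$info$column)
  w <- unname(model$coef[i] / model$info$sd[i])
  tibble(band = band,
         theta0 = atan2(w[2], w[1]),
         depth = sqrt(sum(w^2)))
}

#' Covariance of the fitted parameters
#'
#' Inverse observed (expected) Fisher information of the unpenalized
#' likelihood at the fitted parameters, for Wald-type standard errors.  Valid
#' as a sampling covariance when `alpha` is negligible.
#'
#' @param object A `ppglm`.
#' @param design The (z-scored) training design.
#' @param ... Unused.
#' @return `(p+1) x (p+1)` covariance matrix; the first row/column is `mu`.
#' @export
vcov.ppglm <- function(object, design, ...) {
  X <- design_X(design)
  lam_d <- drop(pp_prob_cpp(X, object$mu, object$coef, object$delta))
  X1 <- cbind(`(mu)` = 1, X)
  info <- crossprod(X1 * sqrt(lam_d))
  V <- solve(info)
  dimnames(V) <- list(c("(mu)", object$info$column),
                      c("(mu)", object$info$column))
  V
}

#' @export
tidy.ppglm <- function(x, ...) {
  tibble(term = x$info$column,
         group = x$info$group,
         estimate = unname(x$coef),
         estimate_raw = unname(x$coef) / x$info$sd)
}

#' @export
glance.ppglm <- function(x, ...) {
  tibble(alpha = x$alpha, nll = x$nll, baseline_rate = exp(x$mu),
         n_bins = x$n, n_spikes = x$n_spikes, converged = x$converged)
}

#' @export
coef.ppglm <- function(object, ...) c(`(mu)` = object$mu, object$coef)
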