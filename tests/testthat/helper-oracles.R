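# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the ROC hull oracle enumerates thresholds and uses
# grDevices::chull; gradients come from central finite differences; tiny
# likelihood optima come from iterative grid refinement.

# Predictive power by exhaustive threshold enumeration + convex hull.
oracle_roc_hull_pp <- function(prob, y) {
  stopifnot(length(prob) == length(y), sum(y) > 0, sum(1 - y) > 0)
  th <- sort(unique(prob))
  cuts <- c(-Inf, (th[-1] + th[-length(th)]) / 2, Inf)
  if (length(th) == 1) cuts <- c(-Inf, Inf)
  P <- sum(y); N <- sum(1 - y)
  pts <- t(vapply(cuts, function(ct) {
    pred <- prob > ct
    c(sum(pred & y == 0) / N, sum(pred & y == 1) / P)
  }, numeric(2)))
  pts <- rbind(pts, c(0, 0), c(1, 1), c(1, 0)) # (1,0) anchors the lower hull
  pts <- unique(pts)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[h, , drop = FALSE]
  i00 <- which(hp[, 1] == 0 & hp[, 2] == 0)
  i11 <- which(hp[, 1] == 1 & hp[, 2] == 1)
  i10 <- which(hp[, 1] == 1 & hp[, 2] == 0)
  stopifnot(length(i00) == 1, length(i11) == 1, length(i10) == 1)
  nh <- nrow(hp)
  walk <- function(from, to, avoid) {
    path <- from
    i <- from
    repeat {
      i <- if (i == nh) 1 else i + 1
      if (i == avoid) return(NULL)
      path <- c(path, i)
      if (i == to) return(path)
    }
  }
  path <- walk(i00, i11, i10)
  if (is.null(path)) {
    path <- rev(walk(i11, i00, i10))
  }
  up <- hp[path, , drop = FALSE]
  up <- up[order(up[, 1], up[, 2]), , drop = FALSE]
  auc <- sum(diff(up[, 1]) * (up[-1, 2] + up[-nrow(up), 2]) / 2)
  2 * auc - 1
}

# Central finite-difference gradient of the penalized NLL.
oracle_fd_gradient <- function(mu, A, X, y, alpha, delta = 1e-3, h = 1e-6) {
  f <- function(m, a) penalized_nll(m, a, X, y, alpha, delta)$value
  gmu <- (f(mu + h, A) - f(mu - h, A)) / (2 * h)
  gA <- vapply(seq_along(A), function(j) {
    e <- numeric(length(A)); e[j] <- h
    (f(mu, A + e) - f(mu, A - e)) / (2 * h)
  }, numeric(1))
  list(grad_mu = gmu, grad_A = gA)
}

# Direct (R-level, per-definition) penalized NLL for cross-checking.
oracle_nll <- function(mu, A, X, y, alpha, delta = 1e-3) {
  lam <- exp(mu + drop(as.matrix(X) %*% A))
  -mean(y * log(lam * delta) - lam * delta) + alpha * sum(A^2)
}

# Iterative grid-refinement minimizer for tiny instances (p <= 2).
oracle_grid_fit <- function(X, y, alpha, delta = 1e-3, rounds = 6) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(p <= 2)
  ctr <- c(log(mean(y) / delta), numeric(p))
  hw <- rep(2, p + 1)
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p + 1), function(j) {
      seq(ctr[j] - hw[j], ctr[j] + hw[j], length.out = 13)
    })
    best <- Inf; barg <- ctr
    combos <- expand.grid(grids)
    for (i in seq_len(nrow(combos))) {
      th <- as.numeric(combos[i, ])
      v <- oracle_nll(th[1], th[-1], X, y, alpha, delta)
      if (v < best) { best <- v; barg <- th }
    }
    ctr <- barg
    hw <- hw / 4
  }
  list(mu = ctr[1], A = ctr[-1], nll = best)
}

# Small synthetic fixture shared by several tests: a short session with a
# kinematics-driven unit (cheap to generate, enough spikes to fit).
local_small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(generate_session(
        ground_truth_spec(), duration_s = 60, n_units = 2, seed = 101))
    }
    cache
  }
})
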