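make_design <- function(T = 400, p = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(T * p), T, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  blocks <- list(x = tibble::as_tibble(X))
  d <- assemble_design(blocks)
  A <- rnorm(p, 0, 0.4)
  eta <- log(15) + drop(d$X %*% A)
  y <- as.integer(runif(T) < pmin(exp(eta) * 1e-3, 1))
  list(d = d, y = y, A = A)
}

test_that("self-scored design has unit-mean-zero columns; constants are dropped", {
  set.seed(41)
  b <- tibble::tibble(t_ms = 0:99, a = rnorm(100), const = 1, c = runif(100))
  expect_warning(d <- assemble_design(list(kin = b)), "zero-variance")
  expect_equal(ncol(d$X), 2)
  expect_lt(max(abs(colMeans(d$X))), 1e-9)
  expect_lt(max(abs(apply(d$X, 2, sd) - 1)), 1e-9)
  expect_equal(d$info$group, c("kin", "kin"))
})

test_that("test data standardized with training statistics differ from self-scoring", {
  set.seed(42)
  tr <- tibble::tibble(t_ms = 0:199, a = rnorm(200, 0, 1))
  te <- tibble::tibble(t_ms = 0:199, a = rnorm(200, 3, 2))
  dtr <- assemble_design(list(x = tr))
  dte_tr <- assemble_design(list(x = te), stats_from = dtr)
  dte_own <- assemble_design(list(x = te))
  expect_gt(abs(mean(dte_tr$X)), 1) # shifted distribution shows through
  expect_lt(abs(mean(dte_own$X)), 1e-9)
})

test_that("penalized NLL closed forms", {
  X <- matrix(rnorm(50), 50, 1)
  y0 <- integer(50)
  mu <- log(7)
  r <- penalized_nll(mu, 0, X, y0, alpha = 0)
  expect_equal(r$value, exp(mu) * 1e-3, tolerance = 1e-12)
  expect_equal(r$grad_mu, exp(mu) * 1e-3, tolerance = 1e-12)
  # zero weights: penalty contributes nothing regardless of alpha
  y <- y0; y[c(3, 20)] <- 1L
  expect_equal(penalized_nll(mu, 0, X, y, alpha = 0)$value,
               penalized_nll(mu, 0, X, y, alpha = 50)$value)
})

test_that("analytic gradient matches central finite differences", {
  for (seed in 1:5) {
    set.seed(seed)
    T <- 150; p <- 4
    X <- matrix(rnorm(T * p), T, p)
    y <- as.integer(runif(T) < 0.05)
    mu <- rnorm(1, log(20), 0.5)
    A <- rnorm(p, 0, 0.3)
    alpha <- runif(1, 0, 0.1)
    got <- penalized_nll(mu, A, X, y, alpha)
    fd <- oracle_fd_gradient(mu, A, X, y, alpha)
    expect_equal(got$grad_mu, fd$grad_mu, tolerance = 1e-6)
    expect_equal(got$grad_A, fd$grad_A, tolerance = 1e-6)
  }
})

test_that("conditional intensity agrees with per-row evaluation", {
  mk <- make_design(seed = 5)
  fit <- fit_ppglm(mk$d, mk$y, alpha = 1e-4)
  lam <- conditional_intensity(fit, mk$d)
  byrow <- vapply(seq_len(nrow(mk$d$X)), function(t) {
    exp(fit$mu + sum(fit$coef * mk$d$X[t, ]))
  }, numeric(1))
  expect_equal(lam, byrow, tolerance = 1e-12)
  expect_true(all(lam > 0))
})

test_that("intensity closed forms at zero weights", {
  d <- structure(list(X = matrix(0, 10, 0),
                      info = tibble::tibble(column = character(0),
                                            group = character(0),
                                            mean = numeric(0), sd = numeric(0)),
                      t_ms = 0:9, scaled = TRUE), class = "pp_design")
  m0 <- fit_ppglm(d, c(1, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(exp(m0$mu) * 1e-3, 0.2, tolerance = 1e-9) # closed-form MLE
  expect_equal(unname(conditional_intensity(m0, d)[1]), 200, tolerance = 1e-6)
})

test_that("covariate-free fit returns the closed-form baseline", {
  set.seed(43)
  y <- as.integer(runif(5000) < 0.012)
  d <- structure(list(X = matrix(0, 5000, 0),
                      info = tibble::tibble(column = character(0),
                                            group = character(0),
                                            mean = numeric(0), sd = numeric(0)),
                      t_ms = seq_len(5000) - 1, scaled = TRUE),
                 class = "pp_design")
  fit <- fit_ppglm(d, y)
  expect_equal(fit$mu, log(mean(y) / 1e-3), tolerance = 1e-10)
})

test_that("a huge penalty shrinks the weights but not the baseline", {
  mk <- make_design(T = 2000, seed = 6)
  fit <- fit_ppglm(mk$d, mk$y, alpha = 1e6)
  expect_lt(sqrt(sum(fit$coef^2)), 1e-3)
  expect_equal(fit$mu, log(mean(mk$y) / 1e-3), tolerance = 1e-3)
})

test_that("fits from different starts agree (convex objective)", {
  mk <- make_design(T = 1000, p = 4, seed = 7)
  fits <- lapply(1:5, function(i) {
    set.seed(i)
    fit_ppglm(mk$d, mk$y, alpha = 1e-3,
              init = list(mu = rnorm(1, log(10), 1), A = rnorm(4, 0, 0.5)))
  })
  objs <- vapply(fits, function(f) f$nll, numeric(1))
  expect_lt(max(objs) - min(objs), 1e-8)
  pars <- sapply(fits, function(f) c(f$mu, f$coef))
  expect_lt(max(apply(pars, 1, function(v) diff(range(v)))), 1e-4)
})

test_that("the weight norm is non-increasing in the penalty", {
  mk <- make_design(T = 1500, p = 5, seed = 8)
  alphas <- c(0, 1e-6, 1e-4, 1e-2, 1, 100)
  norms <- vapply(alphas, function(a) {
    sqrt(sum(fit_ppglm(mk$d, mk$y, alpha = a)$coef^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("tiny unpenalized fits match a grid-search of the likelihood surface", {
  for (seed in c(11, 12)) {
    set.seed(seed)
    T <- 200; p <- 2
    X <- scale(matrix(rnorm(T * p), T, p))
    colnames(X) <- c("a", "b")
    eta <- log(30) + X %*% c(0.5, -0.3)
    y <- as.integer(runif(T) < exp(eta) * 1e-3)
    if (sum(y) < 3) next
    d <- assemble_design(list(x = tibble::as_tibble(X)))
    fit <- fit_ppglm(d, y, alpha = 0)
    gs <- oracle_grid_fit(d$X, y, alpha = 0)
    expect_equal(fit$mu, gs$mu, tolerance = 5e-3)
    expect_equal(unname(fit$coef), gs$A, tolerance = 5e-3)
  }
})

test_that("ridge fits agree with glmnet's Poisson ridge path", {
  skip_if_not_installed("glmnet")
  set.seed(44)
  T <- 4000; p <- 6
  X <- scale(matrix(rnorm(T * p), T, p))
  colnames(X) <- paste0("f", 1:p)
  eta <- log(20) + X %*% rnorm(p, 0, 0.3)
  y <- as.integer(runif(T) < pmin(exp(eta) * 1e-3, 1))
  d <- assemble_design(list(x = tibble::as_tibble(X)))
  for (alpha in c(1e-4, 1e-2)) {
    fit <- fit_ppglm(d, y, alpha = alpha)
    # glmnet poisson: -(1/N) loglik + lambda * ||b||^2 / 2, offset log(delta)
    gn <- glmnet::glmnet(d$X, y, family = "poisson", alpha = 0,
                         lambda = 2 * alpha, standardize = FALSE,
                         offset = rep(log(1e-3), T), thresh = 1e-14)
    expect_equal(unname(fit$coef), unname(as.numeric(gn$beta)),
                 tolerance = 5e-4)
    expect_equal(fit$mu, unname(gn$a0), tolerance = 5e-3)
  }
})

test_that("preferred phase is recovered from the cos/sin pair", {
  info <- tibble::tibble(column = c("delta_cos", "delta_sin", "beta_amp"),
                         group = "lfp", mean = 0, sd = c(2, 2, 1))
  m <- structure(list(mu = 0, coef = c(delta_cos = 2, delta_sin = 0,
                                       beta_amp = 1),
                      alpha = 0, info = info, delta = 1e-3),
                 class = "ppglm")
  ph <- preferred_phase(m, "delta")
  expect_equal(ph$theta0, 0)
  expect_equal(ph$depth, 1)
  m$coef <- c(delta_cos = 0, delta_sin = 2, beta_amp = 1)
  ph <- preferred_phase(m, "delta")
  expect_equal(ph$theta0, pi / 2)
  expect_error(preferred_phase(m, "beta"), "no phase features")
})

test_that("tidy and glance return the expected shapes", {
  mk <- make_design(seed = 9)
  fit <- fit_ppglm(mk$d, mk$y, alpha = 1e-3)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_named(td, c("term", "group", "estimate", "estimate_raw"))
  gl <- glance(fit)
  expect_equal(gl$n_bins, 400)
  expect_true(gl$converged)
})
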