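#' Predictive power from the ROC convex hull
#'
#' Builds the ROC curve of the per-bin spike probability against the observed
#' 0/1 spike train over all score thresholds (ties grouped), takes the upper
#' convex hull including (0,0) and (1,1), integrates it by the trapezoid
#' rule, and returns predictive power `PP = 2*AUC - 1`.  The hull guarantees
#' `PP` is in \[0, 1\]: 0 is chance, 1 is perfect prediction of every 1 ms bin.
#'
#' @param prob Score per bin (the model's conditional spike probability).
#' @param y Observed spike train (0/1 per bin), same length.
#' @return Scalar predictive power in \[0, 1\].
#' @export
#' @examples
#' roc_hull_pp(c(.9, .8, .7, .1), c(1, 0, 1, 0))
roc_hull_pp <- function(prob, y) {
  y <- as_spike_vector(y)
  if (length(prob) != length(y)) abort("prob and y lengths differ")
  if (any(!is.finite(prob))) abort("non-finite scores")
  roc_hull_pp_cpp(prob, y)
}

#' ROC curve and its convex hull
#'
#' Returns the ROC operating points and the hull vertices for plotting.
#'
#' @inheritParams roc_hull_pp
#' @return A tibble with `fpr`, `tpr`, `part` (`"roc"` or `"hull"`).
#' @export
roc_hull_curve <- function(prob, y) {
  y <- as_spike_vector(y)
  P <- sum(y); N <- length(y) - P
  if (P == 0 || N == 0) abort("degenerate spike train: all 0 or all 1")
  ord <- order(prob, decreasing = TRUE)
  ys <- y[ord]; ps <- prob[ord]
  last <- c(ps[-1] != ps[-length(ps)], TRUE)
  tpr <- c(0, cumsum(ys)[last] / P, 1)
  fpr <- c(0, cumsum(1 - ys)[last] / N, 1)
  # upper hull, monotone chain
  hx <- hy <- numeric(0)
  for (i in seq_along(fpr)) {
    while (length(hx) >= 2) {
      n <- length(hx)
      cr <- (hx[n] - hx[n - 1]) * (tpr[i] - hy[n - 1]) -
        (hy[n] - hy[n - 1]) * (fpr[i] - hx[n - 1])
      if (cr >= 0) { hx <- hx[-n]; hy <- hy[-n] } else break
    }
    hx <- c(hx, fpr[i]); hy <- c(hy, tpr[i])
  }
  dplyr::bind_rows(
    tibble(fpr = fpr, tpr = tpr, part = "roc"),
    tibble(fpr = hx, tpr = hy, part = "hull")
  )
}

#' Two-tier cross-validation configuration
#'
#' Settings for [nested_cv_fit()]: a 10-fold outer loop assesses
#' generalization, and an inner two-group split selects the L2 penalty from
#' a grid of ten log-spaced values on \[1e-9, 1e2\] plus 0.
#'
#' @param outer_folds Number of outer folds (default 10).
#' @param alpha_grid Penalty grid; must contain 0.
#' @param seed RNG seed controlling fold assignment, inner splits and any
#'   permutations; identical configs give identical folds, so feature-set
#'   comparisons are paired.
#' @param fold_scheme `"contiguous"` (default; outer folds are contiguous
#'   time blocks, which limits leakage through autocorrelation) or
#'   `"random"`.
#' @param tol,inner_tol,refit_tol Convergence tolerances: `tol` for strict
#'   standalone fits, `inner_tol` for the inner selection fits (which only
#'   rank penalties), `refit_tol` for the per-fold refits that produce the
#'   scored probabilities (predictive power is rank-based and insensitive to
#'   sub-1e-6 objective changes).
#' @param maxit Iteration cap per fit.
#' @param block_len_ms Chunk length for block permutations (chance levels).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 10,
                      alpha_grid = c(0, 10^seq(-9, 2, length.out = 10)),
                      seed = 1,
                      fold_scheme = c("contiguous", "random"),
                      tol = 1e-9, inner_tol = 1e-5, refit_tol = 1e-6,
                      maxit = 500, inner_maxit = 40,
                      block_len_ms = 100) {
  fold_scheme <- match.arg(fold_scheme)
  if (!any(alpha_grid == 0)) abort("alpha_grid must contain 0")
  if (any(alpha_grid < 0)) abort("alpha_grid must be non-negative")
  structure(list(outer_folds = outer_folds, alpha_grid = alpha_grid,
                 seed = seed, fold_scheme = fold_scheme, tol = tol,
                 inner_tol = inner_tol, refit_tol = refit_tol,
                 maxit = maxit, inner_maxit = inner_maxit,
                 block_len_ms = block_len_ms),
            class = "cv_config")
}

sd_guard <- function(s) ifelse(s > 0, s, 1)

usable_feature_rows <- function(blocks) {
  raw <- assemble_matrix(blocks)
  which(rowSums(!is.finite(raw$M)) == 0)
}

#' Nested cross-validated predictive power of a feature set
#'
#' The workhorse evaluation: for each outer fold, the training data (90%) are
#' split randomly into two equal groups; every penalty in the grid is fit on
#' each group and scored (predictive power) on the other, the two directions
#' are averaged, and the best penalty is selected.  The model is then refit
#' on all training data with that penalty (z-scoring statistics from the
#' training data only) and scored on the held-out 10%.  Over the 10 folds
#' every usable bin is test data exactly once; per-fold and pooled predictive
#' power are reported.
#'
#' @param blocks Named list of feature tibbles (see [assemble_design()]).
#' @param y Spike train (0/1 per bin) over the same time base.
#' @param config A [cv_config()].
#' @param rows Usable bin indices; defaults to all rows with finite features.
#' @param feature_set Label stored in the result.
#' @param delta Bin width in seconds.
#' @return An object of class `cv_result`: per-fold PP, pooled PP, selected
#'   penalties, and the out-of-fold probability predictions.
#' @export
nested_cv_fit <- function(blocks, y, config = cv_config(), rows = NULL,
                          feature_set = "model", delta = 1e-3) {
  raw <- assemble_matrix(blocks)
  y <- as_spike_vector(y)
  if (nrow(raw$M) != length(y)) abort("blocks and spike train lengths differ")
  rows <- rows %||% usable_feature_rows(blocks)
  nr <- length(rows)
  K <- config$outer_folds
  if (nr < 20 * K) abort("session too short for the outer folds")
  set.seed(config$seed)
  # a random partition into K folds is equivalent to contiguous blocks of a
  # random permutation, so one (range-based, fast) code path serves both
  perm <- switch(config$fold_scheme,
                 contiguous = seq_len(nr),
                 random = sample(nr))
  M <- raw$M[rows[perm], , drop = FALSE]
  yp <- y[rows[perm]]
  st0 <- col_stats_cpp(M, seq_len(nr))
  keep <- which(st0$sd > 0)
  if (length(keep) < ncol(M)) {
    warn(sprintf("dropping %d zero-variance column(s) before cross-validation",
                 ncol(M) - length(keep)))
    M <- M[, keep, drop = FALSE]
  }
  p_ <- ncol(M)
  Mf <- make_f32(M)
  bounds <- round(seq(0, nr, length.out = K + 1))
  fold_id <- rep(seq_len(K), diff(bounds))
  alphas <- sort(config$alpha_grid, decreasing = TRUE) # warm-start path
  nA <- length(alphas)
  pred <- rep(NA_real_, nr)
  pp_fold <- numeric(K)
  sel_alpha <- numeric(K)
  warm_prev <- vector("list", nA)
  for (k in seq_len(K)) {
    lo <- bounds[k] + 1L; hi <- bounds[k + 1L]
    n_te <- hi - lo + 1L; n_tr <- nr - n_te
    tr_pos <- c(seq_len(lo - 1L), if (hi < nr) (hi + 1L):nr)
    hTr <- gather_stats_f32(Mf, tr_pos)
    m_tr <- hTr$mean
    s_tr <- sd_guard(hTr$sd)
    g <- sample(rep_len(1:2, n_tr))
    r1 <- tr_pos[g == 1]; r2 <- tr_pos[g == 2]
    h1 <- gather_stats_f32(Mf, r1); h2 <- gather_stats_f32(Mf, r2)
    s1 <- sd_guard(h1$sd); s2 <- sd_guard(h2$sd)
    y1 <- yp[r1]; y2 <- yp[r2]
    spk1 <- spike_index0(y1); spk2 <- spike_index0(y2)
    mu01 <- log(max(mean(y1), 1e-6) / delta)
    mu02 <- log(max(mean(y2), 1e-6) / delta)
    pp_a <- numeric(nA)
    fits1 <- vector("list", nA)
    w1 <- w2 <- NULL
    for (a in seq_len(nA)) {
      # warm starts: previous fold's solution at this penalty if available
      # (folds share 8/9 of their data), else the previous penalty's solution
      i1 <- warm_prev[[a]] %||% w1
      i2 <- warm_prev[[a]] %||% w2
      f1 <- fit_core_std_f32(h1$xp, p_, spk1, alphas[a],
                             if (is.null(i1)) mu01 else i1$mu,
                             if (is.null(i1)) numeric(p_) else i1$A,
                             delta, config$inner_tol, config$inner_maxit,
                             h1$mean, s1)
      f2 <- fit_core_std_f32(h2$xp, p_, spk2, alphas[a],
                             if (is.null(i2)) mu02 else i2$mu,
                             if (is.null(i2)) numeric(p_) else i2$A,
                             delta, config$inner_tol, config$inner_maxit,
                             h2$mean, s2)
      w1 <- f1; w2 <- f2
      fits1[[a]] <- f1
      p2 <- pp_prob_std_f32(h2$xp, f1$mu, f1$A, delta, h1$mean, s1)
      p1 <- pp_prob_std_f32(h1$xp, f2$mu, f2$A, delta, h2$mean, s2)
      pp_a[a] <- (roc_hull_pp_cpp(p2, y2) + roc_hull_pp_cpp(p1, y1)) / 2
    }
    best <- which.max(pp_a) # ties resolve to the larger penalty
    sel_alpha[k] <- alphas[best]
    init_best <- fits1[[best]]
    warm_prev <- fits1
    rm(h1, h2, fits1)
    spk_tr <- spike_index0(yp[tr_pos])
    refit <- fit_core_std_f32(hTr$xp, p_, spk_tr, alphas[best],
                              init_best$mu, init_best$A,
                              delta, config$refit_tol, config$maxit,
                              m_tr, s_tr)
    rm(hTr)
    pte <- drop(pp_prob_std_rng(M, refit$mu, refit$A, delta, m_tr, s_tr,
                                lo, hi))
    yte <- yp[lo:hi]
    if (sum(yte) < 10) {
      warn(sprintf("fold %d has only %d test spikes; PP is unstable",
                   k, sum(yte)))
    }
    pp_fold[k] <- roc_hull_pp_cpp(pte, yte)
    pred[perm[lo:hi]] <- pte
  }
  fold_orig <- integer(nr)
  fold_orig[perm] <- fold_id
  structure(list(feature_set = feature_set,
                 pp_per_fold = pp_fold,
                 pp_pooled = roc_hull_pp_cpp(pred, y[rows]),
                 selected_alphas = sel_alpha,
                 pred = pred, rows = rows, fold_id = fold_orig,
                 n_spikes = sum(y[rows]), config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result '%s': pooled PP %.3f (folds %.3f-%.3f), alpha in [%g, %g]>\n",
              x$feature_set, x$pp_pooled, min(x$pp_per_fold),
              max(x$pp_per_fold), min(x$selected_alphas),
              max(x$selected_alphas)))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) {
  tibble(feature_set = x$feature_set,
         fold = seq_along(x$pp_per_fold),
         pp = x$pp_per_fold,
         alpha = x$selected_alphas)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble(feature_set = x$feature_set, pp_pooled = x$pp_pooled,
         pp_fold_mean = mean(x$pp_per_fold),
         pp_fold_sd = sd(x$pp_per_fold),
         n_bins = length(x$rows), n_spikes = x$n_spikes)
}

block_perm_indices <- function(n, block_len) {
  nb <- floor(n / block_len)
  if (nb < 2) return(NULL)
  chunks <- split(seq_len(nb * block_len),
                  rep(seq_len(nb), each = block_len))
  c(unlist(chunks[sample(nb)], use.names = FALSE),
    seq_len(n)[-seq_len(nb * block_len)])
}

#' Shuffle a feature block in fixed-length time chunks
#'
#' Partitions the rows into contiguous chunks of `block_len_ms` and permutes
#' the chunk order uniformly at random, moving all columns together.  This
#' destroys the alignment between the features and the spike train while
#' preserving the features' own autocorrelation within chunks — the null
#' used for permutation chance levels.
#'
#' @param block A feature tibble with a `t_ms` column (1 ms rows).
#' @param block_len_ms Chunk length in ms (default 100).
#' @param seed Optional RNG seed.
#' @return The block with rows permuted (the `t_ms` column keeps its order).
#' @export
block_shuffle <- function(block, block_len_ms = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(block)
  idx <- block_perm_indices(n, block_len_ms)
  if (is.null(idx)) {
    warn("fewer than 2 chunks; returning block unchanged")
    return(block)
  }
  out <- block[idx, ]
  if (!is.null(block$t_ms)) out$t_ms <- block$t_ms
  out
}

#' Permutation chance level of predictive power
#'
#' Repeats shuffle-fit-score `n_perm` times: the feature rows are permuted in
#' `block_len_ms` chunks relative to the spike train, a model is fit on the
#' first 90% of the (permuted) session with a fixed penalty and scored on the
#' held-out 10%, and the 95th percentile of the null predictive-power
#' distribution is returned.  The penalty defaults to the value selected by
#' the inner cross-validation on the first permutation, so the null models
#' get the same regularization treatment as the real ones.
#'
#' @inheritParams nested_cv_fit
#' @param n_perm Number of permutations (>= 20).
#' @param alpha Fixed penalty for the null fits; `NULL` selects it by the
#'   two-group inner procedure on the first permutation.
#' @return List with `threshold` (95th percentile), `null_pp` (all `n_perm`
#'   values) and `alpha` (penalty used).
#' @export
chance_level <- function(blocks, y, config = cv_config(), n_perm = 20,
                         rows = NULL, alpha = NULL, delta = 1e-3) {
  if (n_perm < 20) abort("n_perm must be >= 20 for a 95th percentile")
  raw <- assemble_matrix(blocks)
  y <- as_spike_vector(y)
  rows <- rows %||% usable_feature_rows(blocks)
  nr <- length(rows)
  M <- raw$M[rows, , drop = FALSE]
  yr <- y[rows]
  st0 <- col_stats_cpp(M, seq_len(nr))
  keep <- which(st0$sd > 0)
  M <- M[, keep, drop = FALSE]
  p_ <- ncol(M)
  Mf <- make_f32(M)
  set.seed(config$seed + 1L)
  n_tr <- floor(0.9 * nr)
  tr <- seq_len(n_tr); te <- (n_tr + 1):nr
  ytr <- yr[tr]; yte <- yr[te]
  spk_tr <- spike_index0(ytr)
  mu0 <- log(max(mean(ytr), 1e-6) / delta)
  null_pp <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- block_perm_indices(nr, config$block_len_ms)
    if (is.null(perm)) abort("session too short for block permutation")
    h <- gather_stats_f32(Mf, perm[tr])
    s_ <- sd_guard(h$sd)
    if (i == 1 && is.null(alpha)) {
      alpha <- select_alpha_two_group(h$xp, p_, ytr, config, delta)
    }
    fit <- fit_core_std_f32(h$xp, p_, spk_tr, alpha, mu0, numeric(p_),
                            delta, config$inner_tol, config$maxit,
                            h$mean, s_)
    hte <- gather_stats_f32(Mf, perm[te])
    pte <- pp_prob_std_f32(hte$xp, fit$mu, fit$A, delta, h$mean, s_)
    null_pp[i] <- roc_hull_pp_cpp(pte, yte)
  }
  list(threshold = unname(quantile(null_pp, 0.95)),
       null_pp = null_pp, alpha = alpha)
}

# Inner two-group penalty selection on a (float) training matrix pointer.
select_alpha_two_group <- function(xptr, p_, ytr, config, delta) {
  n <- length(ytr)
  g <- sample(rep_len(1:2, n))
  i1 <- which(g == 1); i2 <- which(g == 2)
  h1 <- gather_stats_f32(xptr, i1); h2 <- gather_stats_f32(xptr, i2)
  s1 <- sd_guard(h1$sd); s2 <- sd_guard(h2$sd)
  alphas <- sort(config$alpha_grid, decreasing = TRUE)
  pp_a <- numeric(length(alphas))
  mu0 <- log(max(mean(ytr), 1e-6) / delta)
  spk1 <- spike_index0(ytr[i1]); spk2 <- spike_index0(ytr[i2])
  w1 <- w2 <- NULL
  for (a in seq_along(alphas)) {
    f1 <- fit_core_std_f32(h1$xp, p_, spk1, alphas[a],
                           if (is.null(w1)) mu0 else w1$mu,
                           if (is.null(w1)) numeric(p_) else w1$A,
                           delta, config$inner_tol, config$inner_maxit,
                           h1$mean, s1)
    f2 <- fit_core_std_f32(h2$xp, p_, spk2, alphas[a],
                           if (is.null(w2)) mu0 else w2$mu,
                           if (is.null(w2)) numeric(p_) else w2$A,
                           delta, config$inner_tol, config$inner_maxit,
                           h2$mean, s2)
    w1 <- f1; w2 <- f2
    p2 <- pp_prob_std_f32(h2$xp, f1$mu, f1$A, delta, h1$mean, s1)
    p1 <- pp_prob_std_f32(h1$xp, f2$mu, f2$A, delta, h2$mean, s2)
    pp_a[a] <- (roc_hull_pp_cpp(p2, ytr[i2]) + roc_hull_pp_cpp(p1, ytr[i1])) / 2
  }
  alphas[which.max(pp_a)]
}

#' Compare nested feature sets across a unit population
#'
#' Computes the per-unit change in predictive power between a base and an
#' extended feature set and tests whether the median change differs from
#' zero (two-sided Wilcoxon signed-rank; zero differences discarded by the
#' standard convention, and a fully degenerate comparison reports p = 1).
#' Significance is assessed at `0.05 / n_tests` (Bonferroni).
#'
#' @param pp_tbl A tibble with columns `unit`, `feature_set`, `pp` (pooled
#'   predictive power per unit), e.g. from [run_session()].
#' @param base,extended Feature-set names to compare.
#' @param n_tests Number of tests in the Bonferroni family (default 1).
#' @return An object of class `pp_comparison`.
#' @export
compare_feature_sets <- function(pp_tbl, base, extended, n_tests = 1) {
  b <- pp_tbl[pp_tbl$feature_set == base, c("unit", "pp")]
  e <- pp_tbl[pp_tbl$feature_set == extended, c("unit", "pp")]
  if (nrow(b) == 0 || nrow(e) == 0) abort("feature set not found in pp_tbl")
  m <- dplyr::inner_join(b, e, by = "unit", suffix = c("_base", "_ext"))
  if (nrow(m) != nrow(b) || nrow(m) != nrow(e)) {
    abort("unit lists differ between the two feature sets")
  }
  if (nrow(m) < 6) {
    warn("fewer than 6 units; the signed-rank test has little power")
  }
  d <- m$pp_ext - m$pp_base
  p <- if (all(d == 0)) 1 else
    suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided"))$p.value
  structure(list(base = base, extended = extended,
                 delta_pp = d, units = m$unit,
                 mean_delta = mean(d), median_delta = median(d),
                 p_value = p, n_tests = n_tests,
                 significant = p < 0.05 / n_tests),
            class = "pp_comparison")
}

#' @export
print.pp_comparison <- function(x, ...) {
  cat(sprintf("<pp_comparison %s -> %s: median dPP %+0.4f (mean %+0.4f), p = %.3g%s, n = %d>\n",
              x$base, x$extended, x$median_delta, x$mean_delta, x$p_value,
              if (x$n_tests > 1) sprintf(" (Bonferroni x%d)", x$n_tests) else "",
              length(x$delta_pp)))
  invisible(x)
}

#' @export
tidy.pp_comparison <- function(x, ...) {
  tibble(base = x$base, extended = x$extended,
         n_units = length(x$delta_pp),
         mean_delta = x$mean_delta, median_delta = x$median_delta,
         p_value = x$p_value, n_tests = x$n_tests,
         significant = x$significant)
}
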