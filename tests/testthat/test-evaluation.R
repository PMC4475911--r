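test_that("block shuffle permutes chunks without altering their contents", {
  set.seed(51)
  b <- tibble::tibble(t_ms = 0:999, a = rnorm(1000), c = rnorm(1000))
  sh <- block_shuffle(b, block_len_ms = 100, seed = 3)
  expect_identical(sh$t_ms, b$t_ms)
  expect_equal(sort(sh$a), sort(b$a))
  expect_false(identical(sh$a, b$a))
  # columns move together
  i <- match(b$a[1], sh$a)
  expect_identical(sh$c[i], b$c[1])
  # determinism
  sh2 <- block_shuffle(b, block_len_ms = 100, seed = 3)
  expect_identical(sh, sh2)
})

test_that("block shuffle warns and returns input when there is one chunk", {
  b <- tibble::tibble(t_ms = 0:99, a = rnorm(100))
  expect_warning(out <- block_shuffle(b, block_len_ms = 100), "chunks")
  expect_identical(out, b)
})

test_that("shuffling preserves autocorrelation but destroys alignment", {
  set.seed(52)
  drive <- as.numeric(stats::filter(rnorm(20000), rep(1, 50) / 50,
                                    sides = 1))
  drive[is.na(drive)] <- 0
  drive <- drive / sd(drive)
  y <- as.integer(runif(20000) < plogis(2 * drive - 3.5))
  b <- tibble::tibble(t_ms = seq_len(20000) - 1, drive = drive)
  sh <- block_shuffle(b, 100, seed = 4)
  ac <- function(v) cor(v[-1], v[-length(v)])
  expect_gt(ac(sh$drive), 0.8 * ac(b$drive)) # within-chunk structure intact
  expect_gt(cor(b$drive, y), 0.1)
  # alignment destroyed: residual correlation at the chunk-count noise level
  expect_lt(abs(cor(sh$drive, y)), 0.25 * cor(b$drive, y))
})

test_that("cv_config validates the penalty grid", {
  expect_error(cv_config(alpha_grid = c(1e-3, 1)), "contain 0")
  expect_error(cv_config(alpha_grid = c(0, -1)), "non-negative")
  expect_equal(length(cv_config()$alpha_grid), 11)
})

test_that("outer folds partition the usable bins exactly once", {
  s <- local_small_session()
  y <- s$spikes[[1]]
  cfg <- cv_config(seed = 5)
  cv <- suppressWarnings(
    nested_cv_fit(s$blocks["lfp"], y, cfg, rows = s$usable_rows))
  expect_equal(sort(unique(cv$fold_id)), 1:10)
  expect_equal(length(cv$fold_id), length(s$usable_rows))
  expect_true(all(table(cv$fold_id) >= floor(length(s$usable_rows) / 10) - 1))
  expect_true(all(is.finite(cv$pred)))
  expect_true(all(cv$pp_per_fold >= 0 & cv$pp_per_fold <= 1))
})

test_that("nested CV is deterministic given the config seed", {
  s <- local_small_session()
  y <- s$spikes[[2]]
  blocks <- list(lfp = s$blocks$lfp[c("t_ms", "delta_re", "delta_amp",
                                      "beta_amp")])
  cfg <- cv_config(seed = 6)
  cv1 <- suppressWarnings(nested_cv_fit(blocks, y, cfg, rows = s$usable_rows))
  cv2 <- suppressWarnings(nested_cv_fit(blocks, y, cfg, rows = s$usable_rows))
  expect_identical(cv1$pp_pooled, cv2$pp_pooled)
  expect_identical(cv1$selected_alphas, cv2$selected_alphas)
})

test_that("pure-noise features score near chance; real features score above it", {
  s <- local_small_session()
  y <- s$spikes[[1]]
  cfg <- cv_config(seed = 7)
  noise <- tibble::tibble(t_ms = s$blocks$kin$t_ms,
                          n1 = rnorm(nrow(s$blocks$kin)),
                          n2 = rnorm(nrow(s$blocks$kin)))
  cv_noise <- suppressWarnings(
    nested_cv_fit(list(noise = noise), y, cfg, rows = s$usable_rows))
  cv_kin <- suppressWarnings(
    nested_cv_fit(s$blocks["kin"], y, cfg, rows = s$usable_rows))
  ch <- suppressWarnings(
    chance_level(list(noise = noise), y, cfg, n_perm = 20,
                 rows = s$usable_rows, alpha = 1e-4))
  expect_lt(cv_noise$pp_pooled, max(0.05, ch$threshold * 1.5))
  expect_gt(cv_kin$pp_pooled, 0.3)
  expect_gt(cv_kin$pp_pooled, 3 * cv_noise$pp_pooled)
  expect_equal(length(ch$null_pp), 20)
  expect_lt(abs(median(ch$null_pp)), max(0.05, ch$threshold))
})

test_that("predictive power grows with session length on ground-truth features", {
  tr <- ground_truth_spec()
  s_short <- suppressWarnings(generate_session(tr, 40, 1, seed = 61))
  s_long <- suppressWarnings(generate_session(tr, 150, 1, seed = 61))
  cfg <- cv_config(seed = 8)
  pp_short <- suppressWarnings(
    nested_cv_fit(s_short$blocks["kin"], s_short$spikes[[1]], cfg,
                  rows = s_short$usable_rows))$pp_pooled
  pp_long <- suppressWarnings(
    nested_cv_fit(s_long$blocks["kin"], s_long$spikes[[1]], cfg,
                  rows = s_long$usable_rows))$pp_pooled
  expect_gt(pp_long, 0.3)
  expect_gt(pp_long, pp_short - 0.05) # longer sessions do at least as well
})

test_that("comparison bookkeeping: identical and shifted populations", {
  pp_tbl <- tibble::tibble(unit = rep(1:10, 2),
                           feature_set = rep(c("kin", "kin+x"), each = 10),
                           pp = c(seq(0.2, 0.4, length.out = 10),
                                  seq(0.2, 0.4, length.out = 10)))
  cmp <- compare_feature_sets(pp_tbl, "kin", "kin+x")
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$median_delta, 0)
  pp_tbl$pp[11:20] <- pp_tbl$pp[11:20] + 0.1
  cmp2 <- compare_feature_sets(pp_tbl, "kin", "kin+x", n_tests = 3)
  expect_lt(cmp2$p_value, 0.05 / 3)
  expect_true(cmp2$significant)
  expect_equal(cmp2$median_delta, 0.1)
  expect_error(compare_feature_sets(pp_tbl, "kin", "nope"), "not found")
})

test_that("adding duplicated columns is detected as redundant", {
  s <- local_small_session()
  cfg <- cv_config(seed = 9)
  pp_rows <- list()
  for (u in 1) {
    y <- s$spikes[[u]]
    base <- suppressWarnings(
      nested_cv_fit(s$blocks["kin"], y, cfg, rows = s$usable_rows))
    dup_block <- s$blocks$kin
    names(dup_block) <- c("t_ms", paste0("dup_", names(dup_block)[-1]))
    ext <- suppressWarnings(
      nested_cv_fit(list(kin = s$blocks$kin, dup = dup_block), y, cfg,
                    rows = s$usable_rows))
    pp_rows[[u]] <- tibble::tibble(unit = u,
                                   feature_set = c("kin", "kin+dup"),
                                   pp = c(base$pp_pooled, ext$pp_pooled))
  }
  tbl <- dplyr::bind_rows(pp_rows)
  d <- tbl$pp[tbl$feature_set == "kin+dup"] - tbl$pp[tbl$feature_set == "kin"]
  expect_lt(max(abs(d)), 0.03) # no new information, no PP change
})
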