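test_that("Savitzky-Golay kernels reproduce polynomials exactly", {
  kd <- savgol_kernel(5, 25, deriv = 1)
  ks <- savgol_kernel(5, 25, deriv = 0)
  x <- seq(-25, 25)
  # derivative of a ramp of slope c is c; smoothing reproduces the value
  expect_lt(abs(sum(kd * (3.7 * x + 2)) - 3.7), 1e-10)
  expect_lt(abs(sum(kd * rep(5, 51))), 1e-10)
  expect_lt(abs(sum(ks * (3.7 * x + 2)) - 2), 1e-10)
  # cubic term handled exactly by a 5th-order fit
  expect_lt(abs(sum(kd * x^3)), 1e-9)
})

test_that("the differentiator attenuates above 20 Hz relative to the ideal", {
  k <- savgol_kernel(5, 25, deriv = 1)
  fs <- 240
  gain_at <- function(f) {
    taps <- seq(-25, 25)
    Mod(sum(k * exp(-2i * pi * f / fs * taps)))
  }
  ideal <- function(f) 2 * pi * f / fs
  # near-ideal at low frequency, attenuated at 20+ Hz
  expect_lt(abs(gain_at(2) / ideal(2) - 1), 0.05)
  expect_lt(gain_at(25) / ideal(25), 0.5)
})

test_that("window/order validation", {
  expect_error(savgol_kernel(5, 2), "too short")
  expect_error(savgol_kernel(0, 10), ">= 1")
})

test_that("smooth_velocity recovers the analytic derivative of a tone", {
  fs <- 240
  t <- seq(0, 10, by = 1 / fs)
  kin <- tibble::tibble(t_ms = t * 1000,
                        x = 10 * sin(2 * pi * 1 * t), y = 0 * t, z = 0 * t,
                        aperture = 20 + 0 * t)
  sv <- smooth_velocity(kin)
  expect_equal(diff(sv$t_ms[1:2]), 25) # exactly 40 S/s
  interior <- 20:(nrow(sv) - 20)
  vmax <- max(abs(sv$vx[interior]))
  expect_lt(abs(vmax - 2 * pi * 10) / (2 * pi * 10), 0.03)
  expect_lt(max(abs(sv$vy)), 1e-9)
  expect_lt(max(abs(sv$va)), 1e-9)
})

test_that("differentiation is linear", {
  set.seed(4)
  fs <- 240
  n <- 2400
  mk <- function(v) tibble::tibble(t_ms = (seq_len(n) - 1) / fs * 1000,
                                   x = v, y = v, z = v, aperture = v)
  f <- cumsum(rnorm(n)); g <- cumsum(rnorm(n))
  vf <- smooth_velocity(mk(f))$vx
  vg <- smooth_velocity(mk(g))$vx
  vfg <- smooth_velocity(mk(2 * f - 3 * g))$vx
  expect_lt(max(abs(vfg - (2 * vf - 3 * vg))), 1e-9)
})

test_that("pathlets of a motionless record are zero with constant positions", {
  n <- 240 * 5
  kin <- tibble::tibble(t_ms = (seq_len(n) - 1) / 240 * 1000,
                        x = 12, y = -3, z = 150, aperture = 22)
  pf <- pathlet_features(kin)
  mid <- pf[2000:3000, ]
  vel_cols <- grep("^vel_", names(pf), value = TRUE)
  expect_true(all(abs(as.matrix(mid[vel_cols])) < 1e-12))
  expect_true(all(abs(mid$pos_wx - 12) < 1e-9))
  expect_true(all(abs(mid$pos_ap - 22) < 1e-9))
  expect_true(all(mid$mean_speed_wrist < 1e-9))
})

test_that("pathlet rows have 74 columns and unit-norm wrist trajectories", {
  kin <- generate_kinematics(10, reach_rate_hz = 1, seed = 9)
  pf <- pathlet_features(kin)
  expect_equal(ncol(pf) - 1, 74)
  wcols <- grep("^vel_w", names(pf), value = TRUE)
  acols <- grep("^vel_ap", names(pf), value = TRUE)
  expect_equal(length(wcols), 51)
  expect_equal(length(acols), 17)
  ok <- stats::complete.cases(pf)
  W <- as.matrix(pf[ok, wcols])
  norms <- sqrt(rowSums(W^2))
  moving <- norms > 1e-6
  expect_true(any(moving))
  expect_lt(max(abs(norms[moving] - 1)), 1e-9)
})

test_that("time reversal mirrors, lag-reverses and sign-flips the pathlet", {
  kin <- generate_kinematics(10.5, reach_rate_hz = 1, seed = 10)
  # truncate so the record spans exactly 10 s and the reversal maps the
  # 240 Hz samples (and hence the 25 ms feature grid) onto themselves
  kin <- kin[1:2401, ]
  rkin <- kin
  rkin$x <- rev(kin$x); rkin$y <- rev(kin$y); rkin$z <- rev(kin$z)
  rkin$aperture <- rev(kin$aperture)
  # raw (unnormalized) velocities: the per-row norm spans the asymmetric
  # -100..+300 ms window, which reversal maps onto -300..+100
  pf <- pathlet_features(kin, normalize = FALSE)
  pr <- pathlet_features(rkin, normalize = FALSE)
  lag_nm <- function(l) ifelse(l < 0, paste0("m", -l), paste0("p", l))
  lags_sym <- seq(-100, 100, by = 25) # overlap of the two lag windows
  tg <- seq(1000, 8000, by = 25)
  tm <- 10000 - tg # mirrored grid times, exactly on the 25 ms grid
  for (ch in c("wx", "ap")) {
    A <- as.matrix(pf[match(tg, pf$t_ms),
                      paste0("vel_", ch, "_", lag_nm(lags_sym))])
    B <- as.matrix(pr[match(tm, pr$t_ms),
                      paste0("vel_", ch, "_", lag_nm(-lags_sym))])
    # reversed record at mirrored times: lag-reversed and sign-flipped
    expect_lt(max(abs(A + B), na.rm = TRUE), 1e-8)
  }
})

test_that("position trajectories: 68 columns, ramps differ by slope x lag", {
  n <- 240 * 6
  tt <- (seq_len(n) - 1) / 240
  kin <- tibble::tibble(t_ms = tt * 1000,
                        x = 40 * tt, y = 0, z = 0, aperture = 20)
  pt <- position_trajectory_features(kin)
  expect_equal(ncol(pt) - 1, 68)
  mid <- pt[pt$t_ms == 3000, ]
  x_m100 <- mid[["pos_wx_m100"]]
  x_p300 <- mid[["pos_wx_p300"]]
  expect_lt(abs((x_p300 - x_m100) - 40 * 0.4), 1e-6)
  expect_true(all(abs(as.matrix(mid[grep("pos_ap", names(mid))]) - 20) < 1e-9))
})

test_that("missing samples are rejected", {
  kin <- generate_kinematics(2, seed = 1)
  kin$x[10] <- NA
  expect_error(smooth_velocity(kin), "missing")
})
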