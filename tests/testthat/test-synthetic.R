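test_that("kinematics generation is deterministic and smooth", {
  k1 <- generate_kinematics(10, 0.5, seed = 7)
  k2 <- generate_kinematics(10, 0.5, seed = 7)
  expect_identical(k1, k2)
  # discrete second difference bounded: no jumps
  for (ch in c("x", "y", "z", "aperture")) {
    expect_lt(max(abs(diff(diff(k1[[ch]])))), 5)
  }
})

test_that("zero reach rate gives a motionless record", {
  k <- generate_kinematics(5, 0, seed = 1)
  expect_equal(diff(range(k$x)), 0)
  expect_equal(diff(range(k$aperture)), 0)
})

test_that("delta-only LFP concentrates its power below 2 Hz", {
  tr <- ground_truth_spec(
    band_amps = c(delta = 30, theta = 0, alpha = 0, beta = 0,
                  gamma1 = 0, gamma2 = 0, mua1 = 0, mua2 = 0),
    background_amp = 0, coupling = 0)
  lfp <- generate_lfp(tr, 60, 1000, seed = 8)
  sp <- stats::spec.pgram(stats::ts(lfp$value, frequency = 1000),
                          taper = 0, plot = FALSE)
  inband <- sum(sp$spec[sp$freq <= 2.5])
  expect_gt(inband / sum(sp$spec), 0.9)
})

test_that("zero amplitudes and background give a zero LFP", {
  tr <- ground_truth_spec(
    band_amps = c(delta = 0, theta = 0, alpha = 0, beta = 0,
                  gamma1 = 0, gamma2 = 0, mua1 = 0, mua2 = 0),
    background_amp = 0, coupling = 0)
  lfp <- generate_lfp(tr, 5, 1000, seed = 9)
  expect_identical(lfp$value, numeric(5000))
})

test_that("full coupling ties the delta band to the kinematic speed", {
  set.seed(10)
  kin <- generate_kinematics(120, 0.5)
  sv <- smooth_velocity(kin)
  speed40 <- sqrt(sv$vx^2 + sv$vy^2 + sv$vz^2)
  t_lfp <- seq_len(120 * 1000) - 1
  speed <- stats::approx(sv$t_ms, speed40, xout = t_lfp, rule = 2)$y
  # speed_lead_s = 0 so generated delta and filtered speed align at lag 0;
  # the reference gets the same two filtering stages (generation + analysis)
  # as the speed component embedded in the LFP
  flt <- design_band_filter(0.3, 2, 1000)
  ref <- sos_filtfwd(flt, sos_filtfwd(flt, speed - mean(speed)))
  cors <- vapply(c(0, 0.5, 1), function(cp) {
    tr <- ground_truth_spec(coupling = cp, background_amp = 2)
    lfp <- generate_lfp(tr, 120, 1000, speed = speed, speed_lead_s = 0,
                        seed = 11)
    stats::cor(sos_filtfwd(flt, lfp$value), ref)
  }, numeric(1))
  expect_true(all(diff(cors) > 0)) # monotone in the coupling
  expect_gt(cors[3], 0.9)
})

test_that("homogeneous spiking matches the binomial closed form", {
  tr <- ground_truth_spec(lfp_weights = c(delta_re = 0),
                          kin_weights = c(mean_speed_wrist = 0),
                          history_weights = numeric(10),
                          mu_log = log(10))
  X <- matrix(0, 100000, 1, dimnames = list(NULL, "delta_re"))
  y <- generate_spikes(tr, X, seed = 12)
  ci <- qbinom(c(0.005, 0.995), 100000, 0.01)
  expect_gte(sum(unclass(y)), ci[1])
  expect_lte(sum(unclass(y)), ci[2])
  expect_true(all(unclass(y) %in% c(0L, 1L)))
})

test_that("generation is reproducible and conserves the realized rate", {
  tr <- ground_truth_spec()
  s1 <- generate_session(tr, duration_s = 30, n_units = 1, seed = 13)
  s2 <- generate_session(tr, duration_s = 30, n_units = 1, seed = 13)
  expect_identical(unclass(s1$spikes[[1]]), unclass(s2$spikes[[1]]))
  expect_identical(s1$lfp$value, s2$lfp$value)
  y <- s1$spikes[[1]]
  mu_exp <- attr(y, "expected_spikes")
  se <- sqrt(attr(y, "var_spikes"))
  expect_lt(abs(sum(unclass(y)) - mu_exp), 3 * se)
})

test_that("a refractory history filter suppresses short ISIs", {
  base <- ground_truth_spec(lfp_weights = c(delta_re = 0),
                            kin_weights = c(mean_speed_wrist = 0),
                            history_weights = numeric(10),
                            mu_log = log(40))
  refr <- ground_truth_spec(lfp_weights = c(delta_re = 0),
                            kin_weights = c(mean_speed_wrist = 0),
                            history_weights = c(-15, rep(0, 9)),
                            mu_log = log(40))
  X <- matrix(0, 200000, 1, dimnames = list(NULL, "delta_re"))
  isi_frac <- function(tr, seed) {
    y <- generate_spikes(tr, X, seed = seed)
    isi <- diff(which(unclass(y) == 1))
    mean(isi < 3)
  }
  f_base <- isi_frac(base, 14)
  f_refr <- isi_frac(refr, 14)
  expect_gt(f_base, 0.05) # Poisson at 40 Hz has plenty of short ISIs
  expect_lt(f_refr, 0.01 * f_base + 1e-6)
})

test_that("intensity clipping triggers a warning", {
  tr <- ground_truth_spec(lfp_weights = c(delta_re = 5),
                          kin_weights = c(mean_speed_wrist = 0),
                          history_weights = numeric(10),
                          mu_log = log(500))
  X <- matrix(rnorm(5000), 5000, 1, dimnames = list(NULL, "delta_re"))
  expect_warning(generate_spikes(tr, X, seed = 15), "Bernoulli")
})

test_that("sessions round-trip through the plain-text format", {
  withr::local_seed(16)
  s <- local_small_session()
  dir <- withr::local_tempdir()
  write_session(s, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  s2 <- read_session(dir)
  expect_equal(s2$duration_s, s$duration_s)
  expect_equal(length(s2$spikes), length(s$spikes))
  expect_identical(which(unclass(s2$spikes[[1]]) == 1L),
                   which(unclass(s$spikes[[1]]) == 1L))
  expect_equal(s2$truth$lfp_weights, s$truth$lfp_weights)
  expect_equal(s2$kin$x, s$kin$x, tolerance = 1e-9)
})
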