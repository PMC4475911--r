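#' Ground truth for a synthetic recording session
#'
#' Fully specifies the generative model from which synthetic sessions are
#' drawn: the baseline log-rate, the weights on (z-scored) LFP and kinematic
#' features and on the raw spike-history basis convolutions, the per-band LFP
#' signal amplitudes, and the fraction of delta-band LFP variance driven by
#' the kinematic speed (the shared drive that makes LFP/kinematics redundancy
#' detectable downstream).
#'
#' The defaults describe a motor-cortex-like unit: ~8 spikes/s baseline,
#' cosine phase tuning to the delta band with preferred phase 2*pi/3,
#' a positive delta analytic-signal weight, a negative beta-amplitude weight
#' (firing increases when beta desynchronizes), speed-dominated pathlet
#' tuning, and a strongly refractory short-lag history filter with a mild
#' bursting rebound.
#'
#' @param mu_log Baseline log-rate, log(spikes/s).
#' @param lfp_weights Named weights on LFP feature columns (missing names
#'   default to 0).
#' @param kin_weights Named weights on pathlet feature columns.
#' @param history_weights Weights on the raised-cosine history bases.
#' @param coupling Fraction of delta-band LFP variance driven by kinematic
#'   speed, in \[0, 1\].
#' @param band_amps Named per-band oscillation amplitudes (microvolts).
#' @param background_amp Amplitude (sd, microvolts) of the 1/f background.
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(mu_log = log(8),
                              lfp_weights = default_lfp_weights(),
                              kin_weights = default_kin_weights(),
                              history_weights = default_history_weights(),
                              coupling = 0.5,
                              band_amps = default_band_amps(),
                              background_amp = 10) {
  stopifnot(is.finite(mu_log), all(is.finite(lfp_weights)),
            all(is.finite(kin_weights)), all(is.finite(history_weights)),
            all(is.finite(band_amps)), is.finite(background_amp))
  if (coupling < 0 || coupling > 1) abort("coupling must be in [0, 1]")
  structure(list(mu_log = mu_log, lfp_weights = lfp_weights,
                 kin_weights = kin_weights,
                 history_weights = history_weights,
                 coupling = coupling, band_amps = band_amps,
                 background_amp = background_amp),
            class = "ground_truth_spec")
}

#' @export
print.ground_truth_spec <- function(x, ...) {
  cat(sprintf("<ground_truth_spec: baseline %.1f spikes/s, %d lfp + %d kin + %d history weights, coupling %.2f>\n",
              exp(x$mu_log), sum(x$lfp_weights != 0), sum(x$kin_weights != 0),
              sum(x$history_weights != 0), x$coupling))
  invisible(x)
}

#' @rdname ground_truth_spec
#' @export
default_lfp_weights <- function() {
  theta0 <- 2 * pi / 3
  c(delta_cos = 0.4 * cos(theta0), delta_sin = 0.4 * sin(theta0),
    delta_re = 0.3, beta_amp = -0.15, mua2_amp = 0.2)
}

#' @rdname ground_truth_spec
#' @export
default_kin_weights <- function() {
  lags <- pathlet_lags_ms()
  # adjacent lag columns are strongly correlated, so bump weights add almost
  # coherently; small per-lag weights keep the kinematic drive sd near 0.7
  wx <- 0.08 * exp(-(lags - 100)^2 / (2 * 75^2))
  names(wx) <- paste0("vel_wx_", lag_label(lags))
  ap <- 0.05 * exp(-(lags - 50)^2 / (2 * 75^2))
  names(ap) <- paste0("vel_ap_", lag_label(lags))
  c(mean_speed_wrist = 0.35, mean_speed_ap = 0.15, wx, ap)
}

#' @rdname ground_truth_spec
#' @export
default_history_weights <- function() {
  c(-6, -3, -1, 0.3, 0.15, 0.05, 0, 0, 0, 0)
}

#' @rdname ground_truth_spec
#' @export
default_band_amps <- function() {
  c(delta = 40, theta = 15, alpha = 12, beta = 15,
    gamma1 = 8, gamma2 = 6, mua1 = 4, mua2 = 3)
}

#' Generate smooth 3-D reach-and-grasp kinematics
#'
#' Wrist position follows minimum-jerk point-to-point reaches to random
#' targets in a 300 mm workspace at exponentially distributed intervals
#' (~`reach_rate_hz` reaches per second); the grasp aperture opens during
#' each reach, closes around its end, and relaxes back to baseline.  Sampled
#' at 240 frames/s.
#'
#' @param duration_s Session length in seconds.
#' @param reach_rate_hz Mean reach rate; 0 gives a motionless record.
#' @param seed Optional RNG seed (two calls with the same seed are
#'   identical).
#' @param fs_hz Sampling rate (default 240 frames/s).
#' @return A kinematic record: tibble with `t_ms`, `x`, `y`, `z`, `aperture`
#'   (mm).
#' @export
generate_kinematics <- function(duration_s, reach_rate_hz = 0.4, seed = NULL,
                                fs_hz = 240) {
  check_positive(duration_s, "duration_s")
  if (reach_rate_hz < 0) abort("reach_rate_hz must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  pos <- matrix(0, n, 3)
  ap <- rep(20, n)
  start <- c(0, 0, 100)
  pos[, 1] <- start[1]; pos[, 2] <- start[2]; pos[, 3] <- start[3]
  if (reach_rate_hz > 0) {
    tcur <- stats::rexp(1, reach_rate_hz)
    cur <- start
    minjerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5
    while (tcur < duration_s) {
      dur <- runif(1, 0.4, 0.8)
      target <- c(runif(1, -150, 150), runif(1, -150, 150), runif(1, 0, 300))
      i0 <- floor(tcur * fs_hz) + 1
      i1 <- min(n, floor((tcur + dur) * fs_hz) + 1)
      if (i0 > n) break
      s <- (seq(i0, i1) - i0) / max(i1 - i0, 1)
      prof <- minjerk(pmin(pmax(s, 0), 1))
      for (d in 1:3) {
        pos[i0:i1, d] <- cur[d] + (target[d] - cur[d]) * prof
        if (i1 < n) pos[(i1 + 1):n, d] <- target[d]
      }
      # aperture: open to a grasp-sized peak at 75% of the reach, close, relax
      peak <- runif(1, 60, 90)
      ip <- i0 + round(0.75 * (i1 - i0))
      ic <- min(n, i1 + round(0.2 * fs_hz))
      seg <- function(i_from, i_to, v_from, v_to) {
        if (i_to <= i_from) return()
        ss <- (seq(i_from, i_to) - i_from) / (i_to - i_from)
        ap[i_from:i_to] <<- v_from + (v_to - v_from) * minjerk(ss)
      }
      seg(i0, ip, ap[i0], peak)
      seg(ip, i1, peak, 15)
      seg(i1, ic, 15, 20)
      if (ic < n) ap[(ic + 1):n] <- 20
      cur <- target
      tcur <- tcur + dur + stats::rexp(1, reach_rate_hz)
    }
  }
  tibble(t_ms = t * 1000, x = pos[, 1], y = pos[, 2], z = pos[, 3],
         aperture = ap)
}

#' Generate a multiband synthetic LFP
#'
#' Sums eight narrowband oscillations — band-limited Gaussian noise carriers
#' modulated by slowly varying envelopes (rectified 0.5 Hz low-pass noise) —
#' plus a 1/f background.  The delta-band carrier is a mixture of independent
#' noise and the (delta-band-filtered, standardized) kinematic speed in
#' proportion `sqrt(coupling)`, emulating the strong correlation between
#' slow motor-cortex potentials and movement.
#'
#' @param truth A [ground_truth_spec()].
#' @param duration_s Session length (s).
#' @param fs_hz Sampling rate (>= 1000).
#' @param speed Optional kinematic speed signal sampled at `fs_hz`, required
#'   for `coupling > 0`.
#' @param speed_lead_s Lead (seconds) applied to the speed before it enters
#'   the delta band.  Slow motor potentials accompany or precede movement,
#'   whereas the causal generation and feature-extraction filters together
#'   delay their input by roughly this much at delta frequencies; the lead
#'   cancels that delay so the coupled component reflects concurrent
#'   movement.
#' @param seed Optional RNG seed.
#' @return A tibble with `t_ms` and `value` (microvolts).
#' @export
generate_lfp <- function(truth, duration_s, fs_hz = 1000, speed = NULL,
                         speed_lead_s = 1, seed = NULL) {
  check_positive(duration_s, "duration_s")
  if (fs_hz < 1000) abort("fs_hz must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs_hz)
  bands <- lfp_bands()
  env_lp <- design_lowpass_filter(0.5, fs_hz, 4)
  out <- numeric(n)
  for (i in seq_len(nrow(bands))) {
    amp <- truth$band_amps[[bands$band[i]]] %||% 0
    if (amp == 0) next
    flt <- design_band_filter(bands$low_hz[i], bands$high_hz[i], fs_hz)
    carrier <- sos_filtfwd(flt, rnorm(n))
    carrier <- carrier / max(sd(carrier), 1e-12)
    env <- abs(sos_filtfwd(env_lp, rnorm(n)))
    env <- env / max(mean(env), 1e-12)
    band_sig <- env * carrier
    if (bands$band[i] == "delta" && truth$coupling > 0) {
      if (is.null(speed)) {
        warn("coupling > 0 but no speed signal supplied; delta band left uncoupled")
      } else {
        # the coupled component is a pure functional of the kinematic speed
        # (no envelope modulation), so coupling = 1 makes the delta band
        # fully movement-driven
        k <- round(speed_lead_s * fs_hz)
        sp_in <- if (k > 0 && k < n) {
          c(speed[(k + 1):n], rep(speed[n], k))
        } else speed
        sp <- sos_filtfwd(flt, sp_in - mean(sp_in))
        sp <- sp / max(sd(sp), 1e-12)
        band_sig <- sqrt(1 - truth$coupling) * band_sig +
          sqrt(truth$coupling) * sp
      }
    }
    out <- out + amp * band_sig
  }
  if (truth$background_amp > 0) {
    out <- out + truth$background_amp * one_over_f_noise(n)
  }
  tibble(t_ms = (seq_len(n) - 1) * 1000 / fs_hz, value = out)
}

one_over_f_noise <- function(n) {
  w <- rnorm(n)
  wf <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric frequency index
  shaped <- Re(fft(wf / sqrt(f), inverse = TRUE)) / n
  shaped / sd(shaped)
}

#' Construct a binned spike train
#'
#' @param y 0/1 vector, one entry per 1 ms bin.
#' @param t0_ms Start time of the first bin.
#' @return An object of class `binned_spikes`.
#' @export
binned_spikes <- function(y, t0_ms = 0) {
  y <- as_spike_vector(y)
  if (length(y) < 1) abort("spike train must have length >= 1")
  structure(y, class = "binned_spikes", t0_ms = t0_ms, bin_width_ms = 1)
}

#' @export
print.binned_spikes <- function(x, ...) {
  cat(sprintf("<binned_spikes: %d spikes in %d x 1 ms bins (%.1f spikes/s)>\n",
              sum(unclass(x)), length(x), 1000 * mean(unclass(x))))
  invisible(x)
}

#' @rdname binned_spikes
#' @param x A `binned_spikes` object.
#' @return `spike_times()`: event times in ms (bin centers).
#' @export
spike_times <- function(x) {
  which(unclass(x) == 1L) - 1 + attr(x, "t0_ms") + 0.5
}

#' Simulate spikes from a ground-truth conditional intensity
#'
#' Draws a Bernoulli spike per 1 ms bin with probability
#' `min(lambda_t * Delta, 1)`, where `ln(lambda_t)` is the ground-truth
#' linear predictor over the supplied (z-scored) feature matrix plus the
#' recursive spike-history term: each emitted spike feeds back into the
#' intensity of the following 100 ms through the raised-cosine history
#' filter.  Warns if the Bernoulli approximation is strained (clipping in
#' more than 0.1% of bins).
#'
#' @param truth A [ground_truth_spec()]; weights are matched to the feature
#'   columns by name (unmatched columns get weight 0).
#' @param X Feature matrix or `pp_design` (z-scored), rows at 1 ms.
#' @param seed Optional RNG seed.
#' @param basis History basis (default [raised_cosine_basis()]).
#' @param delta Bin width in seconds.
#' @return A [binned_spikes()] with attributes `expected_spikes` (sum of the
#'   realized per-bin probabilities) and `var_spikes` (their Bernoulli
#'   variance), for rate-conservation checks.
#' @export
generate_spikes <- function(truth, X, seed = NULL,
                            basis = raised_cosine_basis(), delta = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  Xm <- design_X(X)
  w_all <- c(truth$lfp_weights, truth$kin_weights)
  w <- w_all[match(colnames(Xm), names(w_all))]
  w[is.na(w)] <- 0
  eta0 <- truth$mu_log + drop(Xm %*% w)
  hk <- drop(unclass(basis) %*% truth$history_weights)
  sim <- simulate_pp_cpp(eta0, hk, delta)
  if (sim$nclip > 0.001 * length(eta0)) {
    warn(sprintf("intensity exceeded 1/Delta in %.2f%% of bins; Bernoulli approximation is strained",
                 100 * sim$nclip / length(eta0)))
  }
  out <- binned_spikes(sim$y)
  attr(out, "expected_spikes") <- sum(sim$prob)
  attr(out, "var_spikes") <- sum(sim$prob * (1 - sim$prob))
  out
}

#' Generate a complete synthetic session
#'
#' Ties the generators together with the shared-drive structure the analysis
#' assumes: kinematics are drawn first; the wrist speed (interpolated to the
#' LFP rate) drives the delta-band LFP carrier in proportion to
#' `truth$coupling`; LFP and pathlet feature blocks are extracted by the
#' same code paths used for analysis and z-scored over the usable span; and
#' each unit's spike train is simulated from per-unit ground-truth weights
#' (multiplicative log-normal jitter around the template, plus a small
#' preferred-phase rotation, so the population is heterogeneous).
#'
#' @param truth Template [ground_truth_spec()].
#' @param duration_s Session length (default 600 s).
#' @param n_units Number of simultaneously generated units.
#' @param seed RNG seed for the whole session.
#' @param reach_rate_hz Reach rate for the kinematics.
#' @param unit_sd Log-normal sd of the per-unit weight jitter.
#' @param edge_ms Margin excluded from the usable span at both ends (filter
#'   and Hilbert transients, pathlet/history lags).
#' @return An object of class `pp_session`: lfp and kinematic records,
#'   feature blocks, per-unit spike trains and truths, and the usable rows.
#' @export
generate_session <- function(truth = ground_truth_spec(), duration_s = 600,
                             n_units = 1, seed = 1, reach_rate_hz = 0.4,
                             unit_sd = 0.15, edge_ms = 2000) {
  set.seed(seed)
  fs_lfp <- 1000
  kin <- generate_kinematics(duration_s, reach_rate_hz)
  sv <- smooth_velocity(kin)
  speed40 <- sqrt(sv$vx^2 + sv$vy^2 + sv$vz^2)
  n_lfp <- round(duration_s * fs_lfp)
  t_lfp <- (seq_len(n_lfp) - 1) # ms
  speed <- stats::approx(sv$t_ms, speed40, xout = t_lfp, rule = 2)$y
  lfp <- generate_lfp(truth, duration_s, fs_lfp, speed = speed)
  lfp_block <- lfp_feature_block(lfp$value, fs_lfp)
  kin_block <- pathlet_features(kin)
  n <- min(nrow(lfp_block), nrow(kin_block))
  lfp_block <- lfp_block[seq_len(n), ]
  kin_block <- kin_block[seq_len(n), ]
  rows_ok <- usable_feature_rows(list(lfp = lfp_block, kin = kin_block))
  usable <- intersect((edge_ms + 1):(n - edge_ms), rows_ok)
  # generative design: z-scored over the usable span, zero-filled outside it
  zs <- function(b) {
    m <- as.matrix(b[setdiff(names(b), "t_ms")])
    mu <- colMeans(m[usable, , drop = FALSE])
    s <- apply(m[usable, , drop = FALSE], 2, sd)
    mz <- sweep(sweep(m, 2, mu, "-"), 2, sd_guard(s), "/")
    mz[!is.finite(mz)] <- 0
    mz
  }
  Xg <- cbind(zs(lfp_block), zs(kin_block))
  units <- vector("list", n_units)
  truths <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    tu <- jitter_truth(truth, unit_sd)
    truths[[u]] <- tu
    units[[u]] <- generate_spikes(tu, Xg)
  }
  structure(list(lfp = lfp, kin = kin, spikes = units, truths = truths,
                 truth = truth, duration_s = duration_s, fs_lfp = fs_lfp,
                 blocks = list(lfp = lfp_block, kin = kin_block),
                 usable_rows = usable, seed = seed),
            class = "pp_session")
}

# Per-unit heterogeneity: multiplicative log-normal jitter on every weight,
# a small rotation of the delta preferred phase (sd 2 * unit_sd rad), and
# baseline jitter (sd 2/3 * unit_sd); unit_sd = 0 reproduces the template.
jitter_truth <- function(truth, unit_sd) {
  jit <- function(w) w * exp(rnorm(length(w), 0, unit_sd))
  lw <- jit(truth$lfp_weights)
  if (all(c("delta_cos", "delta_sin") %in% names(lw))) {
    th <- atan2(lw[["delta_sin"]], lw[["delta_cos"]]) +
      rnorm(1, 0, 2 * unit_sd)
    dep <- sqrt(lw[["delta_cos"]]^2 + lw[["delta_sin"]]^2)
    lw[["delta_cos"]] <- dep * cos(th)
    lw[["delta_sin"]] <- dep * sin(th)
  }
  ground_truth_spec(mu_log = truth$mu_log + rnorm(1, 0, unit_sd * 2 / 3),
                    lfp_weights = lw,
                    kin_weights = jit(truth$kin_weights),
                    history_weights = jit(truth$history_weights),
                    coupling = truth$coupling,
                    band_amps = truth$band_amps,
                    background_amp = truth$background_amp)
}

#' @export
print.pp_session <- function(x, ...) {
  cat(sprintf("<pp_session: %.0f s, %d unit(s), %d usable 1 ms bins, coupling %.2f, seed %d>\n",
              x$duration_s, length(x$spikes), length(x$usable_rows),
              x$truth$coupling, x$seed))
  invisible(x)
}

#' Write / read a synthetic session as plain text
#'
#' Sessions are stored as a directory of delimited text: one CSV per signal
#' (`lfp.csv`, `kinematics.csv`), spike event times in ms per unit
#' (`spikes_unit<k>.csv`), and a JSON manifest with sampling rates, span and
#' the full ground-truth parameter set.
#'
#' @param session A `pp_session`.
#' @param dir Output directory (created if needed).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a `pp_session` (feature blocks are recomputed lazily by
#'   [run_session()]).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(session$lfp, file.path(dir, "lfp.csv"))
  readr::write_csv(session$kin, file.path(dir, "kinematics.csv"))
  for (u in seq_along(session$spikes)) {
    readr::write_csv(tibble(t_ms = spike_times(session$spikes[[u]])),
                     file.path(dir, sprintf("spikes_unit%02d.csv", u)))
  }
  # jsonlite writes named atomic vectors as unnamed arrays; lists keep names
  named_safe <- function(v) if (!is.null(names(v))) as.list(v) else v
  manifest <- list(
    fs_lfp_hz = session$fs_lfp, fs_kin_hz = kin_fs(session$kin),
    duration_s = session$duration_s, seed = session$seed,
    n_units = length(session$spikes),
    truth = lapply(unclass(session$truth), named_safe)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    abort(sprintf("session manifest not found: %s", mpath))
  }
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  lfp <- readr::read_csv(file.path(dir, "lfp.csv"),
                         show_col_types = FALSE)
  kin <- readr::read_csv(file.path(dir, "kinematics.csv"),
                         show_col_types = FALSE)
  n_ms <- floor(max(lfp$t_ms)) + 1
  spikes <- list()
  for (u in seq_len(man$n_units)) {
    ev <- readr::read_csv(file.path(dir, sprintf("spikes_unit%02d.csv", u)),
                          show_col_types = FALSE)
    y <- integer(n_ms)
    y[floor(ev$t_ms) + 1] <- 1L
    spikes[[u]] <- binned_spikes(y)
  }
  truth <- do.call(ground_truth_spec, lapply(man$truth, function(v) {
    if (is.list(v)) unlist(v) else v
  }))
  structure(list(lfp = lfp, kin = kin, spikes = spikes,
                 truths = NULL, truth = truth,
                 duration_s = man$duration_s, fs_lfp = man$fs_lfp_hz,
                 blocks = NULL, usable_rows = NULL, seed = man$seed),
            class = "pp_session")
}
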