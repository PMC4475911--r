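#' Savitzky-Golay smoothing / differentiation kernel
#'
#' Least-squares polynomial filter used to smooth and differentiate the
#' motion-capture channels.  The defaults (5th-order polynomial, halfwidth 25
#' samples at 240 frames/s) attenuate frequencies above ~20 Hz so the velocity
#' estimate can be down-sampled to 40 S/s without aliasing.
#'
#' @param poly_order Polynomial order (>= 1).
#' @param halfwidth Halfwidth of the window in samples; the kernel has
#'   `2 * halfwidth + 1` taps.
#' @param deriv Derivative order: 0 returns the smoothing kernel, 1 the
#'   differentiation kernel (units 1/sample).
#' @return Numeric kernel of length `2 * halfwidth + 1`, to be applied as a
#'   symmetric FIR filter.
#' @export
#' @examples
#' k <- savgol_kernel(5, 25, deriv = 1)
#' # exact slope recovery on a ramp
#' sum(k * seq(-25, 25) * 0.7)
savgol_kernel <- function(poly_order = 5, halfwidth = 25, deriv = 0) {
  if (poly_order < 1) abort("poly_order must be >= 1")
  n <- 2 * halfwidth + 1
  if (n <= poly_order) abort("window too short for the polynomial order")
  if (deriv > poly_order) abort("derivative order exceeds polynomial order")
  x <- seq(-halfwidth, halfwidth)
  A <- outer(x, 0:poly_order, `^`)
  # row `deriv` of the pseudo-inverse, times deriv! (Taylor coefficient)
  pinv <- solve(crossprod(A), t(A))
  pinv[deriv + 1, ] * factorial(deriv)
}

kin_fs <- function(kin) {
  dt <- diff(kin$t_ms[1:2])
  1000 / dt
}

apply_kernel <- function(x, k) {
  h <- (length(k) - 1) / 2
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  out <- stats::filter(xp, rev(k), sides = 2)  # convolution
  as.numeric(out[(h + 1):(h + length(x))])
}

#' Smoothed positions and velocities at 40 samples/s
#'
#' Applies the Savitzky-Golay differentiation kernel (scaled to mm/s) and the
#' matching smoothing kernel to each kinematic channel, then subsamples to
#' 40 S/s.  Edges are handled by constant extension of the first/last sample.
#'
#' @param kin Kinematic record: a tibble with columns `t_ms`, `x`, `y`, `z`,
#'   `aperture` sampled at 240 frames/s.
#' @param poly_order,halfwidth Kernel parameters, see [savgol_kernel()].
#' @param fs_out Output rate; must divide the input rate.  Default 40.
#' @return A tibble at `fs_out` with `t_ms`, velocities `vx, vy, vz, va`
#'   (mm/s) and smoothed positions `px, py, pz, pa` (mm).
#' @export
smooth_velocity <- function(kin, poly_order = 5, halfwidth = 25, fs_out = 40) {
  need <- c("t_ms", "x", "y", "z", "aperture")
  if (!all(need %in% names(kin))) {
    abort("`kin` must have columns t_ms, x, y, z, aperture")
  }
  if (anyNA(kin[need])) abort("missing samples in kinematic record")
  fs <- kin_fs(kin)
  dec <- fs / fs_out
  if (abs(dec - round(dec)) > 1e-8) abort("fs_out must divide the input rate")
  dec <- round(dec)
  kd <- savgol_kernel(poly_order, halfwidth, deriv = 1)
  ks <- savgol_kernel(poly_order, halfwidth, deriv = 0)
  idx <- seq(1, nrow(kin), by = dec)
  chans <- c(x = "x", y = "y", z = "z", a = "aperture")
  out <- list(t_ms = kin$t_ms[idx])
  for (nm in names(chans)) {
    v <- apply_kernel(kin[[chans[[nm]]]], kd) * fs   # mm/sample -> mm/s
    p <- apply_kernel(kin[[chans[[nm]]]], ks)
    out[[paste0("v", nm)]] <- v[idx]
    out[[paste0("p", nm)]] <- p[idx]
  }
  as_tibble(out)
}

pathlet_lags_ms <- function() seq(-100, 300, by = 25)

lag_label <- function(l) ifelse(l < 0, paste0("m", -l), paste0("p", l))

# Gather lagged values of a 40 S/s channel at the 25 ms grid points.
# Returns a matrix grid-times x lags with NA where a lag falls outside.
lag_matrix <- function(v, lags_steps) {
  n <- length(v)
  out <- matrix(NA_real_, n, length(lags_steps))
  for (j in seq_along(lags_steps)) {
    l <- lags_steps[j]
    src <- seq_len(n) + l
    ok <- src >= 1 & src <= n
    out[ok, j] <- v[src[ok]]
  }
  out
}

#' Normalized velocity-trajectory ("pathlet") features
#'
#' For every model time, the smoothed velocities of wrist x/y/z and grasp
#' aperture are sampled every 25 ms from 100 ms in the past to 300 ms in the
#' future (17 lags x 4 channels).  The 51-element wrist trajectory and the
#' 17-element aperture trajectory are each normalized to unit L2 norm (a
#' zero-norm trajectory maps to zeros), and the mean speed and zero-lag
#' smoothed position are appended, giving 68 + 2 + 4 = 74 columns.  Features
#' are computed on the 25 ms grid and held constant across the intervening
#' 1 ms model bins.
#'
#' Note that by construction these features see up to 300 ms of *future*
#' kinematics; lag sign is encoded in the column labels (`m100` ... `p300`).
#'
#' @inheritParams smooth_velocity
#' @param normalize If `FALSE`, skip the per-trajectory L2 normalization.
#' @return A tibble with one row per 1 ms model bin spanning the kinematic
#'   record, columns `t_ms`, `vel_<ch>_<lag>`, `mean_speed_wrist`,
#'   `mean_speed_ap`, `pos_<ch>`.  Rows whose lag window leaves the record
#'   are `NA`.
#' @export
pathlet_features <- function(kin, poly_order = 5, halfwidth = 25,
                             normalize = TRUE) {
  sv <- smooth_velocity(kin, poly_order, halfwidth)
  lags <- pathlet_lags_ms()
  steps <- lags / 25
  Vw <- list(x = lag_matrix(sv$vx, steps),
             y = lag_matrix(sv$vy, steps),
             z = lag_matrix(sv$vz, steps))
  Va <- lag_matrix(sv$va, steps)
  wrist <- cbind(Vw$x, Vw$y, Vw$z)
  if (normalize) {
    # norms at numerical-noise level (mm/s) are treated as zero: no motion,
    # no signal, rather than a unit vector of rounding error
    eps <- 1e-9
    nw <- sqrt(rowSums(wrist^2))
    na_ <- sqrt(rowSums(Va^2))
    wn <- wrist / ifelse(nw > eps, nw, 1)
    an <- Va / ifelse(na_ > eps, na_, 1)
    wn[nw <= eps, ] <- 0
    an[na_ <= eps, ] <- 0
  } else {
    wn <- wrist
    an <- Va
  }
  speed_w <- rowMeans(sqrt(Vw$x^2 + Vw$y^2 + Vw$z^2))
  speed_a <- rowMeans(abs(Va))
  cols <- list()
  chn <- c("wx", "wy", "wz")
  for (c3 in 1:3) {
    for (j in seq_along(lags)) {
      cols[[paste0("vel_", chn[c3], "_", lag_label(lags[j]))]] <-
        wn[, (c3 - 1) * length(lags) + j]
    }
  }
  for (j in seq_along(lags)) {
    cols[[paste0("vel_ap_", lag_label(lags[j]))]] <- an[, j]
  }
  cols$mean_speed_wrist <- speed_w
  cols$mean_speed_ap <- speed_a
  cols$pos_wx <- sv$px
  cols$pos_wy <- sv$py
  cols$pos_wz <- sv$pz
  cols$pos_ap <- sv$pa
  grid <- as_tibble(c(list(t_ms = sv$t_ms), cols))
  expand_hold_1ms(grid, max(kin$t_ms))
}

#' Lagged position-trajectory features
#'
#' Companion feature set to [pathlet_features()] built from the smoothed
#' positions at the same 17 lags, un-normalized: 4 channels x 17 lags = 68
#' columns.
#'
#' @inheritParams pathlet_features
#' @return A tibble with `t_ms` and `pos_<ch>_<lag>` columns per 1 ms bin.
#' @export
position_trajectory_features <- function(kin, poly_order = 5, halfwidth = 25) {
  sv <- smooth_velocity(kin, poly_order, halfwidth)
  lags <- pathlet_lags_ms()
  steps <- lags / 25
  mats <- list(wx = lag_matrix(sv$px, steps),
               wy = lag_matrix(sv$py, steps),
               wz = lag_matrix(sv$pz, steps),
               ap = lag_matrix(sv$pa, steps))
  cols <- list()
  for (nm in names(mats)) {
    for (j in seq_along(lags)) {
      cols[[paste0("pos_", nm, "_", lag_label(lags[j]))]] <- mats[[nm]][, j]
    }
  }
  grid <- as_tibble(c(list(t_ms = sv$t_ms), cols))
  expand_hold_1ms(grid, max(kin$t_ms))
}

# Hold 25 ms grid rows constant across the intervening 1 ms bins.  Grid
# times are rounded to integer ms first: the 40 S/s grid is nominally exact
# multiples of 25 ms and must align bit-exactly with the 1 ms model bins.
expand_hold_1ms <- function(grid, t_max_ms) {
  t_out <- seq(0, floor(t_max_ms))
  idx <- findInterval(t_out, round(grid$t_ms))
  idx[idx == 0] <- NA
  out <- grid[idx, ]
  out$t_ms <- t_out
  out
}
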