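# IR lineshapes from frequency/TDM time series: the fluctuating frequency
# approximation (FFA), the static (inhomogeneous) limit, and the analytic
# two-site exchange (Kubo) reference lineshape.

# ---- spectrum container -----------------------------------------------------

.new_spectrum <- function(wavenumber, intensity, peaks) {
  out <- tibble::tibble(wavenumber = wavenumber, intensity = intensity)
  attr(out, "peaks") <- peaks
  class(out) <- c("vsm_spectrum", class(out))
  out
}

#' Peak table of a spectrum
#'
#' @param spec A spectrum returned by [ffa_spectrum()],
#'   [inhomogeneous_spectrum()] or [kubo_two_state()].
#' @return A tibble with columns `position` (cm^-1) and `height`, ordered by
#'   decreasing height.
#' @export
spectrum_peaks <- function(spec) {
  stopifnot(inherits(spec, "vsm_spectrum"))
  attr(spec, "peaks")
}

#' @export
print.vsm_spectrum <- function(x, ...) {
  pk <- attr(x, "peaks")
  cat(sprintf("<vsm_spectrum> %d grid points, %.2f-%.2f cm^-1\n",
              nrow(x), min(x$wavenumber), max(x$wavenumber)))
  if (nrow(pk)) {
    cat("Peaks:\n")
    print(as.data.frame(pk), digits = 5)
  } else cat("No peaks detected.\n")
  invisible(x)
}

# Local maxima above a height fraction, refined by parabolic interpolation.
.find_peaks <- function(x, y, min_frac = 0.05) {
  n <- length(y)
  if (n < 3L || max(y) <= 0)
    return(tibble::tibble(position = numeric(), height = numeric()))
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  i <- i[y[i] >= min_frac * max(y)]
  if (!length(i))
    return(tibble::tibble(position = numeric(), height = numeric()))
  h <- x[2] - x[1]
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  p <- ifelse(denom < 0, 0.5 * (y[i - 1L] - y[i + 1L]) / denom, 0)
  p <- pmax(pmin(p, 0.5), -0.5)
  pos <- x[i] + p * h
  height <- y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * p
  ord <- order(height, decreasing = TRUE)
  tibble::tibble(position = pos[ord], height = height[ord])
}

# ---- vibrational spectroscopic map ------------------------------------------

#' Map an environment trajectory to instantaneous frequency and TDM
#'
#' The vibrational spectroscopic map: converts a uniformly sampled series of
#' environment descriptors (field projection, hydrogen-bond occupancy and
#' geometry) into per-frame instantaneous frequency (VSE term plus the
#' geometric blueshift when an HB is present) and transition dipole moment.
#'
#' @param frames Data frame with columns `time_fs` (uniformly spaced),
#'   `field` (MV/cm), `hb` (0/1 occupancy), and `d`/`theta` (geometry for
#'   the bound frames; ignored or NA when `hb = 0`).
#' @param vse A [vse_params()] object.
#' @param blue A [blueshift_params()] object.
#' @return A `probe_trajectory`: a tibble with columns `time_fs`,
#'   `frequency` (cm^-1), `tdm` (D), `hb_state`, carrying the sampling
#'   interval as attribute `dt_fs`.
#' @export
map_trajectory <- function(frames, vse = vse_params(),
                           blue = blueshift_params()) {
  stopifnot(is.data.frame(frames),
            all(c("time_fs", "field", "hb") %in% names(frames)))
  dt <- diff(frames$time_fs)
  if (length(dt) < 1L) stop("Need at least 2 frames.", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1]))
    stop("Mixed sampling intervals: frames must be uniformly spaced.",
         call. = FALSE)
  hb <- as.numeric(frames$hb)
  shift <- numeric(nrow(frames))
  bound <- hb > 0
  if (any(bound)) {
    if (!all(c("d", "theta") %in% names(frames)))
      stop("Bound frames require `d` and `theta` columns.", call. = FALSE)
    shift[bound] <- as.numeric(suppressWarnings(
      hb_blueshift(frames$d[bound], frames$theta[bound], blue)))
  }
  out <- tibble::tibble(
    time_fs = frames$time_fs,
    frequency = vse_frequency(frames$field, vse) + hb * shift,
    tdm = vse_tdm(frames$field, vse),
    hb_state = as.integer(hb > 0))
  attr(out, "dt_fs") <- dt[1]
  class(out) <- c("probe_trajectory", class(out))
  out
}

.traj_dt <- function(traj) {
  dt <- attr(traj, "dt_fs")
  if (is.null(dt)) {
    if (!"time_fs" %in% names(traj))
      stop("Trajectory lacks a `time_fs` column or `dt_fs` attribute.",
           call. = FALSE)
    dt <- diff(traj$time_fs[1:2])
  }
  dt
}

# ---- FFA spectrum -----------------------------------------------------------

#' IR spectrum via the fluctuating frequency approximation
#'
#' Computes the absorption lineshape from a frequency/TDM trajectory as the
#' Fourier transform of the TDM-weighted phase-accumulation correlation
#' function
#' `F(t) = < mu(0) mu(t) exp(i * integral_0^t d_omega(tau) d tau) >`,
#' where `d_omega = 2 pi c (nu - <nu>)` is the angular-frequency fluctuation
#' about the trajectory mean. The phase integral uses the trapezoid rule on
#' the sampling interval; the correlation function is averaged over
#' overlapping time origins within a finite window and optionally apodized
#' by a vibrational lifetime decay `exp(-t / (2 T1))`. The resulting real
#' spectrum is reported on a wavenumber grid about the mean frequency, with
#' peak positions refined by parabolic interpolation. The integrated
#' intensity scales with the mean squared TDM.
#'
#' @param traj A `probe_trajectory` (see [map_trajectory()]), or any data
#'   frame with columns `frequency`, `tdm` and either `time_fs` or a
#'   `dt_fs` attribute. At least 1024 frames are required.
#' @param lifetime_ps Vibrational lifetime for the apodization, ps;
#'   `NULL` disables apodization. Default 3 ps.
#' @param window_ps Correlation window, ps (default 16); origins overlap by
#'   50 percent.
#' @param grid_res Output grid spacing, cm^-1 (default 0.5; the grid is
#'   zero-padded to at least this resolution).
#' @param span Half-width of the reported wavenumber window about the mean
#'   frequency, cm^-1 (default 150).
#' @param min_frac Peak detection threshold as a fraction of the maximum
#'   intensity.
#' @return A `vsm_spectrum` tibble (`wavenumber`, `intensity`) with the
#'   peak table as attribute `"peaks"` (see [spectrum_peaks()]).
#' @export
ffa_spectrum <- function(traj, lifetime_ps = 3, window_ps = 16,
                         grid_res = 0.5, span = 150, min_frac = 0.05) {
  stopifnot(is.data.frame(traj),
            all(c("frequency", "tdm") %in% names(traj)))
  nu <- traj$frequency; mu <- traj$tdm
  if (anyNA(nu) || anyNA(mu) || any(!is.finite(nu)) || any(!is.finite(mu)))
    stop("Trajectory contains NA or non-finite values.", call. = FALSE)
  n <- length(nu)
  if (n < 1024L)
    stop("Trajectory too short for a meaningful lineshape: need at least ",
         "1024 frames, got ", n, ".", call. = FALSE)
  dt <- .traj_dt(traj)
  nu_mean <- mean(nu)
  dw <- 2 * pi * .c_cm_fs * (nu - nu_mean)          # rad/fs
  phase <- c(0, cumsum(0.5 * (dw[-1] + dw[-n]) * dt))
  W <- min(max(16L, as.integer(round(window_ps * 1000 / dt))), n - 1L)
  step <- max(1L, W %/% 2L)
  origins <- seq.int(1L, n - W, by = step)
  e <- exp(1i * phase)
  mu_o <- mu[origins]; e_o <- Conj(e[origins])
  Fcorr <- complex(W + 1L)
  for (lag in 0:W) {
    idx <- origins + lag
    Fcorr[lag + 1L] <- mean(mu_o * mu[idx] * e[idx] * e_o)
  }
  tlag <- (0:W) * dt
  if (!is.null(lifetime_ps))
    Fcorr <- Fcorr * exp(-tlag / (2 * lifetime_ps * 1000))
  npad <- 2^ceiling(log2(max(length(Fcorr),
                             1 / (grid_res * dt * .c_cm_fs))))
  spec_raw <- Re(stats::fft(c(Fcorr, complex(npad - length(Fcorr)))))
  k <- seq_len(npad) - 1L
  freq_bins <- ifelse(k <= npad / 2, k, k - npad) / (npad * dt * .c_cm_fs)
  # fft convention: bin k collects exp(-2 pi i j k / N); the phase factor
  # exp(+i dw t) therefore lands at positive detuning for blue-shifted nu
  wavenumber <- nu_mean + freq_bins
  ord <- order(wavenumber)
  wavenumber <- wavenumber[ord]; spec_raw <- spec_raw[ord]
  keep <- abs(wavenumber - nu_mean) <= span
  wavenumber <- wavenumber[keep]; intensity <- spec_raw[keep]
  peaks <- .find_peaks(wavenumber, intensity, min_frac)
  .new_spectrum(wavenumber, pmax(intensity, 0), peaks)
}

#' Static (inhomogeneous-limit) spectrum
#'
#' The inhomogeneous limit of the IR band: the TDM^2-weighted density of
#' instantaneous frequencies, with no motional effects. This is the
#' lineshape expected when environmental exchange is much slower than the
#' inverse frequency spread.
#'
#' @param frequency_samples Instantaneous frequencies, cm^-1 (>= 100
#'   samples).
#' @param tdm_samples Matching TDM magnitudes, D; constant weight if
#'   omitted.
#' @param grid_res Output grid spacing, cm^-1.
#' @param bw Kernel bandwidth in cm^-1 (default: twice the grid spacing).
#' @param min_frac Peak detection threshold.
#' @return A `vsm_spectrum` tibble.
#' @export
inhomogeneous_spectrum <- function(frequency_samples, tdm_samples = NULL,
                                   grid_res = 0.5, bw = 2 * grid_res,
                                   min_frac = 0.05) {
  .check_finite(frequency_samples, "frequency_samples")
  if (length(frequency_samples) < 100L)
    stop("At least 100 samples are required for the static distribution.",
         call. = FALSE)
  if (is.null(tdm_samples)) tdm_samples <- rep(1, length(frequency_samples))
  .check_finite(tdm_samples, "tdm_samples")
  if (length(tdm_samples) != length(frequency_samples))
    stop("`tdm_samples` must match `frequency_samples` in length.",
         call. = FALSE)
  w <- tdm_samples^2; w <- w / sum(w)
  lo <- min(frequency_samples) - 10; hi <- max(frequency_samples) + 10
  grid <- seq(lo, hi, by = grid_res)
  dens <- stats::density(frequency_samples, weights = w, bw = bw,
                         from = lo, to = hi, n = length(grid))
  intensity <- stats::approx(dens$x, dens$y, xout = grid)$y
  intensity[is.na(intensity)] <- 0
  peaks <- .find_peaks(grid, intensity, min_frac)
  .new_spectrum(grid, intensity, peaks)
}

# ---- analytic two-site exchange ---------------------------------------------

#' Analytic two-site exchange (Kubo) lineshape
#'
#' Closed-form lineshape for a vibration jumping between two substates with
#' distinct frequencies under a stationary Markov exchange. In the static
#' limit (`k_exchange -> 0`) the band splits into Lorentzians at the two
#' site frequencies; in the fast limit it collapses to a single line at the
#' population-weighted mean frequency (motional narrowing). Serves as the
#' validation oracle for the FFA engine on two-state trajectories.
#'
#' The exchange is parameterized by the total rate
#' `k_exchange = 1/tau_1 + 1/tau_2` (ps^-1) and the stationary populations;
#' site `j` is left at rate `k_exchange * p_other`.
#'
#' @param nu_sites Length-2 site frequencies, cm^-1.
#' @param k_exchange Total exchange rate, ps^-1 (>= 0).
#' @param populations Length-2 stationary populations summing to 1.
#' @param lifetime_ps Lifetime broadening as in [ffa_spectrum()]; `NULL`
#'   for (numerically) stick-like lines.
#' @param grid_res Grid spacing, cm^-1.
#' @param span Grid extension beyond the site frequencies, cm^-1.
#' @param min_frac Peak detection threshold.
#' @return A `vsm_spectrum` tibble.
#' @examples
#' kubo_two_state(c(0, 20), k_exchange = 100)   # fast: one line near 10
#' @export
kubo_two_state <- function(nu_sites, k_exchange,
                           populations = c(0.5, 0.5), lifetime_ps = 3,
                           grid_res = 0.5, span = 40, min_frac = 0.05) {
  stopifnot(length(nu_sites) == 2L, length(populations) == 2L)
  .check_finite(nu_sites, "nu_sites")
  if (k_exchange < 0) stop("`k_exchange` must be >= 0.", call. = FALSE)
  if (abs(sum(populations) - 1) > 1e-8 || any(populations < 0))
    stop("`populations` must be non-negative and sum to 1.", call. = FALSE)
  gamma <- if (is.null(lifetime_ps)) 1e-6 else 1 / (2 * lifetime_ps * 1000)
  w1 <- 2 * pi * .c_cm_fs * nu_sites[1]             # rad/fs
  w2 <- 2 * pi * .c_cm_fs * nu_sites[2]
  kex <- k_exchange / 1000                          # ps^-1 -> fs^-1
  k1 <- kex * populations[2]; k2 <- kex * populations[1]
  grid <- seq(min(nu_sites) - span, max(nu_sites) + span, by = grid_res)
  wg <- 2 * pi * .c_cm_fs * grid
  a11 <- 1i * (wg - w1) + gamma + k1
  a22 <- 1i * (wg - w2) + gamma + k2
  det <- a11 * a22 - k1 * k2
  I <- Re(((a22 + k1) * populations[1] + (a11 + k2) * populations[2]) / det)
  peaks <- .find_peaks(grid, I, min_frac)
  .new_spectrum(grid, pmax(I, 0), peaks)
}

#' Coalescence exchange rate for a given splitting
#'
#' The total exchange rate at which two equally populated substates split by
#' `delta_nu` merge into one band: `k_c = 2 pi c delta_nu / sqrt(2)`
#' (rad-based two-site exchange condition), returned in ps^-1.
#'
#' @param delta_nu Substate splitting, cm^-1.
#' @return Total exchange rate in ps^-1.
#' @examples
#' coalescence_rate(20)   # ~ 2.7 ps^-1
#' @export
coalescence_rate <- function(delta_nu) {
  .check_finite(delta_nu, "delta_nu")
  2 * pi * .c_cm_fs * 1000 * delta_nu / sqrt(2)
}

# ---- peak analysis ----------------------------------------------------------

#' Apparent blueshift of a spectrum
#'
#' The position of the main (highest) peak minus a reference frequency due
#' to the Stark effect alone. For a motionally narrowed band this apparent
#' blueshift is smaller than the geometric blueshift of the hydrogen-bonded
#' substate.
#'
#' @param spec A `vsm_spectrum`.
#' @param vse_only_frequency Reference frequency (VSE term only), cm^-1.
#' @return Apparent blueshift, cm^-1.
#' @examples
#' sp <- kubo_two_state(c(2219.1, 2239.1), k_exchange = 100)
#' apparent_blueshift(sp, 2219.1)
#' @export
apparent_blueshift <- function(spec, vse_only_frequency) {
  stopifnot(inherits(spec, "vsm_spectrum"))
  .check_finite(vse_only_frequency, "vse_only_frequency")
  pk <- attr(spec, "peaks")
  if (is.null(pk) || nrow(pk) == 0L)
    stop("No peak detected in the spectrum; cannot compute an apparent ",
         "blueshift.", call. = FALSE)
  pk$position[1] - vse_only_frequency
}

#' Two-band decomposition of a spectrum
#'
#' Least-squares decomposition of a (plausibly bimodal) band into two
#' symmetric Gaussian components, returning their positions, heights and
#' fractional areas. Unimodal inputs return a single dominant component
#' with a warning.
#'
#' @param spec A `vsm_spectrum`.
#' @return A tibble with columns `position`, `height`, `width` (Gaussian
#'   sigma), `area` and `frac_area`, one row per component (two for bimodal
#'   input), ordered by decreasing area.
#' @export
decompose_two_bands <- function(spec) {
  stopifnot(inherits(spec, "vsm_spectrum"))
  x <- spec$wavenumber; y <- spec$intensity
  df <- data.frame(x = x, y = y)
  # moment-based width estimate of the whole band
  w0 <- sqrt(sum(y * (x - sum(y * x) / sum(y))^2) / sum(y))
  x0 <- x[which.max(y)]
  single <- .nls_multistart(
    y ~ h1 * exp(-(x - c1)^2 / (2 * w1^2)), df,
    list(list(h1 = max(y), c1 = x0, w1 = w0),
         list(h1 = max(y), c1 = x0, w1 = max(w0 / 2, 1))))
  rel_single <- sqrt(mean(stats::residuals(single)^2)) / max(y)
  as_single <- function() {
    cf <- stats::coef(single)
    tibble::tibble(position = cf[["c1"]], height = cf[["h1"]],
                   width = abs(cf[["w1"]]),
                   area = cf[["h1"]] * abs(cf[["w1"]]) * sqrt(2 * pi),
                   frac_area = 1)
  }
  if (rel_single < 1e-4) {
    warning("Spectrum is well described by a single symmetric band; ",
            "returning a single-component fit.", call. = FALSE)
    return(as_single())
  }
  # two-component starts: resolved maxima when present, otherwise a
  # symmetric split about the band top
  pk <- .find_peaks(x, y, min_frac = 0.2)
  starts <- list()
  if (nrow(pk) >= 2L)
    starts[[1]] <- list(h1 = pk$height[1], c1 = pk$position[1], w1 = w0 / 2,
                        h2 = pk$height[2], c2 = pk$position[2], w2 = w0 / 2)
  for (split in c(0.5, 1))
    starts[[length(starts) + 1L]] <-
      list(h1 = max(y), c1 = x0 - split * w0, w1 = w0 / 2,
           h2 = max(y), c2 = x0 + split * w0, w2 = w0 / 2)
  two <- tryCatch(
    .nls_multistart(
      y ~ h1 * exp(-(x - c1)^2 / (2 * w1^2)) +
        h2 * exp(-(x - c2)^2 / (2 * w2^2)), df, starts),
    error = function(e) NULL)
  if (is.null(two)) {
    warning("Two-component decomposition did not converge; returning the ",
            "single-component fit.", call. = FALSE)
    return(as_single())
  }
  rel_two <- sqrt(mean(stats::residuals(two)^2)) / max(y)
  if (rel_two > rel_single / 2) {
    warning("Two-component decomposition does not improve on a single ",
            "band; returning the single-component fit.", call. = FALSE)
    return(as_single())
  }
  cf <- stats::coef(two)
  out <- tibble::tibble(
    position = c(cf[["c1"]], cf[["c2"]]),
    height = c(cf[["h1"]], cf[["h2"]]),
    width = abs(c(cf[["w1"]], cf[["w2"]])),
    area = height * width * sqrt(2 * pi))
  out$frac_area <- out$area / sum(out$area)
  dplyr::arrange(out, dplyr::desc(.data$area))
}
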