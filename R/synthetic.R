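# Synthetic inputs: calibration grids that emulate an electronic-structure
# calibration design, two-state hydrogen-bond dynamics trajectories, and a
# Coulomb point-charge field helper.

# Coulomb constant: field of 1 e at 1 Angstrom, in MV/cm
.k_coulomb_MV_cm <- 1439.964

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

# ---- calibration grid -------------------------------------------------------

#' Specification of a synthetic calibration grid
#'
#' Describes a calibration design emulating an electronic-structure
#' campaign: hydrogen-bond donors on a regular distance/angle grid
#' (default 20 x 21 = 420 donor configurations over d = 2.5-5.0 Angstrom,
#' theta = 70-175 degrees) and purely electrostatic point charges placed
#' further out (default 5 x 25 = 125 configurations over 5.0-8.0 Angstrom).
#' Electric fields are assigned by a declared monotone map from the
#' placement distance, `F = -field_slope / d^2` (MV/cm), a configurable
#' surrogate for force-field electrostatics.
#'
#' @param d_range,n_d Donor heavy-atom distance range (Angstrom) and grid
#'   size.
#' @param theta_range,n_theta Donor angle range (degrees) and grid size.
#' @param charge_d_range,n_charge_d,n_charge_theta Point-charge placement
#'   range and grid sizes.
#' @param noise_sd_frequency Gaussian frequency noise, cm^-1.
#' @param noise_sd_tdm Gaussian TDM noise, D.
#' @param field_slope Slope of the distance-to-field map, (MV/cm) A^2.
#' @param donor_label Environment label for the donor records.
#' @param seed Integer seed for the noise draws; `NULL` leaves the RNG
#'   state alone.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(d_range = c(2.5, 5.0), n_d = 20,
                      theta_range = c(70, 175), n_theta = 21,
                      charge_d_range = c(5.0, 8.0), n_charge_d = 5,
                      n_charge_theta = 25,
                      noise_sd_frequency = 0, noise_sd_tdm = 0,
                      field_slope = 500, donor_label = "water",
                      seed = NULL) {
  stopifnot(d_range[1] >= 2.5, d_range[2] <= 8.0,
            theta_range[1] >= 70, theta_range[2] <= 180,
            noise_sd_frequency >= 0, noise_sd_tdm >= 0, field_slope > 0)
  structure(list(d_range = d_range, n_d = n_d, theta_range = theta_range,
                 n_theta = n_theta, charge_d_range = charge_d_range,
                 n_charge_d = n_charge_d, n_charge_theta = n_charge_theta,
                 noise_sd_frequency = noise_sd_frequency,
                 noise_sd_tdm = noise_sd_tdm, field_slope = field_slope,
                 donor_label = donor_label, seed = seed),
            class = "grid_spec")
}

#' Generate a synthetic calibration table
#'
#' Builds calibration records whose frequencies and TDMs are exact
#' evaluations of the VSE + blueshift model at the grid geometries (plus
#' the specified Gaussian noise). Donor records carry their hydrogen-bond
#' geometry; point-charge records have `d = theta = NA` (no hydrogen bond)
#' and enter only through their field.
#'
#' @param spec A [grid_spec()].
#' @param vse A [vse_params()] object (ground truth).
#' @param blue A [blueshift_params()] object (ground truth).
#' @return A tibble of calibration records with columns `env`, `field`
#'   (MV/cm), `d`, `theta`, `freq` (cm^-1), `tdm` (D).
#' @examples
#' g <- generate_calibration_grid(grid_spec())
#' nrow(dplyr::filter(g, env != "point_charge"))  # 420
#' @export
generate_calibration_grid <- function(spec = grid_spec(),
                                      vse = vse_params(),
                                      blue = blueshift_params()) {
  stopifnot(inherits(spec, "grid_spec"))
  donors <- tidyr::expand_grid(
    d = seq(spec$d_range[1], spec$d_range[2], length.out = spec$n_d),
    theta = seq(spec$theta_range[1], spec$theta_range[2],
                length.out = spec$n_theta))
  donors$env <- spec$donor_label
  donors$place <- donors$d
  charges <- tidyr::expand_grid(
    place = seq(spec$charge_d_range[1], spec$charge_d_range[2],
                length.out = spec$n_charge_d),
    theta_place = seq(spec$theta_range[1], spec$theta_range[2],
                      length.out = spec$n_charge_theta))
  charges <- tibble::tibble(d = NA_real_, theta = NA_real_,
                            env = "point_charge", place = charges$place)
  rec <- dplyr::bind_rows(donors[c("env", "d", "theta", "place")], charges)
  rec$field <- -spec$field_slope / rec$place^2
  shift <- numeric(nrow(rec))
  hb <- !is.na(rec$d)
  shift[hb] <- as.numeric(suppressWarnings(
    hb_blueshift(rec$d[hb], rec$theta[hb], blue)))
  .with_seed(spec$seed, {
    rec$freq <- vse_frequency(rec$field, vse) + shift +
      stats::rnorm(nrow(rec), 0, spec$noise_sd_frequency)
    rec$tdm <- vse_tdm(rec$field, vse) +
      stats::rnorm(nrow(rec), 0, spec$noise_sd_tdm)
  })
  rec$place <- NULL
  tibble::as_tibble(rec)
}

# ---- two-state dynamics -----------------------------------------------------

#' Specification of a two-state hydrogen-bond dynamics trajectory
#'
#' Surrogate for the hydrogen-bond kinetics of a solvent-exposed nitrile:
#' occupancy follows a two-state continuous-time Markov chain (bound/free)
#' discretized at the sampling interval; bound-frame geometry is drawn from
#' truncated Gaussians around the means with an anticorrelated
#' distance-angle trend (distance shrinking from 3.35 Angstrom for side-on
#' approaches to 2.93 for head-on); the field follows a mean-reverting
#' (Ornstein-Uhlenbeck) Gaussian process. Setting the spread parameters to
#' zero gives a strict two-state frequency trajectory.
#'
#' @param mean_residence_hb,mean_residence_free Mean residence times, ps.
#' @param hb_d_mean,hb_d_sd Bound-state distance mean/spread, Angstrom.
#' @param hb_theta_mean,hb_theta_sd Bound-state angle mean/spread, degrees.
#' @param field_mean,field_sd Field mean/stationary spread, MV/cm.
#' @param field_correlation_time Field correlation time, ps.
#' @param dt_fs Sampling interval, fs.
#' @param n_frames Number of frames (>= 1024).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A `dynamics_spec` list.
#' @export
dynamics_spec <- function(mean_residence_hb = 2, mean_residence_free = 2,
                          hb_d_mean = 3.00, hb_d_sd = 0.10,
                          hb_theta_mean = 160, hb_theta_sd = 8,
                          field_mean = -64.9, field_sd = 5,
                          field_correlation_time = 1,
                          dt_fs = 20, n_frames = 131072L, seed = 1L) {
  stopifnot(mean_residence_hb > 0, mean_residence_free > 0, dt_fs > 0,
            field_correlation_time > 0, hb_d_sd >= 0, hb_theta_sd >= 0,
            field_sd >= 0)
  if (n_frames < 1024L)
    stop("`n_frames` must be at least 1024.", call. = FALSE)
  if (dt_fs > 1000 * min(mean_residence_hb, mean_residence_free))
    stop("Sampling interval exceeds a mean residence time; the ",
         "discretized chain would be invalid.", call. = FALSE)
  structure(list(mean_residence_hb = mean_residence_hb,
                 mean_residence_free = mean_residence_free,
                 hb_d_mean = hb_d_mean, hb_d_sd = hb_d_sd,
                 hb_theta_mean = hb_theta_mean, hb_theta_sd = hb_theta_sd,
                 field_mean = field_mean, field_sd = field_sd,
                 field_correlation_time = field_correlation_time,
                 dt_fs = dt_fs, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "dynamics_spec")
}

# slope of the declared distance-vs-angle trend: 3.35 A at 70 deg to
# 2.93 A at 180 deg
.d_theta_slope <- (2.93 - 3.35) / (180 - 70)

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate a two-state hydrogen-bond trajectory
#'
#' Generates a frame series of hydrogen-bond occupancy, geometry and field
#' according to a [dynamics_spec()]. The stationary occupancy fraction is
#' `tau_hb / (tau_hb + tau_free)`; dwell times are geometric with the
#' specified means. The same seed always yields a bit-identical series.
#'
#' @param spec A [dynamics_spec()].
#' @return A tibble with columns `time_fs`, `field`, `d`, `theta`, `hb`
#'   (0/1), ready for [map_trajectory()]; the seed and sampling interval
#'   are carried as attributes `seed` and `dt_fs`.
#' @export
simulate_hb_trajectory <- function(spec = dynamics_spec()) {
  stopifnot(inherits(spec, "dynamics_spec"))
  n <- spec$n_frames; dt <- spec$dt_fs
  p_leave <- c(hb = 1 - exp(-dt / (1000 * spec$mean_residence_hb)),
               free = 1 - exp(-dt / (1000 * spec$mean_residence_free)))
  pi_hb <- spec$mean_residence_hb /
    (spec$mean_residence_hb + spec$mean_residence_free)
  .with_seed(spec$seed, {
    state0 <- stats::runif(1) < pi_hb
    # alternating geometric dwells, drawn in vectorized pair blocks, until
    # the frame budget is covered
    frames_per_pair <- 1000 * (spec$mean_residence_hb +
                                 spec$mean_residence_free) / dt
    acc_states <- list(); acc_lens <- list(); total <- 0
    s <- state0
    while (total < n) {
      m <- max(64L, ceiling(1.2 * (n - total) / frames_per_pair))
      pa <- p_leave[[if (s) "hb" else "free"]]
      pb <- p_leave[[if (s) "free" else "hb"]]
      la <- stats::rgeom(m, pa) + 1L
      lb <- stats::rgeom(m, pb) + 1L
      acc_lens[[length(acc_lens) + 1L]] <- as.integer(rbind(la, lb))
      acc_states[[length(acc_states) + 1L]] <- rep_len(c(s, !s), 2L * m)
      total <- total + sum(la) + sum(lb)
    }
    hb <- rep(unlist(acc_states), unlist(acc_lens))[seq_len(n)]
    theta <- d <- rep(NA_real_, n)
    nb <- sum(hb)
    if (nb) {
      theta[hb] <- .rtrunc_norm(nb, spec$hb_theta_mean, spec$hb_theta_sd,
                                70, 180)
      d_mu <- spec$hb_d_mean + .d_theta_slope * (theta[hb] - spec$hb_theta_mean)
      d_raw <- if (spec$hb_d_sd == 0) d_mu else
        d_mu + stats::rnorm(nb, 0, spec$hb_d_sd)
      d[hb] <- pmax(d_raw, 2.5)
    }
    phi <- exp(-dt / (1000 * spec$field_correlation_time))
    innov_sd <- spec$field_sd * sqrt(1 - phi^2)
    field <- numeric(n)
    field[1] <- spec$field_mean +
      if (spec$field_sd > 0) stats::rnorm(1, 0, spec$field_sd) else 0
    if (innov_sd > 0) {
      eps <- stats::rnorm(n - 1, 0, innov_sd)
      dev <- numeric(n); dev[1] <- field[1] - spec$field_mean
      for (i in 2:n) dev[i] <- phi * dev[i - 1] + eps[i - 1]
      field <- spec$field_mean + dev
    } else {
      field[] <- spec$field_mean
    }
    out <- tibble::tibble(time_fs = (seq_len(n) - 1) * dt, field = field,
                          d = d, theta = theta, hb = as.integer(hb))
    attr(out, "dt_fs") <- dt
    attr(out, "seed") <- spec$seed
    out
  })
}

# ---- Coulomb helper ---------------------------------------------------------

#' Axial field of a set of point charges
#'
#' Coulomb electric field projection onto the probe axis at the bond
#' midpoint, in MV/cm: the field of 1 e at 1 Angstrom is 1439.96 MV/cm.
#' Used to construct purely electrostatic test configurations.
#'
#' @param charges Data frame with columns `x`, `y`, `z` (Angstrom) and `q`
#'   (elementary charges).
#' @param cn_axis Length-3 probe axis direction (need not be normalized).
#' @param midpoint Length-3 position of the bond midpoint, Angstrom.
#' @return Signed axial field projection, MV/cm.
#' @examples
#' field_from_point_charges(data.frame(x = 0, y = 0, z = 1, q = 1))
#' @export
field_from_point_charges <- function(charges, cn_axis = c(0, 0, 1),
                                     midpoint = c(0, 0, 0)) {
  stopifnot(is.data.frame(charges),
            all(c("x", "y", "z", "q") %in% names(charges)))
  u <- cn_axis / sqrt(sum(cn_axis^2))
  rx <- midpoint[1] - charges$x
  ry <- midpoint[2] - charges$y
  rz <- midpoint[3] - charges$z
  r2 <- rx^2 + ry^2 + rz^2
  if (any(r2 < 1e-12))
    stop("A charge coincides with the probe midpoint.", call. = FALSE)
  r <- sqrt(r2)
  # field at the midpoint points from a positive charge toward the midpoint
  scale <- .k_coulomb_MV_cm * charges$q / (r2 * r)
  sum(scale * (rx * u[1] + ry * u[2] + rz * u[3]))
}
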