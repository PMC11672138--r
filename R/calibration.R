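# Calibration of the VSE and blueshift models against configuration tables:
# frequency/TDM scaling, linear VSE fits, per-configuration blueshift
# extraction, and the nonlinear distance/angle/joint fits.

# ---- goodness metrics -------------------------------------------------------

#' Goodness-of-fit metrics
#'
#' `goodness()` scores predictions against observations with the regression
#' convention: `R^2 = 1 - SS_res / SS_tot` where `SS_tot` is taken about the
#' mean of the observed values. `R^2` may be negative (the model is then
#' worse than predicting the observed mean). RMSD is the root-mean-square
#' residual and is symmetric in its arguments.
#'
#' `goodness_identity()` scores agreement with the 1:1 line for
#' observed-vs-predicted comparisons: residuals are taken about the identity
#' line and the total variance about the mean of the model values being
#' scored, `R^2 = 1 - sum((values - reference)^2) / sum((values -
#' mean(values))^2)`.
#'
#' @param observed,predicted Equal-length numeric vectors (`n >= 2`).
#' @return A list with elements `r_squared` and `rmsd`.
#' @examples
#' goodness(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
goodness <- function(observed, predicted) {
  .check_finite(observed, "observed"); .check_finite(predicted, "predicted")
  if (length(observed) != length(predicted))
    stop("`observed` and `predicted` must have equal length.", call. = FALSE)
  if (length(observed) < 2L)
    stop("At least 2 points are required.", call. = FALSE)
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       rmsd = sqrt(mean((observed - predicted)^2)))
}

#' @rdname goodness
#' @param values Model (predicted or simulated) values scored against the
#'   identity line.
#' @param reference The observed values defining the identity line.
#' @export
goodness_identity <- function(values, reference) {
  .check_finite(values, "values"); .check_finite(reference, "reference")
  if (length(values) != length(reference))
    stop("`values` and `reference` must have equal length.", call. = FALSE)
  if (length(values) < 2L)
    stop("At least 2 points are required.", call. = FALSE)
  ss_res <- sum((values - reference)^2)
  ss_tot <- sum((values - mean(values))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       rmsd = sqrt(mean((values - reference)^2)))
}

# ---- scaling ----------------------------------------------------------------

#' Scale raw electronic-structure frequencies and transition dipoles
#'
#' Harmonic frequencies and TDM magnitudes from electronic-structure normal
#' mode analysis are scaled to match experimental zero-field observables:
#' frequencies by 0.9598 and TDMs by 0.4464 by default.
#'
#' @param frequency_raw Raw frequency, cm^-1 (positive).
#' @param tdm_raw Raw transition dipole, Debye (positive).
#' @param frequency_scale,tdm_scale Scaling constants; override with 1.0 for
#'   identity.
#' @return A list with elements `frequency` (cm^-1) and `tdm` (D).
#' @examples
#' apply_scaling(2325.5, 0.1120)
#' @export
apply_scaling <- function(frequency_raw, tdm_raw,
                          frequency_scale = 0.9598, tdm_scale = 0.4464) {
  .check_finite(frequency_raw, "frequency_raw")
  .check_finite(tdm_raw, "tdm_raw")
  if (any(frequency_raw <= 0) || any(tdm_raw <= 0))
    stop("Raw frequencies and TDMs must be positive.", call. = FALSE)
  list(frequency = frequency_raw * frequency_scale,
       tdm = tdm_raw * tdm_scale)
}

# ---- fit-report plumbing ----------------------------------------------------

.new_fit_report <- function(subclass, parameters, r_squared, rmsd, n,
                            fitted, residuals, per_environment = NULL,
                            extra = list()) {
  structure(
    c(list(parameters = parameters, r_squared = r_squared, rmsd = rmsd,
           n_points = n, fitted = fitted, residuals = residuals,
           per_environment = per_environment), extra),
    class = c(subclass, "vsemap_fit")
  )
}

#' @export
print.vsemap_fit <- function(x, ...) {
  cat(sprintf("<%s>  n = %d, R^2 = %.3f, RMSD = %.3g\n",
              class(x)[1], x$n_points, x$r_squared, x$rmsd))
  print(x$parameters)
  if (!is.null(x$per_environment)) {
    cat("Per-environment:\n")
    print(x$per_environment)
  }
  invisible(x)
}

#' Tidy a vsemap fit report
#'
#' @param x A fit object returned by one of the `fit_*()` functions.
#' @param ... Unused.
#' @return `tidy()`: a tibble with columns `term`, `estimate`, `std.error`;
#'   `glance()`: a one-row tibble with `r.squared`, `rmsd`, `nobs`.
#' @method tidy vsemap_fit
#' @export
tidy.vsemap_fit <- function(x, ...) x$parameters

#' @rdname tidy.vsemap_fit
#' @method glance vsemap_fit
#' @export
glance.vsemap_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, rmsd = x$rmsd, nobs = x$n_points)
}

# Per-environment goodness table for a vector of predictions.
.per_env_goodness <- function(data, predicted, value_col) {
  obs <- data[[value_col]]
  env <- if ("env" %in% names(data)) data$env else rep("all", nrow(data))
  purrr::map_dfr(split(seq_len(nrow(data)), env), function(idx) {
    g <- goodness(obs[idx], predicted[idx])
    tibble::tibble(n = length(idx), r_squared = g$r_squared, rmsd = g$rmsd)
  }, .id = "env")
}

# Multi-start nonlinear least squares via minpack.lm; deterministic start
# grid, tie-break by lowest RMSD. Reports diagnostics when nothing converges.
.nls_multistart <- function(formula, data, starts, lower = NULL,
                            upper = NULL) {
  fits <- list()
  # near-zero starting values break the relative-step numeric Jacobian;
  # snap them to exact zero
  starts <- lapply(starts, function(st)
    lapply(st, function(v) if (is.numeric(v) && abs(v) < 1e-10) 0 else v))
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        formula, data = data, start = st,
        lower = if (is.null(lower)) rep(-Inf, length(st)) else lower,
        upper = if (is.null(upper)) rep(Inf, length(st)) else upper,
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0L)
    stop("Nonlinear fit failed to converge from all ", length(starts),
         " deterministic starting points; inspect the data ranges or ",
         "provide different starting values.", call. = FALSE)
  rmsds <- vapply(fits, function(f) sqrt(mean(stats::residuals(f)^2)), 0)
  fits[[which.min(rmsds)]]
}

.lm_param_tibble <- function(fit, terms) {
  # summary.lm warns on zero-residual (noiseless) fits; the estimates are fine
  sm <- suppressWarnings(summary(fit)$coefficients)
  tibble::tibble(term = terms, estimate = unname(sm[, 1]),
                 std.error = unname(sm[, 2]))
}

.nls_param_tibble <- function(fit) {
  sm <- summary(fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                 std.error = unname(sm[, 2]))
}

# ---- linear VSE fits --------------------------------------------------------

.assert_records <- function(records, need = c("field", "freq", "tdm")) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("Calibration records lack required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(records)
}

.has_hb <- function(records) {
  if ("d" %in% names(records)) !is.na(records$d) else rep(FALSE, nrow(records))
}

#' Fit the transition-dipole VSE model
#'
#' Least-squares fit of the linear-in-field TDM model (with optional
#' quadratic extension) jointly over all environments, reporting the overall
#' and per-environment goodness. The TDM responds to the field alone, so a
#' single fit describes purely electrostatic and hydrogen-bonded records
#' alike.
#'
#' @param records Calibration table with numeric columns `field` (MV/cm),
#'   `tdm` (D) and optionally `env` (environment label).
#' @param quadratic Include a quadratic field term (default `TRUE`).
#' @return A `vse_tdm_fit` report; see [tidy.vsemap_fit()].
#' @export
fit_vse_tdm <- function(records, quadratic = TRUE) {
  .assert_records(records, c("field", "tdm"))
  if (length(unique(records$field)) < 4L)
    stop("At least 4 records with distinct fields are required.",
         call. = FALSE)
  fit <- if (quadratic) {
    stats::lm(tdm ~ field + I(field^2), data = records)
  } else {
    stats::lm(tdm ~ field, data = records)
  }
  terms <- c("tdm0", "tdm_polarizability", if (quadratic) "tdm_quad")
  pred <- stats::fitted(fit)
  g <- goodness(records$tdm, pred)
  .new_fit_report(
    "vse_tdm_fit", .lm_param_tibble(fit, terms), g$r_squared, g$rmsd,
    nrow(records), pred, records$tdm - pred,
    per_environment = .per_env_goodness(records, pred, "tdm"),
    extra = list(model = fit))
}

#' Fit the frequency VSE model on an electrostatic subset
#'
#' Fits the dipolar VSE frequency model `nu = nu0 + dmu * F +
#' 0.5 * dalpha * F^2` on the purely electrostatic records (those without a
#' hydrogen-bond geometry, or a caller-chosen environment subset). The same
#' parameters are then applied unchanged to every environment present and
#' the per-environment goodness is reported: hydrogen-bonded records score
#' poorly (typically a negative R^2) because the blueshift is not a field
#' effect.
#'
#' @param records Calibration table with columns `field`, `freq`, optionally
#'   `d`/`theta` (NA marks no hydrogen bond) and `env`.
#' @param subset Logical vector selecting the records to fit on; defaults to
#'   the records without a hydrogen bond.
#' @param quadratic Include the difference-polarizability term (default
#'   `TRUE`).
#' @return A `vse_frequency_fit` report; `$vse_params` holds the fitted
#'   [vse_params()] (TDM fields left at defaults).
#' @export
fit_vse_frequency <- function(records, subset = NULL, quadratic = TRUE) {
  .assert_records(records, c("field", "freq"))
  if (is.null(subset)) subset <- !.has_hb(records)
  sub <- records[subset, , drop = FALSE]
  if (length(unique(sub$field)) < (if (quadratic) 3L else 2L))
    stop("Rank-deficient design: the fitting subset needs at least ",
         if (quadratic) 3L else 2L, " distinct field values.", call. = FALSE)
  fit <- if (quadratic) {
    stats::lm(freq ~ field + I(0.5 * field^2), data = sub)
  } else {
    stats::lm(freq ~ field, data = sub)
  }
  terms <- c("nu0", "dmu", if (quadratic) "dalpha")
  cf <- stats::coef(fit)
  vp <- vse_params(nu0 = cf[[1]], dmu = cf[[2]],
                   dalpha = if (quadratic) cf[[3]] else 0)
  pred_all <- vse_frequency(records$field, vp)
  g_sub <- goodness(sub$freq, vse_frequency(sub$field, vp))
  .new_fit_report(
    "vse_frequency_fit", .lm_param_tibble(fit, terms),
    g_sub$r_squared, g_sub$rmsd, nrow(sub),
    pred_all, records$freq - pred_all,
    per_environment = .per_env_goodness(records, pred_all, "freq"),
    extra = list(model = fit, vse_params = vp))
}

#' Extract per-configuration hydrogen-bond blueshifts
#'
#' The blueshift of each record is its observed frequency minus the VSE
#' prediction at that record's field (the frequency decomposition
#' rearranged). For purely electrostatic records the expectation is zero;
#' hydrogen-bonded records reveal the geometric blueshift.
#'
#' @param records Calibration table with columns `field`, `freq`.
#' @param vse_params A [vse_params()] object, typically from
#'   [fit_vse_frequency()] on the electrostatic subset (pass
#'   `fit$vse_params`).
#' @return The records as a tibble with a `blueshift` column (cm^-1).
#' @export
extract_blueshifts <- function(records, vse_params) {
  .assert_records(records, c("field", "freq"))
  stopifnot(inherits(vse_params, "vse_params"))
  out <- tibble::as_tibble(records)
  out$blueshift <- out$freq - vse_frequency(out$field, vse_params)
  out
}

# ---- nonlinear distance/angle fits ------------------------------------------

#' Fit the head-on distance law
#'
#' Fits the blueshift of head-on hydrogen bonds as a function of heavy-atom
#' distance, either as a power law `A * d^n` (exponent free; the canonical
#' model fixes it to the integer -4) or as an exponential `A * exp(-a * d)`.
#'
#' @param points Data frame with columns `d` (Angstrom) and `blueshift`
#'   (cm^-1); at least 3 points with distinct distances.
#' @param variant `"power"` or `"exponential"`.
#' @return A `headon_fit` report with terms `A` and `n` (power) or `A` and
#'   `a` (exponential).
#' @export
fit_headon <- function(points, variant = c("power", "exponential")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(points),
            all(c("d", "blueshift") %in% names(points)))
  if (length(unique(points$d)) < 3L)
    stop("At least 3 distinct distances are required.", call. = FALSE)
  d <- points$d; y <- points$blueshift
  pos <- y > 0
  if (variant == "power") {
    st <- if (sum(pos) >= 2L) {
      cf <- stats::coef(stats::lm(log(y[pos]) ~ log(d[pos])))
      list(A = exp(cf[[1]]), n = cf[[2]])
    } else list(A = 50, n = -4)
    fit <- .nls_multistart(blueshift ~ A * d^n, points,
                           list(st, list(A = 100, n = -4),
                                list(A = 20, n = -2)))
  } else {
    st <- if (sum(pos) >= 2L) {
      cf <- stats::coef(stats::lm(log(y[pos]) ~ d[pos]))
      list(A = exp(cf[[1]]), a = -cf[[2]])
    } else list(A = 500, a = 1.3)
    fit <- .nls_multistart(blueshift ~ A * exp(-a * d), points,
                           list(st, list(A = 1000, a = 1.3),
                                list(A = 100, a = 0.8)))
  }
  pred <- stats::fitted(fit)
  g <- goodness(y, pred)
  .new_fit_report("headon_fit", .nls_param_tibble(fit), g$r_squared, g$rmsd,
                  nrow(points), pred, y - pred,
                  extra = list(model = fit, variant = variant))
}

#' Fit the side-on Buckingham-like distance law
#'
#' Fits `A * (exp(-b * (d - d0)) - (d / d0)^n2)` to side-on blueshift data
#' (distances at or above the 2.5 Angstrom validity bound). The reference
#' distance `d0` is the zero crossing of the fitted shape and is reported as
#' a parameter. The `"two_power"` variant replaces the single power term
#' with two power terms with free exponents,
#' `Ae * exp(-b * d) - C1 * d^p1 - C2 * d^p2`, to probe the robustness of
#' the power-term exponent.
#'
#' @param points Data frame with columns `d` (>= 2.5 Angstrom) and
#'   `blueshift` (cm^-1).
#' @param variant `"buckingham"` (default) or `"two_power"`.
#' @return A `sideon_fit` report; for the default variant the terms are
#'   `A`, `d0`, `b`, `n2` and `$zero_crossing` repeats the fitted `d0`.
#' @export
fit_sideon <- function(points, variant = c("buckingham", "two_power")) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(points),
            all(c("d", "blueshift") %in% names(points)))
  if (any(points$d < 2.5))
    stop("Side-on fitting requires d >= 2.5 Angstrom (validity bound of ",
         "the Buckingham-like form).", call. = FALSE)
  y <- points$blueshift
  if (variant == "buckingham") {
    starts <- list()
    for (A in c(5, 15, 30)) for (dz in c(3.0, 3.5)) for (bb in c(2, 3))
      for (p in c(-6, -8, -10))
        starts[[length(starts) + 1L]] <- list(A = A, d0 = dz, b = bb, n2 = p)
    fit <- .nls_multistart(
      blueshift ~ A * (exp(-b * (d - d0)) - (d / d0)^n2), points, starts,
      lower = c(A = 1e-3, d0 = 2.0, b = 0.1, n2 = -20),
      upper = c(A = 1e3, d0 = 6.0, b = 10, n2 = -0.5))
    pred <- stats::fitted(fit)
    g <- goodness(y, pred)
    .new_fit_report("sideon_fit", .nls_param_tibble(fit), g$r_squared,
                    g$rmsd, nrow(points), pred, y - pred,
                    extra = list(model = fit, variant = variant,
                                 zero_crossing = stats::coef(fit)[["d0"]]))
  } else {
    starts <- list()
    for (p1 in c(-6, -8)) for (p2 in c(-8, -10))
      starts[[length(starts) + 1L]] <-
        list(Ae = 1e4, b = 3, C1 = 1e4, p1 = p1, C2 = 1e4, p2 = p2)
    fit <- .nls_multistart(
      blueshift ~ Ae * exp(-b * d) - C1 * d^p1 - C2 * d^p2, points, starts,
      lower = c(Ae = 1e-3, b = 0.1, C1 = 0, p1 = -20, C2 = 0, p2 = -20),
      upper = c(Ae = 1e9, b = 10, C1 = 1e9, p1 = -0.5, C2 = 1e9, p2 = -0.5))
    pred <- stats::fitted(fit)
    g <- goodness(y, pred)
    .new_fit_report("sideon_fit", .nls_param_tibble(fit), g$r_squared,
                    g$rmsd, nrow(points), pred, y - pred,
                    extra = list(model = fit, variant = variant))
  }
}

#' Fit the angular modulation at fixed distance
#'
#' Fits `A * cos(m * (180 - theta))` to blueshifts sampled across angles at
#' a fixed hydrogen-bond distance (conventionally 3.0 Angstrom, where the
#' side-on well is near-negligible), and reports the implied zero-crossing
#' angle `180 - 90 / m`.
#'
#' @param points Data frame with columns `theta` (degrees, spanning at least
#'   60 degrees) and `blueshift` (cm^-1).
#' @return An `angular_fit` report with terms `A` and `m`;
#'   `$zero_crossing_deg` holds the implied zero-crossing angle.
#' @export
fit_angular <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("theta", "blueshift") %in% names(points)))
  if (diff(range(points$theta)) < 60)
    stop("The angular fit requires a theta range spanning at least 60 ",
         "degrees.", call. = FALSE)
  starts <- list(list(A = max(points$blueshift), m = 0.9),
                 list(A = max(points$blueshift), m = 0.7),
                 list(A = 2 * max(points$blueshift), m = 1.0))
  fit <- .nls_multistart(
    blueshift ~ A * cos(m * (180 - theta) * pi / 180), points, starts,
    lower = c(A = 1e-6, m = 0.1), upper = c(A = 1e3, m = 1.2))
  pred <- stats::fitted(fit)
  g <- goodness(points$blueshift, pred)
  m_hat <- stats::coef(fit)[["m"]]
  .new_fit_report("angular_fit", .nls_param_tibble(fit), g$r_squared, g$rmsd,
                  nrow(points), pred, points$blueshift - pred,
                  extra = list(model = fit, zero_crossing_deg = 180 - 90 / m_hat))
}

#' Joint fit of the VSE and blueshift models
#'
#' Simultaneous nonlinear least-squares fit of the full frequency
#' decomposition over records spanning purely electrostatic and
#' hydrogen-bonded environments:
#' `nu = nu0 + dmu * F + 0.5 * dalpha * F^2 + [has HB] * dnu(d, theta)`,
#' with the blueshift surface of [hb_blueshift()] and the integer exponents
#' held fixed. Free parameters: `nu0`, `dmu`, `dalpha`, `d0`, `dnu_d0`, `b`,
#' `m`.
#'
#' @param records Calibration table with columns `field`, `freq`, and
#'   `d`/`theta` (NA for electrostatic records); optionally `env`.
#' @param quadratic Free the difference polarizability (default `TRUE`).
#' @return A `joint_fit` report with per-environment residual summaries;
#'   `$blueshift_params` and `$vse_params` hold the fitted parameter
#'   objects.
#' @export
fit_joint <- function(records, quadratic = TRUE) {
  .assert_records(records, c("field", "freq"))
  hb <- .has_hb(records)
  if (!any(hb) || all(hb))
    stop("The joint fit needs both electrostatic and hydrogen-bonded ",
         "records.", call. = FALSE)
  df <- tibble::as_tibble(records)
  df$hb <- as.numeric(hb)
  df$d_fit <- ifelse(hb, df$d, 10)       # dummy geometry for non-HB rows,
  df$theta_fit <- ifelse(hb, df$theta, 180)  # multiplied by hb = 0
  es <- fit_vse_frequency(df, subset = !hb, quadratic = quadratic)
  vp0 <- es$vse_params
  starts <- list()
  for (dz in c(3.0, 3.6)) for (D in c(10, 25)) for (bb in c(2, 3.5))
    for (mm in c(0.8, 1.0))
      starts[[length(starts) + 1L]] <-
        list(nu0 = vp0$nu0, dmu = vp0$dmu, dalpha = vp0$dalpha,
             d0 = dz, dnu_d0 = D, b = bb, m = mm)
  fit <- .nls_multistart(
    freq ~ nu0 + dmu * field + 0.5 * dalpha * field^2 +
      hb * .blueshift_surface(d_fit, theta_fit, d0, dnu_d0, b, m),
    df, starts,
    lower = c(nu0 = 0, dmu = -5, dalpha = -1, d0 = 2.0, dnu_d0 = 0.1,
              b = 0.1, m = 0.1),
    upper = c(nu0 = 1e4, dmu = 5, dalpha = 1, d0 = 6.0, dnu_d0 = 1e3,
              b = 10, m = 1.2))
  pred <- stats::fitted(fit)
  g <- goodness(df$freq, pred)
  cf <- stats::coef(fit)
  .new_fit_report(
    "joint_fit", .nls_param_tibble(fit), g$r_squared, g$rmsd, nrow(df),
    pred, df$freq - pred,
    per_environment = .per_env_goodness(df, pred, "freq"),
    extra = list(
      model = fit,
      vse_params = vse_params(nu0 = cf[["nu0"]], dmu = cf[["dmu"]],
                              dalpha = cf[["dalpha"]]),
      blueshift_params = blueshift_params(d0 = cf[["d0"]],
                                          dnu_d0 = cf[["dnu_d0"]],
                                          b = cf[["b"]], m = cf[["m"]])))
}
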