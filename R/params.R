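# Parameter containers for the frequency/TDM model.
#
# Units used throughout the package: cm^-1 (frequencies and blueshifts),
# Angstrom (distances), degrees (angles), MV/cm (electric fields), Debye
# (transition dipoles), fs/ps (time).

# speed of light in cm per fs; bridges wavenumbers and time
.c_cm_fs <- 2.99792458e-5

#' Vibrational Stark effect parameters
#'
#' Bundles the parameters of the dipolar vibrational Stark effect (VSE) model
#' for a nitrile probe: the zero-field frequency, the linear field sensitivity
#' of the frequency (the Stark tuning rate, i.e. the magnitude of the
#' difference dipole), an optional quadratic sensitivity (difference
#' polarizability), and the zero-field transition dipole moment (TDM) with its
#' linear field sensitivity.
#'
#' The sign convention is fixed so that fields are reported as the signed
#' projection onto the C&#8801;N difference-dipole direction: condensed-phase
#' stabilizing fields are negative and red-shift the frequency, i.e.
#' `nu = nu0 + dmu * F + 0.5 * dalpha * F^2` with `F < 0` giving `nu < nu0`.
#'
#' @param nu0 Zero-field frequency, cm^-1. Default 2232.0, the scaled
#'   gas-phase anchor for an aromatic nitrile.
#' @param dmu Stark tuning rate, cm^-1/(MV/cm). Default 0.2748.
#' @param dalpha Difference polarizability, cm^-1/(MV/cm)^2. Usually
#'   negligible; default 0.
#' @param tdm0 Zero-field transition dipole, Debye. Default 0.040.
#' @param tdm_polarizability Linear field sensitivity of the TDM,
#'   D/(MV/cm). Negative: stabilizing (negative) fields increase the TDM.
#'   Default -2.5e-4.
#' @param tdm_quad Optional quadratic TDM field sensitivity, D/(MV/cm)^2.
#'   Default 0.
#' @return An object of class `vse_params` (a named list).
#' @examples
#' p <- vse_params()
#' vse_frequency(-60, p)
#' @export
vse_params <- function(nu0 = 2232.0, dmu = 0.2748, dalpha = 0,
                       tdm0 = 0.040, tdm_polarizability = -2.5e-4,
                       tdm_quad = 0) {
  stopifnot(is.numeric(nu0), length(nu0) == 1L, is.finite(nu0),
            is.numeric(dmu), length(dmu) == 1L, is.finite(dmu),
            is.numeric(dalpha), length(dalpha) == 1L, is.finite(dalpha),
            is.numeric(tdm0), length(tdm0) == 1L, is.finite(tdm0),
            is.numeric(tdm_polarizability), length(tdm_polarizability) == 1L,
            is.finite(tdm_polarizability),
            is.numeric(tdm_quad), length(tdm_quad) == 1L, is.finite(tdm_quad))
  if (nu0 <= 0) stop("`nu0` must be positive (cm^-1).", call. = FALSE)
  if (tdm0 <= 0) stop("`tdm0` must be positive (Debye).", call. = FALSE)
  structure(
    list(nu0 = nu0, dmu = dmu, dalpha = dalpha, tdm0 = tdm0,
         tdm_polarizability = tdm_polarizability, tdm_quad = tdm_quad),
    class = "vse_params"
  )
}

#' Hydrogen-bond blueshift surface parameters
#'
#' Parameters of the hydrogen-bond (HB) geometry-dependent blueshift model:
#' a reference distance `d0` at which the side-on (Buckingham-like) term
#' crosses zero, the blueshift `dnu_d0` at that distance for a head-on HB,
#' the side-on exponential decay constant `b`, and the cosine period
#' modulation `m` of the angular term. The integer exponents of the head-on
#' power law (`n1 = -4`) and of the side-on power term (`n2 = -8`) are fixed
#' in the canonical model. `a` is the decay constant of the optional
#' exponential head-on variant.
#'
#' The defaults are the canonical optimized values of the combined model:
#' `d0 = 3.36` A, `dnu_d0 = 16.6` cm^-1, `b = 2.85` A^-1, `m = 0.91`.
#'
#' @param d0 Reference heavy-atom distance, Angstrom.
#' @param dnu_d0 Head-on blueshift at `d0`, cm^-1.
#' @param b Side-on exponential decay constant, A^-1.
#' @param m Cosine period modulation (dimensionless, 0 < m <= 1.2).
#' @param n1 Head-on power-law exponent; fixed integer -4 in the canonical
#'   model.
#' @param n2 Side-on power-term exponent; fixed integer -8 in the canonical
#'   model.
#' @param a Decay constant of the exponential head-on variant, A^-1.
#' @return An object of class `blueshift_params` (a named list).
#' @examples
#' bp <- blueshift_params()
#' hb_blueshift(2.93, 169, bp)
#' @export
blueshift_params <- function(d0 = 3.36, dnu_d0 = 16.6, b = 2.85, m = 0.91,
                             n1 = -4, n2 = -8, a = 1.30) {
  stopifnot(is.numeric(d0), is.numeric(dnu_d0), is.numeric(b), is.numeric(m),
            is.numeric(n1), is.numeric(n2), is.numeric(a))
  if (d0 <= 0) stop("`d0` must be positive (Angstrom).", call. = FALSE)
  if (b <= 0) stop("`b` must be positive (A^-1).", call. = FALSE)
  if (m <= 0 || m > 1.2) stop("`m` must lie in (0, 1.2].", call. = FALSE)
  structure(
    list(d0 = d0, dnu_d0 = dnu_d0, b = b, m = m, n1 = n1, n2 = n2, a = a),
    class = "blueshift_params"
  )
}

#' @export
print.vse_params <- function(x, ...) {
  cat("VSE parameters:\n")
  cat(sprintf("  nu0    = %.1f cm^-1\n", x$nu0))
  cat(sprintf("  dmu    = %.4f cm^-1/(MV/cm)\n", x$dmu))
  cat(sprintf("  dalpha = %.3g cm^-1/(MV/cm)^2\n", x$dalpha))
  cat(sprintf("  tdm0   = %.4f D, tdm polarizability = %.3g D/(MV/cm)\n",
              x$tdm0, x$tdm_polarizability))
  invisible(x)
}

#' @export
print.blueshift_params <- function(x, ...) {
  cat("HB blueshift parameters:\n")
  cat(sprintf("  d0 = %.2f A, dnu_d0 = %.1f cm^-1, b = %.2f A^-1, m = %.2f\n",
              x$d0, x$dnu_d0, x$b, x$m))
  cat(sprintf("  exponents n1 = %d, n2 = %d; exponential head-on a = %.2f A^-1\n",
              as.integer(x$n1), as.integer(x$n2), x$a))
  invisible(x)
}

#' Read and write model parameter configuration files
#'
#' Parameters are serialized as YAML with named fields matching the model
#' symbols. A bundled default configuration reproducing the canonical
#' parameter set ships with the package (see
#' `system.file("extdata", "default_params.yaml", package = "vsemap")`).
#'
#' @param path Path of the YAML configuration file.
#' @return `read_params()` returns a list with elements `vse` (a
#'   [vse_params()] object) and `blueshift` (a [blueshift_params()] object).
#' @examples
#' cfg <- read_params(system.file("extdata", "default_params.yaml",
#'                                package = "vsemap"))
#' cfg$blueshift$d0
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  list(
    vse = do.call(vse_params, raw$vse),
    blueshift = do.call(blueshift_params, raw$blueshift)
  )
}

#' @rdname read_params
#' @param vse A [vse_params()] object.
#' @param blueshift A [blueshift_params()] object.
#' @export
write_params <- function(vse, blueshift, path) {
  stopifnot(inherits(vse, "vse_params"), inherits(blueshift, "blueshift_params"))
  yaml::write_yaml(list(vse = unclass(vse), blueshift = unclass(blueshift)),
                   path)
  invisible(path)
}
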