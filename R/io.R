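# Delimited-text readers/writers for calibration tables, trajectories and
# spectra, and hydrogen-bond geometry extraction from PDB structures.

#' Read and write calibration tables
#'
#' Calibration tables are tab-separated text with a mandatory header.
#' Either a precomputed `field` projection column (MV/cm) or the three
#' field components `fx`, `fy`, `fz` must be present (components are
#' projected onto `cn_axis` on reading); `d`/`theta` are NA for purely
#' electrostatic records; `freq` (cm^-1), `tdm` (D) and `env` complete a
#' record. Numeric values round-trip losslessly at full double precision.
#'
#' @param path File path.
#' @param cn_axis Probe axis used to project field components when the
#'   table carries `fx`, `fy`, `fz` instead of `field`.
#' @return A tibble of calibration records.
#' @export
read_calibration_table <- function(path, cn_axis = c(0, 0, 1)) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!"field" %in% names(df)) {
    if (!all(c("fx", "fy", "fz") %in% names(df)))
      stop("Calibration table needs a `field` column or `fx`,`fy`,`fz` ",
           "components.", call. = FALSE)
    u <- cn_axis / sqrt(sum(cn_axis^2))
    df$field <- df$fx * u[1] + df$fy * u[2] + df$fz * u[3]
  }
  .assert_records(df, c("field", "freq", "tdm"))
  df
}

#' @rdname read_calibration_table
#' @param records A calibration record tibble.
#' @export
write_calibration_table <- function(records, path) {
  .assert_records(records, c("field", "freq", "tdm"))
  readr::write_tsv(records, path)
  invisible(path)
}

#' Read and write trajectory frame tables
#'
#' Frame series are tab-separated text with header columns `time_fs`,
#' `field`, `d`, `theta`, `hb`. The generating seed, when known, is
#' recorded in a header comment line and restored as an attribute.
#'
#' @param path File path.
#' @return A frames tibble as produced by [simulate_hb_trajectory()].
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1L)
  seed <- NULL
  if (startsWith(first, "# seed:"))
    seed <- as.integer(trimws(sub("# seed:", "", first)))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("time_fs", "field", "hb") %in% names(df)))
  if (nrow(df) >= 2L) attr(df, "dt_fs") <- df$time_fs[2] - df$time_fs[1]
  attr(df, "seed") <- seed
  df
}

#' @rdname read_trajectory
#' @param frames A frames tibble.
#' @export
write_trajectory <- function(frames, path) {
  stopifnot(all(c("time_fs", "field", "hb") %in% names(frames)))
  seed <- attr(frames, "seed")
  if (!is.null(seed)) {
    writeLines(sprintf("# seed: %d", seed), path)
    readr::write_tsv(tibble::as_tibble(frames), path, append = TRUE,
                     col_names = TRUE)
  } else {
    readr::write_tsv(tibble::as_tibble(frames), path)
  }
  invisible(path)
}

#' Read and write spectra
#'
#' Spectra are two-column tab-separated text (`wavenumber` cm^-1,
#' `intensity`); the detected peaks travel in a sidecar file
#' (`<path>.peaks` by default) with columns `position`, `height`.
#'
#' @param path Spectrum file path.
#' @param peaks_path Sidecar path; on reading, peaks are re-detected when
#'   the sidecar is absent.
#' @return A `vsm_spectrum` tibble.
#' @export
read_spectrum <- function(path, peaks_path = paste0(path, ".peaks")) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("wavenumber", "intensity") %in% names(df)))
  peaks <- if (file.exists(peaks_path)) {
    readr::read_tsv(peaks_path, comment = "#", show_col_types = FALSE)
  } else {
    .find_peaks(df$wavenumber, df$intensity)
  }
  .new_spectrum(df$wavenumber, df$intensity, tibble::as_tibble(peaks))
}

#' @rdname read_spectrum
#' @param spec A `vsm_spectrum`.
#' @export
write_spectrum <- function(spec, path, peaks_path = paste0(path, ".peaks")) {
  stopifnot(inherits(spec, "vsm_spectrum"))
  readr::write_tsv(tibble::tibble(wavenumber = spec$wavenumber,
                                  intensity = spec$intensity), path)
  readr::write_tsv(attr(spec, "peaks"), peaks_path)
  invisible(path)
}

# ---- PDB geometry extraction ------------------------------------------------

#' Extract hydrogen-bond geometries around a nitrile probe from a PDB file
#'
#' Locates the nitrile C and N atoms of the probe, finds all donor heavy
#' atoms (O or N, excluding the probe's own residue) within a search radius
#' of the nitrile nitrogen, and reports for each contact the heavy-atom
#' distance `d` (N...donor, Angstrom) and the C&#8801;N...donor angle
#' `theta` at the nitrile nitrogen (degrees; a collinear head-on contact
#' is 180). Only the first model is used; alternate locations are
#' resolved by highest occupancy, ties alphabetically; hydrogens are
#' ignored by design (heavy-atom convention).
#'
#' @param pdb Path to a PDB file, or a `bio3d` pdb object.
#' @param probe_resno Residue number of the probe.
#' @param c_atom,n_atom Atom names (PDB columns) of the nitrile carbon and
#'   nitrogen within that residue.
#' @param probe_chain Chain identifier; `NULL` if unambiguous.
#' @param radius Donor search radius around the nitrile N, Angstrom.
#' @return A tibble of contacts sorted by distance, with columns `chain`,
#'   `resno`, `resid`, `atom`, `element`, `d`, `theta`.
#' @export
extract_hb_geometry <- function(pdb, probe_resno, c_atom, n_atom,
                                probe_chain = NULL, radius = 4.0) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("Package `bio3d` is required for PDB parsing.", call. = FALSE)
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  # altloc: keep the highest-occupancy (then alphabetically first) copy
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  if (any(nzchar(at$alt) & at$alt != " ")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(key, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
             drop = FALSE]
  }
  sel <- at$resno == probe_resno
  if (!is.null(probe_chain)) sel <- sel & at$chain == probe_chain
  cc <- at[sel & at$elety == c_atom, , drop = FALSE]
  nn <- at[sel & at$elety == n_atom, , drop = FALSE]
  if (nrow(cc) != 1L || nrow(nn) != 1L)
    stop(sprintf(
      "Probe selection must match exactly one C (got %d '%s') and one N ",
      nrow(cc), c_atom), sprintf("(got %d '%s') atom in residue %s.",
      nrow(nn), n_atom, probe_resno), call. = FALSE)
  cpos <- c(cc$x, cc$y, cc$z); npos <- c(nn$x, nn$y, nn$z)
  elem <- toupper(substr(gsub("[0-9 ]", "", at$elety), 1, 1))
  if ("elesy" %in% names(at) && any(nzchar(trimws(at$elesy))))
    elem <- ifelse(nzchar(trimws(at$elesy)), toupper(trimws(at$elesy)), elem)
  donors <- at[elem %in% c("O", "N") &
                 !(at$resno == probe_resno &
                     (if (is.null(probe_chain)) TRUE
                      else at$chain == probe_chain)), , drop = FALSE]
  if (nrow(donors) == 0L)
    return(tibble::tibble(chain = character(), resno = integer(),
                          resid = character(), atom = character(),
                          element = character(), d = numeric(),
                          theta = numeric()))
  dx <- donors$x - npos[1]; dy <- donors$y - npos[2]; dz <- donors$z - npos[3]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  keep <- d <= radius & d > 1e-6
  donors <- donors[keep, , drop = FALSE]
  dx <- dx[keep]; dy <- dy[keep]; dz <- dz[keep]; d <- d[keep]
  # theta is the C-N...donor bond angle at the vertex N: rays N->C and
  # N->donor; a collinear head-on contact gives 180 degrees
  nc <- cpos - npos; nc <- nc / sqrt(sum(nc^2))
  cosang <- (dx * nc[1] + dy * nc[2] + dz * nc[3]) / d
  theta <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  elem_keep <- toupper(substr(gsub("[0-9 ]", "", donors$elety), 1, 1))
  out <- tibble::tibble(chain = donors$chain, resno = donors$resno,
                        resid = donors$resid, atom = donors$elety,
                        element = elem_keep, d = d, theta = theta)
  dplyr::arrange(out, d)
}
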