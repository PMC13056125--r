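# Plain-CSV readers/writers for the formats the package exchanges with
# instruments and trackers. Column headers follow the conventions:
# curves (displacement_nm, force_pN), spectra (wavelength_nm, value),
# tracks (t_s, x_um, y_um, theta_deg), device (t_min, pressure_mmHg) and
# (t_min, act_s), efficiency maps long-format (row, col, efficiency).

#' @rdname curve_csv
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  utils::write.csv(data.frame(displacement_nm = curve$displacement,
                              force_pN = curve$force),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read or write a force curve as CSV
#'
#' @param curve a [force_curve()].
#' @param path file path.
#' @param mode,condition,baseline_window curve metadata (sidecar information
#'   not carried by the CSV itself).
#' @return `read_curve_csv()` returns a [force_curve()];
#'   `write_curve_csv()` returns the path invisibly.
#' @name curve_csv
#' @export
read_curve_csv <- function(path, mode = "tangential", condition = "unlabeled",
                           baseline_window = NULL) {
  df <- utils::read.csv(path)
  force_curve(df$displacement_nm, df$force_pN, mode = mode,
              condition = condition, baseline_window = baseline_window)
}

#' @rdname spectrum_csv
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  utils::write.csv(data.frame(wavelength_nm = spec$wavelength,
                              value = spec$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read or write a spectrum as CSV
#'
#' @param spec a [spectrum()].
#' @param path file path.
#' @param kind `"donor"` or `"acceptor"`.
#' @return `read_spectrum_csv()` returns a [spectrum()].
#' @name spectrum_csv
#' @export
read_spectrum_csv <- function(path, kind = "donor") {
  df <- utils::read.csv(path)
  spectrum(df$wavelength_nm, df$value, kind = kind)
}

#' @rdname track_csv
#' @export
write_track_csv <- function(track, path) {
  stopifnot(inherits(track, "tracked_platelet"))
  utils::write.csv(data.frame(t_s = track$t, x_um = track$x, y_um = track$y,
                              theta_deg = track$orientation),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read or write a platelet track as CSV
#'
#' @param track a [tracked_platelet()].
#' @param path file path.
#' @param radius,group,id track metadata (sidecar information).
#' @return `read_track_csv()` returns a [tracked_platelet()].
#' @name track_csv
#' @export
read_track_csv <- function(path, radius = 1.25, group = "discoid",
                           id = "track1") {
  df <- utils::read.csv(path)
  tracked_platelet(df$t_s, df$x_um, df$y_um, df$theta_deg,
                   radius = radius, group = group, id = id)
}

#' @rdname pressure_csv
#' @export
write_pressure_csv <- function(series, path) {
  stopifnot(inherits(series, "pressure_series"))
  utils::write.csv(data.frame(t_min = series$t,
                              pressure_mmHg = series$pressure),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read or write device time series as CSV
#'
#' @param series a [pressure_series()].
#' @param path file path.
#' @param baseline reference pressure (mmHg).
#' @return `read_pressure_csv()` returns a [pressure_series()];
#'   `read_act_csv()` returns a data frame with `t_min`, `act_s`.
#' @name pressure_csv
#' @export
read_pressure_csv <- function(path, baseline = 50) {
  df <- utils::read.csv(path)
  pressure_series(df$t_min, df$pressure_mmHg, baseline = baseline)
}

#' @rdname pressure_csv
#' @export
read_act_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_min", "act_s") %in% names(df)))
  df[c("t_min", "act_s")]
}

#' @rdname map_csv
#' @export
write_map_csv <- function(map, path) {
  stopifnot(is.matrix(map))
  idx <- which(!is.na(map), arr.ind = TRUE)
  utils::write.csv(data.frame(row = idx[, 1L], col = idx[, 2L],
                              efficiency = map[idx]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read or write an efficiency map as long-format CSV
#'
#' @param map numeric matrix (NA = background).
#' @param path file path.
#' @param nrow,ncol output dimensions; inferred from the data when omitted.
#' @return `read_map_csv()` returns a numeric matrix.
#' @name map_csv
#' @export
read_map_csv <- function(path, nrow = NULL, ncol = NULL) {
  df <- utils::read.csv(path)
  nr <- if (is.null(nrow)) max(df$row) else nrow
  nc <- if (is.null(ncol)) max(df$col) else ncol
  m <- matrix(NA_real_, nr, nc)
  m[cbind(df$row, df$col)] <- df$efficiency
  m
}
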