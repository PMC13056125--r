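#' Spectrum on a uniform wavelength grid
#'
#' Either a donor emission spectrum (arbitrary intensity; area-normalised
#' inside [overlap_integral()]) or an acceptor excitation spectrum in molar
#' extinction units (M^-1 cm^-1).
#'
#' @param wavelength strictly increasing, uniform wavelength grid (nm),
#'   at least 16 points.
#' @param value nonnegative per-wavelength values.
#' @param kind `"donor"` or `"acceptor"` (informational).
#' @return an object of class `spectrum` (a data frame).
#' @export
spectrum <- function(wavelength, value, kind = c("donor", "acceptor")) {
  kind <- match.arg(kind)
  if (length(wavelength) < 16L) stop_bad("a spectrum needs >= 16 grid points")
  if (length(value) != length(wavelength)) stop_bad("grid/value length mismatch")
  d <- diff(wavelength)
  if (any(d <= 0)) stop_bad("wavelength grid must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d)) stop_bad("wavelength grid must be uniform")
  if (any(value < 0)) stop_bad("spectrum values must be nonnegative")
  structure(data.frame(wavelength = as.numeric(wavelength),
                       value = as.numeric(value)),
            class = c("spectrum", "data.frame"), kind = kind)
}

#' Donor quantum yield, orientation factor and refractive index
#'
#' Photophysical parameters entering the Forster radius. Defaults are the
#' DiO/Rhodamine B head-to-membrane configuration in PBS: orientation factor
#' kappa^2 = 2/3 (isotropic dynamic averaging), refractive index 1.33, donor
#' quantum yield 0.4.
#'
#' @param kappa2 orientation factor, in (0, 4].
#' @param n_refr medium refractive index.
#' @param phi_d donor fluorescence quantum yield.
#' @return an object of class `fret_params`.
#' @export
fret_params <- function(kappa2 = 2 / 3, n_refr = 1.33, phi_d = 0.4) {
  check_number(kappa2, "kappa2", lower = 0, upper = 4, strict_lower = TRUE)
  check_number(n_refr, "n_refr", lower = 0, strict_lower = TRUE)
  check_number(phi_d, "phi_d", lower = 0, strict_lower = TRUE)
  structure(list(kappa2 = kappa2, n_refr = n_refr, phi_d = phi_d),
            class = "fret_params")
}

#' Spectral overlap integral J
#'
#' `J = integral f_D(lambda) eps_A(lambda) lambda^4 dlambda` by the trapezoid
#' rule on the donor grid, with the donor emission renormalised to unit
#' trapezoid area and the acceptor extinction linearly interpolated onto the
#' donor grid (zero outside its support). Units M^-1 cm^-1 nm^4 when the
#' acceptor is in M^-1 cm^-1 and wavelengths in nm.
#'
#' @param donor donor emission [spectrum()].
#' @param acceptor acceptor excitation [spectrum()] in molar extinction units.
#' @return the overlap integral J (M^-1 cm^-1 nm^4); 0 with a warning when
#'   the bands do not overlap.
#' @export
overlap_integral <- function(donor, acceptor) {
  stopifnot(inherits(donor, "spectrum"), inherits(acceptor, "spectrum"))
  lam <- donor$wavelength
  area <- trapz_grid(lam, donor$value)
  if (area <= 0) stop_bad("donor spectrum has zero area")
  fd <- donor$value / area
  eps <- stats::approx(acceptor$wavelength, acceptor$value, xout = lam,
                       yleft = 0, yright = 0)$y
  j <- trapz_grid(lam, fd * eps * lam^4)
  if (j <= 0) {
    warning("donor and acceptor bands do not overlap; J = 0", call. = FALSE)
    return(0)
  }
  j
}

#' Forster radius from the overlap integral
#'
#' `R0 = 0.02108 (kappa^2 Phi_D n^-4 J)^(1/6)` nm, with J in
#' M^-1 cm^-1 nm^4. R0 is the donor-acceptor separation at which transfer
#' efficiency is 50%.
#'
#' @param J overlap integral (M^-1 cm^-1 nm^4), nonnegative.
#' @param params a [fret_params()] object.
#' @return Forster radius (nm).
#' @export
forster_radius <- function(J, params = fret_params()) {
  stopifnot(inherits(params, "fret_params"))
  check_number(J, "J", lower = 0)
  0.02108 * (params$kappa2 * params$phi_d * params$n_refr^-4 * J)^(1 / 6)
}

#' FRET efficiency at a given donor-acceptor distance
#'
#' Forster law `E = 1 / (1 + (r/R0)^6)`.
#'
#' @param r separation (nm), nonnegative.
#' @param R0 Forster radius (nm), positive.
#' @return transfer efficiency in (0, 1].
#' @export
distance_to_efficiency <- function(r, R0) {
  check_number(R0, "R0", lower = 0, strict_lower = TRUE)
  if (any(r < 0)) stop_bad("`r` must be nonnegative")
  1 / (1 + (r / R0)^6)
}

#' Donor-acceptor distance from FRET efficiency
#'
#' Exact inverse of [distance_to_efficiency()]:
#' `r = R0 ((1 - E) / E)^(1/6)`.
#'
#' @param E transfer efficiency, strictly in (0, 1).
#' @param R0 Forster radius (nm), positive.
#' @return separation (nm).
#' @export
efficiency_to_distance <- function(E, R0) {
  check_number(R0, "R0", lower = 0, strict_lower = TRUE)
  if (any(E <= 0) || any(E >= 1)) stop_bad("`E` must lie strictly in (0, 1)")
  R0 * ((1 - E) / E)^(1 / 6)
}

#' FRET efficiency from donor lifetimes
#'
#' FLIM-FRET relation `E = 1 - tau_DA / tau_D`: lifetime is independent of
#' intensity and fluorophore concentration, so the quenched donor lifetime in
#' presence of the acceptor (`tau_da`) against the unquenched lifetime
#' (`tau_d`) gives the efficiency directly.
#'
#' @param tau_da donor lifetime with acceptor (ns), `0 <= tau_da <= tau_d`.
#' @param tau_d donor-only lifetime (ns), positive.
#' @return efficiency in `[0, 1]`.
#' @export
lifetime_efficiency <- function(tau_da, tau_d) {
  check_number(tau_d, "tau_d", lower = 0, strict_lower = TRUE)
  check_number(tau_da, "tau_da", lower = 0)
  if (tau_da > tau_d)
    stop_bad("tau_da > tau_d: negative efficiency suggests mislabeled channels")
  1 - tau_da / tau_d
}

#' Activated fraction from a two-state efficiency mixture
#'
#' Linear two-state mixture of apparent FRET efficiency: a region whose
#' apparent efficiency `E_region` lies between the resting (bent-closed)
#' efficiency `E_rest` and the fully activated (extended) efficiency
#' `E_active` contains a fraction
#' `f = (E_rest - E_region) / (E_rest - E_active)` of activated receptors.
#' By default `E_active` is evaluated at the 19-nm extended head-to-membrane
#' distance rather than assumed 0; the difference is below 0.1% of the
#' fraction.
#'
#' @param E_rest apparent efficiency of resting membrane regions.
#' @param E_region apparent efficiency of the region of interest.
#' @param E_active apparent efficiency of the fully activated state.
#' @param R0 Forster radius (nm) used for the default `E_active`.
#' @param r_active extended-state head-to-membrane distance (nm) used for the
#'   default `E_active`.
#' @return list with `fraction` (raw, in `[0, 1]`) and `percent_rounded`
#'   (nearest 10%, the reporting convention).
#' @export
activated_fraction <- function(E_rest, E_region,
                               E_active = distance_to_efficiency(r_active, R0),
                               R0 = 5.25, r_active = 19) {
  check_number(E_rest, "E_rest", lower = 0, upper = 1)
  check_number(E_region, "E_region", lower = 0, upper = 1)
  check_number(E_active, "E_active", lower = 0, upper = 1)
  if (!(E_active <= E_region && E_region <= E_rest))
    stop_bad("need E_active <= E_region <= E_rest")
  if (E_rest <= E_active) stop_bad("E_rest must exceed E_active")
  f <- (E_rest - E_region) / (E_rest - E_active)
  list(fraction = f, percent_rounded = round_to_10pct(f))
}

#' Number of receptor copies shifted to the active conformation
#'
#' @param fraction activated fraction in `[0, 1]`.
#' @param copies receptor copies per cell; default 80,000, the usual
#'   alphaIIb-beta3 surface density estimate.
#' @return rounded molecule count.
#' @export
molecules_shifted <- function(fraction, copies = 80000) {
  check_number(fraction, "fraction", lower = 0, upper = 1)
  check_number(copies, "copies", lower = 0)
  round(fraction * copies)
}

#' Pixelwise activated-fraction map from an apparent-efficiency map
#'
#' Applies the two-state mixture [activated_fraction()] to every pixel of an
#' apparent FRET efficiency map. Pixels outside `[E_active, E_rest]` are
#' clamped to the nearest bound and counted. When region masks are supplied
#' (e.g. from [gen_flim_map()]), per-region mean fractions are reported.
#'
#' @param map numeric matrix of apparent efficiencies in `[0, 1]`
#'   (NA = background).
#' @param E_rest,E_active mixture endpoints as in [activated_fraction()].
#' @param regions optional named list of logical masks (same dimensions).
#' @return list with `fraction_map` (matrix), `n_clamped_low`,
#'   `n_clamped_high`, and `region_means` (named numeric or NULL).
#' @export
map_activated_fraction <- function(map, E_rest,
                                   E_active = distance_to_efficiency(19, 5.25),
                                   regions = NULL) {
  if (!is.matrix(map) || !is.numeric(map)) stop_bad("`map` must be a numeric matrix")
  if (all(is.na(map))) stop_bad("efficiency map is all-NA")
  vals <- map[!is.na(map)]
  if (any(vals < 0 | vals > 1)) stop_bad("efficiency map values must lie in [0, 1]")
  check_number(E_rest, "E_rest", lower = 0, upper = 1)
  check_number(E_active, "E_active", lower = 0, upper = E_rest, strict_upper = TRUE)
  lo <- map < E_active & !is.na(map)
  hi <- map > E_rest & !is.na(map)
  clamped <- pmin(pmax(map, E_active), E_rest)
  frac <- (E_rest - clamped) / (E_rest - E_active)
  region_means <- NULL
  if (!is.null(regions)) {
    region_means <- vapply(regions, function(msk) {
      if (!identical(dim(msk), dim(map))) stop_bad("region mask dimensions differ from map")
      mean(frac[msk], na.rm = TRUE)
    }, numeric(1))
  }
  list(fraction_map = frac, n_clamped_low = sum(lo), n_clamped_high = sum(hi),
       region_means = region_means)
}
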