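#' Specification for a synthetic AFM force-displacement curve
#'
#' Parameterises [gen_force_curve()]. The generated curve has a flat noisy
#' baseline, a monotone loading ramp down to minus the rupture force (drawn
#' from `Normal(rupture_mean, rupture_sd)`), optional pre-rupture peaks
#' superimposed on the ramp, a single terminal jump back to ~0 and a short
#' post-rupture tail. Defaults reproduce the tangential (contact-mode)
#' condition: rupture force 39.9 +/- 6.5 pN with two pre-rupture peaks of
#' 2.2 and 2.15 noise-SD amplitude.
#'
#' @param mode loading mode, `"tangential"` or `"normal"`.
#' @param rupture_mean,rupture_sd mean and SD of the rupture force draw (pN).
#' @param peak_amplitudes_sd_units amplitudes of injected pre-rupture peaks,
#'   in units of the noise SD (numeric vector, possibly empty).
#' @param peak_force_scale pN per SD unit used to scale peak amplitudes when
#'   `noise_sd = 0` (so zero-noise curves still carry finite peaks).
#' @param noise_sd additive Gaussian noise SD (pN).
#' @param n_points number of samples (>= 64). The default is large enough
#'   that a 2.15-SD peak is resolved from the 1.96-SD significance threshold
#'   after detrending and smoothing.
#' @param displacement_span total displacement range (nm).
#' @param seed default seed used by [gen_force_curve()].
#' @return an object of class `curve_spec`.
#' @seealso [gen_force_curve()], [detect_prerupture_peaks()]
#' @export
curve_spec <- function(mode = c("tangential", "normal"),
                       rupture_mean = 39.9,
                       rupture_sd = 6.5,
                       peak_amplitudes_sd_units = if (match.arg(mode) == "tangential") c(2.2, 2.15) else numeric(0),
                       peak_force_scale = 2,
                       noise_sd = 2,
                       n_points = 16384L,
                       displacement_span = 500,
                       seed = 1L) {
  mode <- match.arg(mode)
  check_number(rupture_mean, "rupture_mean", lower = 0, strict_lower = TRUE)
  check_number(rupture_sd, "rupture_sd", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(peak_force_scale, "peak_force_scale", lower = 0, strict_lower = TRUE)
  n_points <- check_count(n_points, "n_points", lower = 64L)
  check_number(displacement_span, "displacement_span", lower = 0, strict_lower = TRUE)
  if (length(peak_amplitudes_sd_units) &&
      (!is.numeric(peak_amplitudes_sd_units) || any(peak_amplitudes_sd_units <= 0)))
    stop_bad("`peak_amplitudes_sd_units` must be positive numbers")
  structure(list(mode = mode, rupture_mean = rupture_mean,
                 rupture_sd = rupture_sd,
                 peak_amplitudes_sd_units = as.numeric(peak_amplitudes_sd_units),
                 peak_force_scale = peak_force_scale, noise_sd = noise_sd,
                 n_points = n_points, displacement_span = displacement_span,
                 seed = check_count(seed, "seed", lower = 0L)),
            class = "curve_spec")
}

#' Specification for synthetic donor/acceptor spectra
#'
#' Parameterises [gen_spectra()]: a Gaussian donor emission band
#' (area-normalised on the grid) and a Gaussian acceptor extinction band whose
#' peak value is `acceptor_eps_max`. Defaults emulate the DiO (membrane donor)
#' / Rhodamine B (integrin-head acceptor) pair.
#'
#' @param donor_peak,donor_width donor emission band centre and Gaussian width (nm).
#' @param acceptor_peak,acceptor_width acceptor excitation band centre and width (nm).
#' @param acceptor_eps_max peak molar extinction coefficient (M^-1 cm^-1).
#' @param grid_start,grid_stop,grid_step wavelength grid (nm); must cover both
#'   bands out to three widths.
#' @return an object of class `spectra_spec`.
#' @export
spectra_spec <- function(donor_peak = 501, donor_width = 18,
                         acceptor_peak = 554, acceptor_width = 22,
                         acceptor_eps_max = 106000,
                         grid_start = 400, grid_stop = 700, grid_step = 1) {
  check_number(donor_width, "donor_width", lower = 0, strict_lower = TRUE)
  check_number(acceptor_width, "acceptor_width", lower = 0, strict_lower = TRUE)
  check_number(acceptor_eps_max, "acceptor_eps_max", lower = 0, strict_lower = TRUE)
  check_number(grid_step, "grid_step", lower = 0, strict_lower = TRUE)
  if (grid_stop <= grid_start) stop_bad("`grid_stop` must exceed `grid_start`")
  covers <- function(peak, width)
    grid_start <= peak - 3 * width && grid_stop >= peak + 3 * width
  if (!covers(donor_peak, donor_width) || !covers(acceptor_peak, acceptor_width))
    stop_bad("wavelength grid must cover both bands out to 3 widths")
  structure(list(donor_peak = donor_peak, donor_width = donor_width,
                 acceptor_peak = acceptor_peak, acceptor_width = acceptor_width,
                 acceptor_eps_max = acceptor_eps_max,
                 grid_start = grid_start, grid_stop = grid_stop,
                 grid_step = grid_step),
            class = "spectra_spec")
}

#' Specification for a synthetic platelet wall track
#'
#' Parameterises [gen_track()]. Rolling tracks convert translation into
#' rotation (orientation increment per frame = `slip` x arc displacement /
#' radius, plus angular noise); sliding tracks translate with angular noise
#' only. The default translational speed of 0.8 um/s matches platelet motion
#' on the venous wall.
#'
#' @param kind `"rolling"` or `"sliding"`.
#' @param radius platelet radius (um); default 1.25 um, a typical platelet.
#' @param speed_profile `"constant"`, `"accelerating"` or `"decelerating"`.
#' @param slip rolling coupling in `[0, 1]`: 1 = no-slip rolling, 0 = the
#'   rolling contribution is fully removed.
#' @param speed_um_s mean translational speed (um/s).
#' @param noise_sd_pos per-frame centroid noise SD (um).
#' @param noise_sd_angle per-frame orientation noise SD (deg).
#' @param n_frames number of frames (>= 3).
#' @param dt frame interval (s).
#' @param seed default seed used by [gen_track()].
#' @return an object of class `track_spec`.
#' @export
track_spec <- function(kind = c("rolling", "sliding"),
                       radius = 1.25,
                       speed_profile = c("constant", "accelerating", "decelerating"),
                       slip = 1,
                       speed_um_s = 0.8,
                       noise_sd_pos = 0,
                       noise_sd_angle = 0,
                       n_frames = 61L,
                       dt = 1,
                       seed = 1L) {
  kind <- match.arg(kind)
  speed_profile <- match.arg(speed_profile)
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  check_number(slip, "slip", lower = 0, upper = 1)
  check_number(speed_um_s, "speed_um_s", lower = 0, strict_lower = TRUE)
  check_number(noise_sd_pos, "noise_sd_pos", lower = 0)
  check_number(noise_sd_angle, "noise_sd_angle", lower = 0)
  n_frames <- check_count(n_frames, "n_frames", lower = 3L)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  structure(list(kind = kind, radius = radius, speed_profile = speed_profile,
                 slip = slip, speed_um_s = speed_um_s,
                 noise_sd_pos = noise_sd_pos, noise_sd_angle = noise_sd_angle,
                 n_frames = n_frames, dt = dt,
                 seed = check_count(seed, "seed", lower = 0L)),
            class = "track_spec")
}

#' Specification for a synthetic extracorporeal-circuit run
#'
#' Parameterises [gen_pressure_series()]. Fibre occlusion grows logistically
#' from 0 toward `occlusion_max`; inlet pressure follows the parallel-conduit
#' resistance model `P(t) = baseline / (1 - o(t))` plus noise, and the paired
#' activated clotting time (ACT) series decays linearly from `act_baseline`.
#'
#' @param baseline_pressure inlet pressure at start (mmHg); default 50.
#' @param occlusion_growth logistic growth rate (per min); 0 means no clot.
#' @param occlusion_max asymptotic occluded fraction, in `[0, 1)`.
#' @param occlusion_midpoint logistic midpoint (min); default `duration / 2`.
#' @param duration run length (min).
#' @param sample_interval sampling interval (min).
#' @param act_baseline starting ACT (s).
#' @param act_decay ACT decline rate (s per min).
#' @param noise_sd pressure noise SD (mmHg).
#' @param seed default seed used by [gen_pressure_series()].
#' @return an object of class `device_spec`.
#' @export
device_spec <- function(baseline_pressure = 50,
                        occlusion_growth = 0.4,
                        occlusion_max = 0.6,
                        occlusion_midpoint = duration / 2,
                        duration = 45,
                        sample_interval = 1,
                        act_baseline = 140,
                        act_decay = 2.5,
                        noise_sd = 0,
                        seed = 1L) {
  check_number(baseline_pressure, "baseline_pressure", lower = 0, strict_lower = TRUE)
  check_number(occlusion_growth, "occlusion_growth", lower = 0)
  check_number(occlusion_max, "occlusion_max", lower = 0, upper = 1, strict_upper = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(sample_interval, "sample_interval", lower = 0, strict_lower = TRUE)
  check_number(act_baseline, "act_baseline", lower = 0, strict_lower = TRUE)
  check_number(act_decay, "act_decay", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(occlusion_midpoint, "occlusion_midpoint", lower = 0)
  structure(list(baseline_pressure = baseline_pressure,
                 occlusion_growth = occlusion_growth,
                 occlusion_max = occlusion_max,
                 occlusion_midpoint = occlusion_midpoint,
                 duration = duration, sample_interval = sample_interval,
                 act_baseline = act_baseline, act_decay = act_decay,
                 noise_sd = noise_sd,
                 seed = check_count(seed, "seed", lower = 0L)),
            class = "device_spec")
}

#' Specification for platelet spherification/recovery shape kinetics
#'
#' Parameterises [gen_shape_kinetics()]: a piecewise single-exponential
#' discoid-fraction time course. During drug exposure the fraction decays from
#' `initial_discoid_fraction` toward `plateau_fraction`; after the drug-removal
#' switch time it relaxes toward `recovery_plateau`. Defaults reproduce
#' colchicine spherification (90% -> ~10% within 30 min) and recovery to 65%
#' by 120 min.
#'
#' @param initial_discoid_fraction discoid fraction at t = 0.
#' @param plateau_fraction asymptote during drug exposure.
#' @param rate spherification rate (per min).
#' @param recovery_plateau asymptote after drug removal.
#' @param recovery_rate recovery rate (per min).
#' @param switch_times increasing phase boundaries (min): end of the
#'   spherification phase, then the drug-removal time that starts recovery.
#' @param t_max,dt time grid (min).
#' @param seed default seed (used by [sample_shape_labels()]).
#' @return an object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(initial_discoid_fraction = 0.90,
                          plateau_fraction = 0.10,
                          rate = 0.15,
                          recovery_plateau = 0.65,
                          recovery_rate = 0.08,
                          switch_times = c(30, 60),
                          t_max = 120,
                          dt = 1,
                          seed = 1L) {
  for (nm in c("initial_discoid_fraction", "plateau_fraction", "recovery_plateau"))
    check_number(get(nm), nm, lower = 0, upper = 1)
  check_number(rate, "rate", lower = 0)
  check_number(recovery_rate, "recovery_rate", lower = 0)
  if (!is.numeric(switch_times) || length(switch_times) < 1L ||
      any(diff(switch_times) <= 0) || any(switch_times < 0))
    stop_bad("`switch_times` must be a nonnegative strictly increasing vector")
  check_number(t_max, "t_max", lower = max(switch_times))
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  structure(list(initial_discoid_fraction = initial_discoid_fraction,
                 plateau_fraction = plateau_fraction, rate = rate,
                 recovery_plateau = recovery_plateau,
                 recovery_rate = recovery_rate,
                 switch_times = as.numeric(switch_times),
                 t_max = t_max, dt = dt,
                 seed = check_count(seed, "seed", lower = 0L)),
            class = "kinetics_spec")
}
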