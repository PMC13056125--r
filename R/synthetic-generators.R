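# Seeded generators for every input the analysis modules consume. All
# randomness is funnelled through with_seed(): same spec + same seed gives
# byte-identical output and the caller's RNG state is untouched.

# flat-topped raised-cosine bump of unit height, length top + 2*shoulder
.bump <- function(top, shoulder) {
  up <- if (shoulder > 0) (1 - cos(pi * seq_len(shoulder) / (shoulder + 1))) / 2
        else numeric(0)
  c(up, rep(1, top), rev(up))
}

#' Generate a synthetic AFM force-displacement curve
#'
#' Builds a curve with a flat noisy baseline (first 20% of samples), a linear
#' loading ramp descending to minus the rupture force (drawn from
#' `Normal(rupture_mean, rupture_sd)`), injected flat-topped pre-rupture peaks
#' on the middle of the ramp, a single-sample terminal jump back to ~0 and a
#' short post-rupture tail. Peak amplitude is `amplitude_sd_units x noise_sd`
#' (or `x peak_force_scale` when `noise_sd = 0`). Peak widths are tied to the
#' curve length so they survive the analysis module's moving-median detrend
#' yet span its smoothing window.
#'
#' The generative ground truth is attached as attributes: `rupture_true`
#' (pN), `peak_index` and `peak_amplitude_pN`.
#'
#' @param spec a [curve_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return a [force_curve()] with ground-truth attributes.
#' @export
gen_force_curve <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "curve_spec"))
  with_seed(seed, {
    n <- spec$n_points
    nb <- round(0.2 * n)
    nt <- max(16L, round(0.02 * n))
    ramp_idx <- seq.int(nb + 1L, n - nt)
    L <- length(ramp_idx)
    jump <- n - nt                       # last ramp sample = rupture point

    repeat {
      rupture <- stats::rnorm(1, spec$rupture_mean, spec$rupture_sd)
      if (rupture > 0) break
    }

    f <- numeric(n)
    f[ramp_idx] <- -rupture * seq_len(L) / L

    amps <- spec$peak_amplitudes_sd_units *
      if (spec$noise_sd > 0) spec$noise_sd else spec$peak_force_scale
    peak_index <- integer(0)
    if (length(amps)) {
      top <- max(3L, round(0.014 * L))
      sh <- max(2L, round(0.0045 * L))
      shape <- .bump(top, sh)
      centers <- ramp_idx[1L] - 1L +
        round(seq(0.35, 0.75, length.out = length(amps)) * L)
      for (i in seq_along(amps)) {
        pos <- centers[i] - (length(shape) %/% 2L) + seq_along(shape) - 1L
        keep <- pos >= ramp_idx[1L] & pos <= jump
        f[pos[keep]] <- f[pos[keep]] + amps[i] * shape[keep]
      }
      peak_index <- centers
    }

    f <- f + stats::rnorm(n, 0, spec$noise_sd)
    d <- seq(0, spec$displacement_span, length.out = n)
    curve <- force_curve(d, f, mode = spec$mode,
                         condition = paste0("Fgn_",
                                            if (spec$mode == "tangential") "T" else "N"),
                         baseline_window = seq_len(nb))
    attr(curve, "rupture_true") <- rupture
    attr(curve, "peak_index") <- peak_index
    attr(curve, "peak_amplitude_pN") <- amps
    curve
  })
}

#' Generate donor emission and acceptor excitation spectra
#'
#' Gaussian bands on the spec grid: the donor emission is area-normalised
#' (trapezoid area 1 on the grid), the acceptor extinction peaks at
#' `acceptor_eps_max`.
#'
#' @param spec a [spectra_spec()].
#' @return list with elements `donor` and `acceptor`, both [spectrum()]s.
#' @export
gen_spectra <- function(spec) {
  stopifnot(inherits(spec, "spectra_spec"))
  lam <- seq(spec$grid_start, spec$grid_stop, by = spec$grid_step)
  donor_raw <- exp(-(lam - spec$donor_peak)^2 / (2 * spec$donor_width^2))
  donor <- donor_raw / trapz_grid(lam, donor_raw)
  acc <- spec$acceptor_eps_max *
    exp(-(lam - spec$acceptor_peak)^2 / (2 * spec$acceptor_width^2))
  list(donor = spectrum(lam, donor, "donor"),
       acceptor = spectrum(lam, acc, "acceptor"))
}

#' Rescale acceptor extinction so the pair realises a target Forster radius
#'
#' Because `R0` scales as the sixth root of the overlap integral, and J is
#' linear in the acceptor extinction, the calibration is closed-form:
#' `eps_max_new = eps_max (R0_target / R0_current)^6`.
#'
#' @param spec a [spectra_spec()].
#' @param target_R0 desired Forster radius (nm), positive.
#' @param params a [fret_params()].
#' @return the calibrated `spectra_spec`.
#' @export
calibrate_spectra_to_R0 <- function(spec, target_R0, params = fret_params()) {
  stopifnot(inherits(spec, "spectra_spec"))
  check_number(target_R0, "target_R0", lower = 0, strict_lower = TRUE)
  sp <- gen_spectra(spec)
  j <- suppressWarnings(overlap_integral(sp$donor, sp$acceptor))
  if (j <= 0) stop_bad("bands do not overlap: Forster radius is uncalibratable")
  r0 <- forster_radius(j, params)
  spec$acceptor_eps_max <- spec$acceptor_eps_max * (target_R0 / r0)^6
  spec
}

#' Generate a synthetic platelet wall track
#'
#' Translation along +x with the spec's speed profile; for rolling tracks the
#' orientation increment per frame is `slip x (arc displacement / radius)`
#' plus angular noise, for sliding tracks angular noise only. Stored
#' orientation is wrapped to `[-180, 180)` degrees, as a tracker would report.
#' The true kind is attached as attribute `kind_true`.
#'
#' @param spec a [track_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return a [tracked_platelet()].
#' @export
gen_track <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "track_spec"))
  with_seed(seed, {
    n <- spec$n_frames
    u <- (seq_len(n - 1L) - 0.5) / (n - 1L)   # mid-step fraction of the run
    v <- switch(spec$speed_profile,
                constant = rep(spec$speed_um_s, n - 1L),
                accelerating = spec$speed_um_s * (0.5 + u),
                decelerating = spec$speed_um_s * (1.5 - u))
    ds <- v * spec$dt
    x <- c(0, cumsum(ds)) + stats::rnorm(n, 0, spec$noise_sd_pos)
    y <- stats::rnorm(n, 0, spec$noise_sd_pos)
    dtheta_deg <- if (spec$kind == "rolling")
      spec$slip * (ds / spec$radius) * 180 / pi else rep(0, n - 1L)
    theta <- c(0, cumsum(dtheta_deg)) + stats::rnorm(n, 0, spec$noise_sd_angle)
    track <- tracked_platelet(t = (seq_len(n) - 1L) * spec$dt, x = x, y = y,
                              orientation = ((theta + 180) %% 360) - 180,
                              radius = spec$radius,
                              group = if (spec$kind == "rolling") "spherical" else "discoid")
    attr(track, "kind_true") <- spec$kind
    track
  })
}

#' Generate two labelled cohorts of tracks with given rolling probabilities
#'
#' Each track in a group is independently rolling with that group's
#' probability, otherwise sliding; group assignment and true kinds are
#' recorded. Emulates the spherical-versus-discoid rolling-probability
#' comparison.
#'
#' @param p_roll_a,p_roll_b per-track rolling probability of each group.
#' @param n_per_group number of tracks per group (>= 1).
#' @param spec a [track_spec()] used as template for every track.
#' @param seed integer seed.
#' @return an object of class `platelet_cohort`: list with `tracks` (list of
#'   [tracked_platelet()]), `group` (factor `"a"`/`"b"`) and `kind_true`.
#' @export
gen_cohort <- function(p_roll_a, p_roll_b, n_per_group, spec = track_spec(),
                       seed = spec$seed) {
  check_number(p_roll_a, "p_roll_a", lower = 0, upper = 1)
  check_number(p_roll_b, "p_roll_b", lower = 0, upper = 1)
  n_per_group <- check_count(n_per_group, "n_per_group", lower = 1L)
  stopifnot(inherits(spec, "track_spec"))
  with_seed(seed, {
    rolling <- c(stats::rbinom(n_per_group, 1L, p_roll_a),
                 stats::rbinom(n_per_group, 1L, p_roll_b)) == 1L
    seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_group)
    tracks <- lapply(seq_along(rolling), function(i) {
      sp <- spec
      sp$kind <- if (rolling[i]) "rolling" else "sliding"
      gen_track(sp, seed = seeds[i])
    })
    structure(list(tracks = tracks,
                   group = factor(rep(c("a", "b"), each = n_per_group)),
                   kind_true = ifelse(rolling, "rolling", "sliding")),
              class = "platelet_cohort")
  })
}

#' Generate a device pressure/ACT time series
#'
#' Occlusion fraction grows logistically from 0 at t = 0 toward
#' `occlusion_max`; inlet pressure follows the identical-parallel-conduit
#' resistance model `P(t) = baseline / (1 - o(t))` plus Gaussian noise. The
#' paired ACT series decays linearly from `act_baseline` at `act_decay`
#' s/min (floored at 0). Zero `occlusion_growth` means no clot: pressure
#' stays at baseline.
#'
#' @param spec a [device_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return list of class `device_series` with `pressure`
#'   (a [pressure_series()]), `act` (data frame `t_min`, `act_s`) and
#'   `occlusion` (the true occluded-fraction series).
#' @export
gen_pressure_series <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "device_spec"))
  with_seed(seed, {
    t <- seq(0, spec$duration, by = spec$sample_interval)
    if (spec$occlusion_growth == 0) {
      o <- rep(0, length(t))
    } else {
      lgt <- function(tt) 1 / (1 + exp(-spec$occlusion_growth * (tt - spec$occlusion_midpoint)))
      l0 <- lgt(0)
      o <- spec$occlusion_max * (lgt(t) - l0) / (1 - l0)
    }
    p <- spec$baseline_pressure / (1 - o) + stats::rnorm(length(t), 0, spec$noise_sd)
    act <- pmax(0, spec$act_baseline - spec$act_decay * t)
    structure(list(pressure = pressure_series(t, p, baseline = spec$baseline_pressure),
                   act = data.frame(t_min = t, act_s = act),
                   occlusion = o),
              class = "device_series")
  })
}

#' Generate a discoid-fraction kinetics series
#'
#' Piecewise single-exponential shape kinetics: decay from
#' `initial_discoid_fraction` toward `plateau_fraction` at `rate` while the
#' drug is present, then relaxation toward `recovery_plateau` at
#' `recovery_rate` after the drug-removal switch (the last element of
#' `switch_times`). Phases are labelled `treatment`, `circulation`,
#' `recovery` from the switch times.
#'
#' @param spec a [kinetics_spec()].
#' @return a data frame of class `shape_series` with columns `t_min`,
#'   `discoid_fraction`, `phase`.
#' @export
gen_shape_kinetics <- function(spec) {
  stopifnot(inherits(spec, "kinetics_spec"))
  t <- seq(0, spec$t_max, by = spec$dt)
  t_remove <- spec$switch_times[length(spec$switch_times)]
  decay <- spec$plateau_fraction +
    (spec$initial_discoid_fraction - spec$plateau_fraction) * exp(-spec$rate * t)
  f_remove <- spec$plateau_fraction +
    (spec$initial_discoid_fraction - spec$plateau_fraction) * exp(-spec$rate * t_remove)
  recov <- spec$recovery_plateau +
    (f_remove - spec$recovery_plateau) * exp(-spec$recovery_rate * (t - t_remove))
  f <- ifelse(t < t_remove, decay, recov)
  bounds <- c(0, spec$switch_times, Inf)
  labels <- c("treatment", "circulation", "recovery")[seq_len(length(bounds) - 1L)]
  phase <- labels[findInterval(t, bounds, rightmost.closed = FALSE)]
  structure(data.frame(t_min = t, discoid_fraction = pmin(1, pmax(0, f)),
                       phase = phase),
            class = c("shape_series", "data.frame"))
}

#' Sample per-cell shape labels from a true fraction series
#'
#' Binomial sampling of `n_cells` per frame at the series' true discoid
#' fraction; feeds [discoid_fraction_series()].
#'
#' @param series a `shape_series` from [gen_shape_kinetics()].
#' @param n_cells cells observed per frame.
#' @param seed integer seed.
#' @return data frame with columns `t_min`, `label`
#'   (`"discoid"`/`"spherical"`) — one row per cell per frame, aggregated as
#'   counts via `n_discoid`/`n_total` columns for compactness.
#' @export
sample_shape_labels <- function(series, n_cells, seed = 1L) {
  stopifnot(inherits(series, "shape_series"))
  n_cells <- check_count(n_cells, "n_cells", lower = 1L)
  with_seed(seed, {
    k <- stats::rbinom(nrow(series), n_cells, series$discoid_fraction)
    data.frame(t_min = series$t_min, n_discoid = k, n_total = n_cells)
  })
}

#' Generate a synthetic FLIM apparent-efficiency map
#'
#' Grid of per-pixel apparent FRET efficiencies: each region mask gets its
#' specified mean efficiency plus Gaussian pixel noise (clamped to `[0, 1]`),
#' background pixels are NA.
#'
#' @param region_efficiencies list of `list(mask = <logical matrix>,
#'   efficiency = <value in [0, 1]>)`; masks must share dimensions and must
#'   not overlap.
#' @param noise_sd per-pixel efficiency noise SD.
#' @param seed integer seed.
#' @return list with `map` (numeric matrix) and `regions` (named list of
#'   masks, `region1`, `region2`, ...).
#' @export
gen_flim_map <- function(region_efficiencies, noise_sd = 0, seed = 1L) {
  if (!length(region_efficiencies)) stop_bad("no regions supplied")
  check_number(noise_sd, "noise_sd", lower = 0)
  dims <- dim(region_efficiencies[[1L]]$mask)
  cover <- matrix(0L, dims[1L], dims[2L])
  for (re in region_efficiencies) {
    if (!is.logical(re$mask) || !identical(dim(re$mask), dims))
      stop_bad("all masks must be logical matrices of identical dimensions")
    check_number(re$efficiency, "efficiency", lower = 0, upper = 1)
    cover <- cover + re$mask
  }
  if (any(cover > 1L)) stop_bad("region masks overlap")
  with_seed(seed, {
    map <- matrix(NA_real_, dims[1L], dims[2L])
    for (re in region_efficiencies) {
      k <- sum(re$mask)
      map[re$mask] <- pmin(1, pmax(0, re$efficiency + stats::rnorm(k, 0, noise_sd)))
    }
    regions <- lapply(region_efficiencies, `[[`, "mask")
    names(regions) <- paste0("region", seq_along(regions))
    list(map = map, regions = regions)
  })
}
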