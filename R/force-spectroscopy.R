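#' AFM force-displacement curve
#'
#' Container for one atomic force microscopy force-displacement record. The
#' force channel is the tangential friction force (contact mode, sliding) or
#' the normal force (tapping mode, rolling) depending on `mode`. Attractive
#' load is negative force; the terminal rupture is a jump back toward 0.
#'
#' @param displacement strictly increasing displacement grid (nm).
#' @param force force series (pN), same length as `displacement`.
#' @param mode loading mode, `"tangential"` or `"normal"`.
#' @param condition free condition label (e.g. `"Fgn_T"`, `"BSA_N"`).
#' @param baseline_window integer indices of the pre-contact baseline segment;
#'   must be non-empty and precede the loading ramp.
#' @return an object of class `force_curve`.
#' @export
force_curve <- function(displacement, force,
                        mode = c("tangential", "normal"),
                        condition = "unlabeled",
                        baseline_window = NULL) {
  mode <- match.arg(mode)
  n <- length(displacement)
  if (n < 64L) stop_bad("a force curve needs at least 64 samples")
  if (length(force) != n) stop_bad("`displacement` and `force` lengths differ")
  if (any(!is.finite(displacement)) || any(!is.finite(force)))
    stop_bad("non-finite values in curve")
  if (any(diff(displacement) <= 0))
    stop_bad("`displacement` must be strictly increasing")
  if (is.null(baseline_window)) baseline_window <- seq_len(max(16L, n %/% 5L))
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) == 0L || min(baseline_window) < 1L ||
      max(baseline_window) > n)
    stop_bad("`baseline_window` must be a non-empty index range inside the curve")
  structure(list(displacement = as.numeric(displacement),
                 force = as.numeric(force), mode = mode,
                 condition = as.character(condition),
                 baseline_window = baseline_window),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d samples, mode=%s, condition=%s\n",
              length(x$force), x$mode, x$condition))
  cat(sprintf("  displacement %.1f..%.1f nm, force %.1f..%.1f pN\n",
              min(x$displacement), max(x$displacement),
              min(x$force), max(x$force)))
  invisible(x)
}

#' Robust baseline noise model of a force curve
#'
#' Baseline level and noise SD from the pre-contact window: baseline is the
#' window median; the SD is the scale-normalised median absolute deviation
#' (1.4826 x MAD), robust to occasional drift. Errors if the window is shorter
#' than 16 samples or carries a trend large relative to its own noise (a sign
#' that it overlaps the loading ramp).
#'
#' @param curve a [force_curve()].
#' @param window optional index window overriding `curve$baseline_window`.
#' @return an object of class `noise_model` with fields `baseline` (pN),
#'   `sd` (pN) and `method`.
#' @export
estimate_noise <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  idx <- if (is.null(window)) curve$baseline_window else as.integer(window)
  if (length(idx) < 16L) stop_bad("baseline window shorter than 16 samples")
  if (min(idx) < 1L || max(idx) > length(curve$force))
    stop_bad("baseline window outside the curve")
  f <- curve$force[idx]
  fit <- stats::lm.fit(cbind(1, seq_along(f)), f)
  trend <- abs(fit$coefficients[2L]) * (length(f) - 1)
  resid_scale <- stats::mad(fit$residuals)
  if (trend > 10 * resid_scale + 1e-8 * max(1, max(abs(f))))
    stop_bad("baseline window overlaps the loading ramp (trend detected)")
  structure(list(baseline = stats::median(f), sd = stats::mad(f),
                 method = "median/MAD"),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> baseline %.3f pN, sd %.3f pN (%s)\n",
              x$baseline, x$sd, x$method))
  invisible(x)
}

# Short-window running medians used by the rupture detector: step height at i
# is median(force[i+1 .. i+m]) - median(force[i-m+1 .. i]).
.step_series <- function(f, m) {
  r <- stats::runmed(f, m, endrule = "median")
  h <- (m - 1L) %/% 2L
  n <- length(f)
  i <- seq.int(m, n - m)
  list(i = i, step = r[i + h + 1L] - r[i - h])
}

#' Detect the terminal rupture jump of a force curve
#'
#' Locates the largest single-step force increase back toward baseline (the
#' detachment jump) and measures the rupture magnitude. Step height is the
#' difference of short-window (9-sample) medians across each candidate point,
#' so the 5-SD jump criterion stays meaningful on long noisy curves; ties are
#' broken toward the latest index (the terminal detachment). The magnitude is
#' the baseline minus the median force over the window just before the jump,
#' which equals the generative rupture force exactly at zero noise and is
#' unbiased under additive noise.
#'
#' @param curve a [force_curve()].
#' @param noise a [estimate_noise()] model (computed from the curve if omitted).
#' @param step_window half-structure window (samples) for the robust step
#'   estimator; default 9.
#' @return an object of class `rupture_event` with fields `index`,
#'   `displacement_at` (nm), `magnitude` (pN) and `jump_span` (samples).
#'   Errors with condition class `spheromech_no_rupture` when no step exceeds
#'   5 x noise SD.
#' @export
detect_rupture <- function(curve, noise = estimate_noise(curve),
                           step_window = 9L) {
  stopifnot(inherits(curve, "force_curve"), inherits(noise, "noise_model"))
  m <- check_count(step_window, "step_window", lower = 3L)
  if (m %% 2L == 0L) m <- m + 1L
  f <- curve$force
  ss <- .step_series(f, m)
  thr <- 5 * noise$sd
  big <- max(ss$step)
  if (!(big > thr))
    stop(structure(class = c("spheromech_no_rupture", "error", "condition"),
                   list(message = "no rupture jump exceeds 5 x noise SD",
                        call = NULL)))
  j <- max(ss$i[ss$step == big])      # ties -> latest index
  # refine to the exact jump sample: largest single-sample increase within
  # one step window (the windowed-median step localises only to ~half a
  # window)
  lo <- max(1L, j - m); hi <- min(length(f) - 1L, j + m)
  dseg <- diff(f[lo:hi])
  j <- lo + max(which(dseg == max(dseg))) - 1L
  # rupture force: local linear fit over the samples just before the jump,
  # extrapolated to the jump point -- exact at zero noise, unbiased under
  # additive noise (a raw minimum or plain median would be slope-biased)
  fw <- min(25L, j)
  idx <- (j - fw + 1L):j
  fit <- stats::lm.fit(cbind(1, idx), f[idx])
  pre <- sum(fit$coefficients * c(1, j))
  magnitude <- noise$baseline - pre
  if (magnitude <= 0)
    stop(structure(class = c("spheromech_no_rupture", "error", "condition"),
                   list(message = "candidate jump is not a release toward baseline",
                        call = NULL)))
  post <- stats::median(f[(j + 1L):min(length(f), j + m)])
  span <- which(f[(j + 1L):min(length(f), j + m)] >= post - 3 * noise$sd)
  structure(list(index = j, displacement_at = curve$displacement[j],
                 magnitude = magnitude,
                 jump_span = if (length(span)) min(span) else 1L),
            class = "rupture_event")
}

#' @export
print.rupture_event <- function(x, ...) {
  cat(sprintf("<rupture_event> %.2f pN at %.1f nm (index %d)\n",
              x$magnitude, x$displacement_at, x$index))
  invisible(x)
}

#' Detect pre-rupture unfolding peaks on the loading ramp
#'
#' Detrends the loading ramp with a moving median (window = 5% of ramp
#' length, minimum 7 samples), smooths the residual with a moving average
#' (window = detrend window / 4) to suppress sample-level noise, and reports
#' local maxima of the smoothed residual before the rupture as pre-rupture
#' peaks. Because a peak inflates the moving median under itself (which would
#' bias its measured amplitude low), the baseline is re-estimated in a second
#' pass with the candidate peak regions masked and bridged by local linear
#' interpolation, and amplitudes are measured against that repaired baseline.
#' Each peak carries its amplitude in pN and in noise-SD units; a peak is
#' significant when its SD-unit amplitude strictly exceeds `threshold_sd`
#' (default 1.96, the two-sided 5% Gaussian point). Maxima closer than one
#' detrend window are merged (highest wins) and maxima below
#' `min_amplitude_sd` are not reported at all.
#'
#' @param curve a [force_curve()].
#' @param rupture a [detect_rupture()] event for the same curve.
#' @param noise a [estimate_noise()] model; its `sd` is the significance
#'   denominator.
#' @param threshold_sd significance threshold in noise-SD units (strict `>`).
#' @param min_amplitude_sd reporting floor in noise-SD units.
#' @return an object of class `prerupture_peaks`: a data frame with columns
#'   `index`, `displacement_at`, `amplitude_pN`, `amplitude_sd_units`,
#'   `significant`.
#' @export
detect_prerupture_peaks <- function(curve, rupture,
                                    noise = estimate_noise(curve),
                                    threshold_sd = 1.96,
                                    min_amplitude_sd = 0.5) {
  stopifnot(inherits(curve, "force_curve"), inherits(rupture, "rupture_event"),
            inherits(noise, "noise_model"))
  check_number(threshold_sd, "threshold_sd", lower = 0)
  a <- max(curve$baseline_window) + 1L
  b <- rupture$index
  L <- b - a + 1L
  k <- max(7L, round(0.05 * L))
  if (k %% 2L == 0L) k <- k + 1L
  if (L < k) stop_bad("loading ramp shorter than the detrend window")
  ramp <- curve$force[a:b]
  residual <- ramp - stats::runmed(ramp, k, endrule = "median")
  w <- max(3L, round(k / 4))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- as.numeric(stats::filter(residual, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- -Inf

  # candidate local maxima, excluding detrend-unreliable edges
  lo <- k + 1L
  hi <- L - k
  if (hi <= lo) return(.empty_peaks(threshold_sd))
  is_max <- logical(L)
  core <- seq.int(lo, hi)
  is_max[core] <- !is.na(sm[core]) &
    sm[core] > c(-Inf, sm)[core] & sm[core] >= sm[core + 1L]
  cand <- which(is_max)
  s <- noise$sd
  if (s > 0) {
    cand <- cand[sm[cand] / s > min_amplitude_sd]
  } else {
    cand <- cand[sm[cand] > 1e-6]
  }
  if (!length(cand)) return(.empty_peaks(threshold_sd))

  # merge maxima closer than one detrend window, keeping the highest
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) if (!length(kept) || all(abs(kept - i) > k)) kept <- c(kept, i)
  kept <- sort(kept)

  # second pass: re-measure each amplitude against a local linear baseline
  # fitted to the ramp around the candidate with all candidate regions
  # masked out (the pass-1 moving median under a peak is biased toward it)
  half <- k %/% 2L
  masked <- logical(L)
  for (i in kept) masked[max(1L, i - half):min(L, i + half)] <- TRUE
  amp <- numeric(length(kept))
  for (jj in seq_along(kept)) {
    i <- kept[jj]
    span <- max(1L, i - 2L * k):min(L, i + 2L * k)
    sel <- span[!masked[span]]
    fit <- stats::lm.fit(cbind(1, sel), ramp[sel])
    win_ext <- max(1L, i - half):min(L, i + half)
    res2 <- ramp[win_ext] - (fit$coefficients[1L] + fit$coefficients[2L] * win_ext)
    sm2 <- as.numeric(stats::filter(res2, rep(1 / w, w), sides = 2))
    sm2[is.na(sm2)] <- -Inf
    rel <- which(win_ext >= i - w %/% 2L & win_ext <= i + w %/% 2L)
    amp[jj] <- max(sm2[rel])
    kept[jj] <- win_ext[rel[which.max(sm2[rel])]]
  }
  sd_units <- if (s > 0) amp / s else ifelse(amp > 0, Inf, 0)
  # strict inequality with a numerical guard so an exactly-threshold peak
  # (up to float rounding of the smoothing sum) is non-significant
  out <- data.frame(index = a - 1L + kept,
                    displacement_at = curve$displacement[a - 1L + kept],
                    amplitude_pN = amp,
                    amplitude_sd_units = sd_units,
                    significant = sd_units - threshold_sd > 1e-9)
  structure(out, class = c("prerupture_peaks", "data.frame"),
            threshold_sd = threshold_sd)
}

.empty_peaks <- function(threshold_sd) {
  structure(data.frame(index = integer(0), displacement_at = numeric(0),
                       amplitude_pN = numeric(0),
                       amplitude_sd_units = numeric(0),
                       significant = logical(0)),
            class = c("prerupture_peaks", "data.frame"),
            threshold_sd = threshold_sd)
}

#' Classify a curve as unfolded or folded from its pre-rupture peaks
#'
#' A curve with at least one significant pre-rupture peak shows stepwise
#' inter-domain separation (`"unfolded"`); none means the integrin kept its
#' bent-closed state until detachment (`"folded"`).
#'
#' @param peaks a [detect_prerupture_peaks()] result.
#' @return `"unfolded"` or `"folded"`.
#' @export
classify_unfolding <- function(peaks) {
  stopifnot(inherits(peaks, "prerupture_peaks"))
  if (any(peaks$significant)) "unfolded" else "folded"
}

#' Summarise rupture forces for one condition
#'
#' @param events list of [detect_rupture()] events, or a numeric vector of
#'   rupture magnitudes (pN).
#' @param condition condition label.
#' @return an object of class `condition_summary` with `condition`, `n`,
#'   `mean_force`, `sd_force` (0 with an `n1` flag when `n = 1`) and the raw
#'   `magnitudes`.
#' @export
summarize_condition <- function(events, condition = "unlabeled") {
  mags <- if (is.numeric(events)) events
          else vapply(events, function(e) {
            stopifnot(inherits(e, "rupture_event")); e$magnitude
          }, numeric(1))
  if (!length(mags)) stop_bad("no rupture events to summarise")
  structure(list(condition = as.character(condition), n = length(mags),
                 mean_force = mean(mags),
                 sd_force = if (length(mags) > 1L) stats::sd(mags) else 0,
                 n1 = length(mags) == 1L, magnitudes = as.numeric(mags)),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %s: %.1f +/- %.1f pN (n = %d%s)\n",
              x$condition, x$mean_force, x$sd_force, x$n,
              if (x$n1) ", sd undefined" else ""))
  invisible(x)
}

#' Welch comparison of rupture forces between two conditions
#'
#' @param a,b [summarize_condition()] objects carrying their raw magnitudes
#'   (both `n >= 2`).
#' @return list with `difference` (mean a - mean b), `statistic` (Welch t),
#'   `df`, `p_value`.
#' @export
compare_conditions <- function(a, b) {
  stopifnot(inherits(a, "condition_summary"), inherits(b, "condition_summary"))
  if (a$n < 2L || b$n < 2L) stop_bad("both conditions need n >= 2")
  ht <- stats::t.test(a$magnitudes, b$magnitudes)
  list(difference = a$mean_force - b$mean_force,
       statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = ht$p.value)
}
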