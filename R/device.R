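#' Dialyzer inlet-pressure time series
#'
#' @param t increasing time stamps (min).
#' @param pressure inlet pressures (mmHg), positive.
#' @param baseline starting/reference pressure (mmHg); default 50.
#' @return an object of class `pressure_series`.
#' @export
pressure_series <- function(t, pressure, baseline = 50) {
  if (!length(t)) stop_bad("empty pressure series")
  if (length(pressure) != length(t)) stop_bad("`t`/`pressure` length mismatch")
  if (any(diff(t) <= 0)) stop_bad("`t` must be strictly increasing")
  if (any(pressure <= 0)) stop_bad("pressures must be positive")
  check_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  structure(list(t = as.numeric(t), pressure = as.numeric(pressure),
                 baseline = baseline),
            class = "pressure_series")
}

#' @export
print.pressure_series <- function(x, ...) {
  cat(sprintf("<pressure_series> %d samples over %g min, baseline %g mmHg, last %.1f mmHg\n",
              length(x$t), max(x$t), x$baseline, x$pressure[length(x$pressure)]))
  invisible(x)
}

#' Percent pressure rise over baseline
#'
#' @param baseline reference pressure (mmHg), positive.
#' @param current current pressure (mmHg).
#' @return rise in percent: `100 (current - baseline) / baseline`.
#' @export
percent_rise <- function(baseline, current) {
  check_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  100 * (current - baseline) / baseline
}

#' Clotting time from a pressure-rise termination rule
#'
#' First timestamp at which the pressure rise over the series baseline
#' strictly exceeds the rule threshold — `list(percent = 50)` for a relative
#' rule or `list(absolute = 25)` for an absolute one (the two coincide at a
#' 50 mmHg baseline). No interpolation between samples: the first sample
#' beyond the threshold defines the clotting time, matching discrete
#' sampling. A series that never crosses is censored.
#'
#' @param series a [pressure_series()].
#' @param rule `list(percent = <p>)` or `list(absolute = <mmHg>)`.
#' @return list with `clotting_time` (min, NA when censored) and `censored`.
#' @export
clotting_time <- function(series, rule = list(percent = 50)) {
  stopifnot(inherits(series, "pressure_series"))
  if (!is.list(rule) || length(rule) != 1L ||
      !(names(rule) %in% c("percent", "absolute")))
    stop_bad("`rule` must be list(percent = ...) or list(absolute = ...)")
  thr <- if (names(rule) == "percent")
    series$baseline * (1 + rule[[1L]] / 100) else series$baseline + rule[[1L]]
  hit <- which(series$pressure > thr)
  if (!length(hit)) return(list(clotting_time = NA_real_, censored = TRUE))
  list(clotting_time = series$t[hit[1L]], censored = FALSE)
}

#' Percent prolongation of the clotting time under treatment
#'
#' @param t_control control clotting time (min), positive.
#' @param t_treated treated clotting time (min).
#' @return `100 (t_treated - t_control) / t_control` (negative when
#'   shortened).
#' @export
prolongation_percent <- function(t_control, t_treated) {
  check_number(t_control, "t_control", lower = 0, strict_lower = TRUE)
  check_number(t_treated, "t_treated", lower = 0)
  100 * (t_treated - t_control) / t_control
}

#' Fraction of dialyzer fibers occluded by thrombus
#'
#' @param occluded_fibers occluded fiber count.
#' @param total_fibers total fiber count, positive.
#' @return fraction in `[0, 1]`.
#' @export
occlusion_ratio <- function(occluded_fibers, total_fibers) {
  occluded_fibers <- check_count(occluded_fibers, "occluded_fibers", lower = 0L)
  total_fibers <- check_count(total_fibers, "total_fibers", lower = 1L)
  if (occluded_fibers > total_fibers)
    stop_bad("occluded fibers exceed the total")
  occluded_fibers / total_fibers
}

#' Convert a mass concentration to molarity
#'
#' `nM = ng/mL x 1000 / (g/mol)`; e.g. the 6.19 ng/mL colchicine peak plasma
#' concentration is ~15.5 nM at 399.4 g/mol.
#'
#' @param conc_ng_per_mL mass concentration (ng/mL).
#' @param molar_mass molar mass (g/mol), positive.
#' @return molar concentration (nM).
#' @export
dose_to_molar <- function(conc_ng_per_mL, molar_mass) {
  check_number(conc_ng_per_mL, "conc_ng_per_mL", lower = 0)
  check_number(molar_mass, "molar_mass", lower = 0, strict_lower = TRUE)
  conc_ng_per_mL * 1000 / molar_mass
}

#' Summarise one extracorporeal circuit run
#'
#' Bundles the pressure-rule clotting time, the ACT change (last minus first
#' sample), the fiber occlusion ratio and the total thrombus mass (dialyzer
#' plus venous-canister capture when present).
#'
#' @param series a [pressure_series()].
#' @param act data frame with columns `t_min`, `act_s` (may be NULL).
#' @param occluded_fibers,total_fibers fiber counts for [occlusion_ratio()].
#' @param thrombus_mass_mg thrombus mass in the dialyzer (mg).
#' @param canister_mass_mg thrombus mass captured in the venous canister (mg).
#' @param rule termination rule passed to [clotting_time()].
#' @param label run label (e.g. `"D_24min"`).
#' @return an object of class `run_outcome`.
#' @export
summarize_run <- function(series, act = NULL,
                          occluded_fibers = 0L, total_fibers = 10000L,
                          thrombus_mass_mg = 0, canister_mass_mg = 0,
                          rule = list(percent = 50), label = "run") {
  ct <- clotting_time(series, rule)
  act_delta <- if (!is.null(act) && nrow(act) >= 2L)
    act$act_s[nrow(act)] - act$act_s[1L] else NA_real_
  check_number(thrombus_mass_mg, "thrombus_mass_mg", lower = 0)
  check_number(canister_mass_mg, "canister_mass_mg", lower = 0)
  structure(list(label = as.character(label),
                 clotting_time = ct$clotting_time, censored = ct$censored,
                 act_series = act, act_delta = act_delta,
                 occlusion_ratio = occlusion_ratio(occluded_fibers, total_fibers),
                 thrombus_mass = thrombus_mass_mg + canister_mass_mg),
            class = "run_outcome")
}

#' @export
print.run_outcome <- function(x, ...) {
  ctxt <- if (x$censored) "censored" else sprintf("%g min", x$clotting_time)
  cat(sprintf("<run_outcome> %s: clotting time %s, occlusion %.0f%%, thrombus %g mg\n",
              x$label, ctxt, 100 * x$occlusion_ratio, x$thrombus_mass))
  if (!is.na(x$act_delta)) cat(sprintf("  ACT change %+.0f s\n", x$act_delta))
  invisible(x)
}
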