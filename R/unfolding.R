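# Coarse-grained bond-graph surrogate of integrin alphaIIb-beta3 unfolding.
# Tangential load unfolds the beta-leg by breaking the Hybrid/I-EGF4 then
# Hybrid/I-EGF3 hydrogen bonds; normal load instead rotates the head
# (Calf-1/Calf-2 hinge), forms extra calf-contact hydrogen bonds and detaches
# from the ligand before the strengthened bond network can be dissociated.

.baseline_bonds <- function() {
  data.frame(pair = c("PRO381-ARG563", "SER367-SER551"),
             barrier_force = c(58, 60),          # pN, I4 then I3 separation
             stage = c("SeparationI4", "SeparationI3"),
             state = "intact", contact_formed = FALSE,
             stringsAsFactors = FALSE)
}

.contact_bonds <- function() {
  data.frame(pair = c("LYS549-LYS402", "LYS549-LYS402", "LYS549-SER369"),
             barrier_force = NA_real_,            # collective 140 pN network
             stage = "Dissociation",
             state = "latent", contact_formed = TRUE,
             stringsAsFactors = FALSE)
}

#' Build the default coarse-grained integrin domain graph
#'
#' Six domains (beta-head+Hybrid, I-EGF3, I-EGF4, Thigh, Calf-1, Calf-2), the
#' two baseline interdomain hydrogen bonds of the unfolding path
#' (PRO381-ARG563 at 58 pN for the Separation I4 stage, SER367-SER551 at
#' 60 pN for Separation I3), three latent calf-contact bonds
#' (LYS549-LYS402 x2 and LYS549-SER369) that form only after the Rotation
#' stage, and the two hinge angles: theta (Thigh/Calf-1) = 45 deg,
#' phi (Calf-1/Calf-2) = 140 deg.
#'
#' @return an object of class `domain_graph`.
#' @export
build_default_integrin <- function() {
  structure(list(domains = c("beta-head+Hybrid", "I-EGF3", "I-EGF4",
                             "Thigh", "Calf-1", "Calf-2"),
                 theta = 45, phi = 140,
                 bonds = rbind(.baseline_bonds(), .contact_bonds()),
                 calf_contact = FALSE,
                 network_threshold = 140),        # pN, five-bond dissociation
            class = "domain_graph")
}

#' @export
print.domain_graph <- function(x, ...) {
  nb <- sum(x$bonds$state == "intact")
  nl <- sum(x$bonds$state == "latent")
  cat(sprintf("<domain_graph> %d domains, theta=%g deg, phi=%g deg\n",
              length(x$domains), x$theta, x$phi))
  cat(sprintf("  %d intact bond(s), %d latent contact bond(s), calf contact: %s\n",
              nb, nl, x$calf_contact))
  invisible(x)
}

#' Loading protocol for the coarse-grained unfolding model
#'
#' @param direction `"tangential"` (sliding friction) or `"normal"`
#'   (rolling detachment).
#' @param mode `"constant_force"` or `"constant_velocity"`.
#' @param force applied force (pN) for constant-force mode.
#' @param speed pulling speed (um/s) for constant-velocity mode.
#' @param ligand_strength integrin-ligand dissociation force (pN);
#'   default 70, the alphaIIb-beta3/RGD bond strength.
#' @param stiffness effective loading stiffness converting speed to loading
#'   rate (pN per um); only relative rates matter.
#' @param max_steps step budget for constant-velocity ramps.
#' @return an object of class `loading_protocol`.
#' @export
loading_protocol <- function(direction = c("tangential", "normal"),
                             mode = c("constant_force", "constant_velocity"),
                             force = 70, speed = 0.8,
                             ligand_strength = 70,
                             stiffness = 10, max_steps = 10000L) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  check_number(force, "force", lower = 0)
  check_number(speed, "speed", lower = 0, strict_lower = TRUE)
  check_number(ligand_strength, "ligand_strength", lower = 0, strict_lower = TRUE)
  check_number(stiffness, "stiffness", lower = 0, strict_lower = TRUE)
  structure(list(direction = direction, mode = mode, force = force,
                 speed = speed, ligand_strength = ligand_strength,
                 stiffness = stiffness,
                 max_steps = check_count(max_steps, "max_steps", lower = 1L)),
            class = "loading_protocol")
}

# linear angle ramp helper for the stage series
.ramp_to <- function(from, to, k = 20L) seq(from, to, length.out = k)

#' Simulate loading of the domain graph and emit the stage trace
#'
#' Tangential constant force `F`: breaks the I4 bond iff `F >= 58` pN, then
#' the I3 bond iff `F >= 60` pN (Separation I4 always before Separation I3);
#' theta ramps 45 -> 75 deg across the two separations while phi is
#' unchanged. The ligand-detachment check is not applied tangentially:
#' sliding friction transmits force until unfolding. Normal constant force:
#' the head rotates (phi 140 -> 100 deg), calf contact forms the three extra
#' hydrogen bonds, and then the ligand detaches iff `ligand_strength` is
#' below the 140-pN five-bond network threshold — otherwise the network
#' dissociates iff `F > 140` pN. The final state is `extended` iff both
#' baseline bonds broke, else `bent`. Constant-velocity mode ramps the force
#' at `speed x stiffness` per unit time and applies the same thresholds as
#' the force crosses them.
#'
#' @param graph a [build_default_integrin()] domain graph.
#' @param protocol a [loading_protocol()].
#' @return an object of class `unfolding_trace`: ordered `events`,
#'   `theta_series`/`phi_series` (deg), `final_state`, `broken_bond_count`
#'   and the final `graph`.
#' @export
simulate_loading <- function(graph, protocol) {
  stopifnot(inherits(graph, "domain_graph"), inherits(protocol, "loading_protocol"))
  f_max <- if (protocol$mode == "constant_force") protocol$force else {
    rate <- protocol$speed * protocol$stiffness   # pN per unit time
    rate * protocol$max_steps * 0.01              # 0.01 time units per step
  }
  events <- character(0)
  theta_series <- graph$theta
  phi_series <- graph$phi

  if (protocol$direction == "tangential") {
    base <- graph$bonds$stage %in% c("SeparationI4", "SeparationI3")
    theta_mid <- (45 + 75) / 2
    if (f_max >= 58) {
      events <- c(events, "SeparationI4")
      graph$bonds$state[graph$bonds$stage == "SeparationI4"] <- "broken"
      theta_series <- c(theta_series, .ramp_to(45, theta_mid)[-1])
      graph$theta <- theta_mid
      if (f_max >= 60) {
        events <- c(events, "SeparationI3")
        graph$bonds$state[graph$bonds$stage == "SeparationI3"] <- "broken"
        theta_series <- c(theta_series, .ramp_to(theta_mid, 75)[-1])
        graph$theta <- 75
      }
    }
    phi_series <- rep(graph$phi, length(theta_series))
  } else {  # normal
    if (f_max > 0) {
      events <- c(events, "Rotation")
      phi_series <- c(phi_series, .ramp_to(140, 100)[-1])
      graph$phi <- 100
      graph$calf_contact <- TRUE
      graph$bonds$state[graph$bonds$state == "latent"] <- "intact"
      events <- c(events, "ContactBondsFormed")
      if (protocol$ligand_strength < graph$network_threshold) {
        events <- c(events, "LigandDetach")
      } else if (f_max > graph$network_threshold) {
        events <- c(events, "Dissociation")
        graph$bonds$state <- "broken"
      }
    }
    theta_series <- rep(graph$theta, length(phi_series))
  }

  baseline <- graph$bonds$stage %in% c("SeparationI4", "SeparationI3")
  broken <- sum(graph$bonds$state == "broken")
  final_state <- if (all(graph$bonds$state[baseline] == "broken")) "extended" else "bent"
  structure(list(events = events, theta_series = theta_series,
                 phi_series = phi_series, final_state = final_state,
                 broken_bond_count = broken, direction = protocol$direction,
                 graph = graph),
            class = "unfolding_trace")
}

#' @export
print.unfolding_trace <- function(x, ...) {
  cat(sprintf("<unfolding_trace> %s loading: %s\n", x$direction,
              paste(x$events, collapse = " -> ")))
  cat(sprintf("  final state %s, %d broken bond(s), theta %g deg, phi %g deg\n",
              x$final_state, x$broken_bond_count,
              tail(x$theta_series, 1), tail(x$phi_series, 1)))
  invisible(x)
}

#' Count hydrogen bonds on the unfolding path for a loading direction
#'
#' Tangential: the baseline interdomain bonds (2 in the default graph).
#' Normal: baseline bonds plus the calf-contact bonds that are active after
#' the Rotation stage (5 in the default graph, matching the five-bond
#' dissociation network).
#'
#' @param graph a `domain_graph`.
#' @param direction `"tangential"` or `"normal"`.
#' @return integer bond count.
#' @export
count_path_bonds <- function(graph, direction = c("tangential", "normal")) {
  stopifnot(inherits(graph, "domain_graph"))
  direction <- match.arg(direction)
  if (!nrow(graph$bonds)) stop_bad("empty bond graph")
  base <- graph$bonds$stage %in% c("SeparationI4", "SeparationI3") &
    graph$bonds$state != "broken"
  if (direction == "tangential") return(sum(base))
  sum(base) + sum(graph$bonds$contact_formed & graph$bonds$state != "broken")
}

#' Bell-model rescaling of an unbinding force to another loading rate
#'
#' `f = f_ref + (kB T / x_dagger) ln(rate / rate_ref)`, floored at 0; the
#' standard slip-bond loading-rate dependence that reconciles simulated
#' forces at ~10^6-fold higher loading rates with experimental values.
#' kB T is fixed to 4.114 pN nm at 298 K and scaled linearly in temperature.
#'
#' @param f_ref reference force (pN) at `rate_ref`.
#' @param rate_ref,rate loading rates (pN/s), positive; only their ratio
#'   matters.
#' @param x_dagger distance to the transition state (nm), positive.
#' @param temperature temperature (K).
#' @return rescaled force (pN).
#' @export
bell_force_scale <- function(f_ref, rate_ref, rate, x_dagger,
                             temperature = 298) {
  check_number(f_ref, "f_ref", lower = 0)
  check_number(rate_ref, "rate_ref", lower = 0, strict_lower = TRUE)
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  check_number(x_dagger, "x_dagger", lower = 0, strict_lower = TRUE)
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  kbt <- 4.114 * temperature / 298
  max(0, f_ref + (kbt / x_dagger) * log(rate / rate_ref))
}

#' Emit the synthetic force curve carrying a trace's unfolding signature
#'
#' Each Separation I4/I3 event in the trace becomes a pre-rupture peak on the
#' loading ramp (default amplitude 6 pN, the observed inter-domain separation
#' peak scale); the terminal ligand detachment or dissociation becomes the
#' rupture jump. Normal traces therefore yield curves with zero pre-rupture
#' peaks.
#'
#' @param trace an [simulate_loading()] `unfolding_trace` that reached a
#'   terminal event (`LigandDetach` or `Dissociation`).
#' @param curve_spec a [curve_spec()] template; its mode and peak list are
#'   overridden from the trace.
#' @param peak_amplitude_pN amplitude of each separation peak (pN).
#' @param seed integer seed.
#' @return a [force_curve()].
#' @export
emit_synthetic_curve <- function(trace, curve_spec = NULL,
                                 peak_amplitude_pN = 6, seed = 1L) {
  stopifnot(inherits(trace, "unfolding_trace"))
  # tangential scans always end in probe detachment; normal traces must have
  # reached their terminal event explicitly
  if (trace$direction == "normal" &&
      !any(trace$events %in% c("LigandDetach", "Dissociation")))
    stop_bad("trace is incomplete: no terminal detachment event")
  if (is.null(curve_spec))
    curve_spec <- spheromech::curve_spec(mode = trace$direction, noise_sd = 2,
                                         peak_amplitudes_sd_units = numeric(0))
  n_peaks <- sum(trace$events %in% c("SeparationI4", "SeparationI3"))
  unit <- if (curve_spec$noise_sd > 0) curve_spec$noise_sd else curve_spec$peak_force_scale
  curve_spec$mode <- trace$direction
  curve_spec$peak_amplitudes_sd_units <- rep(peak_amplitude_pN / unit, n_peaks)
  gen_force_curve(curve_spec, seed = seed)
}

#' Predicted activation signal from the tangential (sliding) motion fraction
#'
#' Linear map from the fraction of sliding motion to the activation-marker
#' fluorescence signal: 20% at pure rolling, 60% at pure sliding.
#'
#' @param fraction sliding fraction in `[0, 1]`.
#' @return predicted activation signal (percent).
#' @export
activation_vs_tangential_fraction <- function(fraction) {
  check_number(fraction, "fraction", lower = 0, upper = 1)
  20 + 40 * fraction
}
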