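# Experiment profiles: tether design, motor kinetics, initiation and noise
# models bundled into named, frozen parameter sets for the built-in
# study conditions.

#' Tether design for flap-loaded magnetic-tweezers substrates
#'
#' Describes a surface-anchored duplex insert carrying a poly-dT 5' flap
#' that acts as the motor loading site, and optionally a site-specific
#' nick in either strand.
#'
#' @param insert_length duplex insert length in bp.
#' @param loading_site_offset distance of the flap from the surface-anchored
#'   end, bp.
#' @param flap_length loading flap length in nt.
#' @param track_length bp available for translocation from the loading site
#'   toward the bead-proximal end.
#' @param nick `NULL`, or `list(strand = "top"|"bottom", position = bp)` with
#'   position measured downstream of the loading site.
#' @return An object of class `tether_design`.
#' @export
tether_design <- function(insert_length = 6600, loading_site_offset = 445,
                          flap_length = 37, track_length = 6155,
                          nick = NULL) {
  stopifnot(insert_length > 0, loading_site_offset > 0,
            loading_site_offset < insert_length,
            flap_length > 0, track_length > 0,
            track_length <= insert_length)
  if (!is.null(nick)) {
    stopifnot(is.list(nick), nick$strand %in% c("top", "bottom"),
              nick$position > 0, nick$position < track_length)
  }
  structure(list(insert_length = insert_length,
                 loading_site_offset = loading_site_offset,
                 flap_length = flap_length,
                 track_length = track_length,
                 nick = nick),
            class = "tether_design")
}

#' Convert a per-event occurrence fraction to a Poisson entry rate
#'
#' For a Poisson process with rate `lambda` observed over an exponentially
#' distributed exposure with mean `mean_duration`, the probability of at
#' least one occurrence per event is `p = 1 - 1/(1 + lambda * T)`, hence
#' `lambda = p / ((1 - p) * T)`. Used to translate per-event pause and
#' backslide percentages into the entry rates of the simulator.
#'
#' @param fraction per-event occurrence probability in [0, 1).
#' @param mean_duration mean exposure duration in s.
#' @return entry rate in 1/s.
#' @export
event_fraction_to_rate <- function(fraction, mean_duration) {
  stopifnot(fraction >= 0, fraction < 1, mean_duration > 0)
  fraction / ((1 - fraction) * mean_duration)
}

#' Motor kinetic parameters
#'
#' @param unwind_rate_mean mean per-event unwinding rate v, bp/s.
#' @param unwind_rate_cv between-event coefficient of variation of v.
#' @param rate_dist between-event rate law: `"normal"` (truncated at
#'   `min_rate`) or `"gamma"`.
#' @param detach_per_bp detachment probability per bp; event lengths are
#'   exponential with mean `1/detach_per_bp`.
#' @param pause_entry_rate Poisson pause entry rate during unwinding, 1/s.
#' @param pause_mean_duration mean pause duration, s.
#' @param rehyb_rate rehybridization speed, bp/s.
#' @param rehyb_pause_entry_rate pause entry rate during rehybridization, 1/s.
#' @param backslide_rate backslide entry rate during unwinding, 1/s.
#' @param backslide_complete_fraction probability a backslide retreats all
#'   the way to baseline.
#' @param backslide_restart_delay delay before unwinding resumes after a
#'   backslide, s.
#' @param min_rate lower truncation for per-event rate draws, bp/s. The
#'   default keeps every simulated event above the resolution limit of the
#'   3 Hz derivative analysis; events translocating below the velocity
#'   threshold of that analysis would be invisible to it (and to the
#'   measured rate distributions the defaults reproduce).
#' @return An object of class `motor_kinetics`.
#' @export
motor_kinetics <- function(unwind_rate_mean = 215, unwind_rate_cv = 0.5,
                           rate_dist = c("normal", "gamma"),
                           detach_per_bp = 1 / 900,
                           pause_entry_rate = 0, pause_mean_duration = 8,
                           rehyb_rate = 2000, rehyb_pause_entry_rate = 0,
                           backslide_rate = 0,
                           backslide_complete_fraction = 0.97,
                           backslide_restart_delay = 0.5,
                           min_rate = 50) {
  rate_dist <- match.arg(rate_dist)
  vals <- c(unwind_rate_mean, unwind_rate_cv, detach_per_bp,
            pause_entry_rate, pause_mean_duration, rehyb_rate,
            rehyb_pause_entry_rate, backslide_rate,
            backslide_restart_delay, min_rate)
  if (any(vals < 0)) stop("kinetic rates and durations must be >= 0")
  stopifnot(unwind_rate_mean > 0, detach_per_bp > 0, rehyb_rate > 0,
            backslide_complete_fraction >= 0,
            backslide_complete_fraction <= 1)
  structure(list(unwind_rate_mean = unwind_rate_mean,
                 unwind_rate_cv = unwind_rate_cv,
                 rate_dist = rate_dist,
                 detach_per_bp = detach_per_bp,
                 pause_entry_rate = pause_entry_rate,
                 pause_mean_duration = pause_mean_duration,
                 rehyb_rate = rehyb_rate,
                 rehyb_pause_entry_rate = rehyb_pause_entry_rate,
                 backslide_rate = backslide_rate,
                 backslide_complete_fraction = backslide_complete_fraction,
                 backslide_restart_delay = backslide_restart_delay,
                 min_rate = min_rate),
            class = "motor_kinetics")
}

#' Initiation model: bimolecular association from free solution
#'
#' Waiting times between the end of one event and the next initiation are
#' exponential with mean `1/(kon * protein_conc)`.
#'
#' @param kon second-order association rate constant, 1/(M s).
#' @param protein_conc protein concentration, M.
#' @return An object of class `initiation_model`.
#' @export
initiation_model <- function(kon = 5.9e5, protein_conc = 30e-9) {
  stopifnot(kon > 0, protein_conc >= 0)
  structure(list(kon = kon, protein_conc = protein_conc),
            class = "initiation_model")
}

#' Camera and bead noise model
#'
#' @param sampling_rate acquisition rate, Hz.
#' @param z_noise_sd bead-height noise SD per raw sample, nm.
#' @param drift_rate linear stage drift, nm/s.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sampling_rate = 60, z_noise_sd = 15, drift_rate = 0) {
  stopifnot(sampling_rate > 0, z_noise_sd >= 0)
  structure(list(sampling_rate = sampling_rate, z_noise_sd = z_noise_sd,
                 drift_rate = drift_rate),
            class = "noise_model")
}

#' Bundle of experimental conditions
#'
#' @param name profile name.
#' @param tether a [tether_design()].
#' @param kinetics a [motor_kinetics()].
#' @param initiation an [initiation_model()].
#' @param noise a [noise_model()].
#' @param force applied force, pN.
#' @param geometry `"looping"` (bead height decreases by the translocated
#'   distance regardless of force) or `"canonical"` (height change per bp
#'   follows the ssDNA-minus-dsDNA extension difference, changing sign at
#'   the ~6 pN crossover).
#' @param ssb `NULL`, or `list(rehyb_slowdown =, backslide_suppression =)`
#'   describing single-stranded-DNA-binding protein: rehybridization is
#'   slowed by `rehyb_slowdown` and the backslide entry rate multiplied by
#'   `backslide_suppression`.
#' @return An object of class `experiment_profile`.
#' @export
experiment_profile <- function(name, tether = tether_design(),
                               kinetics = motor_kinetics(),
                               initiation = initiation_model(),
                               noise = noise_model(), force = 8,
                               geometry = c("looping", "canonical"),
                               ssb = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(is.character(name), length(name) == 1L, force > 0,
            inherits(tether, "tether_design"),
            inherits(kinetics, "motor_kinetics"),
            inherits(initiation, "initiation_model"),
            inherits(noise, "noise_model"))
  if (!is.null(ssb))
    stopifnot(ssb$rehyb_slowdown >= 1,
              ssb$backslide_suppression >= 0, ssb$backslide_suppression <= 1)
  structure(list(name = name, tether = tether, kinetics = kinetics,
                 initiation = initiation, noise = noise, force = force,
                 geometry = geometry, ssb = ssb),
            class = "experiment_profile")
}

#' @export
print.experiment_profile <- function(x, ...) {
  cat("experiment_profile:", x$name, "\n")
  cat("  force:", x$force, "pN; geometry:", x$geometry, "\n")
  cat("  v =", x$kinetics$unwind_rate_mean, "bp/s (",
      x$kinetics$rate_dist, ", cv", x$kinetics$unwind_rate_cv, "); <L> =",
      round(1 / x$kinetics$detach_per_bp), "bp\n")
  cat("  [protein] =", x$initiation$protein_conc * 1e9, "nM; kon =",
      format(x$initiation$kon, digits = 4), "/M/s\n")
  if (!is.null(x$tether$nick))
    cat("  nick:", x$tether$nick$strand, "strand at",
        x$tether$nick$position, "bp\n")
  if (!is.null(x$ssb)) cat("  SSB present\n")
  invisible(x)
}

# Per-event occurrence fractions for pauses and backslides, by condition.
# Entry rates are derived with event_fraction_to_rate() over the mean
# unwinding duration <L>/v (pauses, backslides) or the mean rehybridization
# duration <L>/rehyb_rate (rehybridization pauses).
.profile_kinetics <- function(v, mean_L, p_pause_u, p_pause_r, p_back,
                              f_complete, rate_dist = "normal",
                              rehyb_rate = 2000) {
  t_unwind <- mean_L / v
  t_rehyb <- mean_L / rehyb_rate
  motor_kinetics(
    unwind_rate_mean = v, unwind_rate_cv = 0.5, rate_dist = rate_dist,
    detach_per_bp = 1 / mean_L,
    pause_entry_rate = event_fraction_to_rate(p_pause_u, t_unwind),
    pause_mean_duration = 8,
    rehyb_rate = rehyb_rate,
    rehyb_pause_entry_rate = event_fraction_to_rate(p_pause_r, t_rehyb),
    backslide_rate = event_fraction_to_rate(p_back, t_unwind),
    backslide_complete_fraction = f_complete)
}

#' Built-in experiment profiles
#'
#' Frozen parameter bundles for the study conditions:
#' \describe{
#'   \item{LOW30}{30 nM motor, v = 215 bp/s, mean event length 900 bp,
#'     mean inter-event dwell 61 s; pauses in 5\% of unwinding and 22\% of
#'     rehybridization events; backslides in 24\% of events (97\% complete).}
#'   \item{MED50}{50 nM; pauses 10\%/41\%, backslides 21\% (52\% complete).}
#'   \item{HIGH163}{163 nM, v = 159 bp/s (gamma-distributed between events),
#'     mean length 1181 bp, mean dwell 11.6 s; pauses 21\%/37\%, backslides
#'     27\% (58\% complete).}
#'   \item{NICKTOP}{LOW30 kinetics on a substrate nicked in the translocated
#'     (top) strand at 2800 bp: translocation arrests at the nick.}
#'   \item{NICKBOT}{LOW30 kinetics, mean length 870 bp, nick in the
#'     non-translocated (bottom) strand: transparent to the motor.}
#'   \item{SSB}{LOW30 plus single-stranded-DNA-binding protein:
#'     rehybridization slowed 10-fold and backslides suppressed to ~7\% of
#'     events.}
#'   \item{CANONICAL}{LOW30 kinetics under the canonical (non-looping)
#'     unwinding geometry sign convention.}
#' }
#'
#' Initiation: the LOW30 and HIGH163 dwell means (61 s, 11.6 s) are encoded
#' as effective association constants `kon = 1/(dwell * conc)`; MED50 uses
#' kon = 5.9e5 /M/s.
#'
#' @param name one of `"LOW30"`, `"MED50"`, `"HIGH163"`, `"NICKTOP"`,
#'   `"NICKBOT"`, `"SSB"`, `"CANONICAL"`.
#' @return An [experiment_profile()].
#' @examples
#' build_profile("LOW30")
#' @export
build_profile <- function(name) {
  valid <- c("LOW30", "MED50", "HIGH163", "NICKTOP", "NICKBOT", "SSB",
             "CANONICAL")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown profile '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  low_kin <- .profile_kinetics(v = 215, mean_L = 900, p_pause_u = 0.05,
                               p_pause_r = 0.22, p_back = 0.24,
                               f_complete = 0.97)
  switch(name,
    LOW30 = experiment_profile(
      name = "LOW30", kinetics = low_kin,
      initiation = initiation_model(kon = 1 / (61 * 30e-9),
                                    protein_conc = 30e-9)),
    MED50 = experiment_profile(
      name = "MED50",
      kinetics = .profile_kinetics(v = 190, mean_L = 1000, p_pause_u = 0.10,
                                   p_pause_r = 0.41, p_back = 0.21,
                                   f_complete = 0.52),
      initiation = initiation_model(kon = 5.9e5, protein_conc = 50e-9)),
    HIGH163 = experiment_profile(
      name = "HIGH163",
      kinetics = .profile_kinetics(v = 159, mean_L = 1181, p_pause_u = 0.21,
                                   p_pause_r = 0.37, p_back = 0.27,
                                   f_complete = 0.58, rate_dist = "gamma"),
      initiation = initiation_model(kon = 1 / (11.6 * 163e-9),
                                    protein_conc = 163e-9)),
    NICKTOP = experiment_profile(
      name = "NICKTOP", kinetics = low_kin,
      tether = tether_design(nick = list(strand = "top", position = 600)),
      initiation = initiation_model(kon = 1 / (61 * 30e-9),
                                    protein_conc = 30e-9)),
    NICKBOT = experiment_profile(
      name = "NICKBOT",
      kinetics = .profile_kinetics(v = 215, mean_L = 870, p_pause_u = 0.05,
                                   p_pause_r = 0.22, p_back = 0.24,
                                   f_complete = 0.97),
      tether = tether_design(nick = list(strand = "bottom", position = 600)),
      initiation = initiation_model(kon = 1 / (61 * 30e-9),
                                    protein_conc = 30e-9)),
    SSB = experiment_profile(
      name = "SSB", kinetics = low_kin,
      initiation = initiation_model(kon = 1 / (61 * 30e-9),
                                    protein_conc = 30e-9),
      ssb = list(rehyb_slowdown = 10, backslide_suppression = 0.25)),
    CANONICAL = experiment_profile(
      name = "CANONICAL", kinetics = low_kin,
      initiation = initiation_model(kon = 1 / (61 * 30e-9),
                                    protein_conc = 30e-9),
      geometry = "canonical"))
}

#' SD of the Gaussian jitter on arrest positions at a top-strand nick, bp
#' @noRd
.arrest_jitter_sd <- 100
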