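# Stochastic state-machine simulator of a loop-extruding DNA motor observed
# as bead height versus time. Event times are generated exactly
# (Gillespie-style competing exponential clocks) as a piecewise-linear
# position path, then sampled onto the camera grid.

# Draw one per-event unwinding rate.
.draw_rate <- function(k) {
  if (k$rate_dist == "gamma") {
    shape <- 1 / k$unwind_rate_cv^2
    r <- stats::rgamma(1, shape = shape,
                       scale = k$unwind_rate_mean * k$unwind_rate_cv^2)
    return(max(r, k$min_rate))
  }
  repeat {
    r <- stats::rnorm(1, k$unwind_rate_mean,
                      k$unwind_rate_cv * k$unwind_rate_mean)
    if (r >= k$min_rate) return(r)
  }
}

# Accumulator for path breakpoints and ground-truth rows.
.new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$t <- 0; env$pos <- 0
  env$ts <- c(0); env$ps <- c(0)
  env$truth <- list()
  env
}
.log_move <- function(log, dt, new_pos) {
  log$t <- log$t + dt
  log$pos <- new_pos
  log$ts <- c(log$ts, log$t); log$ps <- c(log$ps, new_pos)
}
.log_truth <- function(log, type, t0, t1, bp0, bp1, complete = NA,
                       rate = NA_real_) {
  log$truth[[length(log$truth) + 1L]] <-
    data.frame(event_type = type, t_start = t0, t_end = t1,
               bp_start = bp0, bp_end = bp1, complete = complete,
               rate_bp_s = rate)
}

# One unwinding event from initiation to detachment; returns invisibly,
# mutating the log. Pause and backslide clocks run only while the motor is
# on fresh (first-passage) track: re-unwinding of a stretch already melted
# and re-annealed behind a backslide proceeds without new entries, which
# keeps the per-event occurrence statistics at their calibrated values and
# bounds the event duration even for slow rate draws.
.simulate_unwinding <- function(log, k, L_total, v, bs_rate, rehyb_rate) {
  t0 <- log$t
  pos <- 0
  fresh_max <- 0
  repeat {
    if (pos < fresh_max) {
      # re-climb previously traversed track, clocks suspended
      .log_move(log, (fresh_max - pos) / v, fresh_max)
      pos <- fresh_max
    }
    t_finish <- (L_total - pos) / v
    t_pause <- if (k$pause_entry_rate > 0)
      stats::rexp(1, k$pause_entry_rate) else Inf
    t_back <- if (bs_rate > 0) stats::rexp(1, bs_rate) else Inf
    if (t_finish <= t_pause && t_finish <= t_back) {
      .log_move(log, t_finish, L_total)
      break
    }
    if (t_pause <= t_back) {
      .log_move(log, t_pause, pos + v * t_pause)
      pos <- pos + v * t_pause
      dur <- stats::rexp(1, 1 / k$pause_mean_duration)
      .log_truth(log, "pause", log$t, log$t + dur, pos, pos)
      .log_move(log, dur, pos)
    } else {
      .log_move(log, t_back, pos + v * t_back)
      pos <- pos + v * t_back
      fresh_max <- max(fresh_max, pos)   # top reached before the retreat
      complete <- stats::runif(1) < k$backslide_complete_fraction
      depth <- if (complete) pos else stats::runif(1, 0.1, 0.9) * pos
      tb0 <- log$t
      .log_move(log, depth / rehyb_rate, pos - depth)
      .log_truth(log, "backslide", tb0, log$t, pos, pos - depth, complete)
      pos <- pos - depth
      .log_move(log, k$backslide_restart_delay, pos)
    }
    fresh_max <- max(fresh_max, pos)
  }
  .log_truth(log, "unwinding", t0, log$t, 0, L_total, rate = v)
  invisible(log)
}

# Rehybridization from `from_bp` back to baseline, with optional pauses.
.simulate_rehyb <- function(log, k, from_bp, rehyb_rate) {
  t0 <- log$t
  pos <- from_bp
  repeat {
    t_finish <- pos / rehyb_rate
    t_pause <- if (k$rehyb_pause_entry_rate > 0)
      stats::rexp(1, k$rehyb_pause_entry_rate) else Inf
    if (t_finish <= t_pause) {
      .log_move(log, t_finish, 0)
      break
    }
    .log_move(log, t_pause, pos - rehyb_rate * t_pause)
    pos <- pos - rehyb_rate * t_pause
    dur <- stats::rexp(1, 1 / k$pause_mean_duration)
    .log_truth(log, "pause", log$t, log$t + dur, pos, pos)
    .log_move(log, dur, pos)
  }
  .log_truth(log, "rehybridization", t0, log$t, from_bp, 0)
  invisible(log)
}

#' Simulate a bead-height trace
#'
#' Runs the continuous-time state machine (waiting -> unwinding with
#' pauses/backslides -> rehybridization -> waiting) for one tether and
#' samples the resulting piecewise-linear motor position onto the camera
#' grid. In the looping geometry the bead height decreases by the
#' translocated distance times the duplex rise per bp at the applied force;
#' the canonical geometry instead applies the ssDNA-minus-dsDNA extension
#' difference per bp, which changes sign at the ~6 pN crossover. A nick in
#' the top (translocated) strand arrests each event at the nick position
#' with Gaussian jitter; a bottom-strand nick is transparent and never
#' releases the tether.
#'
#' @param profile an [experiment_profile()] or a profile name accepted by
#'   [build_profile()].
#' @param duration trace duration in s.
#' @param seed integer seed; identical `(profile, duration, seed)` give
#'   byte-identical traces.
#' @return An object of class `mt_trace`: `times` (s), `z` (nm), `force`,
#'   `profile`, `sampling_rate`, `seed`, `baseline_z`, and `truth`, a
#'   data frame of ground-truth events (`event_type`, `t_start`, `t_end`,
#'   `bp_start`, `bp_end`, `complete`).
#' @export
simulate_trace <- function(profile, duration, seed = 1L) {
  if (is.character(profile)) profile <- build_profile(profile)
  stopifnot(inherits(profile, "experiment_profile"))
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  set.seed(as.integer(seed))

  k <- profile$kinetics
  te <- profile$tether
  ns <- profile$noise
  el <- duplex_elasticity()
  rise <- duplex_rise_per_bp(profile$force, el)
  dz_per_bp <- if (profile$geometry == "looping") -rise else
    ssdna_extension_per_nt(profile$force) - rise
  baseline_z <- te$insert_length * rise

  rehyb_rate <- k$rehyb_rate
  bs_rate <- k$backslide_rate
  if (!is.null(profile$ssb)) {
    rehyb_rate <- rehyb_rate / profile$ssb$rehyb_slowdown
    bs_rate <- bs_rate * profile$ssb$backslide_suppression
  }
  init_rate <- profile$initiation$kon * profile$initiation$protein_conc
  nick_top <- !is.null(te$nick) && te$nick$strand == "top"

  log <- .new_log()
  clipped <- FALSE
  while (log$t < duration && init_rate > 0) {
    wait <- stats::rexp(1, init_rate)
    .log_move(log, wait, 0)
    if (log$t >= duration) break
    .log_truth(log, "initiation", log$t, log$t, 0, 0)
    v <- .draw_rate(k)
    L_total <- stats::rexp(1, k$detach_per_bp)
    arrested <- FALSE
    if (nick_top) {
      arrest_pos <- stats::rnorm(1, te$nick$position, .arrest_jitter_sd)
      arrest_pos <- min(max(arrest_pos, te$nick$position - 3 * .arrest_jitter_sd, 1),
                        te$nick$position + 3 * .arrest_jitter_sd,
                        te$track_length)
      if (L_total > arrest_pos) {
        L_total <- arrest_pos
        arrested <- TRUE
      }
    }
    if (L_total > te$track_length) {
      L_total <- te$track_length
      clipped <- TRUE
    }
    .simulate_unwinding(log, k, L_total, v, bs_rate, rehyb_rate)
    if (arrested) {
      # stall at the nick before releasing the track
      stall <- stats::rexp(1, 1 / 3)
      .log_move(log, stall, L_total)
    }
    .simulate_rehyb(log, k, L_total, rehyb_rate)
  }
  if (clipped)
    warning("event position(s) exceeding track_length were clipped")

  n <- floor(duration * ns$sampling_rate)
  times <- (seq_len(n) - 1L) / ns$sampling_rate
  pos_t <- if (length(log$ts) >= 2)
    stats::approx(log$ts, log$ps, xout = times, rule = 2)$y
  else rep(0, n)
  z <- baseline_z + dz_per_bp * pos_t + ns$drift_rate * times +
    stats::rnorm(n, 0, ns$z_noise_sd)

  truth <- if (length(log$truth)) do.call(rbind, log$truth) else
    data.frame(event_type = character(), t_start = numeric(),
               t_end = numeric(), bp_start = numeric(), bp_end = numeric(),
               complete = logical())
  truth <- truth[truth$t_start < duration, , drop = FALSE]
  truth$t_end <- pmin(truth$t_end, duration)
  rownames(truth) <- NULL

  structure(list(times = times, z = z, force = profile$force,
                 profile = profile$name, sampling_rate = ns$sampling_rate,
                 seed = as.integer(seed), baseline_z = baseline_z,
                 geometry = profile$geometry, truth = truth),
            class = "mt_trace")
}

#' @export
print.mt_trace <- function(x, ...) {
  cat("mt_trace:", x$profile, "|", length(x$z), "samples @",
      x$sampling_rate, "Hz (", round(max(x$times), 1), "s ) |",
      x$force, "pN | seed", x$seed, "\n")
  nev <- sum(x$truth$event_type == "unwinding")
  cat("  ground truth:", nev, "unwinding events\n")
  invisible(x)
}

#' Draw unwinding event lengths directly from the kinetic model
#'
#' Event lengths implied by the state machine: exponential with mean
#' `1/detach_per_bp`, truncated at the (jittered) nick position when a
#' top-strand nick is present.
#'
#' @param k a [motor_kinetics()].
#' @param n number of draws (>= 1).
#' @param seed integer seed.
#' @param nick optional nick description as in [tether_design()].
#' @return numeric vector of lengths in bp.
#' @export
simulate_event_lengths <- function(k, n, seed = 1L, nick = NULL) {
  stopifnot(inherits(k, "motor_kinetics"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  set.seed(as.integer(seed))
  L <- stats::rexp(n, k$detach_per_bp)
  if (!is.null(nick) && nick$strand == "top") {
    arrest <- stats::rnorm(n, nick$position, .arrest_jitter_sd)
    arrest <- pmin(pmax(arrest, nick$position - 3 * .arrest_jitter_sd, 1),
                   nick$position + 3 * .arrest_jitter_sd)
    L <- pmin(L, arrest)
  }
  L
}
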