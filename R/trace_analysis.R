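# Trace processing: boxcar filtering, bead-height to base-pair conversion,
# derivative-threshold event segmentation, pause/backslide classification
# and dwell-time extraction.

#' Segmentation thresholds
#'
#' Defaults are matched to a 3 Hz analysis bandwidth with ~10 bp effective
#' position noise; on flat traces they bound false events well below one
#' per hour (see the package vignette for the detection analysis behind
#' `t_min` and `min_event_length`).
#'
#' @param v_min velocity threshold separating movement from rest, bp/s.
#' @param v_pause velocity magnitude below which a within-event sample
#'   counts as paused, bp/s.
#' @param t_min minimum duration of the initial moving run that opens an
#'   event, s.
#' @param t_pause minimum duration of a stationary sub-run to count as a
#'   pause, s.
#' @param min_event_length minimum net event length, bp.
#' @param baseline_tol position tolerance for "returned to baseline", bp.
#' @param backslide_window renewed unwinding within this time of a
#'   rehybridization attaches it to the parent event as a backslide, s.
#' @param min_backslide_depth minimum retreat depth for a backslide, bp;
#'   guards against single-sample velocity excursions inside long pauses.
#' @return An object of class `segment_config`.
#' @export
segment_config <- function(v_min = 30, v_pause = 30, t_min = 0.5,
                           t_pause = 1, min_event_length = 50,
                           baseline_tol = 50, backslide_window = 1.5,
                           min_backslide_depth = 50) {
  stopifnot(v_min > 0, v_pause > 0, t_min > 0, t_pause > 0,
            min_event_length > 0, baseline_tol > 0, backslide_window > 0,
            min_backslide_depth >= 0)
  structure(list(v_min = v_min, v_pause = v_pause, t_min = t_min,
                 t_pause = t_pause, min_event_length = min_event_length,
                 baseline_tol = baseline_tol,
                 backslide_window = backslide_window,
                 min_backslide_depth = min_backslide_depth),
            class = "segment_config")
}

#' Downsample a raw trace by boxcar averaging
#'
#' Non-overlapping boxcar means over windows of
#' `sampling_rate / target_rate` raw samples, the standard reduction of
#' 60 Hz magnetic-tweezers data to a 3 Hz analysis bandwidth. A final
#' partial window is dropped with a message.
#'
#' @param raw an `mt_trace` from [simulate_trace()] / [read_trace()].
#' @param target_rate output rate in Hz; must be below the raw rate.
#' @return An object of class `processed_trace` with fields `times`,
#'   `value` (nm), `unit`, `rate`, `window`, `method`, `force`.
#' @export
downsample_filter <- function(raw, target_rate = 3) {
  stopifnot(inherits(raw, "mt_trace"))
  if (target_rate >= raw$sampling_rate)
    stop("target_rate must be below the raw sampling rate")
  window <- raw$sampling_rate / target_rate
  if (window != round(window)) {
    window <- floor(window)
    message("non-divisible rates: using window of ", window, " samples (",
            signif(raw$sampling_rate / window, 4), " Hz effective)")
  }
  window <- as.integer(window)
  n_out <- floor(length(raw$z) / window)
  if (n_out * window < length(raw$z))
    message("dropping final partial window of ",
            length(raw$z) - n_out * window, " samples")
  keep <- seq_len(n_out * window)
  value <- colMeans(matrix(raw$z[keep], nrow = window))
  times <- colMeans(matrix(raw$times[keep], nrow = window))
  structure(list(times = times, value = value, unit = "nm",
                 rate = raw$sampling_rate / window, window = window,
                 method = "boxcar", force = raw$force,
                 profile = raw$profile),
            class = "processed_trace")
}

#' @export
print.processed_trace <- function(x, ...) {
  cat("processed_trace:", length(x$value), "samples @", signif(x$rate, 4),
      "Hz [", x$unit, "] (", x$method, ", window", x$window, ")\n")
  invisible(x)
}

#' Convert bead height to motor position in base pairs
#'
#' The baseline (no-event) height is estimated as the mode of the series
#' (histogram with bins equivalent to 25 bp), robust to traces that start
#' mid-event. In the looping geometry forward motion shortens the tether by
#' the duplex rise per bp at the applied force, so position is
#' `(baseline - z) / rise`; the canonical geometry divides by the
#' ssDNA-minus-dsDNA extension difference per bp instead, making forward
#' motion positive in both force regimes.
#'
#' @param p a `processed_trace` in nm.
#' @param force applied force, pN (> 0); defaults to the trace's force.
#' @param e a [duplex_elasticity()].
#' @param geometry `"looping"` or `"canonical"`.
#' @param ss an [ssdna_elasticity()] (canonical geometry only).
#' @return the trace with `value` replaced by position in bp (`unit` "bp")
#'   and fields `conversion_nm_per_bp` and `baseline_nm` added.
#' @export
z_to_bp <- function(p, force = p$force, e = duplex_elasticity(),
                    geometry = c("looping", "canonical"),
                    ss = ssdna_elasticity()) {
  stopifnot(inherits(p, "processed_trace"), identical(p$unit, "nm"))
  geometry <- match.arg(geometry)
  if (!is.numeric(force) || force <= 0) stop("force must be > 0")
  rise <- duplex_rise_per_bp(force, e)
  conv <- if (geometry == "looping") -rise else
    ssdna_extension_per_nt(force, ss, thermal_context(e$temperature)) - rise
  if (abs(conv) < 1e-6)
    stop("degenerate nm-per-bp conversion at ", force,
         " pN (ss/ds crossover); cannot convert")
  # baseline: mode of the height histogram, bins equivalent to 25 bp
  binw <- 25 * abs(conv)
  breaks <- seq(min(p$value) - binw, max(p$value) + binw, by = binw)
  h <- graphics::hist(p$value, breaks = breaks, plot = FALSE)
  top <- which.max(h$counts)
  in_bin <- p$value >= h$breaks[top] & p$value <= h$breaks[top + 1L]
  baseline <- mean(p$value[in_bin])
  out <- p
  out$value <- (p$value - baseline) / conv
  out$unit <- "bp"
  out$force <- force
  out$geometry <- geometry
  out$conversion_nm_per_bp <- conv
  out$baseline_nm <- baseline
  out
}

# Run-length encode velocity labels (U: forward, R: backward, S: still)
# into a data frame of runs with sample indices, times and positions.
.velocity_runs <- function(pos, times, rate, cfg) {
  n <- length(pos)
  v <- rep(NA_real_, n)
  if (n >= 3)
    v[2:(n - 1)] <- (pos[3:n] - pos[1:(n - 2)]) * rate / 2
  lab <- rep("S", n)
  lab[!is.na(v) & v > cfg$v_min] <- "U"
  lab[!is.na(v) & v < -cfg$v_min] <- "R"
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(label = r$values, i0 = starts, i1 = ends,
                    t0 = times[starts], t1 = times[ends],
                    p0 = pos[starts], p1 = pos[ends],
                    dur = (ends - starts + 1L) / rate)
  attr(out, "velocity") <- v
  out
}

# A forward run counts as genuine motion (able to open, extend or resume an
# event) when it lasts at least t_min and its net displacement is
# consistent with sustained movement above v_min; this keeps single-sample
# noise excursions during dwells from opening or chaining events.
.is_motion_run <- function(runs, k, cfg, floor_mult = 1) {
  runs$label[k] == "U" && runs$dur[k] >= cfg$t_min &&
    (runs$p1[k] - runs$p0[k]) >=
      pmax(cfg$v_min * runs$dur[k], floor_mult * cfg$min_backslide_depth)
}

# A stationary run counts as a pause when it lasts at least t_pause and its
# net velocity is well below the stillness threshold; slow events whose
# velocity flickers around v_min produce sub-threshold runs with net
# velocity just under v_pause, which this rejects.
.is_pause_run <- function(runs, m, cfg, rate) {
  if (runs$label[m] != "S" || runs$dur[m] < cfg$t_pause) return(FALSE)
  k <- runs$i1[m] - runs$i0[m]
  abs(runs$p1[m] - runs$p0[m]) / (max(k, 1L) / rate) < cfg$v_pause / 2
}

# Pauses inside a backward retreat are flanked by fast backward motion --
# the motor is disengaged, so there is no slow-translocation flicker to
# reject and even a single stationary sample is unambiguous.
.is_retreat_pause <- function(runs, m, cfg, rate) {
  if (runs$label[m] != "S") return(FALSE)
  k <- runs$i1[m] - runs$i0[m]
  if (k == 0L) return(TRUE)
  abs(runs$p1[m] - runs$p0[m]) / (k / rate) < cfg$v_pause
}

# Collect a backward retreat starting at R-run r0: consumes R runs and the
# stationary stretches between them (rehybridization pauses, possibly
# interrupted by single-sample noise excursions). Stops once baseline is
# reached or genuine forward motion resumes. Returns the index of the last
# run belonging to the retreat.
.collect_retreat <- function(runs, r0, cfg) {
  r1 <- r0
  j <- r0 + 1L
  nr <- nrow(runs)
  while (runs$p1[r1] > cfg$baseline_tol && j <= nr) {
    if (runs$label[j] == "R") {
      r1 <- j; j <- j + 1L
      next
    }
    # only strong forward motion interrupts a retreat: a marginal
    # two-sample excursion inside a rehybridization pause must not
    if (.is_motion_run(runs, j, cfg, floor_mult = 1.5)) break
    k <- j
    while (k <= nr && runs$label[k] != "R" &&
           !.is_motion_run(runs, k, cfg, floor_mult = 1.5))
      k <- k + 1L
    if (k <= nr && runs$label[k] == "R") {
      r1 <- k; j <- k + 1L
    } else break
  }
  r1
}

#' Segment a processed trace into unwinding events and dwells
#'
#' Derivative-threshold segmentation on the filtered series: the
#' central-difference velocity classifies each sample as moving forward
#' (unwinding), moving backward (rehybridization) or stationary. A forward
#' run lasting at least `t_min` opens an event; the event absorbs
#' stationary runs (pauses when longer than `t_pause`) and backward
#' retreats that either fail to reach baseline or reach it but are followed
#' by renewed unwinding within `backslide_window` (backslides, complete
#' when they reach `baseline_tol`). A retreat that returns to baseline with
#' no renewed unwinding terminates the event as its rehybridization;
#' stationary interruptions of that retreat longer than `t_pause` are
#' rehybridization pauses. Dwells measure the time from the end of each
#' terminal rehybridization to the start of the next event on the same
#' trace.
#'
#' @param p a `processed_trace` in bp (see [z_to_bp()]).
#' @param cfg a [segment_config()].
#' @param trace_id identifier recorded in the output tables.
#' @return A list of data frames: `events` (one row per unwinding event:
#'   times, `length_bp`, pause-excluded `mean_rate`, `rate_incl_pauses`,
#'   pause/backslide counts, `max_position`, `terminated_by`, `truncated`),
#'   `pauses`, `backslides`, `rehybs`, and `dwells` (`dt`,
#'   `follows_backslide`). Empty inputs give empty tables, not an error.
#' @export
segment_events <- function(p, cfg = segment_config(), trace_id = 1L) {
  stopifnot(inherits(p, "processed_trace"), identical(p$unit, "bp"),
            inherits(cfg, "segment_config"))
  empty <- list(
    events = data.frame(trace_id = integer(), event_id = integer(),
                        t_start = numeric(), t_end = numeric(),
                        length_bp = numeric(), mean_rate = numeric(),
                        rate_incl_pauses = numeric(), n_pauses = integer(),
                        pause_time = numeric(), n_backslides = integer(),
                        n_backslides_complete = integer(),
                        n_rehyb_pauses = integer(), max_position = numeric(),
                        start_position = numeric(),
                        terminated_by = character(), truncated = logical()),
    pauses = data.frame(trace_id = integer(), event_id = integer(),
                        t_start = numeric(), t_end = numeric(),
                        phase = character()),
    backslides = data.frame(trace_id = integer(), event_id = integer(),
                            t_start = numeric(), t_end = numeric(),
                            depth_bp = numeric(), complete = logical()),
    rehybs = data.frame(trace_id = integer(), event_id = integer(),
                        t_start = numeric(), t_end = numeric(),
                        n_pauses = integer()),
    dwells = data.frame(trace_id = integer(), dt = numeric(),
                        t_start = numeric(), t_end = numeric(),
                        follows_backslide = logical()))
  if (length(p$value) < 2L * max(3L, ceiling(p$rate * cfg$t_min)))
    return(empty)

  runs <- .velocity_runs(p$value, p$times, p$rate, cfg)
  nr <- nrow(runs)
  ev <- list(); pa <- list(); bs <- list(); rh <- list(); dw <- list()
  i <- 1L
  event_id <- 0L
  last_rehyb_end <- NA_real_

  while (i <= nr) {
    if (!.is_motion_run(runs, i, cfg)) {
      i <- i + 1L
      next
    }
    # --- open an event at run i ---
    u_runs <- i
    j <- i + 1L
    terminated_by <- "trace-end"
    rehyb <- NULL
    i_term <- NA_integer_   # first sample of the terminal retreat
    term_r0 <- NA_integer_  # first run of the terminal retreat
    ev_bs <- list(); ev_pa <- list()
    nrp_attached <- 0L      # rehyb pauses inside attached complete retreats
    while (j <= nr) {
      lab <- runs$label[j]
      if (lab == "U") {
        if (.is_motion_run(runs, j, cfg)) u_runs <- c(u_runs, j)
        j <- j + 1L
      } else if (lab == "S") {
        j <- j + 1L   # pause candidate; classified once the event closes
      } else {
        r0 <- j
        r1 <- .collect_retreat(runs, r0, cfg)
        retreat_end_t <- runs$t1[r1]
        retreat_end_pos <- runs$p1[r1]
        depth <- runs$p0[r0] - retreat_end_pos
        reached_base <- retreat_end_pos <= cfg$baseline_tol
        j <- r1 + 1L
        # does unwinding genuinely resume shortly after the retreat?
        # (stationary stretches and weak sub-threshold forward runs inside
        # the window do not count as resumption but do not block it either)
        k <- j
        while (k <= nr && !.is_motion_run(runs, k, cfg) &&
               runs$label[k] != "R" &&
               (runs$t0[k] - retreat_end_t) <= cfg$backslide_window)
          k <- k + 1L
        resumes <- k <= nr && .is_motion_run(runs, k, cfg) &&
          (runs$t0[k] - retreat_end_t) <= cfg$backslide_window
        if (resumes) {
          if (depth >= cfg$min_backslide_depth) {
            ev_bs[[length(ev_bs) + 1L]] <-
              data.frame(t_start = runs$t0[r0], t_end = retreat_end_t,
                         depth_bp = depth, complete = reached_base)
            # a complete attached retreat is itself a rehybridization;
            # score its internal pauses with the rehyb pauses
            if (reached_base && r1 > r0 + 1L)
              for (m in (r0 + 1L):(r1 - 1L))
                if (.is_retreat_pause(runs, m, cfg, p$rate)) {
                  nrp_attached <- nrp_attached + 1L
                  ev_pa[[length(ev_pa) + 1L]] <-
                    data.frame(t_start = runs$t0[m], t_end = runs$t1[m],
                               phase = "rehybridization")
                }
          }
          next   # stay inside the event (shallow excursions ignored)
        }
        if (reached_base) {
          n_rp <- 0L
          if (r1 > r0 + 1L) for (m in (r0 + 1L):(r1 - 1L))
            if (.is_retreat_pause(runs, m, cfg, p$rate)) {
              n_rp <- n_rp + 1L
              ev_pa[[length(ev_pa) + 1L]] <-
                data.frame(t_start = runs$t0[m], t_end = runs$t1[m],
                           phase = "rehybridization")
            }
          rehyb <- list(t0 = runs$t0[r0], t1 = retreat_end_t,
                        n_pauses = n_rp)
          terminated_by <- "rehybridization"
          i_term <- runs$i0[r0]
          term_r0 <- r0
        } else {
          if (depth >= cfg$min_backslide_depth)
            ev_bs[[length(ev_bs) + 1L]] <-
              data.frame(t_start = runs$t0[r0], t_end = retreat_end_t,
                         depth_bp = depth, complete = reached_base)
          terminated_by <- "arrest"
          i_term <- runs$i0[r0]
        }
        break
      }
    }
    last_u <- u_runs[length(u_runs)]
    t_start <- runs$t0[u_runs[1L]]
    t_end <- runs$t1[last_u]
    # start level: median of the last fully stationary samples before the
    # first forward run (motion is detected with up to one window latency)
    i_first <- max(runs$i0[u_runs[1L]] - 1L, 1L)
    start_pos <- stats::median(p$value[max(i_first - 2L, 1L):i_first])
    # peak: highest position between motion onset and the terminal retreat
    # (slow final climbs can fragment into sub-threshold runs after the
    # last qualifying forward run, so do not stop at that run)
    i_last <- if (!is.na(i_term)) i_term else
      min(runs$i1[last_u] + 1L, length(p$value))
    i_last <- max(i_last, runs$i1[last_u])
    span <- i_first:i_last
    max_pos <- max(p$value[span])
    # The boxcar window holding the peak averages ascent and rapid
    # rehybridization and clips it. When detachment follows the last
    # forward run closely (within a few samples), extrapolate that run's
    # interior slope to the estimated detachment time (midpoint of the
    # gap); a longer gap means the event ended on a measurable plateau.
    i1 <- runs$i1[last_u]
    gap_s <- if (!is.na(i_term)) i_term - i1
    else if (last_u < nr && runs$label[last_u + 1L] == "R") 1L
    else NA_integer_
    k <- i1 - runs$i0[last_u] + 1L
    if (!is.na(gap_s) && gap_s >= 1L && gap_s <= 2L && k >= 4L) {
      v_end <- (p$value[i1 - 1L] - p$value[runs$i0[last_u] + 1L]) *
        p$rate / (k - 3L)
      t_det <- p$times[i1] + gap_s / (2 * p$rate)
      peak <- p$value[i1 - 1L] + v_end * (t_det - p$times[i1 - 1L])
      if (v_end > 0) max_pos <- max(max_pos, peak)
    }
    length_bp <- max_pos - start_pos
    # stationary runs between the first forward run and the terminal
    # retreat (or last forward run) -> unwinding pauses; the range past the
    # last forward run catches pauses that immediately precede detachment
    # Merge stationary runs separated only by single-sample noise
    # excursions into one candidate (noise splits short pauses into
    # sub-threshold fragments), then score candidates on duration and
    # net velocity.
    scan_end <- if (!is.na(term_r0)) term_r0 - 1L else last_u - 1L
    if (scan_end > u_runs[1L]) {
      bs_ends <- vapply(ev_bs, function(b) b$t_end, numeric(1))
      cand_i0 <- NA_integer_; cand_i1 <- NA_integer_
      close_candidate <- function() {
        if (is.na(cand_i0)) return()
        dur <- (cand_i1 - cand_i0 + 1L) / p$rate
        netv <- abs(p$value[cand_i1] - p$value[cand_i0]) /
          (max(cand_i1 - cand_i0, 1L) / p$rate)
        t0c <- p$times[cand_i0]
        after_bs <- length(bs_ends) &&
          any(t0c - bs_ends >= -1e-9 & t0c - bs_ends < 2 / p$rate + 1e-9)
        if (dur >= cfg$t_pause && netv < cfg$v_pause / 2 && !after_bs)
          ev_pa[[length(ev_pa) + 1L]] <<-
            data.frame(t_start = t0c, t_end = p$times[cand_i1],
                       phase = "unwinding")
      }
      for (m in (u_runs[1L] + 1L):scan_end) {
        if (runs$label[m] == "S") {
          if (is.na(cand_i0)) cand_i0 <- runs$i0[m]
          cand_i1 <- runs$i1[m]
        } else if (!is.na(cand_i0) &&
                   runs$i1[m] - runs$i0[m] == 0L &&
                   !.is_motion_run(runs, m, cfg)) {
          # single-sample noise excursion inside a stationary stretch
          cand_i1 <- runs$i1[m]
        } else {
          close_candidate()
          cand_i0 <- NA_integer_; cand_i1 <- NA_integer_
        }
      }
      close_candidate()
    }
    # Pause-excluded rate from the moving runs. Boundary samples of a run
    # sit in boxcar windows that straddle the onset/offset and underestimate
    # the velocity, so runs of >= 4 samples contribute only their interior
    # displacement; shorter runs fall back on their largest instantaneous
    # velocity (their most fully-averaged window).
    vel <- attr(runs, "velocity")
    move_disp <- 0; move_time <- 0
    for (u in u_runs) {
      k <- runs$i1[u] - runs$i0[u] + 1L
      if (k >= 4L) {
        move_disp <- move_disp + p$value[runs$i1[u] - 1L] -
          p$value[runs$i0[u] + 1L]
        move_time <- move_time + (k - 3L) / p$rate
      } else {
        move_disp <- move_disp +
          max(vel[runs$i0[u]:runs$i1[u]], na.rm = TRUE) / p$rate
        move_time <- move_time + 1 / p$rate
      }
    }
    if (length_bp >= cfg$min_event_length) {
      event_id <- event_id + 1L
      pa_unw <- Filter(function(x) x$phase == "unwinding", ev_pa)
      pause_time <- if (length(pa_unw))
        sum(vapply(pa_unw, function(x) x$t_end - x$t_start, numeric(1)))
      else 0
      ev[[event_id]] <- data.frame(
        trace_id = trace_id, event_id = event_id,
        t_start = t_start, t_end = t_end, length_bp = length_bp,
        mean_rate = move_disp / move_time,
        rate_incl_pauses = length_bp / (t_end - t_start),
        n_pauses = length(pa_unw), pause_time = pause_time,
        n_backslides = length(ev_bs),
        n_backslides_complete = if (length(ev_bs))
          sum(vapply(ev_bs, function(b) b$complete, logical(1))) else 0L,
        n_rehyb_pauses = nrp_attached +
          (if (is.null(rehyb)) 0L else rehyb$n_pauses),
        max_position = max_pos, start_position = start_pos,
        terminated_by = terminated_by,
        truncated = terminated_by == "trace-end")
      if (length(ev_pa))
        pa[[length(pa) + 1L]] <- cbind(trace_id = trace_id,
                                       event_id = event_id,
                                       do.call(rbind, ev_pa))
      if (length(ev_bs))
        bs[[length(bs) + 1L]] <- cbind(trace_id = trace_id,
                                       event_id = event_id,
                                       do.call(rbind, ev_bs))
      if (!is.null(rehyb))
        rh[[length(rh) + 1L]] <- data.frame(
          trace_id = trace_id, event_id = event_id,
          t_start = rehyb$t0, t_end = rehyb$t1, n_pauses = rehyb$n_pauses)
    }
    # dwell bookkeeping: every detected initiation delimits a dwell, even
    # when the ensuing event falls below min_event_length, so that small
    # events do not silently merge two waiting periods into one
    if (!is.na(last_rehyb_end)) {
      dt <- t_start - last_rehyb_end
      if (dt > 0)
        dw[[length(dw) + 1L]] <- data.frame(
          trace_id = trace_id, dt = dt, t_start = last_rehyb_end,
          t_end = t_start,
          follows_backslide = dt < cfg$backslide_window)
    }
    last_rehyb_end <- if (is.null(rehyb)) NA_real_ else rehyb$t1
    i <- j
  }

  # split dwells at sub-threshold initiation blips: an event too small to
  # segment still lifts the position visibly above baseline, and leaving it
  # inside a dwell would merge two waiting periods into one
  if (length(dw)) {
    dw2 <- list()
    for (d in dw) {
      idx <- which(p$times > d$t_start + 0.4 & p$times < d$t_end - 0.4)
      # local robust centring: the dwell's own median and spread set the
      # blip threshold, so small baseline offsets cannot leak noise in
      loc <- stats::median(p$value[idx])
      sp <- max(stats::mad(p$value[idx]), 8)
      hot <- idx[p$value[idx] > loc + 4 * sp]
      if (!length(hot)) {
        dw2[[length(dw2) + 1L]] <- d
        next
      }
      cuts <- c(d$t_start, p$times[hot[1]])
      if (length(hot) > 1L) {
        gaps <- which(diff(p$times[hot]) > 2)
        for (g in gaps) cuts <- c(cuts, p$times[hot[g]], p$times[hot[g + 1L]])
      }
      cuts <- c(cuts, p$times[hot[length(hot)]], d$t_end)
      for (s in seq(1, length(cuts) - 1, by = 2)) {
        dt <- cuts[s + 1] - cuts[s]
        if (dt > 0)
          dw2[[length(dw2) + 1L]] <- data.frame(
            trace_id = d$trace_id, dt = dt, t_start = cuts[s],
            t_end = cuts[s + 1],
            follows_backslide = dt < cfg$backslide_window)
      }
    }
    dw <- dw2
  }

  out <- empty
  if (length(ev)) out$events <- do.call(rbind, ev)
  if (length(pa)) out$pauses <- do.call(rbind, pa)
  if (length(bs)) out$backslides <- do.call(rbind, bs)
  if (length(rh)) out$rehybs <- do.call(rbind, rh)
  if (length(dw)) out$dwells <- do.call(rbind, dw)
  rownames(out$events) <- NULL
  out
}

#' Run the filter -> bp conversion -> segmentation chain on one trace
#'
#' @param trace an `mt_trace`.
#' @param cfg a [segment_config()].
#' @param target_rate analysis bandwidth, Hz.
#' @param e a [duplex_elasticity()].
#' @param trace_id identifier for the output tables.
#' @return as [segment_events()].
#' @export
analyze_trace <- function(trace, cfg = segment_config(), target_rate = 3,
                          e = duplex_elasticity(), trace_id = 1L) {
  p <- downsample_filter(trace, target_rate)
  p <- z_to_bp(p, force = trace$force, e = e,
               geometry = if (identical(trace$geometry, "canonical"))
                 "canonical" else "looping")
  segment_events(p, cfg, trace_id = trace_id)
}

#' Simulate several tethers and pool their segmented events
#'
#' @param profile profile name or [experiment_profile()].
#' @param n_traces number of tethers.
#' @param duration duration per tether, s.
#' @param seed integer seed; tether i uses `seed + i - 1`.
#' @param cfg a [segment_config()].
#' @return pooled list as [segment_events()], with `trace_id` distinguishing
#'   tethers.
#' @export
simulate_and_segment <- function(profile, n_traces, duration, seed = 1L,
                                 cfg = segment_config()) {
  if (is.character(profile)) profile <- build_profile(profile)
  parts <- lapply(seq_len(n_traces), function(i) {
    tr <- simulate_trace(profile, duration, seed = as.integer(seed) + i - 1L)
    analyze_trace(tr, cfg, trace_id = i)
  })
  list(events = do.call(rbind, lapply(parts, `[[`, "events")),
       pauses = do.call(rbind, lapply(parts, `[[`, "pauses")),
       backslides = do.call(rbind, lapply(parts, `[[`, "backslides")),
       rehybs = do.call(rbind, lapply(parts, `[[`, "rehybs")),
       dwells = do.call(rbind, lapply(parts, `[[`, "dwells")))
}

#' Tabulate pause and backslide frequencies
#'
#' Per-event percentages in the layout of the pause/backslide frequency
#' table: percent of events with pauses during unwinding, percent with
#' pauses during rehybridization, percent with backsliding, and percent of
#' backslides that are complete.
#'
#' @param events events data frame from [segment_events()].
#' @param dwells dwells data frame (counted for `n_dwells`).
#' @return An object of class `event_summary`.
#' @export
summarize_events <- function(events, dwells = NULL) {
  n <- if (is.null(events)) 0L else nrow(events)
  if (n == 0L)
    return(structure(list(n_beads = 0L, n_events = 0L, n_dwells = 0L,
                          pct_pause_unwinding = 0, pct_pause_rehyb = 0,
                          pct_backslide = 0, pct_backslide_complete = 0),
                     class = "event_summary"))
  n_bs <- sum(events$n_backslides)
  structure(list(
    n_beads = length(unique(events$trace_id)),
    n_events = n,
    n_dwells = if (is.null(dwells)) 0L else nrow(dwells),
    pct_pause_unwinding = 100 * mean(events$n_pauses > 0),
    pct_pause_rehyb = 100 * mean(events$n_rehyb_pauses > 0),
    pct_backslide = 100 * mean(events$n_backslides > 0),
    pct_backslide_complete = if (n_bs == 0) 0 else
      100 * sum(events$n_backslides_complete) / n_bs),
    class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("%-38s %d\n", "Beads analysed", x$n_beads))
  cat(sprintf("%-38s %d\n", "Unwinding events", x$n_events))
  cat(sprintf("%-38s %.0f%%\n", "Pauses during unwinding events",
              x$pct_pause_unwinding))
  cat(sprintf("%-38s %.0f%%\n", "Pauses during rehybridization events",
              x$pct_pause_rehyb))
  cat(sprintf("%-38s %.0f%% (of which %.0f%% complete)\n",
              "Backsliding during unwinding events",
              x$pct_backslide, x$pct_backslide_complete))
  invisible(x)
}

#' Extract fitting samples from segmented event tables
#'
#' Codify which events enter each distribution fit:
#' \describe{
#'   \item{event_length_sample}{lengths of events that ran to completion
#'     (terminated by rehybridization, not clipped by the trace end) and
#'     that started from baseline — events cut short by the trace end or
#'     split by a failed backslide re-attachment are censored
#'     measurements, not draws from the length distribution.}
#'   \item{event_rate_sample}{pause-excluded rates of events of at least
#'     `min_length` bp: shorter events span too few filtered samples for
#'     the derivative to resolve their velocity.}
#'   \item{dwell_sample}{dwell times not flagged as backslide restarts.}
#' }
#'
#' @param events,dwells tables from [segment_events()].
#' @param cfg a [segment_config()].
#' @param min_length minimum event length for rate estimation, bp.
#' @return numeric vector.
#' @export
event_length_sample <- function(events, cfg = segment_config()) {
  if (is.null(events) || nrow(events) == 0L) return(numeric())
  keep <- !events$truncated & events$terminated_by == "rehybridization" &
    events$start_position <= 2 * cfg$baseline_tol
  events$length_bp[keep]
}

#' @rdname event_length_sample
#' @export
event_rate_sample <- function(events, min_length = 300) {
  if (is.null(events) || nrow(events) == 0L) return(numeric())
  keep <- !events$truncated & events$length_bp >= min_length &
    events$mean_rate > 0
  events$mean_rate[keep]
}

#' @rdname event_length_sample
#' @export
dwell_sample <- function(dwells) {
  if (is.null(dwells) || nrow(dwells) == 0L) return(numeric())
  dwells$dt[!dwells$follows_backslide]
}

#' Maximum position reached per event
#'
#' For nicked-substrate experiments: the arrest/turnaround position of
#' each event, used downstream to discriminate Gaussian (arrest at a fixed
#' lesion) from exponential (unperturbed processivity) length
#' distributions.
#'
#' @param events events data frame from [segment_events()].
#' @return numeric vector of positions in bp.
#' @export
arrest_positions <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return(numeric())
  events$max_position
}
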