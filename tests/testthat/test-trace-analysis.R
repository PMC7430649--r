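# Filtering, bp conversion and event segmentation.

test_that("boxcar downsampling preserves constants and cancels alternation", {
  tr <- make_trace(rep(2000, 1200))
  p <- downsample_filter(tr, 3)
  expect_true(all(p$value == 2000))
  expect_equal(p$rate, 3)
  tr2 <- make_trace(2000 + rep(c(1, -1), 600))
  p2 <- downsample_filter(tr2, 3)
  expect_true(all(abs(p2$value - 2000) < 1e-12))
})

test_that("boxcar filtering reduces white noise as the mean of the window", {
  set.seed(31)
  tr <- make_trace(rnorm(2e5, 2000, 15))
  p <- downsample_filter(tr, 3)
  expect_gt(length(p$value), 9999)
  expect_lt(abs(stats::sd(p$value) - 15 / sqrt(20)) / (15 / sqrt(20)), 0.15)
})

test_that("partial final windows are dropped with a note", {
  tr <- make_trace(rep(1, 130))
  expect_message(p <- downsample_filter(tr, 3), "partial")
  expect_equal(length(p$value), 6)
  expect_error(downsample_filter(tr, 60), "below")
})

test_that("height-to-bp conversion references the histogram-mode baseline", {
  # flat at baseline -> 0 bp
  tr <- make_trace(rep(2148, 600))
  p <- z_to_bp(downsample_filter(tr, 3))
  expect_true(all(abs(p$value) < 1e-9))

  # a 320 nm drop at 8 pN equals 320 / 0.3254750 = 983.25 bp (oracle)
  z <- c(rep(2148, 1200), rep(2148 - 320, 300), rep(2148, 600))
  p2 <- z_to_bp(downsample_filter(make_trace(z), 3))
  plateau <- p2$value[p2$value > 500]
  expect_equal(stats::median(plateau), 320 / (0.34 * oracle_wlc_fraction(8)),
               tolerance = 1e-4)
  expect_error(z_to_bp(downsample_filter(make_trace(z), 3), force = -2),
               "force")
})

test_that("conversion inverts a noiseless simulated trace", {
  p <- build_profile("LOW30")
  p$noise <- noise_model(z_noise_sd = 0)
  tr <- simulate_trace(p, 600, seed = 18)
  pr <- structure(list(times = tr$times, value = tr$z, unit = "nm",
                       rate = tr$sampling_rate, window = 1L,
                       method = "none", force = tr$force),
                  class = "processed_trace")
  pos <- z_to_bp(pr)$value
  truth_pos <- (tr$baseline_z - tr$z) / duplex_rise_per_bp(8)
  expect_lt(max(abs(pos - truth_pos)), 1)
})

test_that("a clean ramp is segmented as one event with its rate", {
  # noiseless position series at the analysis bandwidth: 1000 bp at
  # 200 bp/s, then an immediate fast return to baseline
  t_brk <- c(0, 30, 35, 35.5, 65)
  p_brk <- c(0, 0, 1000, 0, 0)
  times <- seq(0, 65, by = 1 / 3)
  pos <- stats::approx(t_brk, p_brk, xout = times)$y
  p <- structure(list(times = times, value = pos, unit = "bp", rate = 3,
                      window = 20L, method = "boxcar", force = 8),
                 class = "processed_trace")
  res <- segment_events(p)
  expect_equal(nrow(res$events), 1)
  expect_lt(abs(res$events$length_bp - 1000) / 1000, 0.02)
  expect_lt(abs(res$events$mean_rate - 200) / 200, 0.02)
  expect_equal(res$events$terminated_by, "rehybridization")
})

test_that("a partial retreat with resumption is one incomplete backslide", {
  seg <- data.frame(dur = c(30, 4, 0.075, 0.5, 2, 0.5, 30),
                    to_bp = c(0, 800, 650, 650, 1050, 0, 0))
  tr <- path_trace(seg)
  res <- analyze_trace(tr)
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$n_backslides, 1)
  expect_false(res$backslides$complete[1])
  expect_lt(abs(res$backslides$depth_bp[1] - 150), 60)
})

test_that("flat noisy traces produce no events and empty inputs no error", {
  set.seed(77)
  tr <- make_trace(rnorm(60 * 3600, 2148, 15))
  res <- analyze_trace(tr)
  expect_equal(nrow(res$events), 0)
  expect_lte(nrow(res$dwells), 2)

  short <- make_trace(rnorm(30, 2148, 15))
  res2 <- analyze_trace(short)
  expect_equal(nrow(res2$events), 0)
})

test_that("segmentation recovers most ground-truth events with their length", {
  found <- 0; n_big <- 0; relerr <- c()
  for (s in 1:2) {
    tr <- simulate_trace("LOW30", 1800, seed = 22 + s)
    res <- analyze_trace(tr)
    tu <- tr$truth[tr$truth$event_type == "unwinding" &
                     tr$truth$bp_end >= 200 & tr$truth$t_end < 1795, ]
    n_big <- n_big + nrow(tu)
    for (j in seq_len(nrow(tu))) {
      ov <- which(res$events$t_start < tu$t_end[j] + 1 &
                    res$events$t_end > tu$t_start[j] - 1)
      if (length(ov)) {
        found <- found + 1
        relerr <- c(relerr, abs(res$events$length_bp[ov[1]] - tu$bp_end[j]) /
                      tu$bp_end[j])
      }
    }
  }
  expect_gte(found / n_big, 0.90)
  expect_lte(stats::median(relerr), 0.10)
})

test_that("pauses nest inside events and dwells do not overlap them", {
  res <- simulate_and_segment("HIGH163", 2, 1200, seed = 33)
  ev <- res$events
  for (k in seq_len(nrow(res$pauses))) {
    pa <- res$pauses[k, ]
    parent <- ev[ev$trace_id == pa$trace_id & ev$event_id == pa$event_id, ]
    expect_equal(nrow(parent), 1)
    # rehybridization pauses sit between event end and the rehyb tail
    expect_gte(pa$t_start, parent$t_start - 1)
  }
  for (k in seq_len(nrow(res$dwells))) {
    dw <- res$dwells[k, ]
    inside <- ev$trace_id == dw$trace_id &
      ev$t_start < dw$t_end - 0.5 & ev$t_end > dw$t_start + 0.5
    expect_equal(sum(inside), 0)
  }
  # backslide depths cannot exceed the parent event's reach
  for (k in seq_len(nrow(res$backslides))) {
    b <- res$backslides[k, ]
    parent <- ev[ev$trace_id == b$trace_id & ev$event_id == b$event_id, ]
    expect_lte(b$depth_bp, parent$max_position + 100)
  }
})

test_that("detected event count is monotone in the thresholds", {
  tr <- simulate_trace("LOW30", 2500, seed = 44)
  p <- z_to_bp(downsample_filter(tr, 3))
  counts_v <- vapply(c(20, 30, 45, 60, 90), function(v)
    nrow(segment_events(p, segment_config(v_min = v, v_pause = v))$events),
    numeric(1))
  expect_true(all(diff(counts_v) <= 0))
  counts_l <- vapply(c(50, 100, 200, 400, 800), function(L)
    nrow(segment_events(p, segment_config(min_event_length = L))$events),
    numeric(1))
  expect_true(all(diff(counts_l) <= 0))
})

test_that("event summaries mirror the event table", {
  res <- simulate_and_segment("LOW30", 2, 1500, seed = 55)
  s <- summarize_events(res$events, res$dwells)
  expect_equal(s$n_events, nrow(res$events))
  expect_equal(s$n_beads, length(unique(res$events$trace_id)))
  pcts <- c(s$pct_pause_unwinding, s$pct_pause_rehyb, s$pct_backslide,
            s$pct_backslide_complete)
  expect_true(all(pcts >= 0 & pcts <= 100))
  s0 <- summarize_events(NULL, NULL)
  expect_equal(s0$n_events, 0)
  expect_equal(s0$pct_backslide, 0)
})

test_that("arrest positions report the per-event maximum", {
  ev <- data.frame(max_position = c(500))
  expect_equal(arrest_positions(ev), 500)
  expect_length(arrest_positions(NULL), 0)
})
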