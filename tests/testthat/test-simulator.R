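# Stochastic motor simulator: determinism, event-length law, initiation
# statistics, nick and SSB behaviour, geometry bookkeeping.

test_that("identical (profile, duration, seed) give identical traces", {
  a <- simulate_trace("LOW30", 300, seed = 7)
  b <- simulate_trace("LOW30", 300, seed = 7)
  expect_identical(a$z, b$z)
  expect_identical(a$truth, b$truth)
  c <- simulate_trace("LOW30", 300, seed = 8)
  expect_false(identical(a$z, c$z))
})

test_that("zero initiation rate yields a flat trace at baseline", {
  p <- build_profile("LOW30")
  p$initiation$protein_conc <- 0
  tr <- simulate_trace(p, 120, seed = 3)
  se <- stats::sd(tr$z) / sqrt(length(tr$z))
  expect_lt(abs(mean(tr$z) - tr$baseline_z), 3 * se)
  expect_equal(nrow(tr$truth), 0)
})

test_that("invalid simulation inputs are rejected", {
  expect_error(simulate_trace("LOW30", -5), "positive")
  expect_error(simulate_event_lengths(motor_kinetics(), 0), ">= 1")
})

test_that("event lengths are exponential with the configured mean", {
  k <- motor_kinetics(detach_per_bp = 1 / 900)
  L1 <- simulate_event_lengths(k, 1, seed = 1)
  expect_gte(L1, 0)
  L <- simulate_event_lengths(k, 1e4, seed = 2)
  se <- 900 / sqrt(1e4)
  expect_lt(abs(mean(L) - 900), 3 * se)
  # KS against the generative law
  L2 <- simulate_event_lengths(k, 5000, seed = 3)
  ks <- stats::ks.test(L2, "pexp", 1 / 900)
  expect_gt(ks$p.value, 0.01)
})

test_that("top-strand nicks truncate event lengths at the jittered nick", {
  k <- motor_kinetics(detach_per_bp = 1 / 900)
  nick <- list(strand = "top", position = 2000)
  L <- simulate_event_lengths(k, 5000, seed = 4, nick = nick)
  expect_true(all(L <= 2000 + 3 * 100))
  expect_gt(mean(L > 1800), 0.05)  # a fair share actually arrests
})

test_that("simulated trace event lengths match direct exponential sampling", {
  # pauses and backslides disabled; fast cycling to accumulate events
  k <- motor_kinetics(unwind_rate_mean = 215, unwind_rate_cv = 0.5,
                      detach_per_bp = 1 / 900)
  p <- experiment_profile("fastcycle", kinetics = k,
                          initiation = initiation_model(5.9e5, 1e-6))
  lens <- c()
  for (s in 1:4) {
    tr <- simulate_trace(p, 1600, seed = s)
    tu <- tr$truth[tr$truth$event_type == "unwinding" &
                     tr$truth$t_end < 1600, ]
    lens <- c(lens, tu$bp_end)
  }
  expect_gt(length(lens), 700)
  # sampling bound: three standard errors of the mean of Exp(900) draws
  expect_lt(abs(mean(lens) - 900), 3 * 900 / sqrt(length(lens)))
})

test_that("initiation waiting times follow the bimolecular model", {
  waits <- c()
  for (s in c(9, 10)) {
    th <- simulate_trace("HIGH163", 4000, seed = s)$truth
    ini <- th$t_start[th$event_type == "initiation"]
    reh <- th[th$event_type == "rehybridization", ]
    for (j in seq_len(nrow(reh))) {
      nx <- ini[ini > reh$t_end[j] - 1e-9]
      if (length(nx)) waits <- c(waits, nx[1] - reh$t_end[j])
    }
  }
  expect_gt(length(waits), 200)
  expect_lt(abs(mean(waits) - 11.6) / 11.6, 0.10)
  expect_gt(stats::ks.test(waits, "pexp", 1 / 11.6)$p.value, 0.01)
})

test_that("looping geometry conserves the available track", {
  tr <- simulate_trace("LOW30", 2000, seed = 12)
  track <- build_profile("LOW30")$tether$track_length
  tu <- tr$truth[tr$truth$event_type == "unwinding", ]
  expect_true(all(tu$bp_end <= track + 1e-9))
  rise <- duplex_rise_per_bp(8)
  noise_margin <- 6 * 15
  expect_lte(max(abs(tr$z - tr$baseline_z)), track * rise + noise_margin)
})

test_that("events beyond the track are clipped with a warning", {
  p <- build_profile("LOW30")
  p$tether <- tether_design(track_length = 300)
  expect_warning(simulate_trace(p, 600, seed = 5), "clipped")
})

test_that("NICKTOP ground truth never exceeds the nick plus jitter", {
  tr <- simulate_trace("NICKTOP", 3000, seed = 14)
  tu <- tr$truth[tr$truth$event_type == "unwinding", ]
  expect_gt(nrow(tu), 20)
  nickpos <- build_profile("NICKTOP")$tether$nick$position
  expect_true(all(tu$bp_end <= nickpos + 3 * 100 + 1e-9))
})

test_that("bottom-strand nicks are transparent and keep the tether", {
  tr <- simulate_trace("NICKBOT", 3000, seed = 15)
  tu <- tr$truth[tr$truth$event_type == "unwinding", ]
  expect_gt(mean(tu$bp_end > 600), 0.2)   # events pass the nick position
  expect_true(all(is.finite(tr$z)))
})

test_that("SSB slows rehybridization and suppresses backslides", {
  dur_rehyb <- function(profile, seed) {
    tr <- simulate_trace(profile, 2500, seed = seed)
    th <- tr$truth
    reh <- th[th$event_type == "rehybridization", ]
    nev <- sum(th$event_type == "unwinding")
    bs_ev <- 0
    tu <- th[th$event_type == "unwinding", ]
    bs <- th[th$event_type == "backslide", ]
    if (nrow(bs) && nrow(tu))
      bs_ev <- sum(vapply(seq_len(nrow(tu)), function(i)
        any(bs$t_start >= tu$t_start[i] & bs$t_end <= tu$t_end[i]),
        logical(1)))
    list(med = stats::median(reh$t_end - reh$t_start),
         frac_bs = bs_ev / max(nev, 1))
  }
  s <- dur_rehyb("SSB", 21)
  l <- dur_rehyb("LOW30", 21)
  expect_gte(s$med, 5 * l$med)
  expect_lte(s$frac_bs, 0.10)
})

test_that("canonical geometry raises the bead above the crossover force", {
  tr <- simulate_trace("CANONICAL", 800, seed = 16)
  tu <- tr$truth[tr$truth$event_type == "unwinding", ]
  tu <- tu[tu$t_end - tu$t_start > 3, ]
  expect_gt(nrow(tu), 0)
  sel <- tr$times > tu$t_start[1] & tr$times < tu$t_end[1]
  expect_gt(mean(tr$z[sel]) - tr$baseline_z, 0)

  # below the crossover the same motion lowers the bead
  p <- build_profile("CANONICAL")
  p$force <- 4
  tr4 <- simulate_trace(p, 800, seed = 16)
  tu4 <- tr4$truth[tr4$truth$event_type == "unwinding", ]
  tu4 <- tu4[tu4$t_end - tu4$t_start > 3, ]
  sel4 <- tr4$times > tu4$t_start[1] & tr4$times < tu4$t_end[1]
  expect_lt(mean(tr4$z[sel4]) - tr4$baseline_z, 0)
})
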