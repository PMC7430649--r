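# Independent oracles used to freeze expected values.

# Bisection on the (extensible) Marko-Siggia interpolation, written
# independently of the package's solver: scans fractional extension
# directly rather than substituting variables.
oracle_wlc_fraction <- function(force, P = 50, S = 1000, temperature = 296) {
  kBT <- 0.0138065 * temperature
  if (force == 0) return(0)
  f_of <- function(l) (kBT / P) *
    (1 / (4 * (1 - l + force / S)^2) - 0.25 + l - force / S)
  lo <- 0; hi <- 1.05
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f_of(mid) < force) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Closed-form freely-jointed chain extension per nt.
oracle_fjc <- function(force, b = 1.5, Lnt = 0.57, temperature = 296) {
  kBT <- 0.0138065 * temperature
  x <- force * b / kBT
  if (x == 0) return(0)
  Lnt * (1 / tanh(x) - 1 / x)
}

# Brute-force likelihood grid for the exponential mean.
oracle_exp_mle_grid <- function(x) {
  grid <- seq(mean(x) * 0.5, mean(x) * 2, length.out = 20001)
  ll <- vapply(grid, function(m) sum(stats::dexp(x, 1 / m, log = TRUE)),
               numeric(1))
  grid[which.max(ll)]
}

# Golden-section-free least-squares oracle for the dwell hyperbola.
oracle_hyperbola_ls <- function(conc, dt) {
  f <- function(k) sum((dt - 1 / (k * conc))^2)
  stats::optimize(f, c(1e-12, 1e12), tol = 1e-14)$minimum
}

# Two-point closed-form Michaelis-Menten solve.
oracle_mm_two_point <- function(s1, v1, s2, v2) {
  Km <- (v2 - v1) / (v1 / s1 - v2 / s2)
  kcat <- v1 * (Km + s1) / s1
  c(kcat = kcat, Km = Km)
}

# Build a bare trace object around a given height series (for fixtures).
make_trace <- function(z, rate = 60, force = 8, geometry = "looping",
                       baseline_z = 2148) {
  structure(list(times = (seq_along(z) - 1) / rate, z = z, force = force,
                 profile = "fixture", sampling_rate = rate, seed = 0L,
                 baseline_z = baseline_z, geometry = geometry,
                 truth = data.frame()),
            class = "mt_trace")
}

# Piecewise-linear height path sampled at 60 Hz: segments is a data frame
# with columns dur (s) and to_bp (target position at segment end).
path_trace <- function(segments, rate = 60, rise = 0.3254750,
                       baseline_z = 2148, noise_sd = 0, seed = 1) {
  set.seed(seed)
  t_brk <- cumsum(c(0, segments$dur))
  p_brk <- c(0, segments$to_bp)
  times <- seq(0, max(t_brk), by = 1 / rate)
  pos <- stats::approx(t_brk, p_brk, xout = times)$y
  z <- baseline_z - pos * rise + stats::rnorm(length(pos), 0, noise_sd)
  make_trace(z, rate = rate, baseline_z = baseline_z)
}
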