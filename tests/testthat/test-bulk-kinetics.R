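# Bulk enzymology fits, their generators, and iron stoichiometry.

test_that("Michaelis-Menten fit is exact on noiseless data", {
  d <- generate_bulk_dataset("mm", list(kcat = 100, Km = 200),
                             noise_cv = 0, seed = 1)
  f <- fit_michaelis_menten(d)
  expect_equal(f$estimate$kcat, 100, tolerance = 1e-6)
  expect_equal(f$estimate$Km, 200, tolerance = 1e-6)
})

test_that("MM fit matches the two-point closed form and Lineweaver-Burk", {
  o <- oracle_mm_two_point(100, 100 * 100 / 300, 800, 100 * 800 / 1000)
  expect_equal(unname(o["kcat"]), 100, tolerance = 1e-9)
  expect_equal(unname(o["Km"]), 200, tolerance = 1e-9)

  d <- generate_bulk_dataset("mm", list(kcat = 100, Km = 200),
                             noise_cv = 0, seed = 1)
  # Lineweaver-Burk: 1/v = (Km/kcat)(1/S) + 1/kcat, exact without noise
  lb <- stats::lm(I(1 / y) ~ I(1 / x), data = d)
  kcat_lb <- 1 / stats::coef(lb)[[1]]
  km_lb <- stats::coef(lb)[[2]] * kcat_lb
  f <- fit_michaelis_menten(d)
  expect_equal(f$estimate$kcat, kcat_lb, tolerance = 1e-6)
  expect_equal(f$estimate$Km, km_lb, tolerance = 1e-6)
})

test_that("MM fit is invariant to row permutation and warns off-range", {
  d <- generate_bulk_dataset("mm", seed = 5)
  f1 <- fit_michaelis_menten(d)
  d2 <- d[sample(nrow(d)), ]
  f2 <- fit_michaelis_menten(d2)
  expect_equal(f1$estimate$kcat, f2$estimate$kcat, tolerance = 1e-9)
  low <- bulk_dataset("mm", x = c(1, 2, 4, 8),
                      y = 101 * c(1, 2, 4, 8) / (223 + c(1, 2, 4, 8)))
  expect_warning(fit_michaelis_menten(low), "span")
})

test_that("activation fit recovers basal, Vmax and K_DNA", {
  d0 <- generate_bulk_dataset("activation",
                              list(basal = 1, Vmax = 101, K_DNA = 1.66),
                              noise_cv = 0, seed = 2)
  f0 <- fit_activation(d0)
  expect_equal(f0$estimate$basal, 1, tolerance = 1e-6)
  expect_equal(f0$estimate$Vmax, 101, tolerance = 1e-6)
  expect_equal(f0$estimate$K_DNA, 1.66, tolerance = 1e-6)
  expect_error(fit_activation(bulk_dataset("activation", x = c(1, 2, 4, 8),
                                           y = c(2, 3, 4, 5))), "zero-DNA")
  allz <- bulk_dataset("activation", x = rep(0, 6), y = rnorm(6, 1, 0.01))
  expect_warning(fz <- fit_activation(allz), "degenerate")
  expect_equal(fz$estimate$basal, mean(allz$y))
})

test_that("progress-curve fit is exact without noise and flags outliers", {
  d <- generate_bulk_dataset("progress",
                             list(kobs = 0.48, amplitude = 0.9),
                             noise_cv = 0, seed = 3)
  f <- fit_progress_curve(d)
  expect_equal(f$estimate$kobs, 0.48, tolerance = 1e-6)
  expect_equal(f$estimate$amplitude, 0.9, tolerance = 1e-6)
  bad <- bulk_dataset("progress", x = c(0, 1, 2, 3, 4),
                      y = c(0, 0.8, 0.1, 0.85, 0.9))
  expect_warning(fit_progress_curve(bad), "non-monotone")
})

test_that("fitted kobs matches the half-life of the noiseless curve", {
  d <- generate_bulk_dataset("progress", list(kobs = 0.66, amplitude = 0.9),
                             design = seq(0, 4, length.out = 200),
                             replicates = 1L, noise_cv = 0, seed = 4)
  f <- fit_progress_curve(d)
  # interpolate the time at half amplitude: kobs = ln 2 / t_half
  t_half <- stats::approx(d$y, d$x, xout = 0.45)$y
  expect_lt(abs(f$estimate$kobs - log(2) / t_half) / f$estimate$kobs, 0.01)
})

test_that("noisy generator output is recovered within 10%", {
  dm <- generate_bulk_dataset("mm", noise_cv = 0.03, seed = 11)
  fm <- fit_michaelis_menten(dm)
  expect_lt(abs(fm$estimate$kcat - 101) / 101, 0.10)
  expect_lt(abs(fm$estimate$Km - 223) / 223, 0.10)
  da <- generate_bulk_dataset("activation", noise_cv = 0.03, seed = 12)
  fa <- fit_activation(da)
  expect_lt(abs(fa$estimate$K_DNA - 1.66) / 1.66, 0.10)
  dp <- generate_bulk_dataset("progress",
                              params = bulk_profile("unwinding"),
                              noise_cv = 0.05, seed = 13)
  fp <- fit_progress_curve(dp)
  expect_lt(abs(fp$estimate$kobs - 0.66) / 0.66, 0.10)
})

test_that("the generator is deterministic with calibrated noise", {
  a <- generate_bulk_dataset("mm", noise_cv = 0.05, seed = 9)
  b <- generate_bulk_dataset("mm", noise_cv = 0.05, seed = 9)
  expect_identical(a$y, b$y)
  d <- generate_bulk_dataset("mm", list(kcat = 100, Km = 200),
                             design = 500, replicates = 1e4,
                             noise_cv = 0.05, seed = 10)
  cv_emp <- stats::sd(d$y) / mean(d$y)
  expect_lt(abs(cv_emp - 0.05) / 0.05, 0.10)
  exact <- generate_bulk_dataset("mm", list(kcat = 100, Km = 200),
                                 noise_cv = 0, seed = 1)
  expect_equal(exact$y, 100 * exact$x / (200 + exact$x), tolerance = 1e-12)
})

test_that("iron stoichiometry follows Beer-Lambert and the dilution scheme", {
  expect_equal(iron_per_protein(0), 0)
  # no dilution, 1 uM protein: A = 0.1 -> 4.47 uM iron -> 4.47 Fe/protein
  cfg1 <- iron_assay_config(protein_volume_ul = 10, assay_volume_ul = 10,
                            protein_conc_uM = 1)
  expect_equal(iron_per_protein(0.1, cfg1), 0.1 / 22369 / 1e-6,
               tolerance = 1e-9)
  # absorbance constructed for 3 Fe per protein at the 15 uM stock
  a535 <- 3 * 15e-6 * (10 / 143) * 22369
  expect_equal(iron_per_protein(a535), 3, tolerance = 0.01)
  expect_error(iron_assay_config(protein_conc_uM = 0), "positive")
  expect_error(iron_per_protein(-0.1), ">= 0")
})
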