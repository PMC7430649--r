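# Bulk-assay kinetics: Michaelis-Menten ATPase, ssDNA activation,
# single-exponential progress curves, iron stoichiometry, and matched
# synthetic-data generators.

#' Bulk dataset container
#'
#' @param kind `"mm"` (rate vs substrate), `"activation"` (rate vs DNA) or
#'   `"progress"` (fraction product vs time).
#' @param x concentration (µM for mm/activation) or time (min).
#' @param y rate (1/s) or fraction product.
#' @param replicate replicate identifier.
#' @return An object of class `bulk_dataset` (a data frame).
#' @export
bulk_dataset <- function(kind = c("mm", "activation", "progress"),
                         x, y, replicate = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)),
            all(x >= 0))
  if (kind == "progress" && any(y < 0 | y > 1.05))
    stop("progress-curve fractions must lie in [0, 1]")
  structure(data.frame(kind = kind, x = x, y = y, replicate = replicate),
            class = c("bulk_dataset", "data.frame"))
}

#' Built-in bulk kinetic parameter profiles
#'
#' Frozen generative truths for the synthetic bulk assays:
#' `"atpase_mm"` (kcat 101 1/s, Km 223 µM ATP), `"atpase_activation"`
#' (basal 1 1/s, Vmax 101 1/s, K_DNA 1.66 µM nucleotides),
#' `"displacement"` (streptavidin displacement, kobs 0.48 1/min,
#' amplitude 0.9) and `"unwinding"` (strand displacement, kobs 0.66 1/min,
#' amplitude 0.9).
#'
#' @param name profile name.
#' @return named list of parameters.
#' @export
bulk_profile <- function(name = c("atpase_mm", "atpase_activation",
                                  "displacement", "unwinding")) {
  name <- match.arg(name)
  switch(name,
    atpase_mm = list(kcat = 101, Km = 223),
    atpase_activation = list(basal = 1, Vmax = 101, K_DNA = 1.66),
    displacement = list(kobs = 0.48, amplitude = 0.9),
    unwinding = list(kobs = 0.66, amplitude = 0.9))
}

.bulk_model <- function(kind, x, params) {
  switch(kind,
    mm = params$kcat * x / (params$Km + x),
    activation = params$basal +
      (params$Vmax - params$basal) * x / (params$K_DNA + x),
    progress = params$amplitude * (1 - exp(-params$kobs * x)))
}

#' Generate a synthetic bulk dataset
#'
#' Evaluates the model curve for the given kind and applies multiplicative
#' lognormal noise with the requested coefficient of variation
#' (mean-preserving: E\[noise\] = 1). Deterministic for a fixed seed.
#'
#' @param kind `"mm"`, `"activation"` or `"progress"`.
#' @param params named list of generative parameters (see [bulk_profile()]).
#' @param design x values (concentrations in µM, or times in min). Defaults:
#'   mm, 8 ATP points log-spaced 50-2000 µM; activation, 8 DNA points
#'   0-20 µM nucleotides; progress, 8 points over 4 min including t = 0.
#' @param replicates number of replicates per x.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return a [bulk_dataset()].
#' @export
generate_bulk_dataset <- function(kind = c("mm", "activation", "progress"),
                                  params = NULL, design = NULL,
                                  replicates = 3L, noise_cv = 0.03,
                                  seed = 1L) {
  kind <- match.arg(kind)
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (is.null(params))
    params <- switch(kind, mm = bulk_profile("atpase_mm"),
                     activation = bulk_profile("atpase_activation"),
                     progress = bulk_profile("displacement"))
  if (is.null(design))
    design <- switch(kind,
      mm = exp(seq(log(50), log(2000), length.out = 8)),
      activation = c(0, 0.5, 1, 2, 4, 8, 14, 20),
      progress = seq(0, 4, length.out = 8))
  set.seed(as.integer(seed))
  x <- rep(design, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(design))
  mu <- .bulk_model(kind, x, params)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else noise <- rep(1, length(x))
  y <- mu * noise
  if (kind == "progress") y <- pmin(y, 1)
  bulk_dataset(kind, x, y, rep_id)
}

.check_kind <- function(d, kind) {
  stopifnot(inherits(d, "bulk_dataset"))
  if (!all(d$kind == kind))
    stop("expected a '", kind, "' dataset, got '", d$kind[1], "'")
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least squares of `v = kcat * S / (Km + S)` to
#' rate-vs-substrate data (rates already normalised per enzyme).
#'
#' @param d a [bulk_dataset()] of kind `"mm"` with at least 4 distinct
#'   substrate concentrations.
#' @return A `fit_result` with parameters `kcat` (1/s) and `Km` (µM).
#' @export
fit_michaelis_menten <- function(d) {
  .check_kind(d, "mm")
  if (length(unique(d$x)) < 4)
    stop("need at least 4 distinct substrate concentrations")
  kcat0 <- max(d$y); km0 <- stats::median(d$x)
  fit <- minpack.lm::nlsLM(y ~ kcat * x / (Km + x), data = d,
                           start = list(kcat = kcat0, Km = km0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  s <- summary(fit)$coefficients
  if (max(d$x) < 2 * s["Km", "Estimate"])
    warning("substrate range does not span Km: estimates poorly constrained")
  est <- list(kcat = s["kcat", "Estimate"], Km = s["Km", "Estimate"])
  se <- list(kcat = s["kcat", "Std. Error"], Km = s["Km", "Std. Error"])
  .fit_result("michaelis-menten", est, se,
              as.numeric(stats::logLik(fit)), NA_real_, nrow(d))
}

#' Fit hyperbolic DNA activation of the ATPase
#'
#' `v = basal + (Vmax - basal) * [DNA] / (K_DNA + [DNA])`, requiring a
#' zero-DNA point to pin the basal turnover.
#'
#' @param d a [bulk_dataset()] of kind `"activation"` including x = 0.
#' @return A `fit_result` with parameters `basal`, `Vmax` (1/s) and
#'   `K_DNA` (µM nucleotides).
#' @export
fit_activation <- function(d) {
  .check_kind(d, "activation")
  if (!any(d$x == 0))
    stop("activation fit requires a zero-DNA point")
  if (all(d$x == 0)) {
    warning("all DNA concentrations are zero: degenerate basal-only fit")
    m <- mean(d$y)
    return(.fit_result("activation",
                       list(basal = m, Vmax = NA_real_, K_DNA = NA_real_),
                       list(basal = stats::sd(d$y) / sqrt(nrow(d)),
                            Vmax = NA_real_, K_DNA = NA_real_),
                       NA_real_, NA_real_, nrow(d)))
  }
  b0 <- mean(d$y[d$x == 0]); v0 <- max(d$y)
  k0 <- stats::median(d$x[d$x > 0])
  fit <- minpack.lm::nlsLM(y ~ basal + (Vmax - basal) * x / (K + x),
                           data = d,
                           start = list(basal = b0, Vmax = v0, K = k0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  s <- summary(fit)$coefficients
  est <- list(basal = s["basal", "Estimate"], Vmax = s["Vmax", "Estimate"],
              K_DNA = s["K", "Estimate"])
  se <- list(basal = s["basal", "Std. Error"],
             Vmax = s["Vmax", "Std. Error"], K_DNA = s["K", "Std. Error"])
  .fit_result("activation", est, se, as.numeric(stats::logLik(fit)),
              NA_real_, nrow(d))
}

#' Fit a single-exponential progress curve
#'
#' `fraction(t) = A * (1 - exp(-kobs * t))`, the standard model for
#' streptavidin-displacement and strand-displacement time courses.
#'
#' @param d a [bulk_dataset()] of kind `"progress"` with >= 5 timepoints
#'   including t = 0.
#' @return A `fit_result` with parameters `kobs` (1/min) and `amplitude`.
#' @export
fit_progress_curve <- function(d) {
  .check_kind(d, "progress")
  if (length(unique(d$x)) < 5) stop("need at least 5 timepoints")
  if (!any(d$x == 0)) stop("progress fit requires a t = 0 point")
  # flag gross non-monotone outliers against a smoothed trend
  med <- stats::aggregate(y ~ x, data = d, FUN = stats::median)
  if (any(diff(med$y[order(med$x)]) < -0.25))
    warning("progress curve is grossly non-monotone; check for outliers")
  a0 <- max(d$y); k0 <- 1 / max(stats::median(d$x), 1e-6)
  fit <- minpack.lm::nlsLM(y ~ A * (1 - exp(-k * x)), data = d,
                           start = list(A = a0, k = k0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  s <- summary(fit)$coefficients
  est <- list(kobs = s["k", "Estimate"], amplitude = s["A", "Estimate"])
  se <- list(kobs = s["k", "Std. Error"], amplitude = s["A", "Std. Error"])
  .fit_result("progress", est, se, as.numeric(stats::logLik(fit)),
              NA_real_, nrow(d))
}

#' Iron-chelation assay configuration
#'
#' Beer-Lambert and dilution bookkeeping for the ferrous-iron chelation
#' assay: a small protein aliquot is acid-denatured and the chelator
#' complex read at 535 nm in a larger neutralised volume.
#'
#' @param epsilon_535 chelator-complex extinction coefficient, 1/(M cm).
#' @param path_length cuvette path, cm.
#' @param protein_volume_ul protein aliquot volume, µl.
#' @param assay_volume_ul final assay volume, µl.
#' @param protein_conc_uM protein stock concentration, µM.
#' @param protein_epsilon_280 protein extinction coefficient, 1/(M cm).
#' @return An object of class `iron_assay_config`.
#' @export
iron_assay_config <- function(epsilon_535 = 22369, path_length = 1,
                              protein_volume_ul = 10, assay_volume_ul = 143,
                              protein_conc_uM = 15,
                              protein_epsilon_280 = 195960) {
  stopifnot(epsilon_535 > 0, path_length > 0, protein_volume_ul > 0,
            assay_volume_ul >= protein_volume_ul, protein_epsilon_280 > 0)
  if (protein_conc_uM <= 0)
    stop("protein concentration must be strictly positive")
  structure(list(epsilon_535 = epsilon_535, path_length = path_length,
                 protein_volume_ul = protein_volume_ul,
                 assay_volume_ul = assay_volume_ul,
                 protein_conc_uM = protein_conc_uM,
                 protein_epsilon_280 = protein_epsilon_280),
            class = "iron_assay_config")
}

#' Iron stoichiometry from chelation-assay absorbance
#'
#' Converts A535 to the iron concentration in the assay by Beer-Lambert,
#' rescales by the aliquot dilution, and divides by the protein stock
#' concentration to give mol Fe per mol protein.
#'
#' @param a535 absorbance at 535 nm (>= 0).
#' @param cfg an [iron_assay_config()].
#' @return mol iron per mol protein.
#' @export
iron_per_protein <- function(a535, cfg = iron_assay_config()) {
  stopifnot(inherits(cfg, "iron_assay_config"))
  if (!is.numeric(a535) || any(!is.finite(a535)) || any(a535 < 0))
    stop("a535 must be finite and >= 0")
  fe_assay_M <- a535 / (cfg$epsilon_535 * cfg$path_length)
  fe_stock_M <- fe_assay_M * cfg$assay_volume_ul / cfg$protein_volume_ul
  fe_stock_M / (cfg$protein_conc_uM * 1e-6)
}
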