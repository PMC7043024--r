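#' Published condition table for the two reactions
#'
#' Post-equilibrium apparent parameters and unimolecular exchange
#' parameters for the demethylation of K4meK9 and the deacetylation of
#' K4K9ac under the four conditions (apo complex, 2-PCPA-inhibited,
#' MS275-inhibited, InsP6-activated).  Values where only an upper bound
#' was reported (`kex(E)` for 2-PCPA demethylation and apo deacetylation)
#' are stored as the bound itself with `NA` error.  MS275 deacetylation
#' has no reliable parameters and is absent.
#'
#' @return A data.frame with one row per supported (reaction, condition).
#' @export
condition_table <- function() {
  tab <- rbind(
    data.frame(reaction = "demethylation",
               condition = c("APO", "PCPA", "MS275", "InsP6"),
               kcat_post = c(0.032, 0.0077, 0.023, 0.093),
               kcat_post_err = c(0.002, 0.0012, 0.003, 0.007),
               KM_post = c(2.3, 26, 9.2, 190),
               KM_post_err = c(1.7, 5, 1.6, 30),
               efficiency = c(14, 0.30, 2.5, 0.48),
               efficiency_err = c(7, 0.02, 0.4, 0.04),
               Keq_E = c(7.0, 7.4, 1.7, 3.0),
               Keq_E_err = c(2.4, 0.5, 0.6, 0.3),
               kex_E = c(0.0074, 5e-4, 0.0028, 0.0015),
               kex_E_err = c(0.0024, NA, 0.0015, 0.0013),
               Keq_ES = c(76, 129, 146, 49),
               Keq_ES_err = c(28, 30, 38, 4),
               kex_ES = c(0.0055, 0.0050, 0.0060, 0.047),
               kex_ES_err = c(0.0012, 0.0008, 0.0024, 0.020)),
    data.frame(reaction = "deacetylation",
               condition = c("APO", "PCPA", "InsP6"),
               kcat_post = c(0.70, 0.52, 0.78),
               kcat_post_err = c(0.03, 0.05, 0.18),
               KM_post = c(33, 22, 12),
               KM_post_err = c(6, 4, 5),
               efficiency = c(21, 23, 70),
               efficiency_err = c(2, 3, 50),
               Keq_E = c(6.8, 5.5, 1.9),
               Keq_E_err = c(2.3, 2.2, 2.1),
               kex_E = c(1e-7, 0.0031, 0.14),
               kex_E_err = c(NA, 0.0017, 0.17),
               Keq_ES = c(2560, 280, 1990),
               Keq_ES_err = c(1620, 220, 1600),
               kex_ES = c(0.077, 0.0028, 0.09),
               kex_ES_err = c(0.042, 0.0016, 0.07)))
  tab
}

#' Experimental design of a real-time NMR progression series
#'
#' Describes one acquisition campaign: a set of initial substrate
#' concentrations (one progression curve each), enzyme concentration,
#' sampling interval (one 1D spectrum per `interval` seconds), total
#' duration, deadtime between enzyme addition and the first spectrum, and
#' the additive concentration noise of the quantification.
#'
#' Defaults mirror the study design: substrate 50-800 uM, enzyme
#' 0.05-0.2 uM, 61 s per spectrum, ~80 s deadtime, sigma = 1 uM.  Values
#' outside the customary ranges are allowed but draw a warning.
#'
#' @param substrate substrate id: `"K4meK9"`, `"K4K9ac"` or `"K4meK9ac"`.
#' @param S0 numeric vector of initial substrate concentrations, uM.
#' @param E0 enzyme (complex) concentration, uM.
#' @param interval sampling interval, s.
#' @param duration total observed duration, s.
#' @param deadtime reaction age at the first observed point, s.
#' @param sigma additive concentration noise sd, uM.
#' @param seed integer seed making generated noise reproducible.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(substrate = c("K4meK9", "K4K9ac", "K4meK9ac"),
                              S0, E0 = 0.2, interval = 61, duration,
                              deadtime = 80, sigma = 1, seed = 1L) {
  substrate <- match.arg(substrate)
  stopifnot(length(S0) >= 1, all(S0 > 0), E0 > 0, interval > 0,
            duration > interval, deadtime >= 0, sigma >= 0)
  if (any(S0 < 50 | S0 > 800))
    warning("S0 outside the customary 50-800 uM design range")
  if (E0 < 0.05 || E0 > 0.2)
    warning("E0 outside the customary 0.05-0.2 uM design range")
  structure(list(substrate = substrate, S0 = as.numeric(S0), E0 = E0,
                 interval = interval, duration = duration,
                 deadtime = deadtime, sigma = sigma,
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %s: S0 = {%s} uM, E0 = %g uM\n",
              x$substrate, paste(x$S0, collapse = ", "), x$E0))
  cat(sprintf("  every %g s for %g s, deadtime %g s, sigma %g uM, seed %d\n",
              x$interval, x$duration, x$deadtime, x$sigma, x$seed))
  invisible(x)
}

# run code with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate noisy progression curves for one experiment
#'
#' Simulates the design's noise-free curves from the ground-truth rate
#' parameters and adds i.i.d. Gaussian noise of sd `design$sigma` to every
#' observed concentration.  Deterministic given `design$seed`; the truth
#' is attached so parameter-recovery tests can compare against it.
#'
#' @param design an [experiment_design()].
#' @param truth a [rate_params()] object (single-substrate scheme), or a
#'   named list of them (`me`, `ac`, optionally `dme`, `dac`) for the
#'   coupled dual-substrate scheme.
#' @param ... passed to [build_coupled_scheme()] when `truth` is a list
#'   (occupancy/tie flags), and on to the integrator.
#' @return A list of `progression_curve`s (one per `design$S0` value) with
#'   attributes `truth`, `design`.
#' @export
make_experiment <- function(design, truth, ...) {
  stopifnot(inherits(design, "experiment_design"))
  t_grid <- seq(0, design$duration, by = design$interval)
  if (inherits(truth, "rate_params")) {
    scheme <- build_single_substrate_scheme(truth)
    make_S0 <- function(s0) s0
  } else {
    scheme <- build_coupled_scheme(truth$me, truth$ac, truth$dme, truth$dac, ...)
    make_S0 <- function(s0) stats::setNames(s0, design$substrate)
  }
  curves <- with_seed(design$seed, lapply(design$S0, function(s0) {
    cv <- progression_curve(scheme, make_S0(s0), design$E0, t_grid,
                            deadtime = design$deadtime,
                            method = "rosenbrock", rel_tol = 1e-9,
                            abs_tol = 1e-11)
    if (design$sigma > 0) {
      obs <- setdiff(names(cv), "time_s")
      for (sp in obs)
        cv[[sp]] <- cv[[sp]] + stats::rnorm(nrow(cv), sd = design$sigma)
    }
    attr(cv, "sigma") <- design$sigma
    if (!inherits(truth, "rate_params")) attr(cv, "substrate") <- design$substrate
    cv
  }))
  structure(curves, truth = truth, design = design)
}

#' Ground-truth fixtures reproducing the published parameter regimes
#'
#' Returns an [experiment_design()] matching the figure conditions
#' (demethylation: S0 = 300 and 80 uM with 200 nM enzyme; deacetylation:
#' S0 = 660 and 100 uM with 50 nM enzyme) and a micro-kinetic
#' [rate_params()] set constructed by inverting the closed-form apparent
#' and exchange expressions so that `apparent_post_params()` and the
#' Keq/kex pairs reproduce the condition's printed values exactly.
#'
#' The inversion has one free degree of freedom.  It is resolved by a
#' reaction-level rule: for demethylation the alternate complex is
#' catalytically dead (`kcat_Estar = 0`); for deacetylation both states
#' catalyse at the apparent rate (`kcat_E = kcat_Estar = kcat_app`).  The
#' ES dissociation rate then follows from `k_off = k1 KM_E - kcat_E`; a
#' user-supplied `k_off` inside the feasible interval overrides the rule.
#'
#' @param condition `"APO"`, `"PCPA"`, `"MS275"` or `"InsP6"`.
#' @param reaction `"demethylation"` or `"deacetylation"`.
#' @param k_off optional ES dissociation rate, s^-1, overriding the
#'   default rule (must keep both catalytic rates non-negative).
#' @param sigma,seed forwarded to the design.
#' @return A list with elements `design`, `params` and `printed` (the
#'   condition's table row).
#' @export
paperlike_fixture <- function(condition = c("APO", "PCPA", "MS275", "InsP6"),
                              reaction = c("demethylation", "deacetylation"),
                              k_off = NULL, sigma = 1, seed = 1L) {
  condition <- match.arg(condition)
  reaction <- match.arg(reaction)
  tab <- condition_table()
  row <- tab[tab$reaction == reaction & tab$condition == condition, ]
  if (nrow(row) == 0L)
    stop("unsupported condition: no reliable parameters for ", condition,
         " ", reaction, call. = FALSE)
  params <- invert_apparent(
    KM_app = row$KM_post, kcat_app = row$kcat_post,
    Keq_E = row$Keq_E, kex_E = row$kex_E,
    Keq_ES = row$Keq_ES, kex_ES = row$kex_ES,
    dead_alternate = reaction == "demethylation", k_off = k_off)
  if (reaction == "demethylation") {
    S0 <- c(300, 80); E0 <- 0.2; substrate <- "K4meK9"
  } else {
    S0 <- c(660, 100); E0 <- 0.05; substrate <- "K4K9ac"
  }
  # duration: ~95% conversion of the largest S0 under the apparent
  # Michaelis-Menten limit (the post-depletion tail carries the KM
  # information), rounded to whole sampling intervals
  t95 <- (0.95 * max(S0) + row$KM_post * log(20)) / (row$kcat_post * E0)
  duration <- min(ceiling(1.1 * t95 / 61) * 61, 64000)
  design <- experiment_design(substrate = substrate, S0 = S0, E0 = E0,
                              interval = 61, duration = duration,
                              deadtime = 80, sigma = sigma, seed = seed)
  list(design = design, params = params, printed = row)
}

#' Spectral peak definition
#'
#' A mixed Gaussian/Lorentzian peak: unit-height shape
#' `f * Gaussian + (1 - f) * Lorentzian`, both with common full width at
#' half maximum `width_hz`, scaled by `response` intensity units per uM of
#' the reporting species.
#'
#' @param center chemical shift, ppm.
#' @param width_hz full width at half maximum, Hz.
#' @param gaussian_fraction mixing fraction f in `[0, 1]`.
#' @param response peak height per uM.
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, width_hz, gaussian_fraction = 0.5, response = 1) {
  stopifnot(width_hz > 0, gaussian_fraction >= 0, gaussian_fraction <= 1,
            response > 0)
  structure(list(center = center, width_hz = width_hz,
                 gaussian_fraction = gaussian_fraction, response = response),
            class = "peak_spec")
}

# unit-height mixed lineshape on a ppm axis
mixed_lineshape <- function(ppm, center, fwhm_ppm, f) {
  u <- 2 * (ppm - center) / fwhm_ppm
  f * exp(-log(2) * u^2) + (1 - f) / (1 + u^2)
}

# analytic area (in Hz x intensity) of the unit-height mixed lineshape
lineshape_area_factor <- function(width_hz, f) {
  width_hz * (f * sqrt(pi) / (2 * sqrt(log(2))) + (1 - f) * pi / 2)
}

#' Generate a synthetic pseudo-2D spectral series from progression curves
#'
#' Each time slice is the sum of the species' mixed Gaussian/Lorentzian
#' peaks with height `response * concentration(t)` plus white noise.  Peak
#' shape parameters are constant across the series, emulating a time
#' series in which lineshape and position do not change.
#'
#' @param curve a `progression_curve` whose species columns drive the peaks.
#' @param peaks named list of [peak_spec()]s; names must be species
#'   columns of `curve`.
#' @param noise_sd white-noise sd in intensity units.
#' @param seed RNG seed for the noise.
#' @param ppm ppm axis (decreasing, NMR convention).
#' @param field_mhz spectrometer frequency used to convert Hz to ppm.
#' @return A `spectrum_series`: list with `ppm`, `intensity`
#'   (length(ppm) x n_times matrix), `times`, `field_mhz`.
#' @export
synth_spectrum_series <- function(curve, peaks, noise_sd = 0, seed = 1L,
                                  ppm = seq(2.4, 1.4, length.out = 2048),
                                  field_mhz = 500) {
  stopifnot(inherits(curve, "progression_curve"), length(peaks) >= 1)
  if (is.null(names(peaks)) || !all(names(peaks) %in% names(curve)))
    stop("peaks must be named by species columns of the curve", call. = FALSE)
  if (is.unsorted(rev(ppm), strictly = TRUE))
    stop("ppm axis must be strictly decreasing", call. = FALSE)
  nt <- nrow(curve)
  inten <- matrix(0, length(ppm), nt)
  for (sp in names(peaks)) {
    pk <- peaks[[sp]]
    shape <- mixed_lineshape(ppm, pk$center, pk$width_hz / field_mhz,
                             pk$gaussian_fraction)
    inten <- inten + outer(shape, pk$response * curve[[sp]])
  }
  if (noise_sd > 0)
    inten <- inten + with_seed(seed,
      matrix(stats::rnorm(length(inten), sd = noise_sd), nrow(inten)))
  structure(list(ppm = ppm, intensity = inten, times = curve$time_s,
                 field_mhz = field_mhz, peaks = peaks),
            class = "spectrum_series")
}

#' Read and write spectrum series as a delimited matrix plus JSON sidecar
#'
#' The main file is tab-separated with the ppm axis in the first column
#' and one intensity column per time point; acquisition times and the
#' field strength go to `<path>.meta.json`.
#'
#' @param series a `spectrum_series`.
#' @param path file path for the matrix.
#' @export
write_spectrum_series <- function(series, path) {
  stopifnot(inherits(series, "spectrum_series"))
  df <- data.frame(ppm = series$ppm, series$intensity)
  names(df) <- c("ppm", sprintf("t%d", seq_along(series$times)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(times = series$times,
                            field_mhz = series$field_mhz),
                       paste0(path, ".meta.json"), digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_series
#' @export
read_spectrum_series <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  structure(list(ppm = df$ppm,
                 intensity = as.matrix(df[, -1, drop = FALSE]),
                 times = meta$times, field_mhz = meta$field_mhz),
            class = "spectrum_series")
}
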