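#' Micro-kinetic rate constants for the alternate-state (E/E*) scheme
#'
#' One enzyme's full parameterization of the two-state reaction scheme in
#' which both the free enzyme (E/E*) and the enzyme-substrate complex
#' (ES/E*S) interconvert slowly between a ground and an alternate state
#' with distinct catalytic and dissociation rates.  Units are seconds,
#' micromolar and s^-1 throughout; the second-order association rate `k1`
#' is in s^-1 uM^-1 (the diffusion-limited default 0.2 s^-1 uM^-1 equals
#' 200,000 s^-1 M^-1).
#'
#' The scheme is circular (E -> ES -> E*S -> E* -> E), so only seven of the
#' eight first-order rates are independent: the dissociation rate of E*S
#' (`k_off_star`) is always derived by [cycle_closure()] and is never an
#' independent parameter.
#'
#' @param kcat_E catalytic rate from ES, s^-1.
#' @param k_off substrate dissociation rate from ES (k_-1), s^-1.
#' @param kE_fwd,kE_rev free-enzyme exchange rates E -> E* and E* -> E, s^-1.
#' @param kES_fwd,kES_rev complex exchange rates ES -> E*S and E*S -> ES, s^-1.
#' @param kcat_Estar catalytic rate from E*S, s^-1 (0 for a catalytically
#'   dead alternate complex).
#' @param k1 second-order association rate shared by E+S and E*+S,
#'   s^-1 uM^-1.
#' @return An object of class `rate_params`.
#' @seealso [cycle_closure()], [michaelis_constants()], [apparent_post_params()]
#' @export
rate_params <- function(kcat_E, k_off, kE_fwd, kE_rev, kES_fwd, kES_rev,
                        kcat_Estar = 0, k1 = 0.2) {
  p <- list(k1 = k1, k_off = k_off, kcat_E = kcat_E,
            kcat_Estar = kcat_Estar, kE_fwd = kE_fwd, kE_rev = kE_rev,
            kES_fwd = kES_fwd, kES_rev = kES_rev)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("rate '", nm, "' must be a single non-negative number", call. = FALSE)
  }
  structure(p, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>  (s, uM units)\n")
  cat(sprintf("  k1        = %g s^-1 uM^-1   k_off     = %g s^-1\n", x$k1, x$k_off))
  cat(sprintf("  kcat_E    = %g s^-1        kcat_E*   = %g s^-1\n",
              x$kcat_E, x$kcat_Estar))
  cat(sprintf("  E <-> E*  : %g / %g s^-1 (Keq %.4g)\n",
              x$kE_fwd, x$kE_rev,
              if (x$kE_rev > 0) x$kE_fwd / x$kE_rev else NA_real_))
  cat(sprintf("  ES<-> E*S : %g / %g s^-1 (Keq %.4g)\n",
              x$kES_fwd, x$kES_rev,
              if (x$kES_rev > 0) x$kES_fwd / x$kES_rev else NA_real_))
  if (x$kE_rev > 0 && x$kES_fwd > 0)
    cat(sprintf("  k_off* (cycle closure) = %g s^-1\n", cycle_closure(x)))
  invisible(x)
}

#' Thermodynamic cycle closure: derived dissociation rate of E*S
#'
#' The reaction scheme is a closed cycle E -> ES -> E*S -> E* -> E, so the
#' products of rate constants around the cycle must be equal in the two
#' directions for the scheme to admit an equilibrium (detailed balance).
#' This fixes the dissociation rate of the alternate complex:
#' `k_off_star = Keq(E)/Keq(ES) * k_off`, with `Keq(E) = kE_fwd/kE_rev`
#' and `Keq(ES) = kES_fwd/kES_rev`.
#'
#' @param params a [rate_params()] object.
#' @return The derived E*S dissociation rate, s^-1.
#' @export
cycle_closure <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  if (params$k_off == 0) return(0)
  if (params$kE_rev <= 0)
    stop("degenerate cycle: kE_rev is zero, Keq(E) undefined", call. = FALSE)
  if (params$kES_fwd <= 0)
    stop("degenerate cycle: kES_fwd is zero, Keq(ES) undefined", call. = FALSE)
  keq_E <- params$kE_fwd / params$kE_rev
  keq_ES <- params$kES_fwd / params$kES_rev
  keq_E / keq_ES * params$k_off
}

#' Equilibrium constant / exchange rate parameterization
#'
#' A slow unimolecular two-site exchange is reported as a dimensionless
#' equilibrium constant `Keq = k_fwd/k_rev` and an exchange rate
#' `kex = k_fwd + k_rev` (the NMR convention).  `eq_params()` bundles the
#' pair; [eq_to_rates()] and [rates_to_eq()] convert losslessly between the
#' (Keq, kex) and (forward, reverse) parameterizations.
#'
#' @param Keq equilibrium constant, dimensionless, > 0.
#' @param kex exchange rate (sum of forward and reverse rates), s^-1.
#' @return An object of class `eq_params`.
#' @export
eq_params <- function(Keq, kex) {
  if (!is.numeric(Keq) || length(Keq) != 1L || is.na(Keq) || Keq <= 0)
    stop("Keq must be a single positive number", call. = FALSE)
  if (!is.numeric(kex) || length(kex) != 1L || is.na(kex) || kex < 0)
    stop("kex must be a single non-negative number", call. = FALSE)
  structure(list(Keq = Keq, kex = kex), class = "eq_params")
}

#' @rdname eq_params
#' @param eq an `eq_params` object.
#' @return `eq_to_rates()`: named numeric `c(forward, reverse)` in s^-1.
#' @export
eq_to_rates <- function(eq) {
  stopifnot(inherits(eq, "eq_params"))
  c(forward = eq$kex * eq$Keq / (1 + eq$Keq),
    reverse = eq$kex / (1 + eq$Keq))
}

#' @rdname eq_params
#' @param forward,reverse forward and reverse first-order rates, s^-1.
#' @return `rates_to_eq()`: the corresponding `eq_params`.
#' @export
rates_to_eq <- function(forward, reverse) {
  if (reverse <= 0) stop("reverse rate must be positive", call. = FALSE)
  eq_params(Keq = forward / reverse, kex = forward + reverse)
}

#' State-specific Michaelis constants of the two enzyme forms
#'
#' `KM_E = (kcat_E + k_off) / k1` for the ground state and
#' `KM_Estar = (kcat_Estar + k_off * Keq(E)/Keq(ES)) / k1` for the
#' alternate state (whose dissociation rate is the cycle-closed
#' `k_off_star`).
#'
#' @inheritParams cycle_closure
#' @return Named numeric `c(KM_E, KM_Estar)` in uM.
#' @export
michaelis_constants <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  if (params$k1 <= 0) stop("k1 must be positive", call. = FALSE)
  KM_E <- (params$kcat_E + params$k_off) / params$k1
  k_off_star <- if (params$k_off == 0) 0 else cycle_closure(params)
  KM_Estar <- (params$kcat_Estar + k_off_star) / params$k1
  c(KM_E = KM_E, KM_Estar = KM_Estar)
}

#' Post-equilibrium apparent Michaelis-Menten parameters
#'
#' Once the E/E* and ES/E*S exchange has equilibrated (t >> 1/kex), the
#' two-state scheme behaves like a single-enzyme Michaelis-Menten system
#' with apparent parameters
#' `KM_app = KM_E * (1 + Keq(E)) / (1 + Keq(ES))` and
#' `kcat_app = (kcat_E + Keq(ES) * kcat_Estar) / (1 + Keq(ES))`.
#' The catalytic form used here is algebraically identical to the
#' `kcat_E (1 + Keq(ES) kcat_Estar / kcat_E) / (1 + Keq(ES))` expression
#' but remains defined when `kcat_E = 0`.  These parameters are only valid
#' as a long-time limit, after exchange equilibrium has fully been reached.
#'
#' @inheritParams cycle_closure
#' @return An object of class `apparent_params`: a list with `KM_app` (uM),
#'   `kcat_app` (s^-1), and `efficiency` (`kcat_app/KM_app`, s^-1 mM^-1).
#' @export
apparent_post_params <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  if (params$kE_rev <= 0 || params$kES_rev <= 0)
    stop("apparent parameters require positive reverse exchange rates",
         call. = FALSE)
  keq_E <- params$kE_fwd / params$kE_rev
  keq_ES <- params$kES_fwd / params$kES_rev
  KM_E <- michaelis_constants(params)[["KM_E"]]
  KM_app <- KM_E * (1 + keq_E) / (1 + keq_ES)
  kcat_app <- (params$kcat_E + keq_ES * params$kcat_Estar) / (1 + keq_ES)
  apparent_params(KM_app, kcat_app)
}

#' @rdname apparent_post_params
#' @param KM_app apparent Michaelis constant, uM.
#' @param kcat_app apparent catalytic rate, s^-1.
#' @export
apparent_params <- function(KM_app, kcat_app) {
  if (KM_app < 0 || kcat_app < 0)
    stop("apparent parameters must be non-negative", call. = FALSE)
  structure(list(KM_app = KM_app, kcat_app = kcat_app,
                 # uM -> mM conversion: kcat/KM in s^-1 mM^-1
                 efficiency = if (KM_app > 0) kcat_app / KM_app * 1000 else NA_real_),
            class = "apparent_params")
}

#' @export
print.apparent_params <- function(x, ...) {
  cat(sprintf("<apparent_params> KM_app = %.4g uM, kcat_app = %.4g s^-1, kcat/KM = %.4g s^-1 mM^-1\n",
              x$KM_app, x$kcat_app, x$efficiency))
  invisible(x)
}

#' Short-time initial rate of the two-state scheme
#'
#' At times short compared with 1/kex, the E and E* pools convert substrate
#' independently with the pre-equilibrated population split
#' `p_E = 1/(1 + Keq(E))`.  Under a quasi-steady-state assumption for both
#' ES and E*S the initial rate is
#' \deqn{v_0 = \frac{E_0}{1+K_{eq}(E)}\;
#'   \frac{k_{cat,E} + k_{cat,E^*} K_{eq}(E)}
#'        {1 + K_{M,E}/S + K_{M,E^*}/S + K_{M,E}K_{M,E^*}/S^2}.}
#' Unlike the long-time limit this cannot be cast in Michaelis-Menten form.
#' The expression is used verbatim; its large-S limit is the
#' population-weighted catalytic rate
#' `E0 (kcat_E + kcat_Estar Keq(E)) / (1 + Keq(E))`.
#'
#' @inheritParams cycle_closure
#' @param S substrate concentration(s), uM (> 0); vectorized.
#' @param E0 total enzyme concentration, uM.
#' @return Initial rate(s) `v0` in uM s^-1.
#' @export
initial_rate_short_time <- function(params, S, E0) {
  stopifnot(inherits(params, "rate_params"))
  if (any(S <= 0)) stop("S must be positive", call. = FALSE)
  if (E0 < 0) stop("E0 must be non-negative", call. = FALSE)
  keq_E <- if (params$kE_fwd == 0 && params$kE_rev == 0) 0
           else params$kE_fwd / params$kE_rev
  km <- michaelis_constants(params)
  num <- params$kcat_E + params$kcat_Estar * keq_E
  den <- 1 + km[["KM_E"]] / S + km[["KM_Estar"]] / S +
    km[["KM_E"]] * km[["KM_Estar"]] / S^2
  unname(E0 / (1 + keq_E) * num / den)
}

#' Read and write rate parameters as JSON
#'
#' Rates are keyed by their conventional symbols: `k1`, `k_m1` (k_-1),
#' `kcat_E`, `kcat_Estar`, `kE`, `k_mE`, `kES`, `k_mES`.
#'
#' @param params a [rate_params()] object.
#' @param path file path.
#' @return `read_rate_params()` returns a `rate_params` object;
#'   `write_rate_params()` returns `path` invisibly.
#' @export
write_rate_params <- function(params, path) {
  stopifnot(inherits(params, "rate_params"))
  out <- list(k1 = params$k1, k_m1 = params$k_off,
              kcat_E = params$kcat_E, kcat_Estar = params$kcat_Estar,
              kE = params$kE_fwd, k_mE = params$kE_rev,
              kES = params$kES_fwd, k_mES = params$kES_rev)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rate_params
#' @export
read_rate_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("k1", "k_m1", "kcat_E", "kcat_Estar", "kE", "k_mE", "kES", "k_mES")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("rate file missing keys: ", paste(miss, collapse = ", "), call. = FALSE)
  rate_params(k1 = x$k1, k_off = x$k_m1, kcat_E = x$kcat_E,
              kcat_Estar = x$kcat_Estar, kE_fwd = x$kE, kE_rev = x$k_mE,
              kES_fwd = x$kES, kES_rev = x$k_mES)
}

# Internal: modify a rate_params with a named list of replacements.
update_rates <- function(params, new) {
  p <- unclass(params)
  for (nm in names(new)) {
    if (!nm %in% names(p)) stop("unknown rate '", nm, "'", call. = FALSE)
    p[[nm]] <- new[[nm]]
  }
  do.call(rate_params, p[c("kcat_E", "k_off", "kE_fwd", "kE_rev",
                           "kES_fwd", "kES_rev", "kcat_Estar", "k1")])
}
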