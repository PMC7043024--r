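#' Construct micro-rates from apparent and exchange parameters
#'
#' Inverts the closed-form expressions for the post-equilibrium apparent
#' parameters: given (KM_app, kcat_app) and the two exchange pairs
#' (Keq(E), kex(E)) and (Keq(ES), kex(ES)), returns a cycle-closed
#' [rate_params()] whose [apparent_post_params()] reproduce the inputs
#' exactly.  The inversion is under-determined by one degree of freedom;
#' it is resolved by `dead_alternate`:
#' \itemize{
#'   \item `TRUE`: the alternate complex is catalytically dead
#'     (`kcat_Estar = 0`, the demethylation finding), so
#'     `kcat_E = kcat_app (1 + Keq(ES))`;
#'   \item `FALSE`: both states catalyse at the apparent rate
#'     (`kcat_E = kcat_Estar = kcat_app`, the deacetylation finding).
#' }
#' An explicit `k_off` (s^-1) overrides the rule; it must lie inside the
#' feasible interval that keeps both catalytic rates non-negative.
#'
#' @param KM_app apparent Michaelis constant, uM.
#' @param kcat_app apparent catalytic rate, s^-1.
#' @param Keq_E,kex_E free-enzyme exchange equilibrium constant and rate.
#' @param Keq_ES,kex_ES complex exchange equilibrium constant and rate.
#' @param dead_alternate resolve the free degree of freedom with a dead
#'   E*S (`TRUE`) or equal catalytic rates (`FALSE`).
#' @param k_off optional explicit ES dissociation rate, s^-1.
#' @param k1 association rate, s^-1 uM^-1.
#' @return A [rate_params()] object.
#' @export
invert_apparent <- function(KM_app, kcat_app, Keq_E, kex_E, Keq_ES, kex_ES,
                            dead_alternate = TRUE, k_off = NULL, k1 = 0.2) {
  kE <- eq_to_rates(eq_params(Keq_E, kex_E))
  kES <- eq_to_rates(eq_params(Keq_ES, kex_ES))
  KM_E <- KM_app * (1 + Keq_ES) / (1 + Keq_E)
  kcat_tot <- kcat_app * (1 + Keq_ES) # kcat_E + Keq_ES * kcat_Estar
  if (is.null(k_off)) {
    kcat_E <- if (dead_alternate) kcat_tot else kcat_app
    k_off <- k1 * KM_E - kcat_E
  } else {
    kcat_E <- k1 * KM_E - k_off
  }
  kcat_Estar <- (kcat_tot - kcat_E) / Keq_ES
  if (k_off < 0 || kcat_E < 0 || kcat_Estar < -1e-12)
    stop("infeasible inversion: feasible k_off interval is [",
         signif(max(0, k1 * KM_E - kcat_tot), 4), ", ", signif(k1 * KM_E, 4),
         "] s^-1", call. = FALSE)
  rate_params(kcat_E = kcat_E, k_off = k_off,
              kE_fwd = kE[["forward"]], kE_rev = kE[["reverse"]],
              kES_fwd = kES[["forward"]], kES_rev = kES[["reverse"]],
              kcat_Estar = max(kcat_Estar, 0), k1 = k1)
}

#' Rough post-equilibrium Michaelis-Menten prefit of progression curves
#'
#' Fits the integrated one-enzyme Michaelis-Menten model
#' `dS/dt = -kcat E0 S / (KM + S)` to the late portion of one or more
#' progression curves (each with a free effective starting concentration),
#' ignoring the pre-equilibrium burst.  This is a cheap, closed-model
#' estimate of (KM_app, kcat_app) used to seed grid searches of the full
#' alternate-state fit in apparent-parameter space.
#'
#' @param curves a `progression_curve` or list of them.
#' @param E0 enzyme concentration, uM (defaults to the curves' metadata).
#' @param t_burn initial time span to exclude, s (exchange relaxation).
#' @return List with `KM_app`, `kcat_app`, `S0_eff` (per curve), `ss`
#'   (residual sum of squares).
#' @export
estimate_apparent_mm <- function(curves, E0 = NULL, t_burn = 600) {
  if (inherits(curves, "progression_curve")) curves <- list(curves)
  if (is.null(E0)) E0 <- attr(curves[[1]], "E0")
  dat <- lapply(curves, function(cv) {
    keep <- cv$time_s >= t_burn
    list(t = cv$time_s[keep] - t_burn,
         y = cv[[attr(cv, "substrate")]][keep])
  })
  nc <- length(dat)
  obj <- function(theta) {
    KM <- exp(theta[1]); kcat <- exp(theta[2])
    ss <- 0
    for (i in seq_len(nc)) {
      s0 <- exp(theta[2 + i])
      pred <- mm_closed_form(dat[[i]]$t, s0, KM, kcat * E0)
      ss <- ss + sum((pred - dat[[i]]$y)^2)
    }
    ss
  }
  s0_init <- vapply(dat, function(d) max(d$y[1], 1e-3), numeric(1))
  theta0 <- log(c(10, 0.05, s0_init))
  opt <- stats::optim(theta0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(KM_app = exp(opt$par[1]), kcat_app = exp(opt$par[2]),
       S0_eff = exp(opt$par[3:(2 + nc)]), ss = opt$value)
}

# closed-form integrated Michaelis-Menten progression,
# S(t) = KM * W(exp(z)), z = S0/KM - Vmax t / KM + log(S0/KM)
mm_closed_form <- function(t, S0, KM, Vmax) {
  z <- S0 / KM - Vmax * t / KM + log(S0 / KM)
  KM * lambert_w_exp(z)
}

# solve w + log(w) = z (i.e. w = W(e^z)) by Newton iteration, vectorized
lambert_w_exp <- function(z) {
  w <- ifelse(z > 1, z - log(pmax(z, 1e-300)), exp(z - exp(z - 1)))
  w <- pmax(w, 1e-300)
  for (i in 1:50) {
    f <- w + log(w) - z
    w_new <- pmax(w - f * w / (w + 1), 1e-300)
    if (max(abs(w_new - w) / pmax(w_new, 1e-12)) < 1e-12) { w <- w_new; break }
    w <- w_new
  }
  w
}
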