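#' Regularized incomplete beta function
#'
#' In-package evaluation of `I_x(a, b)` by the standard continued-fraction
#' expansion (modified Lentz algorithm), with the symmetry
#' `I_x(a,b) = 1 - I_{1-x}(b,a)` applied for fast convergence.  This is
#' the primitive behind the F-distribution tail probabilities of
#' [f_test()]; it deliberately does not call `pbeta()` so the test suite
#' can use R's implementation as an independent oracle.
#'
#' @param x evaluation point(s) in `[0, 1]`; vectorized.
#' @param a,b positive shape parameters.
#' @return `I_x(a, b)`.
#' @export
inc_beta <- function(x, a, b) {
  stopifnot(a > 0, b > 0, all(x >= 0), all(x <= 1))
  vapply(x, inc_beta1, numeric(1), a = a, b = b)
}

inc_beta1 <- function(x, a, b) {
  if (x == 0) return(0)
  if (x == 1) return(1)
  lbt <- lgamma(a + b) - lgamma(a) - lgamma(b) + a * log(x) + b * log1p(-x)
  if (x < (a + 1) / (a + b + 2)) {
    exp(lbt) * beta_cf(a, b, x) / a
  } else {
    1 - exp(lbt) * beta_cf(b, a, 1 - x) / b
  }
}

# continued fraction for the incomplete beta (modified Lentz)
beta_cf <- function(a, b, x, max_iter = 500L, eps = 1e-15) {
  tiny <- 1e-300
  qab <- a + b; qap <- a + 1; qam <- a - 1
  c <- 1
  d <- 1 - qab * x / qap
  if (abs(d) < tiny) d <- tiny
  d <- 1 / d
  h <- d
  for (m in seq_len(max_iter)) {
    m2 <- 2 * m
    aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
    d <- 1 + aa * d; if (abs(d) < tiny) d <- tiny
    c <- 1 + aa / c; if (abs(c) < tiny) c <- tiny
    d <- 1 / d
    h <- h * d * c
    aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
    d <- 1 + aa * d; if (abs(d) < tiny) d <- tiny
    c <- 1 + aa / c; if (abs(c) < tiny) c <- tiny
    d <- 1 / d
    del <- d * c
    h <- h * del
    if (abs(del - 1) < eps) return(h)
  }
  warning("incomplete beta continued fraction did not converge")
  h
}

# upper tail of the F distribution via the incomplete beta
f_tail <- function(F, d1, d2) {
  if (F <= 0) return(1)
  inc_beta(d2 / (d2 + d1 * F), d2 / 2, d1 / 2)
}

#' F-test between nested least-squares fits
#'
#' Compares a restricted model (fewer free parameters, chi2_r at dof_r)
#' against a fuller nested model (chi2_f at dof_f < dof_r):
#' `F = ((chi2_r - chi2_f) / (dof_r - dof_f)) / (chi2_f / dof_f)`, with
#' the p-value from the F-distribution upper tail evaluated by the
#' in-package regularized incomplete beta function.  A restricted fit
#' that (numerically) beats the full one yields p = 1 with a warning.
#'
#' @param chi2_r,dof_r chi-square and degrees of freedom of the
#'   restricted model (or a `fit_result`, from which both are taken).
#' @param chi2_f,dof_f same for the full model.
#' @return A `model_comparison`: list with `F`, `df1`, `df2`, `p`,
#'   `chi2_r`, `chi2_f`, `dof_r`, `dof_f`.
#' @export
f_test <- function(chi2_r, dof_r, chi2_f, dof_f) {
  if (inherits(chi2_r, "fit_result")) {
    dof_r <- chi2_r$dof; chi2_r <- chi2_r$chi2
  }
  if (inherits(chi2_f, "fit_result")) {
    dof_f <- chi2_f$dof; chi2_f <- chi2_f$chi2
  }
  stopifnot(chi2_r >= 0, chi2_f >= 0)
  if (!(dof_r > dof_f) || dof_f <= 0)
    stop("models not nested: need dof_r > dof_f > 0 (got ", dof_r, ", ",
         dof_f, ")", call. = FALSE)
  d1 <- dof_r - dof_f
  d2 <- dof_f
  if (chi2_r < chi2_f) {
    warning("restricted chi2 below full chi2; p set to 1")
    F <- 0
    p <- 1
  } else {
    F <- ((chi2_r - chi2_f) / d1) / (chi2_f / d2)
    p <- f_tail(F, d1, d2)
  }
  structure(list(F = F, df1 = d1, df2 = d2, p = p, chi2_r = chi2_r,
                 chi2_f = chi2_f, dof_r = dof_r, dof_f = dof_f),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  cat(sprintf("  chi2: restricted %.6g (dof %d) vs full %.6g (dof %d)\n",
              x$chi2_r, x$dof_r, x$chi2_f, x$dof_f))
  invisible(x)
}

#' Condition summary in the published table layout
#'
#' Derives the post-equilibrium apparent parameters (kcat_post, KM_post,
#' efficiency) and the two exchange rows (Keq(E), kex(E), Keq(ES),
#' kex(ES)) from a converged single-substrate fit, with errors propagated
#' to the derived quantities by the first-order delta method from the
#' covariance matrix, or taken from bootstrap replicates when available.
#'
#' @param fit a converged `fit_result` on a single-group alternate-state
#'   scheme.
#' @param label condition label for the summary.
#' @return A `condition_summary`: data.frame with columns `quantity`,
#'   `value`, `error`.
#' @export
summarize_condition <- function(fit, label = "condition") {
  stopifnot(inherits(fit, "fit_result"))
  problem <- fit$problem
  derived <- function(values) {
    p <- apply_theta(problem, values)[[1]]
    app <- apparent_post_params(p)
    c(kcat_post = app$kcat_app, KM_post = app$KM_app,
      efficiency = app$efficiency,
      Keq_E = p$kE_fwd / p$kE_rev, kex_E = p$kE_fwd + p$kE_rev,
      Keq_ES = p$kES_fwd / p$kES_rev, kex_ES = p$kES_fwd + p$kES_rev)
  }
  vals <- derived(fit$values)
  err <- rep(NA_real_, length(vals))
  if (!is.null(fit$bootstrap)) {
    reps <- fit$bootstrap$replicates
    ok <- stats::complete.cases(reps)
    dmat <- t(apply(reps[ok, , drop = FALSE], 1, derived))
    err <- apply(dmat, 2, stats::sd)
  } else if (!is.null(fit$J)) {
    # delta method on the log-scale covariance
    A <- crossprod(fit$J)
    cov <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
    if (!is.null(cov)) {
      free_nm <- fit$theta_names[fit$free_mask]
      grad <- matrix(0, length(vals), length(free_nm))
      h <- 1e-5
      for (j in seq_along(free_nm)) {
        v2 <- fit$values
        v2[free_nm[j]] <- v2[free_nm[j]] * exp(h) # step in log space
        grad[, j] <- (derived(v2) - vals) / h
      }
      err <- sqrt(pmax(diag(grad %*% cov %*% t(grad)), 0))
    }
  }
  structure(data.frame(quantity = names(vals), value = unname(vals),
                       error = err, row.names = NULL),
            label = label, class = c("condition_summary", "data.frame"))
}

#' Limiting-rate overlays for a progression curve
#'
#' Computes the two limiting descriptions shown against measured
#' progression curves: the short-time line `S0 - v0 t` with `v0` from
#' [initial_rate_short_time()] (valid before the ES/E*S exchange has
#' relaxed), and the long-time post-equilibrium curve obtained by
#' integrating the one-enzyme Michaelis-Menten system
#' `dS/dt = -kcat_app E0 S / (KM_app + S)` with the apparent parameters.
#'
#' @param params cycle-closed [rate_params()].
#' @param S0 initial substrate, uM.
#' @param E0 enzyme, uM.
#' @param t_grid times, s.
#' @return List with data.frames `initial` (dotted line) and `post`
#'   (dashed curve), each with `time_s` and `S`.
#' @export
limiting_overlays <- function(params, S0, E0, t_grid) {
  stopifnot(inherits(params, "rate_params"))
  v0 <- initial_rate_short_time(params, S0, E0)
  initial <- data.frame(time_s = t_grid, S = pmax(S0 - v0 * t_grid, 0))
  app <- apparent_post_params(params)
  # classic RK4 on the scalar MM rate law, substeps well below 1/v scale
  rate <- function(S) -app$kcat_app * E0 * S / (app$KM_app + S)
  S <- numeric(length(t_grid))
  s <- S0
  tprev <- t_grid[1]
  if (tprev > 0) s <- mm_rk4(rate, S0, 0, tprev)
  S[1] <- s
  for (i in seq_along(t_grid)[-1]) {
    s <- mm_rk4(rate, s, t_grid[i - 1], t_grid[i])
    S[i] <- s
  }
  list(initial = initial, post = data.frame(time_s = t_grid, S = pmax(S, 0)))
}

mm_rk4 <- function(rate, s, t0, t1, max_h = 5) {
  n <- max(1L, ceiling((t1 - t0) / max_h))
  h <- (t1 - t0) / n
  for (i in seq_len(n)) {
    k1 <- rate(s)
    k2 <- rate(s + h / 2 * k1)
    k3 <- rate(s + h / 2 * k2)
    k4 <- rate(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (s < 0) s <- 0
  }
  s
}
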