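#' Assemble a global progression-curve fitting problem
#'
#' Bundles one or more progression curves with a reaction-scheme builder,
#' the set of free micro-kinetic rates, bounds and the data uncertainty
#' into a least-squares problem whose chi-square is
#' `sum_{i,k} ([S]_calc(t_k; S0_i, k_j) - [S]_obs,i(t_k))^2 / sigma^2`,
#' the sum running over curves i and time points k.  All curves share the
#' rate constants of their parameter group; each curve contributes its own
#' free initial substrate concentration (the association rate `k1` is
#' fixed unless explicitly listed as free).
#'
#' Free parameters are optimized in log space (all are positive rates or
#' concentrations).  A parameter whose lower and upper bounds coincide is
#' pinned: it is fixed at that value and dropped from the free set.
#'
#' @param curves list of `progression_curve`s (attributes `E0`, `deadtime`,
#'   `substrate` are used; `S0` provides the starting value).
#' @param params a [rate_params()] template, or a named list of templates
#'   (parameter groups) for multi-substrate fits.
#' @param free character vector of free rate names (single group), or a
#'   named list mapping group to rate names.  Defaults to all seven
#'   independent rates with `k1` held fixed.
#' @param groups character vector assigning each curve to a parameter
#'   group (defaults to the single group).
#' @param builder `function(params_list, group)` returning the
#'   [kinetic_scheme()] used for curves of `group`; defaults to the
#'   single-substrate alternate-state scheme of that group's rates.
#' @param bounds length-2 numeric `c(lower, upper)` in natural units
#'   applied to every free parameter, or a named list of such pairs
#'   overriding individual parameters (equal pair = pinned).
#' @param sigma concentration uncertainty, uM (1 uM default).
#' @param fit_S0 free per-curve initial substrate concentrations?
#' @param include_products include product columns of each curve as extra
#'   residual blocks (same sigma)?  Default substrate-only.
#' @param rel_tol,abs_tol,method integrator settings for model evaluation
#'   (the stiff Rosenbrock stepper is the default in fits).
#' @return An object of class `fit_problem`.
#' @export
fit_problem <- function(curves, params,
                        free = c("k_off", "kcat_E", "kcat_Estar", "kE_fwd",
                                 "kE_rev", "kES_fwd", "kES_rev"),
                        groups = NULL, builder = NULL,
                        bounds = c(1e-7, 1e4), sigma = 1, fit_S0 = TRUE,
                        include_products = FALSE,
                        rel_tol = 1e-7, abs_tol = 1e-8,
                        method = "rosenbrock",
                        parameterization = c("micro", "apparent"),
                        dead_alternate = TRUE) {
  if (inherits(curves, "progression_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, "progression_curve")))
  parameterization <- match.arg(parameterization)
  single <- inherits(params, "rate_params")
  if (single) params <- list(main = params)
  stopifnot(all(vapply(params, inherits, TRUE, "rate_params")))
  if (parameterization == "apparent") {
    if (length(params) > 1L || !is.null(builder))
      stop("apparent parameterization requires a single parameter group ",
           "and the default scheme", call. = FALSE)
    free <- list(main = apparent_theta_names)
  }
  if (is.character(free)) {
    free <- stats::setNames(rep(list(free), length(params)), names(params))
  }
  legal <- if (parameterization == "apparent") apparent_theta_names
           else c("k1", "k_off", "kcat_E", "kcat_Estar",
                  "kE_fwd", "kE_rev", "kES_fwd", "kES_rev")
  for (g in names(free)) {
    bad <- setdiff(free[[g]], legal)
    if (length(bad))
      stop("unknown free rate(s): ", paste(bad, collapse = ", "), call. = FALSE)
    if (is.null(params[[g]]))
      stop("free set names unknown group '", g, "'", call. = FALSE)
  }
  if (is.null(groups)) groups <- rep(names(params)[1], length(curves))
  stopifnot(length(groups) == length(curves), all(groups %in% names(params)))
  per_group_builder <- is.null(builder)
  if (is.null(builder))
    builder <- function(p, g) build_single_substrate_scheme(p[[g]])

  if (is.numeric(bounds)) bounds <- list(.default = bounds)
  if (is.null(bounds$.default)) bounds$.default <- c(1e-7, 1e4)

  # pack free-parameter names and starting values
  nm_rate <- unlist(lapply(names(free), function(g) {
    if (!length(free[[g]])) return(character(0))
    if (single) free[[g]] else paste0(g, ".", free[[g]])
  }), use.names = FALSE)
  nm_s0 <- if (fit_S0) sprintf("S0[%d]", seq_along(curves)) else character()
  theta_names <- c(nm_rate, nm_s0)
  bnd <- t(vapply(theta_names, function(nm) {
    b <- bounds[[nm]]
    if (is.null(b)) b <- bounds$.default
    as.numeric(b)
  }, numeric(2)))
  pinned <- bnd[, 1] == bnd[, 2]

  problem <- structure(list(curves = curves, params0 = params, free = free,
                            groups = groups, builder = builder,
                            per_group_builder = per_group_builder,
                            single = single, theta_names = theta_names,
                            parameterization = parameterization,
                            dead_alternate = dead_alternate,
                            bounds = bnd, pinned = pinned, sigma = sigma,
                            fit_S0 = fit_S0,
                            include_products = include_products,
                            rel_tol = rel_tol, abs_tol = abs_tol,
                            method = method),
                       class = "fit_problem")
  problem$n_obs <- length(unlist(problem_observed(problem)))
  if (problem$n_obs - sum(!pinned) <= 0)
    stop("no degrees of freedom: ", problem$n_obs, " observations, ",
         sum(!pinned), " free parameters", call. = FALSE)
  problem
}

#' @export
print.fit_problem <- function(x, ...) {
  cat(sprintf("<fit_problem> %d curve(s), %d observations, %d free parameter(s), sigma = %g uM\n",
              length(x$curves), x$n_obs, sum(!x$pinned), x$sigma))
  cat("  free:", paste(x$theta_names[!x$pinned], collapse = ", "), "\n")
  invisible(x)
}

# which columns of curve i enter the chi-square
fit_columns <- function(problem, i) {
  cv <- problem$curves[[i]]
  sub <- attr(cv, "substrate")
  cols <- intersect(sub, names(cv))
  if (isTRUE(problem$include_products))
    cols <- setdiff(names(cv), "time_s")
  if (!length(cols))
    stop("curve ", i, ": substrate column '", sub, "' not present", call. = FALSE)
  cols
}

problem_observed <- function(problem) {
  lapply(seq_along(problem$curves), function(i) {
    cv <- problem$curves[[i]]
    unlist(cv[fit_columns(problem, i)], use.names = FALSE)
  })
}

# default starting vector: template rates + each curve's recorded S0
default_init <- function(problem) {
  vals <- vapply(problem$theta_names, function(nm) {
    if (grepl("^S0\\[", nm)) {
      i <- as.integer(sub("^S0\\[(\\d+)\\]$", "\\1", nm))
      s0 <- attr(problem$curves[[i]], "S0")
      if (!is.null(names(s0))) s0 <- s0[[attr(problem$curves[[i]], "substrate")]]
      as.numeric(s0)
    } else if (identical(problem$parameterization, "apparent")) {
      p0 <- problem$params0[[1]]
      app <- apparent_post_params(p0)
      eqE <- rates_to_eq(p0$kE_fwd, p0$kE_rev)
      eqES <- rates_to_eq(p0$kES_fwd, p0$kES_rev)
      switch(nm, KM_app = app$KM_app, kcat_app = app$kcat_app,
             Keq_E = eqE$Keq, kex_E = eqE$kex,
             Keq_ES = eqES$Keq, kex_ES = eqES$kex)
    } else {
      g <- "main"; rn <- nm
      if (grepl(".", nm, fixed = TRUE) && !problem$single) {
        g <- sub("\\..*$", "", nm)
        rn <- sub("^[^.]*\\.", "", nm)
      }
      problem$params0[[g]][[rn]]
    }
  }, numeric(1))
  # pinned parameters sit at their bound value
  vals[problem$pinned] <- problem$bounds[problem$pinned, 1]
  vals
}

apparent_theta_names <- c("KM_app", "kcat_app", "Keq_E", "kex_E",
                          "Keq_ES", "kex_ES")

# substitute a natural-scale named value vector into the parameter groups
apply_theta <- function(problem, values) {
  if (identical(problem$parameterization, "apparent")) {
    p <- invert_apparent(values[["KM_app"]], values[["kcat_app"]],
                         values[["Keq_E"]], values[["kex_E"]],
                         values[["Keq_ES"]], values[["kex_ES"]],
                         dead_alternate = problem$dead_alternate,
                         k1 = problem$params0[[1]]$k1)
    return(list(main = p))
  }
  params <- problem$params0
  for (g in names(problem$free)) {
    nms <- problem$free[[g]]
    if (!length(nms)) next
    keys <- if (problem$single) nms else paste0(g, ".", nms)
    params[[g]] <- update_rates(params[[g]],
                                stats::setNames(as.list(values[keys]), nms))
  }
  params
}

# residual blocks (one numeric vector per curve) at natural-scale values
problem_residuals <- function(problem, values, which_curves = NULL) {
  params <- apply_theta(problem, values)
  cache <- new.env(parent = emptyenv())
  if (is.null(which_curves)) which_curves <- seq_along(problem$curves)
  out <- vector("list", length(problem$curves))
  for (i in which_curves) {
    cv <- problem$curves[[i]]
    g <- problem$groups[i]
    scheme <- if (is.null(cache[[g]])) {
      cache[[g]] <- problem$builder(params, g)
    } else cache[[g]]
    s0 <- attr(cv, "S0")
    if (problem$fit_S0) {
      v <- values[[sprintf("S0[%d]", i)]]
      if (!is.null(names(s0))) s0[[attr(cv, "substrate")]] <- v else s0 <- v
    }
    y0 <- initial_state(scheme, s0, attr(cv, "E0"))
    traj <- integrate_scheme(scheme, y0, cv$time_s + attr(cv, "deadtime"),
                             rel_tol = problem$rel_tol,
                             abs_tol = problem$abs_tol,
                             method = problem$method)
    cols <- fit_columns(problem, i)
    pred <- unlist(traj[cols], use.names = FALSE)
    obs <- unlist(cv[cols], use.names = FALSE)
    out[[i]] <- (pred - obs) / problem$sigma
  }
  out
}

#' Chi-square of a parameter vector
#'
#' @param problem a [fit_problem()].
#' @param values named numeric vector on the natural scale covering the
#'   problem's free parameters (rates and `S0[i]`); defaults to the
#'   template rates and the curves' recorded initial concentrations.
#' @return The chi-square value (residuals scaled by sigma).
#' @export
chi_square <- function(problem, values = NULL) {
  stopifnot(inherits(problem, "fit_problem"))
  values <- complete_values(problem, values)
  sum(unlist(problem_residuals(problem, values))^2)
}

complete_values <- function(problem, values) {
  full <- default_init(problem)
  if (!is.null(values)) {
    bad <- setdiff(names(values), names(full))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    full[names(values)] <- values
    full[problem$pinned] <- problem$bounds[problem$pinned, 1]
  }
  full
}

#' Exhaustive grid search for starting parameters
#'
#' Evaluates the chi-square on the full Cartesian grid spanned by the
#' supplied per-parameter candidate values (parameters not listed stay at
#' their template values) and returns the best grid point.
#'
#' @param problem a [fit_problem()].
#' @param grid named list of candidate value vectors (natural scale).
#' @return Named numeric vector of the best grid point (all free
#'   parameters), with attributes `chi2` and `n_evaluated`.
#' @export
grid_search_init <- function(problem, grid) {
  stopifnot(inherits(problem, "fit_problem"))
  if (length(grid) == 0 || any(!lengths(grid)))
    stop("empty grid", call. = FALSE)
  bad <- setdiff(names(grid), problem$theta_names)
  if (length(bad))
    stop("grid names unknown parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  best_chi2 <- Inf
  for (r in seq_len(nrow(pts))) {
    v <- complete_values(problem, unlist(pts[r, , drop = FALSE]))
    c2 <- tryCatch(sum(unlist(problem_residuals(problem, v))^2),
                   error = function(e) Inf)
    if (c2 < best_chi2) { best_chi2 <- c2; best <- v }
  }
  if (!is.finite(best_chi2))
    stop("all grid points failed to evaluate", call. = FALSE)
  structure(best, chi2 = best_chi2, n_evaluated = nrow(pts))
}

# ---- Levenberg-Marquardt core (log-space, residual-block sparsity) ----

# resid_fn(values) -> list of residual blocks; affects(j) -> block indices
lm_core <- function(resid_fn, values0, free_mask, lower, upper, affects,
                    max_iter = 500, fd_step = 1e-4, reltol = 1e-8,
                    steptol = 1e-10) {
  nm <- names(values0)
  theta <- log(pmin(pmax(values0, lower), upper))
  lo <- log(lower); hi <- log(upper)
  idx_free <- which(free_mask)
  nat <- function(th) stats::setNames(exp(th), nm)

  blocks <- resid_fn(nat(theta))
  chi2 <- sum(unlist(blocks)^2)
  n_iter <- 0L
  converged <- FALSE
  singular <- FALSE
  lambda <- 1e-3
  n_small <- 0L # consecutive near-stationary accepted steps
  J <- NULL

  repeat {
    if (n_iter >= max_iter) break
    n_iter <- n_iter + 1L
    # numerical Jacobian, only a priori non-zero blocks recomputed
    r0 <- unlist(blocks)
    block_len <- lengths(blocks)
    block_off <- c(0L, cumsum(block_len))
    J <- matrix(0, length(r0), length(idx_free))
    for (jj in seq_along(idx_free)) {
      j <- idx_free[jj]
      h <- fd_step
      thp <- theta
      thp[j] <- min(thp[j] + h, hi[j])
      if (thp[j] == theta[j]) { thp[j] <- theta[j] - h }
      hh <- thp[j] - theta[j]
      aff <- affects(j)
      bl <- resid_fn_safe(resid_fn, nat(thp), aff, blocks)
      if (is.null(bl)) { # e.g. infeasible forward step: try backward
        thp <- theta
        thp[j] <- max(theta[j] - h, lo[j])
        hh <- thp[j] - theta[j]
        if (hh != 0) bl <- resid_fn_safe(resid_fn, nat(thp), aff, blocks)
      }
      if (is.null(bl)) next # leave a zero column rather than abort
      for (b in aff) {
        rows <- (block_off[b] + 1L):block_off[b + 1L]
        J[rows, jj] <- (bl[[b]] - blocks[[b]]) / hh
      }
    }
    A <- crossprod(J)
    g <- crossprod(J, r0)
    dA <- diag(A)
    dA[dA <= 0] <- max(dA, 1) * 1e-12

    improved <- FALSE
    for (try in 1:40) {
      M <- A
      diag(M) <- diag(A) + lambda * dA
      delta <- tryCatch(solve(M, -g), error = function(e) NULL)
      if (is.null(delta)) { singular <- TRUE; lambda <- lambda * 10; next }
      th_new <- theta
      th_new[idx_free] <- pmin(pmax(theta[idx_free] + delta, lo[idx_free]),
                               hi[idx_free])
      bl_new <- tryCatch(resid_fn(nat(th_new)), error = function(e) NULL)
      if (!is.null(bl_new)) {
        chi2_new <- sum(unlist(bl_new)^2)
        if (is.finite(chi2_new) && chi2_new <= chi2) {
          step_norm <- max(abs(th_new - theta))
          rel_dec <- (chi2 - chi2_new) / max(chi2_new, .Machine$double.eps)
          theta <- th_new
          blocks <- bl_new
          improved <- TRUE
          lambda <- max(lambda / 3, 1e-12)
          # a single tiny decrease can be a damping artifact on a sloppy
          # valley; demand three in a row (or a vanishing step) before
          # declaring the minimum reached
          n_small <- if (rel_dec < reltol) n_small + 1L else 0L
          if (n_small >= 3L || step_norm < steptol) converged <- TRUE
          chi2 <- chi2_new
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e13) break
    }
    if (!improved) { converged <- TRUE; break } # cannot improve: at a minimum
    if (converged) break
  }

  list(theta = theta, values = nat(theta), chi2 = chi2, J = J,
       free_mask = free_mask, n_iter = n_iter, converged = converged,
       singular = singular)
}

# perturbed residuals: only affected blocks recomputed, others reused;
# NULL signals an evaluation failure (e.g. infeasible parameter point)
resid_fn_safe <- function(resid_fn, values, aff, base) {
  out <- tryCatch(resid_fn(values, which_curves = aff), error = function(e) e)
  if (inherits(out, "error")) {
    # retry without block selection (plain residual functions), then give up
    out <- tryCatch(resid_fn(values), error = function(e) NULL)
    if (is.null(out)) return(NULL)
  }
  for (b in seq_along(base)) if (is.null(out[[b]])) out[[b]] <- base[[b]]
  out
}

#' Levenberg-Marquardt global fit
#'
#' Minimizes the problem chi-square over the free parameters in log space
#' with a damped Gauss-Newton (Levenberg-Marquardt) iteration.  The
#' Jacobian is obtained by forward finite differences, and only the
#' residual blocks known a priori to depend on a parameter are recomputed
#' (a per-curve initial concentration only touches its own curve).
#' Convergence is declared when the relative chi-square decrease falls
#' below `reltol` (1e-8) or the step norm below `steptol` (1e-10); hitting
#' the iteration cap flags the result as non-converged rather than
#' raising.
#'
#' @param problem a [fit_problem()].
#' @param init optional named starting values (natural scale), e.g. from
#'   [grid_search_init()]; defaults to the template values.
#' @param max_iter iteration cap.
#' @param fd_step finite-difference step in log space.
#' @return A `fit_result`: best-fit `values`, `chi2`, `n_obs`, `n_free`,
#'   `dof`, `converged`, `n_iter`, the scaled Jacobian at the optimum, and
#'   the problem.
#' @export
fit_lm <- function(problem, init = NULL, max_iter = 500, fd_step = 1e-4) {
  stopifnot(inherits(problem, "fit_problem"))
  values0 <- complete_values(problem, init)
  free_mask <- !problem$pinned
  n_curves <- length(problem$curves)
  affects <- function(j) {
    nm <- problem$theta_names[j]
    if (grepl("^S0\\[", nm))
      as.integer(sub("^S0\\[(\\d+)\\]$", "\\1", nm))
    else if (problem$per_group_builder && !problem$single) {
      g <- sub("\\..*$", "", nm)
      which(problem$groups == g)
    } else seq_len(n_curves)
  }
  resid_fn <- function(values, which_curves = NULL)
    problem_residuals(problem, values, which_curves)
  core <- lm_core(resid_fn, values0, free_mask,
                  lower = problem$bounds[, 1], upper = problem$bounds[, 2],
                  affects = affects, max_iter = max_iter, fd_step = fd_step)
  n_free <- sum(free_mask)
  structure(list(values = core$values, chi2 = core$chi2,
                 n_obs = problem$n_obs, n_free = n_free,
                 dof = problem$n_obs - n_free, converged = core$converged,
                 n_iter = core$n_iter, singular = core$singular,
                 J = core$J, theta_names = problem$theta_names,
                 free_mask = free_mask, log_scale = TRUE,
                 problem = problem),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> chi2 = %.6g, dof = %d (%d obs, %d free), %s after %d iteration(s)\n",
              x$chi2, x$dof, x$n_obs, x$n_free,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(signif(x$values, 6))
  invisible(x)
}

#' Standard errors from the covariance matrix
#'
#' Inverts the scaled curvature `J'J` at the optimum (residuals already
#' carry the 1/sigma scaling) and back-transforms the log-space variances
#' to the natural scale (`se_nat = value * se_log`).  A singular
#' curvature raises an error naming the flat (unidentifiable) parameter
#' combination.
#'
#' @param result a `fit_result` from [fit_lm()].
#' @return Named numeric vector of standard errors for the free parameters.
#' @export
covariance_stderr <- function(result) {
  J <- result$J
  A <- crossprod(J)
  nm <- result$theta_names[result$free_mask]
  ev <- eigen(A, symmetric = TRUE)
  if (min(ev$values) <= max(ev$values) * 1e-12) {
    v <- ev$vectors[, which.min(ev$values)]
    big <- nm[order(abs(v), decreasing = TRUE)][seq_len(min(3, length(nm)))]
    stop("singular curvature: unidentifiable parameter direction involving ",
         paste(big, collapse = ", "), call. = FALSE)
  }
  cov <- chol2inv(chol(A))
  se_log <- sqrt(diag(cov))
  se <- se_log
  if (isTRUE(result$log_scale)) se <- se_log * result$values[result$free_mask]
  stats::setNames(se, nm)
}

#' Bootstrap standard errors (residual resampling)
#'
#' Resamples the base-fit residuals within each curve (preserving the
#' acquisition time design), adds them to the base-fit model curves, and
#' refits.  Standard errors are the standard deviations of the replicate
#' estimates.  Deterministic given `seed`; a replicate failure rate above
#' 20 percent draws a warning.
#'
#' @param problem the [fit_problem()] that produced `result`.
#' @param result a converged `fit_result`.
#' @param n_runs number of bootstrap replicates (500 by default).
#' @param seed RNG seed.
#' @param max_iter iteration cap per replicate refit (warm-started).
#' @return `result` with an added `bootstrap` element: list with `se`
#'   (named vector), `replicates` (matrix n_runs x n_params) and `n_fail`.
#' @export
bootstrap_stderr <- function(problem, result, n_runs = 500, seed = 1L,
                             max_iter = 100) {
  stopifnot(inherits(problem, "fit_problem"), inherits(result, "fit_result"))
  base_blocks <- problem_residuals(problem, result$values)
  obs <- problem_observed(problem)
  # residual blocks are (pred - obs)/sigma, so pred = obs + sigma * block
  resids <- lapply(base_blocks, function(b) -b * problem$sigma)
  preds <- lapply(seq_along(obs), function(i) obs[[i]] - resids[[i]])

  reps <- with_seed(seed, {
    out <- matrix(NA_real_, n_runs, length(result$values),
                  dimnames = list(NULL, names(result$values)))
    for (r in seq_len(n_runs)) {
      prob_r <- problem
      for (i in seq_along(prob_r$curves)) {
        cols <- fit_columns(problem, i)
        e_star <- sample(resids[[i]], length(resids[[i]]), replace = TRUE)
        newy <- preds[[i]] + e_star
        off <- 0L
        for (cl in cols) {
          n <- nrow(prob_r$curves[[i]])
          prob_r$curves[[i]][[cl]] <- newy[(off + 1):(off + n)]
          off <- off + n
        }
      }
      fr <- tryCatch(fit_lm(prob_r, init = result$values,
                            max_iter = max_iter),
                     error = function(e) NULL)
      if (!is.null(fr) && fr$converged) out[r, ] <- fr$values
    }
    out
  })
  n_fail <- sum(!stats::complete.cases(reps))
  if (n_fail > 0.2 * n_runs)
    warning(n_fail, " of ", n_runs, " bootstrap replicates failed to converge")
  se <- apply(reps[, result$free_mask, drop = FALSE], 2, stats::sd,
              na.rm = TRUE)
  result$bootstrap <- list(se = se, replicates = reps, n_fail = n_fail,
                           n_runs = n_runs, seed = seed)
  result
}
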