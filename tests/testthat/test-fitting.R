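noiseless_problem <- function(S0 = c(150, 60), n_points = 40,
                              free = c("k_off", "kcat_E", "kcat_Estar"),
                              p = quick_params(), ...) {
  des <- quick_design(S0 = S0, n_points = n_points, sigma = 0)
  curves <- make_experiment(des, p)
  fit_problem(curves, p, free = free, rel_tol = 1e-9, abs_tol = 1e-11, ...)
}

test_that("chi-square matches its definition", {
  pr <- noiseless_problem()
  # generating truth on noiseless data: zero to integrator accuracy
  expect_lt(chi_square(pr), 1e-6)

  # a curve offset by exactly 1 uM at every point with sigma = 1
  p <- quick_params()
  des <- quick_design(S0 = 150, n_points = 100, sigma = 0)
  curves <- make_experiment(des, p)
  curves[[1]]$S <- curves[[1]]$S + 1
  pr1 <- fit_problem(curves, p, rel_tol = 1e-9, abs_tol = 1e-11, sigma = 1)
  n <- nrow(curves[[1]])
  expect_equal(chi_square(pr1), n, tolerance = 1e-4)

  # chi2/n concentrates near 1 under matching noise
  des_n <- quick_design(S0 = c(150, 60), n_points = 250, sigma = 1, seed = 5)
  curves_n <- make_experiment(des_n, p)
  prn <- fit_problem(curves_n, p, sigma = 1)
  expect_equal(chi_square(prn) / prn$n_obs, 1, tolerance = 0.1)

  expect_error(chi_square(pr, c(bogus = 1)), "unknown parameter")
})

test_that("fit_lm recovers the generating parameters on noiseless data", {
  pr <- noiseless_problem(free = c("k_off", "kcat_E", "kcat_Estar",
                                   "kES_fwd", "kES_rev"))
  truth <- nmrkin:::default_init(pr)
  fit <- fit_lm(pr) # init at truth: must stay put
  expect_true(fit$converged)
  expect_equal(unname(fit$values), unname(truth), tolerance = 1e-3)

  # perturbed start x3 lands in the same minimum (identifiable free set:
  # the exchange rates are held, they span the sloppy directions)
  pr3 <- noiseless_problem(free = c("k_off", "kcat_E", "kcat_Estar"))
  truth3 <- nmrkin:::default_init(pr3)
  init <- truth3
  rates <- setdiff(names(init), grep("^S0", names(init), value = TRUE))
  init[rates] <- init[rates] * 3
  init[grep("^S0", names(init))] <- init[grep("^S0", names(init))] * 1.1
  fit2 <- fit_lm(pr3, init = init, max_iter = 300)
  fit2b <- fit_lm(pr3, init = fit2$values, max_iter = 100) # fresh damping
  if (fit2b$chi2 < fit2$chi2) fit2 <- fit2b
  expect_lt(fit2$chi2, 1e-2)
  expect_equal(unname(fit2$values[c("k_off", "kcat_E", "kcat_Estar")]),
               unname(truth3[c("k_off", "kcat_E", "kcat_Estar")]),
               tolerance = 0.01)
  expect_equal(unname(fit2$values[grep("^S0", names(init))]),
               unname(truth3[grep("^S0", names(init))]), tolerance = 1e-3)
})

test_that("a parameter pinned by equal bounds behaves like a fixed one", {
  p <- quick_params()
  des <- quick_design(S0 = 150, n_points = 30, sigma = 0)
  curves <- make_experiment(des, p)
  pinned <- fit_problem(curves, p, free = c("k_off", "kcat_E"),
                        bounds = list(.default = c(1e-7, 1e4),
                                      kcat_E = c(p$kcat_E, p$kcat_E)),
                        rel_tol = 1e-9, abs_tol = 1e-11)
  fixed <- fit_problem(curves, p, free = "k_off",
                       rel_tol = 1e-9, abs_tol = 1e-11)
  f1 <- fit_lm(pinned)
  f2 <- fit_lm(fixed)
  expect_equal(f1$values[["kcat_E"]], p$kcat_E)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-8)
  expect_equal(f1$n_free, f2$n_free)
})

test_that("grid search is exhaustive and deterministic", {
  pr <- noiseless_problem(S0 = 150, n_points = 20,
                          free = c("k_off", "kcat_E"))
  truth <- nmrkin:::default_init(pr)

  # a grid containing the truth returns the truth
  grid <- list(k_off = c(1, truth[["k_off"]], 20),
               kcat_E = c(0.3, truth[["kcat_E"]], 4))
  best <- grid_search_init(pr, grid)
  expect_equal(best[["k_off"]], truth[["k_off"]])
  expect_equal(best[["kcat_E"]], truth[["kcat_E"]])

  # one-point grid returns that point
  one <- grid_search_init(pr, list(kcat_E = 2.5))
  expect_equal(one[["kcat_E"]], 2.5)

  # brute-force check: returned chi2 <= every grid point's chi2
  pr2 <- noiseless_problem(S0 = 150, n_points = 20,
                           free = c("k_off", "kcat_E", "kES_fwd"))
  grid2 <- list(k_off = c(2, 6, 18), kcat_E = c(0.5, 1.1, 2.2),
                kES_fwd = c(0.001, 0.01))
  best2 <- grid_search_init(pr2, grid2)
  pts <- expand.grid(grid2, KEEP.OUT.ATTRS = FALSE)
  all_chi2 <- vapply(seq_len(nrow(pts)), function(r)
    chi_square(pr2, unlist(pts[r, ])), numeric(1))
  expect_equal(attr(best2, "chi2"), min(all_chi2), tolerance = 1e-12)
  expect_equal(attr(best2, "n_evaluated"), nrow(pts))

  expect_error(grid_search_init(pr, list()), "empty grid")
  expect_error(grid_search_init(pr, list(zzz = 1)), "unknown parameter")
})

# a tiny linear regression pushed through the same LM core, so the
# covariance machinery can be checked against the closed form
linear_fit <- function(a_true = 2, sigma = 0.5, n = 40, seed = 1,
                       fd_step = 1e-6) {
  set.seed(seed)
  t <- seq(0.1, 4, length.out = n)
  y <- a_true * t + rnorm(n, sd = sigma)
  resid_fn <- function(values, which_curves = NULL) list((values[["a"]] * t - y) / sigma)
  core <- nmrkin:::lm_core(resid_fn, c(a = 1), free_mask = TRUE,
                           lower = 1e-7, upper = 1e4,
                           affects = function(j) 1L, max_iter = 200,
                           fd_step = fd_step)
  structure(list(values = core$values, chi2 = core$chi2, J = core$J,
                 theta_names = "a", free_mask = TRUE, log_scale = TRUE,
                 n_obs = n, n_free = 1, dof = n - 1,
                 converged = core$converged),
            class = "fit_result")
}

test_that("covariance errors match ordinary least squares", {
  fit <- linear_fit()
  t <- seq(0.1, 4, length.out = 40)
  se_ols <- 0.5 / sqrt(sum(t^2))
  expect_equal(unname(covariance_stderr(fit)), se_ols, tolerance = 1e-6)

  # doubling sigma doubles the errors (kinetic problem)
  p <- quick_params()
  des <- quick_design(S0 = 150, n_points = 40, sigma = 1, seed = 2)
  curves <- make_experiment(des, p)
  f1 <- fit_lm(fit_problem(curves, p, free = c("k_off", "kcat_E"), sigma = 1))
  f2 <- fit_lm(fit_problem(curves, p, free = c("k_off", "kcat_E"), sigma = 2))
  expect_equal(unname(covariance_stderr(f2)),
               unname(2 * covariance_stderr(f1)), tolerance = 1e-3)
})

test_that("perfectly correlated parameters raise a singularity report", {
  set.seed(4)
  t <- seq(0.1, 4, length.out = 30)
  y <- 2 * t + rnorm(30, sd = 0.1)
  # a and b only enter as a product: an exactly flat direction
  resid_fn <- function(values, which_curves = NULL)
    list(values[["a"]] * values[["b"]] * t - y)
  core <- nmrkin:::lm_core(resid_fn, c(a = 1.5, b = 1.5),
                           free_mask = c(TRUE, TRUE),
                           lower = rep(1e-7, 2), upper = rep(1e4, 2),
                           affects = function(j) 1L, max_iter = 50)
  fake <- structure(list(values = core$values, J = core$J,
                         theta_names = c("a", "b"),
                         free_mask = c(TRUE, TRUE), log_scale = TRUE),
                    class = "fit_result")
  expect_error(covariance_stderr(fake), "unidentifiable.*a.*b")
})

test_that("bootstrap errors are reproducible and asymptotically sensible", {
  p <- quick_params()
  des <- quick_design(S0 = 150, n_points = 40, sigma = 1, seed = 3)
  curves <- make_experiment(des, p)
  pr <- fit_problem(curves, p, free = "kcat_E")
  fit <- fit_lm(pr)

  b1 <- bootstrap_stderr(pr, fit, n_runs = 100, seed = 11)
  b2 <- bootstrap_stderr(pr, fit, n_runs = 100, seed = 11)
  expect_identical(b1$bootstrap$replicates, b2$bootstrap$replicates)
  expect_equal(b1$bootstrap$n_fail, 0)

  # against the covariance error on a well-conditioned one-parameter fit
  se_cov <- covariance_stderr(fit)[["kcat_E"]]
  expect_lt(abs(b1$bootstrap$se[["kcat_E"]] - se_cov) / se_cov, 0.2)

  # noiseless data: bootstrap errors collapse
  des0 <- quick_design(S0 = 150, n_points = 25, sigma = 0)
  curves0 <- make_experiment(des0, p)
  pr0 <- fit_problem(curves0, p, free = "kcat_E",
                     rel_tol = 1e-9, abs_tol = 1e-11)
  fit0 <- fit_lm(pr0)
  b0 <- bootstrap_stderr(pr0, fit0, n_runs = 25, seed = 2)
  expect_lt(b0$bootstrap$se[["kcat_E"]], 1e-4 * p$kcat_E)
})

test_that("the fixed association rate barely moves the apparent parameters", {
  # the data cannot pin k1; fits with k1 fixed anywhere in [0.1, 1]
  # recover apparent parameters within 5%
  p <- quick_params(kcat_Estar = 0)
  des <- quick_design(S0 = c(150, 60), n_points = 120, sigma = 0)
  curves <- make_experiment(des, p)
  apps <- lapply(c(0.1, 1.0), function(k1) {
    tmpl <- rate_params(kcat_E = p$kcat_E, k_off = p$k_off,
                        kE_fwd = p$kE_fwd, kE_rev = p$kE_rev,
                        kES_fwd = p$kES_fwd, kES_rev = p$kES_rev,
                        kcat_Estar = 0, k1 = k1)
    pr <- fit_problem(curves, tmpl,
                      free = c("k_off", "kcat_E", "kES_fwd", "kES_rev"))
    fit <- fit_lm(pr, max_iter = 200)
    apparent_post_params(nmrkin:::apply_theta(pr, fit$values)[[1]])
  })
  ref <- apparent_post_params(p)
  for (app in apps) {
    expect_lt(abs(app$KM_app - ref$KM_app) / ref$KM_app, 0.05)
    expect_lt(abs(app$kcat_app - ref$kcat_app) / ref$kcat_app, 0.05)
  }
})

test_that("optimality: the fitted chi2 never exceeds the truth's", {
  p <- quick_params()
  des <- quick_design(S0 = c(150, 60), n_points = 40, sigma = 1, seed = 9)
  curves <- make_experiment(des, p)
  pr <- fit_problem(curves, p, free = c("k_off", "kcat_E", "kcat_Estar"))
  fit <- fit_lm(pr)
  expect_lte(fit$chi2, chi_square(pr))
})
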