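test_that("the in-package incomplete beta matches R's pbeta to 1e-10", {
  xs <- c(1e-6, 0.001, 0.01, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99, 0.999, 1 - 1e-6)
  for (a in c(0.5, 1, 2.5, 10, 50))
    for (b in c(0.5, 1, 3, 25, 100))
      expect_equal(inc_beta(xs, a, b), stats::pbeta(xs, a, b),
                   tolerance = 1e-10)
  expect_equal(inc_beta(0, 2, 3), 0)
  expect_equal(inc_beta(1, 2, 3), 1)
})

test_that("F tail probabilities match an independent evaluation to 1e-10", {
  for (F in c(0.1, 0.5, 1, 2, 5, 20, 100))
    for (d in list(c(1, 5), c(2, 10), c(3, 400), c(8, 1500)))
      expect_equal(nmrkin:::f_tail(F, d[1], d[2]),
                   stats::pf(F, d[1], d[2], lower.tail = FALSE),
                   tolerance = 1e-10)
})

test_that("f_test handles edge cases per contract", {
  cmp <- f_test(100, 52, 100, 50)
  expect_equal(cmp$F, 0)
  expect_equal(cmp$p, 1)

  expect_error(f_test(100, 50, 90, 50), "not nested")
  expect_error(f_test(100, 50, 90, 60), "not nested")

  expect_warning(cmp2 <- f_test(80, 52, 100, 50), "p set to 1")
  expect_equal(cmp2$p, 1)

  cmp3 <- f_test(150, 52, 100, 50)
  expect_equal(cmp3$F, ((150 - 100) / 2) / (100 / 50))
  expect_equal(cmp3$p, stats::pf(cmp3$F, 2, 50, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("condition summaries reproduce the printed table from the truth", {
  fx <- paperlike_fixture("APO", "demethylation")
  des <- modify_design(fx$design, sigma = 0, duration = 60 * 61)
  curves <- make_experiment(des, fx$params)
  pr <- fit_problem(curves, fx$params, free = c("k_off", "kcat_E"),
                    rel_tol = 1e-9, abs_tol = 1e-11)
  fit <- fit_lm(pr)
  s <- summarize_condition(fit, "APO demethylation")
  val <- function(q) s$value[s$quantity == q]
  expect_equal(val("kcat_post"), 0.032, tolerance = 1e-4)
  expect_equal(val("KM_post"), 2.3, tolerance = 1e-3)
  expect_equal(val("efficiency"), 0.032 / 2.3 * 1000, tolerance = 1e-3)
  expect_equal(val("Keq_E"), 7.0, tolerance = 1e-6)
  expect_equal(val("kex_E"), 0.0074, tolerance = 1e-6)
  expect_equal(val("Keq_ES"), 76, tolerance = 1e-6)
  expect_equal(val("kex_ES"), 0.0055, tolerance = 1e-6)
  # efficiency row is always consistent with its own table row
  expect_equal(val("efficiency"),
               val("kcat_post") / val("KM_post") * 1000, tolerance = 1e-9)
})

test_that("bootstrap and delta-method errors agree within a factor of two", {
  p <- quick_params()
  des <- quick_design(S0 = c(150, 60), n_points = 40, sigma = 1, seed = 6)
  curves <- make_experiment(des, p)
  pr <- fit_problem(curves, p, free = c("kcat_E", "kES_rev"))
  fit <- fit_lm(pr)
  s_delta <- summarize_condition(fit, "x")
  fit_b <- bootstrap_stderr(pr, fit, n_runs = 120, seed = 8)
  s_boot <- summarize_condition(fit_b, "x")
  for (q in c("kcat_post", "KM_post")) {
    e1 <- s_delta$error[s_delta$quantity == q]
    e2 <- s_boot$error[s_boot$quantity == q]
    expect_lt(max(e1, e2) / min(e1, e2), 2)
  }
})

test_that("limiting overlays bracket the full model", {
  fx <- paperlike_fixture("APO", "demethylation")
  p <- fx$params
  t_grid <- seq(0, 20000, 61)
  ov <- limiting_overlays(p, 300, 0.2, t_grid)
  expect_equal(ov$initial$S[1], 300)
  expect_equal(ov$post$S[1], 300)

  # the dotted line's slope relates to the one-enzyme MM slope by the
  # extra (1 + KM_Estar/S) factor of the short-time expression
  psym <- quick_params(kcat_Estar = quick_params()$kcat_E)
  km <- michaelis_constants(psym)
  app <- apparent_post_params(psym)
  S0 <- 80
  v0 <- initial_rate_short_time(psym, S0, 0.2)
  v_mm <- app$kcat_app * 0.2 * S0 / (app$KM_app + S0)
  expect_equal(v_mm / v0, 1 + km[["KM_Estar"]] / S0, tolerance = 1e-10)

  # once exchange has relaxed, the full model's instantaneous rate obeys
  # the apparent Michaelis-Menten law at its own substrate concentration.
  # The law's premise is that exchange stays equilibrated during turnover,
  # so it is checked with the exchange rates scaled up (Keq unchanged);
  # at the fitted (very slow) exchange rates the true steady rate runs a
  # few percent below it, which the vignette discusses.
  pfast <- scale_exchange(p, 1e6)
  sch <- build_single_substrate_scheme(pfast)
  y0 <- initial_state_test(sch, 300, 0.2)
  # past both the exchange relaxation and the initial binding burst
  t_eq <- max(10 / (pfast$kES_fwd + pfast$kES_rev), 200)
  tr <- integrate_scheme(sch, y0, c(0, t_eq, t_eq + 61),
                         rel_tol = 1e-10, abs_tol = 1e-12,
                         method = "rosenbrock")
  slope_full <- (tr$S[3] - tr$S[2]) / 61
  appP <- apparent_post_params(p)
  S_mid <- mean(tr$S[2:3])
  slope_mm <- -appP$kcat_app * 0.2 * S_mid / (appP$KM_app + S_mid)
  expect_equal(slope_full / slope_mm, 1, tolerance = 0.02)
})

test_that("the pipeline runs end to end, deterministically, with stage context", {
  out1 <- tempfile("pipe1")
  out2 <- tempfile("pipe2")
  config <- list(synthetic = list(condition = "APO",
                                  reaction = "demethylation", sigma = 1),
                 free = c("k_off", "kcat_E"), seed = 3,
                 label = "APO demethylation", out_dir = out1)
  res <- run_pipeline(config)
  expect_true(file.exists(res$paths[["summary"]]))
  expect_true(file.exists(res$paths[["fit"]]))
  expect_true(res$fit$converged)

  config$out_dir <- out2
  res2 <- run_pipeline(config)
  expect_identical(readLines(res$paths[["summary"]]),
                   readLines(res2$paths[["summary"]]))
  j1 <- readLines(res$paths[["fit"]]); j2 <- readLines(res2$paths[["fit"]])
  expect_identical(j1, j2)

  expect_error(run_pipeline(list(synthetic = list(condition = "XXX",
                                                  reaction = "demethylation"))),
               "stage 'input'")
  expect_error(run_pipeline(list(label = "no input")), "synthetic")
})
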