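test_that("cycle closure derives the E*S dissociation rate", {
  # symmetric exchange: Keq(E) = Keq(ES) = 1, closure returns k_off itself
  p <- rate_params(kcat_E = 0.1, k_off = 1, kE_fwd = 2, kE_rev = 2,
                   kES_fwd = 3, kES_rev = 3)
  expect_equal(cycle_closure(p), 1.0)

  # Keq(E) = 7, Keq(ES) = 76 (apo demethylation magnitudes), k_off = 10
  p <- rate_params(kcat_E = 0.1, k_off = 10, kE_fwd = 7, kE_rev = 1,
                   kES_fwd = 76, kES_rev = 1)
  expect_equal(cycle_closure(p), 7 / 76 * 10, tolerance = 1e-12)

  # no dissociation at all
  p <- rate_params(kcat_E = 0.1, k_off = 0, kE_fwd = 1, kE_rev = 2,
                   kES_fwd = 3, kES_rev = 4)
  expect_equal(cycle_closure(p), 0)

  # degenerate cycles name the offending rate
  p <- rate_params(kcat_E = 0.1, k_off = 1, kE_fwd = 1, kE_rev = 0,
                   kES_fwd = 3, kES_rev = 4)
  expect_error(cycle_closure(p), "kE_rev")
  p <- rate_params(kcat_E = 0.1, k_off = 1, kE_fwd = 1, kE_rev = 1,
                   kES_fwd = 0, kES_rev = 4)
  expect_error(cycle_closure(p), "kES_fwd")
})

test_that("detailed balance holds around the cycle at equilibrium", {
  # analytic equilibrium of the 4-state subsystem at fixed S: every edge
  # has equal forward and backward probability flux
  for (p in random_params(20, seed = 11)) {
    S <- 50
    k_off_star <- cycle_closure(p)
    # equilibrium populations from successive equilibrium constants
    E <- 1
    ES <- p$k1 * S / p$k_off * E
    EstarS <- p$kES_fwd / p$kES_rev * ES
    Estar <- k_off_star / (p$k1 * S) * EstarS
    fluxes <- c(abs(E * p$kE_fwd - Estar * p$kE_rev),
                abs(ES * p$kES_fwd - EstarS * p$kES_rev),
                abs(E * p$k1 * S - ES * p$k_off),
                abs(Estar * p$k1 * S - EstarS * k_off_star))
    expect_lt(max(fluxes) / (E * p$kE_fwd + 1e-300), 1e-10)
    # and the same state is a null vector of the exchange+binding rate matrix
    A <- matrix(0, 4, 4) # order: E, ES, EstarS, Estar
    add <- function(i, j, k) { A[j, i] <<- A[j, i] + k; A[i, i] <<- A[i, i] - k }
    add(1, 2, p$k1 * S); add(2, 1, p$k_off)
    add(2, 3, p$kES_fwd); add(3, 2, p$kES_rev)
    add(4, 3, p$k1 * S); add(3, 4, k_off_star)
    add(1, 4, p$kE_fwd); add(4, 1, p$kE_rev)
    v <- c(E, ES, EstarS, Estar)
    expect_lt(max(abs(A %*% v)) / max(v), 1e-10)
  }
})

test_that("eq_params round-trips with forward/reverse rates", {
  expect_equal(unname(eq_to_rates(eq_params(1, 2))), c(1, 1))
  # Table-style pair: Keq 7.0, kex 0.0074
  fr <- eq_to_rates(eq_params(7.0, 0.0074))
  expect_equal(unname(fr), c(0.006475, 0.000925), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:25) {
    f <- 10^runif(1, -6, 2); r <- 10^runif(1, -6, 2)
    eq <- rates_to_eq(f, r)
    back <- eq_to_rates(eq)
    expect_equal(unname(back), c(f, r), tolerance = 1e-12)
  }
  expect_error(eq_params(0, 1), "Keq")
  expect_error(eq_params(-1, 1), "Keq")
})

test_that("state-specific Michaelis constants follow the closed forms", {
  p <- rate_params(kcat_E = 0, k_off = 0, kE_fwd = 1, kE_rev = 1,
                   kES_fwd = 1, kES_rev = 1, kcat_Estar = 0)
  expect_equal(unname(michaelis_constants(p)[["KM_E"]]), 0)

  p <- rate_params(kcat_E = 0.1, k_off = 10, kE_fwd = 1, kE_rev = 1,
                   kES_fwd = 1, kES_rev = 1, k1 = 0.2)
  expect_equal(michaelis_constants(p)[["KM_E"]], 50.5)

  # symmetry: Keq(E) = Keq(ES) and equal catalytic rates => identical KMs
  p <- rate_params(kcat_E = 0.3, k_off = 8, kE_fwd = 0.02, kE_rev = 0.01,
                   kES_fwd = 0.06, kES_rev = 0.03, kcat_Estar = 0.3)
  km <- michaelis_constants(p)
  expect_equal(km[["KM_Estar"]], km[["KM_E"]])
})

test_that("post-equilibrium apparent parameters reduce and degenerate correctly", {
  # degenerate two-state: same Keq both levels, same kcat => plain MM
  p <- rate_params(kcat_E = 0.3, k_off = 8, kE_fwd = 0.02, kE_rev = 0.01,
                   kES_fwd = 0.06, kES_rev = 0.03, kcat_Estar = 0.3)
  app <- apparent_post_params(p)
  expect_equal(app$KM_app, michaelis_constants(p)[["KM_E"]])
  expect_equal(app$kcat_app, p$kcat_E)

  # all flux trapped in a dead alternate complex
  p <- rate_params(kcat_E = 0.3, k_off = 8, kE_fwd = 0.01, kE_rev = 0.01,
                   kES_fwd = 1e9, kES_rev = 1e-3, kcat_Estar = 0)
  expect_lt(apparent_post_params(p)$kcat_app, 1e-9)

  # division-safe form: kcat_E = 0 with active alternate complex
  p <- rate_params(kcat_E = 0, k_off = 8, kE_fwd = 0.01, kE_rev = 0.01,
                   kES_fwd = 0.02, kES_rev = 0.01, kcat_Estar = 0.5)
  expect_equal(apparent_post_params(p)$kcat_app, (0 + 2 * 0.5) / 3)

  # printed apo demethylation row: KM 2.3 uM, kcat 0.032 1/s -> ~13.9 1/s/mM
  app <- apparent_params(KM_app = 2.3, kcat_app = 0.032)
  expect_equal(app$efficiency, 13.913, tolerance = 1e-4)
})

test_that("short-time initial rate follows the printed expression", {
  # Keq(E) = 0 factorizes: 1 + a + b + ab = (1+a)(1+b)
  p <- rate_params(kcat_E = 0.5, k_off = 5, kE_fwd = 0, kE_rev = 1,
                   kES_fwd = 0.02, kES_rev = 0.01, kcat_Estar = 0.1)
  km <- michaelis_constants(p)
  S <- c(15, 60, 300)
  expect_equal(initial_rate_short_time(p, S, 0.2),
               0.2 * p$kcat_E / ((1 + km[["KM_E"]] / S) *
                                 (1 + km[["KM_Estar"]] / S)),
               tolerance = 1e-12)

  # large-S limit is the population-weighted catalytic rate
  p <- rate_params(kcat_E = 0.4, k_off = 5, kE_fwd = 0.01, kE_rev = 0.01,
                   kES_fwd = 0.02, kES_rev = 0.01, kcat_Estar = 0.2)
  expect_equal(initial_rate_short_time(p, 1e12, 0.2), 0.06, tolerance = 1e-6)

  # no enzyme, no rate; monotone increasing in S
  expect_equal(initial_rate_short_time(p, 100, 0), 0)
  v <- initial_rate_short_time(p, c(1, 5, 20, 100, 400), 0.2)
  expect_true(all(diff(v) > 0))
  expect_error(initial_rate_short_time(p, -1, 0.2), "S")
})

test_that("quasi-steady-state oracle cross-checks the short-time rate", {
  # freeze all four exchange rates, split the enzyme p_E : 1 - p_E, and
  # measure the simulated QSS turnover rate.  With a dead alternate
  # complex the printed short-time expression differs from the frozen
  # two-pool steady state by exactly the (1 + KM_Estar/S) factor of its
  # product-form denominator; the two agree once S dwarfs KM_Estar.
  p0 <- quick_params(kcat_E = 1, k_off = 5, kcat_Estar = 0,
                     kE_fwd = 0.004, kE_rev = 0.002,
                     kES_fwd = 0.006, kES_rev = 0.001)
  keq_E <- p0$kE_fwd / p0$kE_rev
  p_E <- 1 / (1 + keq_E)
  k_off_star <- cycle_closure(p0)
  pf <- rate_params(kcat_E = p0$kcat_E, k_off = p0$k_off, kE_fwd = 0,
                    kE_rev = 0, kES_fwd = 0, kES_rev = 0,
                    kcat_Estar = p0$kcat_Estar, k1 = p0$k1)
  # frozen scheme loses the thermodynamic closure; build it by hand with
  # the closed k_off_star
  scheme <- kinetic_scheme(
    species = c("E", "Estar", "ES", "EstarS", "S", "P"),
    reactions = list(
      list(reactants = c("E", "S"), products = "ES", rate = pf$k1),
      list(reactants = "ES", products = c("E", "S"), rate = pf$k_off),
      list(reactants = c("Estar", "S"), products = "EstarS", rate = pf$k1),
      list(reactants = "EstarS", products = c("Estar", "S"),
           rate = k_off_star),
      list(reactants = "ES", products = c("E", "P"), rate = pf$kcat_E),
      list(reactants = "EstarS", products = c("Estar", "P"),
           rate = pf$kcat_Estar)),
    conserved = list(enzyme = c("E", "Estar", "ES", "EstarS"),
                     substrate = c("S", "ES", "EstarS", "P")))
  E0 <- 0.05
  km_star <- michaelis_constants(p0)[["KM_Estar"]]
  for (S in c(10, 40, 200, 2000)) {
    y0 <- c(E = E0 * p_E, Estar = E0 * (1 - p_E), ES = 0, EstarS = 0,
            S = S, P = 0)
    tr <- integrate_scheme(scheme, y0, c(0, 2), rel_tol = 1e-10,
                           abs_tol = 1e-12, method = "rosenbrock")
    last <- tr[nrow(tr), ]
    v_sim <- pf$kcat_E * last$ES + pf$kcat_Estar * last$EstarS
    v_formula <- initial_rate_short_time(p0, S, E0)
    expect_lt(abs(v_sim - v_formula * (1 + km_star / S)) / v_sim, 0.01)
    if (S >= 100 * km_star) # the expressions coincide at large S
      expect_lt(abs(v_sim - v_formula) / v_sim, 0.01)
  }
})

test_that("rate parameters serialize with conventional symbol names", {
  p <- quick_params()
  path <- tempfile(fileext = ".json")
  write_rate_params(p, path)
  keys <- names(jsonlite::read_json(path))
  expect_setequal(keys, c("k1", "k_m1", "kcat_E", "kcat_Estar", "kE",
                          "k_mE", "kES", "k_mES"))
  p2 <- read_rate_params(path)
  expect_equal(unclass(p2), unclass(p))
  expect_error(read_rate_params({
    bad <- tempfile(); jsonlite::write_json(list(k1 = 1), bad); bad
  }), "missing keys")
})

test_that("rate parameters validate their inputs", {
  expect_error(rate_params(kcat_E = -1, k_off = 1, kE_fwd = 1, kE_rev = 1,
                           kES_fwd = 1, kES_rev = 1), "kcat_E")
  expect_error(rate_params(kcat_E = 1, k_off = NA_real_, kE_fwd = 1,
                           kE_rev = 1, kES_fwd = 1, kES_rev = 1), "k_off")
})
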